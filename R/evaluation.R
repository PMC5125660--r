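## Scoring aligner and variant-caller output against the golden truth.

#' Compare aligned reads against the truth in their names
#'
#' Reads of the test SAM carry golden names (see
#' \code{\link{encodeReadNames}}); each primary record is checked against
#' the truth for its mate: position-correct iff same contig and the mapped
#' position is within `posTolerance` of the true position; CIGAR-correct
#' iff additionally the normalized CIGAR strings match (adjacent same-op
#' runs merged, hard and soft clips equated). Unmapped reads and reads
#' whose name cannot be decoded are counted separately; undecodable reads
#' are excluded from the denominators.
#'
#' @param testSam SAM text file produced by the aligner under test.
#' @param posTolerance allowed absolute position difference (default 0).
#' @return an \linkS4class{AlignmentReport}.
#' @export
compareAlignments <- function(testSam, posTolerance = 0L) {
  sam <- readSam(testSam)
  rec <- sam$records
  ## primary records only
  rec <- rec[!bitwAnd(rec$flag, 256L) & !bitwAnd(rec$flag, 2048L), ,
             drop = FALSE]
  truth <- decodeReadNames(rec$qname)
  nUnknown <- sum(!truth$ok)
  rec <- rec[truth$ok, , drop = FALSE]
  truth <- truth[truth$ok, , drop = FALSE]
  n <- nrow(rec)
  mate2 <- bitwAnd(rec$flag, 128L) > 0L
  truePos <- ifelse(mate2, truth$pos2, truth$pos1)
  trueCigar <- ifelse(mate2, truth$cigar2, truth$cigar1)
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  okPos <- !unmapped & rec$rname == truth$contig &
    abs(rec$pos - truePos) <= posTolerance
  okCigar <- okPos &
    normalizeCigar(rec$cigar) == normalizeCigar(trueCigar)
  mism <- rec[!okPos | !okCigar, c("qname", "flag", "rname", "pos", "cigar"),
              drop = FALSE]
  if (nrow(mism)) {
    mism$truePos <- truePos[!okPos | !okCigar]
    mism$trueCigar <- trueCigar[!okPos | !okCigar]
    mism$trueContig <- truth$contig[!okPos | !okCigar]
  }
  methods::new("AlignmentReport", nReads = n,
               nCorrectPosition = sum(okPos), nCorrectCigar = sum(okCigar),
               nUnmapped = sum(unmapped), nUnknown = nUnknown,
               mismatches = mism)
}

## ---------------------------------------------------------------------------
## VCF comparison
## ---------------------------------------------------------------------------

## split multi-allelic records into biallelic rows
expandVcfTable <- function(v) {
  multi <- grepl(",", v$alt, fixed = TRUE)
  if (!any(multi)) return(v)
  singles <- v[!multi, , drop = FALSE]
  rows <- lapply(which(multi), function(i) {
    alts <- strsplit(v$alt[i], ",", fixed = TRUE)[[1]]
    out <- v[rep(i, length(alts)), , drop = FALSE]
    out$alt <- alts
    out
  })
  out <- rbind(singles, do.call(rbind, rows))
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Compare a test VCF against the golden VCF
#'
#' Variants matching exactly on (contig, position, ref, alt) are true
#' positives. With `equivalence = TRUE` and a reference, the remaining
#' variants are clustered (gap <= `clusterGap` bases) and each cluster's
#' golden and test groups are applied to the reference window: if they
#' spell the same alternate sequence the representations are equivalent and
#' the cluster counts as matched. What remains splits into false positives
#' and false negatives, optionally written to VCF files for inspection.
#' Genotype concordance over exact matches is reported separately and does
#' not affect the TP/FP/FN partition.
#'
#' @param goldenVcf golden VCF path (or variant data.frame).
#' @param testVcf test VCF path (or variant data.frame).
#' @param ref reference DNAStringSet (required for equivalence mode).
#' @param equivalence detect equivalent-but-differently-represented groups.
#' @param clusterGap clustering gap in bases (default 50).
#' @param outPrefix if given, residual FP and FN records are written to
#'   `\{outPrefix\}_FP.vcf` and `\{outPrefix\}_FN.vcf`.
#' @return a \linkS4class{VcfComparisonReport}.
#' @export
compareVcfs <- function(goldenVcf, testVcf, ref = NULL, equivalence = FALSE,
                        clusterGap = 50L, outPrefix = NULL) {
  g <- if (is.character(goldenVcf)) readVcfRecords(goldenVcf) else goldenVcf
  t <- if (is.character(testVcf)) readVcfRecords(testVcf) else testVcf
  g <- expandVcfTable(g); t <- expandVcfTable(t)
  if (!is.null(ref)) {
    badT <- !t$contig %in% names(ref)
    if (any(badT))
      stop("test VCF contig absent from reference: ",
           paste(unique(t$contig[badT]), collapse = ", "))
  }
  gKey <- paste(g$contig, g$pos, g$ref, g$alt)
  tKey <- paste(t$contig, t$pos, t$ref, t$alt)
  tp <- gKey %in% tKey
  fpRes <- t[!(tKey %in% gKey), , drop = FALSE]
  fnRes <- g[!tp, , drop = FALSE]

  gtConc <- NA_real_
  exact <- which(tp)
  if (length(exact)) {
    tgGt <- t$gt[match(gKey[exact], tKey)]
    both <- !is.na(g$gt[exact]) & !is.na(tgGt)
    if (any(both)) {
      norm <- function(x) {
        vapply(strsplit(x, "[|/]"), function(a)
          paste(sort(a), collapse = "/"), character(1))
      }
      gtConc <- mean(norm(g$gt[exact][both]) == norm(tgGt[both]))
    }
  }

  nEq <- 0L
  if (equivalence && nrow(fnRes) && nrow(fpRes)) {
    if (is.null(ref)) stop("equivalence mode needs the reference")
    resid <- rbind(cbind(fnRes, side = "golden"),
                   cbind(fpRes, side = "test"))
    resid <- resid[order(resid$contig, resid$pos), , drop = FALSE]
    newGrp <- c(TRUE, resid$contig[-1L] != resid$contig[-nrow(resid)] |
                  diff(resid$pos) > clusterGap)
    grp <- cumsum(newGrp)
    dropG <- rep(FALSE, nrow(fnRes)); dropT <- rep(FALSE, nrow(fpRes))
    for (gi in unique(grp)) {
      cl <- resid[grp == gi, , drop = FALSE]
      ga <- cl[cl$side == "golden", , drop = FALSE]
      tb <- cl[cl$side == "test", , drop = FALSE]
      if (nrow(ga) == 0L || nrow(tb) == 0L) next
      pad <- max(nchar(c(ga$ref, tb$ref))) + 1L
      ws <- max(0L, min(cl$pos) - pad)
      we <- min(length(ref[[cl$contig[1L]]]), max(cl$pos) + pad + 1L)
      eq <- tryCatch(
        equivalentVariantGroups(ga, tb,
          as.character(Biostrings::subseq(ref[[cl$contig[1L]]],
                                          ws + 1L, we)), ws),
        error = function(e) FALSE)
      if (isTRUE(eq)) {
        nEq <- nEq + 1L
        dropG <- dropG | (paste(fnRes$contig, fnRes$pos, fnRes$ref,
                                fnRes$alt) %in%
                            paste(ga$contig, ga$pos, ga$ref, ga$alt))
        dropT <- dropT | (paste(fpRes$contig, fpRes$pos, fpRes$ref,
                                fpRes$alt) %in%
                            paste(tb$contig, tb$pos, tb$ref, tb$alt))
      }
    }
    fnRes <- fnRes[!dropG, , drop = FALSE]
    fpRes <- fpRes[!dropT, , drop = FALSE]
  }

  if (!is.null(outPrefix) && !is.null(ref)) {
    fp <- fpRes; fn <- fnRes
    if (is.null(fp$gt)) fp$gt <- "."
    if (is.null(fn$gt)) fn$gt <- "."
    fp$gt[is.na(fp$gt)] <- "."; fn$gt[is.na(fn$gt)] <- "."
    writeGoldenVcf(fp, ref, paste0(outPrefix, "_FP.vcf"))
    writeGoldenVcf(fn, ref, paste0(outPrefix, "_FN.vcf"))
  }

  methods::new("VcfComparisonReport", nGolden = nrow(g), nTest = nrow(t),
               TP = nrow(g) - nrow(fnRes), FP = nrow(fpRes),
               FN = nrow(fnRes), nEquivalentGroups = nEq,
               fpRecords = fpRes, fnRecords = fnRes,
               fnCategories = integer(0), genotypeConcordance = gtConc)
}

#' Are two variant groups equivalent representations?
#'
#' Applies each group to the same reference window and compares the
#' resulting alternate sequences; TRUE iff they are identical. When both
#' groups carry parseable genotypes of equal ploidy the comparison is per
#' haplotype copy; otherwise all variants of a group are applied to a
#' single copy. Overlapping variants within one group are an error.
#'
#' @param groupA,groupB data.frames with `pos` (0-based), `ref`, `alt` and
#'   optionally `gt`.
#' @param windowSeq reference sequence of the enclosing window.
#' @param windowStart absolute 0-based start of `windowSeq`.
#' @return logical scalar.
#' @export
equivalentVariantGroups <- function(groupA, groupB, windowSeq, windowStart) {
  checkGroup <- function(gdf) {
    gdf <- gdf[order(gdf$pos), , drop = FALSE]
    if (nrow(gdf) > 1L) {
      ends <- gdf$pos + nchar(gdf$ref)
      if (any(gdf$pos[-1L] < ends[-nrow(gdf)]))
        stop("overlapping variants within one group")
    }
    gdf
  }
  groupA <- checkGroup(groupA); groupB <- checkGroup(groupB)
  ploidyOf <- function(gdf) {
    if (is.null(gdf$gt) || anyNA(gdf$gt)) return(NA_integer_)
    k <- unique(lengths(strsplit(gdf$gt, "[|/]")))
    if (length(k) == 1L && k >= 1L) k else NA_integer_
  }
  pA <- ploidyOf(groupA); pB <- ploidyOf(groupB)
  usePloidy <- if (!is.na(pA) && !is.na(pB) && pA == pB) pA else 1L
  if (usePloidy == 1L) { groupA$gt <- "1"; groupB$gt <- "1" }
  hapsA <- applyMutations(windowSeq, windowStart, groupA, usePloidy)$haps
  hapsB <- applyMutations(windowSeq, windowStart, groupB, usePloidy)$haps
  if (usePloidy == 1L) return(hapsA == hapsB)
  ## copy order is arbitrary between callers: compare as multisets
  identical(sort(hapsA), sort(hapsB))
}

## ---------------------------------------------------------------------------
## Mappability and FN diagnosis
## ---------------------------------------------------------------------------

#' Compute a k-mer mappability track
#'
#' A position is uniquely mappable iff the k-mer starting there occurs
#' exactly once in the whole reference counting both strands (its
#' occurrences plus those of its reverse complement). Positions whose
#' k-mer contains N are non-unique.
#'
#' @param ref reference DNAStringSet.
#' @param k k-mer length (the simulated read length).
#' @return named list per contig of logical vectors of length `L - k + 1`.
#' @export
computeMappability <- function(ref, k) {
  stopifnot(k >= 1L, k <= min(Biostrings::width(ref)))
  kmers <- lapply(setNames(names(ref), names(ref)), function(cn) {
    s <- as.character(ref[[cn]])
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  })
  countsF <- table(unlist(kmers, use.names = FALSE))
  lookup <- function(km) {
    v <- as.integer(countsF[km])
    v[is.na(v)] <- 0L
    v
  }
  lapply(kmers, function(km) {
    rc <- revComp(km)
    pal <- km == rc
    uq <- ifelse(pal, lookup(km) == 1L, lookup(km) + lookup(rc) == 1L)
    uq[grepl("N", km, fixed = TRUE)] <- FALSE
    uq
  })
}

#' Diagnose false-negative variant calls
#'
#' Each FN is labeled `unmappable` if its position lies in a region that is
#' not uniquely mappable at the read length, else `low-coverage` if the
#' golden-alignment depth at the position is below `dpThreshold`, else
#' `other`. Unmappability wins when both conditions hold (it is the root
#' cause; coverage there is ill-defined).
#'
#' @param fnRecords data.frame with `contig` and `pos` (0-based), e.g. the
#'   `fnRecords` of a \linkS4class{VcfComparisonReport}.
#' @param goldenSam golden SAM path (depth source).
#' @param ref reference DNAStringSet.
#' @param mappability result of \code{\link{computeMappability}} (computed
#'   here if NULL).
#' @param readLength k for the mappability track.
#' @param dpThreshold minimum adequate depth (default 10).
#' @return named integer vector: counts per category (`unmappable`,
#'   `low-coverage`, `other`), with per-record labels as attribute
#'   `"labels"`.
#' @export
diagnoseFalseNegatives <- function(fnRecords, goldenSam, ref,
                                   mappability = NULL, readLength = 100L,
                                   dpThreshold = 10L) {
  if (is.null(mappability)) mappability <- computeMappability(ref, readLength)
  depth <- samCoverage(goldenSam, ref)
  labels <- character(nrow(fnRecords))
  for (i in seq_len(nrow(fnRecords))) {
    cn <- fnRecords$contig[i]
    p <- fnRecords$pos[i]          # 0-based
    mp <- mappability[[cn]]
    idx <- min(p + 1L, length(mp))
    if (!isTRUE(mp[idx])) {
      labels[i] <- "unmappable"
    } else if (depth[[cn]][p + 1L] < dpThreshold) {
      labels[i] <- "low-coverage"
    } else labels[i] <- "other"
  }
  out <- c(unmappable = sum(labels == "unmappable"),
           `low-coverage` = sum(labels == "low-coverage"),
           other = sum(labels == "other"))
  attr(out, "labels") <- labels
  out
}
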