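## MutationModel learning, sampling and application.

CONTEXTS <- as.vector(outer(DNA_BASES, DNA_BASES,
                            function(x, z) paste0(x, "_", z)))

uniformAltMatrix <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  m
}

#' Construct a MutationModel
#'
#' @param overallRate per-base mutation probability.
#' @param typeFractions named numeric `c(sub=, ins=, del=)`, sums to 1.
#' @param trinucMatrices named list of 16 4x4 row-stochastic matrices (one
#'   per context `"X_Z"`); missing contexts get a uniform matrix.
#' @param trinucBias named numeric over 64 trinucleotides (default uniform).
#' @param insLengths,delLengths named length distributions (names are the
#'   lengths); empty defaults to a geometric-like distribution over 1..10.
#' @param unobservedRows labels of rows backed by the uniform fallback.
#' @return a \linkS4class{MutationModel}.
#' @export
MutationModel <- function(overallRate = 0.001,
                          typeFractions = c(sub = 0.9, ins = 0.05, del = 0.05),
                          trinucMatrices = NULL, trinucBias = NULL,
                          insLengths = NULL, delLengths = NULL,
                          unobservedRows = character(0)) {
  tm <- setNames(replicate(16, uniformAltMatrix(), simplify = FALSE), CONTEXTS)
  for (nm in names(trinucMatrices)) tm[[nm]] <- trinucMatrices[[nm]]
  if (is.null(trinucBias))
    trinucBias <- setNames(rep(1 / 64, 64), allTrinucs())
  defLen <- normalizeProbs(setNames(0.5^(1:10), 1:10))
  if (is.null(insLengths) || length(insLengths) == 0L) insLengths <- defLen
  if (is.null(delLengths) || length(delLengths) == 0L) delLengths <- defLen
  methods::new("MutationModel", overallRate = overallRate,
               typeFractions = typeFractions[c("sub", "ins", "del")],
               trinucMatrices = tm, trinucBias = trinucBias,
               insLengths = insLengths, delLengths = delLengths,
               unobservedRows = unobservedRows)
}

#' Default (uniform) mutation model
#'
#' All substitution matrices uniform over the three alternate bases, uniform
#' trinucleotide bias, geometric-tailed indel lengths: a simple baseline for
#' testing variant callers.
#'
#' @param rate overall per-base mutation rate.
#' @return a \linkS4class{MutationModel}.
#' @export
defaultMutationModel <- function(rate = 0.001) MutationModel(overallRate = rate)

#' Random mutation model (synthetic-data generator)
#'
#' Draws every conditional distribution from a Dirichlet so round-trip tests
#' exercise non-trivial, asymmetric models.
#'
#' @param rate overall per-base mutation rate.
#' @param concentration Dirichlet concentration (1 = flat).
#' @param seed optional seed.
#' @return a \linkS4class{MutationModel}.
#' @export
randomMutationModel <- function(rate = 0.005, concentration = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rdir <- function(k) {
    g <- stats::rgamma(k, concentration) + 1e-4
    g / sum(g)
  }
  tm <- lapply(setNames(CONTEXTS, CONTEXTS), function(cx) {
    m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (i in 1:4) m[i, -i] <- rdir(3)
    m
  })
  tf <- c(0.7, 0, 0) + 0.3 * rdir(3)
  MutationModel(overallRate = rate,
                typeFractions = setNames(tf, c("sub", "ins", "del")),
                trinucMatrices = tm,
                insLengths = setNames(rdir(6), 1:6),
                delLengths = setNames(rdir(6), 1:6))
}

#' Rescale the overall mutation rate
#'
#' Replaces the overall rate; every conditional distribution is unchanged.
#'
#' @param model MutationModel.
#' @param rate new overall per-base rate (>= 0).
#' @return the rescaled model.
#' @export
rescaleMutationRate <- function(model, rate) {
  stopifnot(rate >= 0)
  model@overallRate <- rate
  methods::validObject(model)
  model
}

## ---------------------------------------------------------------------------
## Learning
## ---------------------------------------------------------------------------

## read a VCF into a plain data.frame: contig, pos (0-based), ref, alt, gt
readVcfRecords <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  gt <- tryCatch({
    g <- v@gt
    if (!is.null(g) && ncol(g) >= 2L) {
      fmt <- strsplit(g[, 1L], ":", fixed = TRUE)
      val <- strsplit(g[, 2L], ":", fixed = TRUE)
      vapply(seq_along(fmt), function(i) {
        j <- match("GT", fmt[[i]])
        if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][j]
      }, character(1))
    } else rep(NA_character_, nrow(fx))
  }, error = function(e) rep(NA_character_, nrow(fx)))
  data.frame(contig = fx[, "CHROM"],
             pos = as.integer(fx[, "POS"]) - 1L,
             ref = fx[, "REF"], alt = fx[, "ALT"], gt = gt,
             stringsAsFactors = FALSE)
}

#' Learn a mutation model from a VCF
#'
#' Each usable record contributes to the sub/ins/del split; SNPs additionally
#' contribute a trinucleotide transition (the bases immediately before and
#' after the variant form the context, so e.g. an AGA->ACA substitution
#' increments row G, column C of the `"A_A"` matrix) and indels contribute
#' their length. Matrix entries are transition counts divided by the
#' reference abundance of the source trinucleotide and then row-normalized
#' into conditional substitution probabilities. Multi-allelic records are
#' resolved by picking one alternate allele at random. The overall rate is
#' the usable variant count divided by the callable (non-N) reference
#' length.
#'
#' Records whose position or reference allele does not match the reference,
#' or whose alleles are not plain ACGT sequences, are skipped and counted.
#'
#' @param vcfPath path to a VCF 4.x file.
#' @param ref reference DNAStringSet.
#' @param census optional precomputed \code{\link{trinucCensus}}.
#' @param regions optional \linkS4class{RegionTrack}; only variants whose
#'   anchor falls inside it are used and the callable length is restricted
#'   accordingly (CDS/nonCDS style stratification).
#' @return a \linkS4class{MutationModel} with attribute `"stats"` (counts of
#'   used/skipped records).
#' @export
learnMutationModel <- function(vcfPath, ref, census = NULL, regions = NULL) {
  if (is.null(census)) census <- trinucCensus(ref)
  rec <- readVcfRecords(vcfPath)
  stats <- c(used = 0L, refMismatch = 0L, badAllele = 0L, offRegion = 0L)

  ## multi-allelic: pick one alternate at random
  multi <- grepl(",", rec$alt, fixed = TRUE)
  if (any(multi))
    rec$alt[multi] <- vapply(strsplit(rec$alt[multi], ",", fixed = TRUE),
                             function(a) a[[sample.int(length(a), 1L)]],
                             character(1))

  keep <- rec$contig %in% names(ref)
  stats[["refMismatch"]] <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]

  ok <- grepl("^[ACGT]+$", rec$ref) & grepl("^[ACGT]+$", rec$alt)
  stats[["badAllele"]] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]

  if (!is.null(regions)) {
    inReg <- vapply(seq_len(nrow(rec)), function(i)
      trackValues(regions, rec$contig[i], rec$pos[i], rec$pos[i] + 1L) > 0,
      logical(1))
    stats[["offRegion"]] <- sum(!inReg)
    rec <- rec[inReg, , drop = FALSE]
  }

  ## verify reference alleles
  if (nrow(rec)) {
    obs <- as.character(Biostrings::subseq(
      ref[rec$contig], start = rec$pos + 1L,
      width = nchar(rec$ref)))
    match <- obs == rec$ref
    stats[["refMismatch"]] <- stats[["refMismatch"]] + sum(!match)
    rec <- rec[match, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no usable VCF records in ", vcfPath)
  stats[["used"]] <- nrow(rec)

  nr <- nchar(rec$ref); na <- nchar(rec$alt)
  isSnp <- nr == 1L & na == 1L
  isIns <- nr == 1L & na > 1L & substr(rec$alt, 1L, 1L) == rec$ref
  isDel <- na == 1L & nr > 1L & substr(rec$ref, 1L, 1L) == rec$alt
  other <- !(isSnp | isIns | isDel)
  if (any(other)) {  # MNVs etc: excluded from the model
    stats[["badAllele"]] <- stats[["badAllele"]] + sum(other)
    stats[["used"]] <- stats[["used"]] - sum(other)
    rec <- rec[!other, , drop = FALSE]
    isIns <- isIns[!other]; isDel <- isDel[!other]; isSnp <- isSnp[!other]
  }

  tf <- normalizeProbs(c(sub = sum(isSnp), ins = sum(isIns), del = sum(isDel)))

  ## SNP trinucleotide transitions
  counts <- array(0, dim = c(16L, 4L, 4L),
                  dimnames = list(CONTEXTS, DNA_BASES, DNA_BASES))
  biasHits <- setNames(rep(0, 64), allTrinucs())
  snp <- rec[isSnp, , drop = FALSE]
  if (nrow(snp)) {
    lens <- setNames(Biostrings::width(ref), names(ref))
    inner <- snp$pos >= 1L & snp$pos + 1L < lens[snp$contig]
    snp <- snp[inner, , drop = FALSE]
    if (nrow(snp)) {
      tri <- as.character(Biostrings::subseq(ref[snp$contig],
                                             start = snp$pos, width = 3L))
      ctxOk <- grepl("^[ACGT]{3}$", tri)
      snp <- snp[ctxOk, , drop = FALSE]; tri <- tri[ctxOk]
      if (nrow(snp)) {
        cx <- contextLabel(substr(tri, 1, 1), substr(tri, 3, 3))
        tab <- table(factor(cx, CONTEXTS), factor(snp$ref, DNA_BASES),
                     factor(snp$alt, DNA_BASES))
        counts <- counts + as.numeric(tab)
        bh <- table(factor(tri, allTrinucs()))
        biasHits <- biasHits + as.numeric(bh)
      }
    }
  }

  unobserved <- character(0)
  tm <- lapply(setNames(CONTEXTS, CONTEXTS), function(cxl) {
    m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (b in DNA_BASES) {
      src <- paste0(substr(cxl, 1, 1), b, substr(cxl, 3, 3))
      row <- counts[cxl, b, ] / max(census[[src]], 1L)
      row[b] <- 0
      if (sum(row) <= 0) {
        row[] <- 1 / 3; row[b] <- 0
        unobserved <<- c(unobserved, paste0(cxl, ":", b))
      } else row <- row / sum(row)
      m[b, ] <- row
    }
    m
  })

  bias <- biasHits / pmax(census, 1L)
  bias <- normalizeProbs(bias)

  tally <- function(lens) {
    if (length(lens) == 0L) return(NULL)
    t <- table(lens)
    setNames(as.numeric(t) / sum(t), names(t))
  }
  insL <- tally(nchar(rec$alt[isIns]) - 1L)
  delL <- tally(nchar(rec$ref[isDel]) - 1L)

  callable <- callableLength(ref, regions)
  rate <- min(0.3, stats[["used"]] / max(callable, 1))

  model <- MutationModel(overallRate = rate, typeFractions = tf,
                         trinucMatrices = tm, trinucBias = bias,
                         insLengths = insL, delLengths = delL,
                         unobservedRows = unobserved)
  attr(model, "stats") <- stats
  model
}

## non-N reference length, optionally restricted to a RegionTrack
callableLength <- function(ref, regions = NULL) {
  if (is.null(regions))
    return(sum(Biostrings::letterFrequency(ref, "ACGT")))
  total <- 0
  gr <- regions@regions
  for (i in seq_along(gr)) {
    cn <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!cn %in% names(ref)) next
    sub <- Biostrings::subseq(ref[[cn]], GenomicRanges::start(gr)[i],
                              min(GenomicRanges::end(gr)[i],
                                  length(ref[[cn]])))
    total <- total + sum(Biostrings::letterFrequency(sub, "ACGT"))
  }
  total
}

## ---------------------------------------------------------------------------
## Sampling
## ---------------------------------------------------------------------------

#' Sample mutation sites within a window core
#'
#' Without a rate track the number of sites is the stochastically rounded
#' product of the callable window length and the overall rate, positions
#' uniform over callable positions. With a track the expected count is the
#' sum of per-position rates and sites are drawn proportional to the local
#' rate, without replacement.
#'
#' @param contig contig name.
#' @param coreStart,coreEnd 0-based half-open window core.
#' @param windowSeq character string of the window core sequence.
#' @param model MutationModel.
#' @param rateTrack optional mutation-rate \linkS4class{RegionTrack};
#'   positions it does not cover have rate 0.
#' @param useTrinucBias draw sites proportional to the model's trinucleotide
#'   bias instead of uniformly (off by default).
#' @return sorted integer vector of absolute 0-based positions.
#' @export
sampleMutationSites <- function(contig, coreStart, coreEnd, windowSeq, model,
                                rateTrack = NULL, useTrinucBias = FALSE) {
  n <- coreEnd - coreStart
  if (n <= 0L) return(integer(0))
  chars <- strsplit(windowSeq, "", fixed = TRUE)[[1]]
  callable <- chars != "N"
  if (!any(callable)) return(integer(0))
  if (!is.null(rateTrack)) {
    w <- trackValues(rateTrack, contig, coreStart, coreEnd, default = 0)
    w[!callable] <- 0
    expected <- sum(w)
    if (expected <= 0) return(integer(0))
    k <- min(stochasticRound(expected), sum(w > 0))
    if (k == 0L) return(integer(0))
    idx <- sample.int(n, k, replace = FALSE, prob = w)
  } else {
    if (model@overallRate <= 0) return(integer(0))
    w <- as.numeric(callable)
    if (useTrinucBias && n > 2L) {
      tri <- substring(windowSeq, 1:(n - 2L), 3:n)
      b <- model@trinucBias[tri]
      b[is.na(b)] <- 0
      w[2:(n - 1L)] <- w[2:(n - 1L)] * b * 64  # keep mean weight ~1
    }
    expected <- model@overallRate * sum(callable)
    k <- min(stochasticRound(expected), sum(w > 0))
    if (k == 0L) return(integer(0))
    idx <- sample.int(n, k, replace = FALSE, prob = w)
  }
  sort(coreStart + idx - 1L)
}

#' Sample one mutation payload
#'
#' Type is drawn from the model's type fractions; a substitution's alternate
#' base comes from the context matrix row for the reference base (uniform
#' fallback when the context contains N or was unobserved); insertion length
#' comes from the learned distribution with inserted bases i.i.d. uniform;
#' deletion length comes from the learned distribution, truncated so the
#' footprint stays inside `[.., maxEnd)`.
#'
#' @param model MutationModel.
#' @param refBase reference base at the site (A/C/G/T).
#' @param context `"X_Z"` flanking context (may contain N).
#' @param downstream reference bases starting at the site (used to build
#'   deletion alleles); its length bounds the deletion.
#' @param maxLen maximum deletable bases.
#' @param upstream the reference base immediately before the site, when
#'   available: a deletion then removes bases starting at the site and the
#'   VCF record anchors one base left (`posShift = -1`), e.g. deleting two
#'   bases at the first C of `AACCT` yields ref `"ACC"`, alt `"A"`. Without
#'   an upstream base the site itself anchors and downstream bases are
#'   deleted.
#' @return list with `type`, `ref`, `alt`, `posShift` (offset of the VCF
#'   anchor relative to the sampled site).
#' @export
sampleMutation <- function(model, refBase, context, downstream, maxLen = 10L,
                           upstream = "") {
  type <- c("sub", "ins", "del")[sampleRows(rbind(model@typeFractions), 1L)]
  if (type == "sub") {
    m <- model@trinucMatrices[[context]]
    row <- if (is.null(m)) NULL else m[refBase, ]
    if (is.null(row) || sum(row) <= 0) {
      row <- setNames(rep(1 / 3, 4), DNA_BASES); row[refBase] <- 0
    }
    alt <- sample(DNA_BASES, 1L, prob = row)
    return(list(type = "sub", ref = refBase, alt = alt, posShift = 0L))
  }
  if (type == "ins") {
    len <- as.integer(sample(names(model@insLengths), 1L,
                             prob = model@insLengths))
    ins <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    return(list(type = "ins", ref = refBase, alt = paste0(refBase, ins),
                posShift = 0L))
  }
  len <- as.integer(sample(names(model@delLengths), 1L,
                           prob = model@delLengths))
  if (upstream %in% DNA_BASES) {
    len <- min(len, maxLen, nchar(downstream))
    if (len >= 1L)
      return(list(type = "del",
                  ref = paste0(upstream, substr(downstream, 1L, len)),
                  alt = upstream, posShift = -1L))
  } else {
    len <- min(len, maxLen - 1L, nchar(downstream) - 1L)
    if (len >= 1L)
      return(list(type = "del", ref = substr(downstream, 1L, len + 1L),
                  alt = refBase, posShift = 0L))
  }
  ## no room to delete: fall back to a substitution
  sampleMutation(rescaleTypeToSub(model), refBase, context, downstream,
                 maxLen, upstream)
}

rescaleTypeToSub <- function(model) {
  model@typeFractions <- c(sub = 1, ins = 0, del = 0)
  model
}

#' Assign a genotype
#'
#' With probability `hetFraction` a single copy (chosen uniformly) carries
#' the alternate allele; otherwise all copies do. Ploidy 1 always yields a
#' hemizygous alternate.
#'
#' @param n number of genotypes to draw.
#' @param ploidy number of copies (>= 1).
#' @param hetFraction probability of a heterozygous call (default 2/3).
#' @return n x ploidy 0/1 integer matrix with >= 1 alternate per row.
#' @export
assignGenotype <- function(n, ploidy, hetFraction = 2 / 3) {
  m <- matrix(0L, n, ploidy)
  if (n == 0L) return(m)
  if (ploidy == 1L) { m[, 1L] <- 1L; return(m) }
  het <- runif(n) < hetFraction
  m[!het, ] <- 1L
  if (any(het))
    m[cbind(which(het), sample.int(ploidy, sum(het), replace = TRUE))] <- 1L
  m
}

## ---------------------------------------------------------------------------
## Application (haplotype construction + coordinate maps)
## ---------------------------------------------------------------------------

#' Apply mutations to a window, per haplotype copy
#'
#' Mutations must be sorted and non-overlapping on the reference. Each copy
#' whose genotype entry is 1 receives the edit. Alongside each haplotype a
#' coordinate map is kept (runs of reference-aligned bases), from which
#' read CIGAR strings against the original reference are later built;
#' copies without indels carry a NULL map (identity).
#'
#' @param windowSeq reference sequence of the window (character string).
#' @param windowStart absolute 0-based start of `windowSeq`.
#' @param muts data.frame with columns `pos` (absolute 0-based anchor),
#'   `ref`, `alt`, `gt` (genotype string `"0|1|..."`).
#' @param ploidy number of copies.
#' @return list with `haps` (character vector of length ploidy) and `maps`
#'   (per copy, NULL or a data.frame `ref0`, `hap0`, `len` of aligned runs).
#' @export
applyMutations <- function(windowSeq, windowStart, muts, ploidy) {
  haps <- character(ploidy)
  maps <- vector("list", ploidy)
  gtm <- gtToMatrix(muts$gt, ploidy)
  wlen <- nchar(windowSeq)
  for (h in seq_len(ploidy)) {
    sel <- which(gtm[, h] == 1L)
    if (length(sel) == 0L) { haps[h] <- windowSeq; next }
    e <- muts[sel, , drop = FALSE]
    parts <- character(0)
    segs <- list()
    cur <- windowStart          # next unconsumed reference position
    segRef <- windowStart; segHap <- 0L; hapLen <- 0L
    for (i in seq_len(nrow(e))) {
      p <- e$pos[i]; rl <- nchar(e$ref[i]); al <- nchar(e$alt[i])
      if (p < cur) next  # overlaps previous edit: skip defensively
      ## general replacement: the first min(rl, al) bases align in place,
      ## the remainder is an insertion (al > rl) or deletion (rl > al)
      k <- min(rl, al)
      pre <- substr(windowSeq, cur - windowStart + 1L, p - windowStart)
      parts <- c(parts, pre, e$alt[i])
      hapLen <- hapLen + nchar(pre)
      if (rl != al) {
        segs[[length(segs) + 1L]] <- c(segRef, segHap, p + k - segRef)
        segRef <- p + rl
        segHap <- hapLen + al
      }
      hapLen <- hapLen + al
      cur <- p + rl
    }
    tailPart <- substr(windowSeq, cur - windowStart + 1L, wlen)
    parts <- c(parts, tailPart)
    hapLen <- hapLen + nchar(tailPart)
    haps[h] <- paste(parts, collapse = "")
    if (length(segs)) {
      segs[[length(segs) + 1L]] <-
        c(segRef, segHap, windowStart + wlen - segRef)
      m <- do.call(rbind, segs)
      maps[[h]] <- data.frame(ref0 = m[, 1L], hap0 = m[, 2L], len = m[, 3L])
    }
  }
  list(haps = haps, maps = maps)
}

## map absolute reference positions onto haplotype offsets (deleted
## positions map to the start of the following aligned run)
refToHap <- function(map, refpos) {
  if (is.null(map)) stop("identity map: convert positions directly")
  i <- findInterval(refpos, map$ref0)
  i[i < 1L] <- 1L
  inRun <- refpos < map$ref0[i] + map$len[i]
  out <- integer(length(refpos))
  out[inRun] <- map$hap0[i[inRun]] + (refpos[inRun] - map$ref0[i[inRun]])
  if (any(!inRun)) {
    j <- pmin(i[!inRun] + 1L, nrow(map))
    out[!inRun] <- map$hap0[j]
  }
  out
}

#' Build full-genome haplotypes from a variant table
#'
#' Independent oracle used to check simulator output: applies a golden
#' variant table to the reference, per contig and copy.
#'
#' @param ref DNAStringSet.
#' @param variants data.frame with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `gt`.
#' @param ploidy number of copies.
#' @return named list (per contig) of character vectors of length ploidy.
#' @export
buildHaplotypes <- function(ref, variants, ploidy) {
  out <- list()
  for (cn in names(ref)) {
    v <- variants[variants$contig == cn, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    out[[cn]] <- applyMutations(as.character(ref[[cn]]), 0L, v, ploidy)$haps
  }
  out
}

## ---------------------------------------------------------------------------
## Serialization
## ---------------------------------------------------------------------------

#' Write / read a mutation model as JSON
#'
#' A single versioned, text-inspectable document.
#'
#' @param model MutationModel.
#' @param path output path.
#' @export
writeMutationModel <- function(model, path) {
  doc <- list(format = "verisim-mutation-model", version = 1L,
              overallRate = model@overallRate,
              typeFractions = as.list(model@typeFractions),
              trinucMatrices = lapply(model@trinucMatrices, function(m)
                as.data.frame(m)),
              trinucBias = as.list(model@trinucBias),
              insLengths = as.list(model@insLengths),
              delLengths = as.list(model@delLengths),
              unobservedRows = model@unobservedRows)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMutationModel
#' @export
readMutationModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "verisim-mutation-model"))
    stop("not a mutation model document: ", path)
  tm <- lapply(doc$trinucMatrices, function(d) {
    m <- as.matrix(d); dimnames(m) <- list(DNA_BASES, DNA_BASES); m
  })
  MutationModel(overallRate = doc$overallRate,
                typeFractions = unlist(doc$typeFractions),
                trinucMatrices = tm,
                trinucBias = unlist(doc$trinucBias),
                insLengths = unlist(doc$insLengths),
                delLengths = unlist(doc$delLengths),
                unobservedRows = as.character(doc$unobservedRows %||% character(0)))
}
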