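## The read-generation engine: reference + mutation model + sequencing model
## -> FASTQ + golden SAM + golden VCF.

#' Simulation configuration constructor
#'
#' @param readLength read length in bases (>= 20).
#' @param coverage requested mean depth.
#' @param paired paired-end (FR) if TRUE, single-end otherwise.
#' @param ploidy haplotype copies per window.
#' @param mutationRate override of the model's overall mutation rate (NA
#'   keeps the model's).
#' @param errorRate requested mean per-base error rate (NA keeps the error
#'   model's scale).
#' @param onTargetFraction,offTargetFraction fractions of the requested
#'   coverage delivered inside / outside target regions (defaults 98%/2%).
#' @param windowSize,windowOverlap reference tiling (defaults 10000/100).
#' @param hetFraction probability a sampled variant is heterozygous.
#' @param writeFastq emit FASTQ files (disabling skips quality and error
#'   draws entirely).
#' @param keepHaplotypes,returnReads retain haplotypes / a per-read table in
#'   the returned object.
#' @param seed integer seed (NA leaves the RNG untouched).
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(readLength = 100L, coverage = 30, paired = TRUE,
                      ploidy = 2L, mutationRate = NA_real_,
                      errorRate = NA_real_, onTargetFraction = 0.98,
                      offTargetFraction = 0.02, windowSize = 10000L,
                      windowOverlap = 100L, hetFraction = 2 / 3,
                      writeFastq = TRUE, keepHaplotypes = FALSE,
                      returnReads = FALSE, seed = NA_real_) {
  methods::new("SimConfig", readLength = as.integer(readLength),
               coverage = coverage, paired = paired,
               ploidy = as.integer(ploidy), mutationRate = mutationRate,
               errorRate = errorRate, onTargetFraction = onTargetFraction,
               offTargetFraction = offTargetFraction,
               windowSize = as.integer(windowSize),
               windowOverlap = as.integer(windowOverlap),
               hetFraction = hetFraction, writeFastq = writeFastq,
               keepHaplotypes = keepHaplotypes, returnReads = returnReads,
               seed = seed)
}

#' Default sequencing model
#'
#' Default quality chain, substitution-dominated error model, no GC bias,
#' Gaussian fragment lengths.
#'
#' @param readLength quality-model read length.
#' @param fragmentMean,fragmentSd Gaussian fragment-length parameters.
#' @return a \linkS4class{SequencingModel}.
#' @export
defaultSequencingModel <- function(readLength = 100L, fragmentMean = 300,
                                   fragmentSd = 30) {
  methods::new("SequencingModel",
               qualityFwd = defaultQualityModel(readLength),
               qualityRev = NULL, error = defaultErrorModel(),
               gcBias = NULL,
               fragment = gaussianFragmentModel(fragmentMean, fragmentSd))
}

#' Assemble a sequencing model from sub-models
#'
#' @param qualityFwd,qualityRev quality chains (reverse may be NULL).
#' @param error ErrorModel.
#' @param gcBias GcBiasModel or NULL.
#' @param fragment FragmentModel.
#' @return a \linkS4class{SequencingModel}.
#' @export
sequencingModel <- function(qualityFwd = defaultQualityModel(),
                            qualityRev = NULL, error = defaultErrorModel(),
                            gcBias = NULL,
                            fragment = gaussianFragmentModel()) {
  methods::new("SequencingModel", qualityFwd = qualityFwd,
               qualityRev = qualityRev, error = error, gcBias = gcBias,
               fragment = fragment)
}

## ---------------------------------------------------------------------------
## Read-name truth encoding
## ---------------------------------------------------------------------------

#' Encode / decode ground-truth read names
#'
#' Both mates of a pair share one name, so the name carries the truth for
#' both: `prefix:serial:contig:pos1:strand1:cigar1:pos2:strand2:cigar2`
#' (1-based leftmost positions; single-end reads carry `.` in the mate-2
#' fields). Decoding splits from the right so contig names containing
#' dashes survive; contig names must not contain `:`.
#'
#' @param prefix name prefix (no `:`).
#' @param serial integer serial per fragment.
#' @param contig,pos1,strand1,cigar1,pos2,strand2,cigar2 truth fields.
#' @return character vector of read names.
#' @export
encodeReadNames <- function(prefix, serial, contig, pos1, strand1, cigar1,
                            pos2 = ".", strand2 = ".", cigar2 = ".") {
  paste(prefix, serial, contig, pos1, strand1, cigar1, pos2, strand2,
        cigar2, sep = ":")
}

#' @rdname encodeReadNames
#' @param names read names to decode (a trailing `/1` or `/2` is accepted).
#' @return for `decodeReadNames`: data.frame with the truth fields and a
#'   logical `ok` column flagging decodable names.
#' @export
decodeReadNames <- function(names) {
  names <- sub("/[12]$", "", names)
  parts <- strsplit(names, ":", fixed = TRUE)
  n <- lengths(parts)
  ok <- n >= 9L
  take <- function(k) vapply(seq_along(parts), function(i)
    if (ok[i]) parts[[i]][n[i] - k] else NA_character_, character(1))
  pos1 <- suppressWarnings(as.integer(take(5L)))
  pos2 <- suppressWarnings(as.integer(take(2L)))
  ok <- ok & !is.na(pos1)
  data.frame(contig = take(6L), pos1 = pos1, strand1 = take(4L),
             cigar1 = take(3L), pos2 = pos2, strand2 = take(1L),
             cigar2 = take(0L), ok = ok, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## CIGAR construction from a haplotype coordinate map
## ---------------------------------------------------------------------------

#' Build a golden CIGAR from a coordinate map
#'
#' Walks the aligned runs of a haplotype coordinate map (see
#' \code{\link{applyMutations}}) from a haplotype offset, emitting M/I/D
#' runs with respect to the original reference; leading and trailing
#' insertions become soft clips. Read-consuming operations sum to
#' `readLength`.
#'
#' @param map data.frame `ref0`, `hap0`, `len` (aligned runs), or NULL for
#'   the identity map.
#' @param hapStart 0-based haplotype offset of the read's first base.
#' @param readLength read length.
#' @return list with `pos` (0-based reference position of the first aligned
#'   base), `cigar`, and `refSpan` (reference bases consumed).
#' @export
buildCigarFromMap <- function(map, hapStart, readLength) {
  if (is.null(map))
    return(list(pos = hapStart, cigar = paste0(readLength, "M"),
                refSpan = readLength))
  nseg <- nrow(map)
  h <- hapStart
  i <- max(1L, findInterval(h, map$hap0))
  ops <- character(0); lens <- integer(0)
  remaining <- readLength
  pos <- NA_integer_
  repeat {
    segEnd <- map$hap0[i] + map$len[i]
    if (h < segEnd) {
      take <- min(segEnd - h, remaining)
      if (is.na(pos)) pos <- map$ref0[i] + (h - map$hap0[i])
      ops <- c(ops, "M"); lens <- c(lens, take)
      remaining <- remaining - take; h <- h + take
      if (remaining == 0L) break
    }
    if (i == nseg) break
    gapEnd <- map$hap0[i + 1L]
    if (h < gapEnd) {                       # insertion gap
      take <- min(gapEnd - h, remaining)
      ops <- c(ops, "I"); lens <- c(lens, take)
      remaining <- remaining - take; h <- h + take
      if (remaining == 0L) break
    }
    gapDel <- map$ref0[i + 1L] - (map$ref0[i] + map$len[i])
    if (gapDel > 0L) { ops <- c(ops, "D"); lens <- c(lens, gapDel) }
    i <- i + 1L
  }
  if (remaining > 0L) { ops <- c(ops, "M"); lens <- c(lens, remaining) }
  ## strip boundary deletions; clip boundary insertions
  while (length(ops) && ops[1L] == "D") { ops <- ops[-1L]; lens <- lens[-1L] }
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (length(ops) && ops[1L] == "I") ops[1L] <- "S"
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  if (is.na(pos)) pos <- map$ref0[min(i + 1L, nseg)]
  ## merge adjacent same ops
  if (length(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lens <- as.integer(tapply(lens, grp, sum))
    ops <- ops[!duplicated(grp)]
  }
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""),
       refSpan = sum(lens[ops %in% c("M", "D")]))
}

## ---------------------------------------------------------------------------
## Fragment planning
## ---------------------------------------------------------------------------

#' Plan fragment sampling for a window core
#'
#' The per-position fragment-start weight is the product of the target
#' factor (`onTargetFraction` inside target intervals, `offTargetFraction`
#' outside; 1 when no target track is given), the GC-bias multiplier of the
#' enclosing GC window, and an N mask (N positions start nothing). The
#' expected fragment count is `coverage / (readsPerFragment * readLength)`
#' times the summed weights, which makes the realized mean depth equal the
#' requested coverage when all weights are 1.
#'
#' @param contigSeq DNAString of the contig.
#' @param contig contig name.
#' @param coreStart,coreEnd 0-based half-open window core.
#' @param config \linkS4class{SimConfig}.
#' @param gcBias GcBiasModel or NULL.
#' @param targetTrack target \linkS4class{RegionTrack} or NULL.
#' @return list with `expected` (fragment count) and `weights`
#'   (per-core-position start weights).
#' @export
planFragmentCount <- function(contigSeq, contig, coreStart, coreEnd, config,
                              gcBias = NULL, targetTrack = NULL) {
  n <- coreEnd - coreStart
  w <- rep(1, n)
  if (!is.null(targetTrack)) {
    tv <- trackValues(targetTrack, contig, coreStart, coreEnd, default = 0)
    w <- ifelse(tv > 0, config@onTargetFraction, config@offTargetFraction)
  }
  if (!is.null(gcBias))
    w <- w * gcWeights(gcBias, contigSeq, coreStart, coreEnd)
  core <- as.character(Biostrings::subseq(contigSeq, coreStart + 1L, coreEnd))
  isN <- utf8ToInt(core) == utf8ToInt("N")
  w[isN] <- 0
  rpf <- if (config@paired) 2L else 1L
  list(expected = config@coverage / (rpf * config@readLength) * sum(w),
       weights = w)
}

## ---------------------------------------------------------------------------
## Window mutation assembly
## ---------------------------------------------------------------------------

## sample + merge mutations for one window core; input variants win
## conflicts. Deletions anchored in the window's head overlap (before
## `headLimit`) are truncated there so no sampled footprint ever crosses a
## window-span boundary.
buildWindowMutations <- function(contig, wseq, wstart, coreEnd, model,
                                 rateTrack, hetFraction, ploidy, inputHere,
                                 headLimit = NULL) {
  coreSeq <- substr(wseq, 1L, coreEnd - wstart)
  sites <- sampleMutationSites(contig, wstart, coreEnd, coreSeq, model,
                               rateTrack)
  occ <- if (!is.null(inputHere) && nrow(inputHere)) {
    cbind(inputHere$pos, inputHere$pos + nchar(inputHere$ref))
  } else matrix(numeric(0), 0L, 2L)
  if (length(sites) && nrow(occ)) {
    hitInput <- vapply(sites, function(p)
      any(p >= occ[, 1L] & p < occ[, 2L]), logical(1))
    sites <- sites[!hitInput]
  }
  sampled <- NULL
  if (length(sites)) {
    rows <- vector("list", length(sites))
    for (k in seq_along(sites)) {
      p <- sites[k]
      rel <- p - wstart + 1L
      refBase <- substr(wseq, rel, rel)
      if (refBase == "N") next
      before <- if (rel > 1L) substr(wseq, rel - 1L, rel - 1L) else "N"
      after <- if (rel < nchar(wseq)) substr(wseq, rel + 1L, rel + 1L) else "N"
      cx <- if (before %in% DNA_BASES && after %in% DNA_BASES)
        contextLabel(before, after) else "N_N"
      down <- substr(wseq, rel, min(rel + 20L, coreEnd - wstart))
      up <- if (rel > 1L) substr(wseq, rel - 1L, rel - 1L) else ""
      maxDel <- coreEnd - p
      if (!is.null(headLimit) && p < headLimit)
        maxDel <- min(maxDel, headLimit - p)
      pay <- sampleMutation(model, refBase, cx, down, maxLen = maxDel,
                            upstream = up)
      rows[[k]] <- data.frame(pos = p + pay$posShift, ref = pay$ref,
                              alt = pay$alt, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      sampled <- do.call(rbind, rows)
      gm <- assignGenotype(nrow(sampled), ploidy, hetFraction)
      sampled$gt <- matrixToGt(gm)
      sampled$origin <- "sampled"
      ## drop sampled mutations whose footprint clashes with input variants
      if (nrow(occ)) {
        clash <- vapply(seq_len(nrow(sampled)), function(j)
          any(sampled$pos[j] < occ[, 2L] &
                sampled$pos[j] + nchar(sampled$ref[j]) > occ[, 1L]),
          logical(1))
        sampled <- sampled[!clash, , drop = FALSE]
      }
    }
  }
  muts <- rbind(inputHere[, c("pos", "ref", "alt", "gt", "origin")],
                sampled[, c("pos", "ref", "alt", "gt", "origin")])
  if (is.null(muts) || nrow(muts) == 0L)
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), gt = character(0),
                      origin = character(0), stringsAsFactors = FALSE))
  muts <- muts[order(muts$pos, muts$origin != "input-vcf"), , drop = FALSE]
  ## resolve residual sampled-vs-sampled overlaps: the later one loses
  keep <- rep(TRUE, nrow(muts))
  lastEnd <- -1
  for (j in seq_len(nrow(muts))) {
    if (muts$pos[j] < lastEnd && muts$origin[j] != "input-vcf") {
      keep[j] <- FALSE
    } else lastEnd <- max(lastEnd, muts$pos[j] + nchar(muts$ref[j]))
  }
  muts[keep, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Golden-output writers
## ---------------------------------------------------------------------------

#' Write a golden VCF
#'
#' VCF 4.1 with contig headers and a single sample carrying phased GT
#' fields (one allele per haplotype copy). Records are sorted by contig
#' (reference order) then position.
#'
#' @param variants data.frame `contig`, `pos` (0-based), `ref`, `alt`, `gt`.
#' @param ref reference DNAStringSet (for contig headers and ordering).
#' @param path output path.
#' @param sampleName sample column name.
#' @export
writeGoldenVcf <- function(variants, ref, path, sampleName = "SIMULATED") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.1",
               "##source=verisim",
               paste0("##contig=<ID=", names(ref), ",length=",
                      Biostrings::width(ref), ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleName, sep = "\t")), con)
  if (nrow(variants)) {
    ord <- order(match(variants$contig, names(ref)), variants$pos)
    v <- variants[ord, , drop = FALSE]
    writeLines(paste(v$contig, v$pos + 1L, ".", v$ref, v$alt, ".", "PASS",
                     ".", "GT", v$gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a golden (or any simple) VCF into a variant table
#'
#' @param path VCF path.
#' @return data.frame `contig`, `pos` (0-based), `ref`, `alt`, `gt`.
#' @export
readGoldenVcf <- function(path) readVcfRecords(path)

writeFastqBlock <- function(con, names, seqs, quals, mate = NULL) {
  suffix <- if (is.null(mate)) "" else paste0("/", mate)
  writeLines(as.vector(rbind(paste0("@", names, suffix), seqs, "+", quals)),
             con)
}

## ---------------------------------------------------------------------------
## The simulator
## ---------------------------------------------------------------------------

#' Simulate sequencing reads with golden truth
#'
#' Works through the reference in sliding windows: builds `ploidy` haplotype
#' copies per window, inserts input-VCF variants verbatim and then sampled
#' mutations, samples fragments to hit the requested depth (modulated by GC
#' bias and the target track), draws quality strings from the Markov chain,
#' applies sequencing errors, and emits FASTQ reads plus golden SAM
#' alignments and a golden VCF. Fully deterministic for a fixed seed.
#'
#' @param ref reference DNAStringSet (or FASTA path).
#' @param outputPrefix path prefix for
#'   `\{prefix\}_read1.fq`, `\{prefix\}_read2.fq`, `\{prefix\}_golden.sam`,
#'   `\{prefix\}_golden.vcf`.
#' @param config \linkS4class{SimConfig}.
#' @param mutationModel \linkS4class{MutationModel}.
#' @param sequencingModel \linkS4class{SequencingModel} (default model if
#'   NULL).
#' @param targetTrack optional target \linkS4class{RegionTrack}.
#' @param mutationRateTrack optional mutation-rate \linkS4class{RegionTrack}.
#' @param inputVcf optional VCF whose variants are inserted verbatim (they
#'   win any conflict with sampled mutations).
#' @param readNamePrefix prefix for encoded read names (no `:`).
#' @return invisibly, a list with the output `paths`, `nFragments`,
#'   `nReads`, the golden `variants` table, and (on request) `haplotypes`
#'   (stitched window cores per contig and copy), `reads` (per-read truth
#'   table) and `errors` (introduced sequencing errors).
#' @export
simulateReads <- function(ref, outputPrefix, config = simConfig(),
                          mutationModel = defaultMutationModel(),
                          sequencingModel = NULL, targetTrack = NULL,
                          mutationRateTrack = NULL, inputVcf = NULL,
                          readNamePrefix = "verisim") {
  if (is.character(ref)) ref <- readReference(ref)
  if (grepl(":", readNamePrefix, fixed = TRUE))
    stop("readNamePrefix must not contain ':'")
  if (any(grepl(":", names(ref), fixed = TRUE)))
    stop("contig names must not contain ':'")
  if (!is.na(config@seed)) set.seed(as.integer(config@seed))
  rl <- config@readLength
  ploidy <- config@ploidy
  paired <- config@paired
  if (is.null(sequencingModel)) sequencingModel <- defaultSequencingModel(rl)
  qmF <- sequencingModel@qualityFwd
  qmR <- sequencingModel@qualityRev %||% qmF
  errm <- sequencingModel@error
  if (!is.na(config@errorRate))
    errm@errorScale <- errorScaleForRate(config@errorRate, qmF, rl)
  mm <- mutationModel
  if (!is.na(config@mutationRate))
    mm <- rescaleMutationRate(mm, config@mutationRate)
  doErrors <- config@writeFastq && errm@errorScale > 0
  margin <- if (doErrors && errm@typeFractions[["del"]] > 0) 12L else 0L

  inputMuts <- NULL
  if (!is.null(inputVcf)) {
    inputMuts <- readVcfRecords(inputVcf)
    bad <- !inputMuts$contig %in% names(ref)
    if (any(bad))
      stop("input VCF contig absent from reference: ",
           paste(unique(inputMuts$contig[bad]), collapse = ", "))
    obs <- as.character(Biostrings::subseq(ref[inputMuts$contig],
                                           start = inputMuts$pos + 1L,
                                           width = nchar(inputMuts$ref)))
    if (any(obs != inputMuts$ref))
      stop("input VCF REF mismatch at ",
           sum(obs != inputMuts$ref), " record(s); first: ",
           inputMuts$contig[obs != inputMuts$ref][1L], ":",
           inputMuts$pos[obs != inputMuts$ref][1L] + 1L)
    gtOk <- !is.na(inputMuts$gt) &
      lengths(strsplit(inputMuts$gt, "[|/]")) == ploidy
    if (any(!gtOk)) {
      gm <- assignGenotype(sum(!gtOk), ploidy, config@hetFraction)
      inputMuts$gt[!gtOk] <- matrixToGt(gm)
    }
    inputMuts$gt <- gsub("/", "|", inputMuts$gt, fixed = TRUE)
    inputMuts$origin <- "input-vcf"
  }

  windows <- tileWindows(ref, config@windowSize, config@windowOverlap)
  samPath <- paste0(outputPrefix, "_golden.sam")
  vcfPath <- paste0(outputPrefix, "_golden.vcf")
  fq1Path <- paste0(outputPrefix, "_read1.fq")
  fq2Path <- paste0(outputPrefix, "_read2.fq")
  conSam <- file(samPath, "w")
  on.exit(close(conSam), add = TRUE)
  writeLines(samHeader(ref, "coordinate"), conSam)
  conF1 <- conF2 <- NULL
  if (config@writeFastq) {
    conF1 <- file(fq1Path, "w")
    on.exit(close(conF1), add = TRUE)
    if (paired) {
      conF2 <- file(fq2Path, "w")
      on.exit(close(conF2), add = TRUE)
    }
  }

  hapAcc <- if (config@keepHaplotypes)
    lapply(setNames(names(ref), names(ref)),
           function(x) vector("list", 0L)) else NULL
  readAcc <- list(); errAcc <- list()
  serial <- 0L
  nFragments <- 0L

  ## pass 1: sample all mutations, per window core (so that pass 2 can
  ## apply every mutation anchored anywhere in a window's span, keeping the
  ## overlap regions of adjacent windows identical)
  allVariants <- list()
  for (wi in seq_len(nrow(windows))) {
    contig <- windows$contig[wi]
    wstart <- windows$start[wi]
    wseq <- as.character(Biostrings::subseq(ref[[contig]], wstart + 1L,
                                            windows$end[wi]))
    inputHere <- if (!is.null(inputMuts)) {
      sel <- inputMuts$contig == contig & inputMuts$pos >= wstart &
        inputMuts$pos < windows$coreEnd[wi]
      inputMuts[sel, , drop = FALSE]
    } else NULL
    muts <- buildWindowMutations(contig, wseq, wstart, windows$coreEnd[wi],
                                 mm, mutationRateTrack, config@hetFraction,
                                 ploidy, inputHere,
                                 headLimit = if (wstart > 0L)
                                   wstart + config@windowOverlap)
    if (nrow(muts))
      allVariants[[length(allVariants) + 1L]] <-
        cbind(data.frame(contig = contig, stringsAsFactors = FALSE), muts)
  }
  variants <- if (length(allVariants)) do.call(rbind, allVariants) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gt = character(0), origin = character(0),
               stringsAsFactors = FALSE)

  ## pass 2: reads
  for (wi in seq_len(nrow(windows))) {
    contig <- windows$contig[wi]
    wstart <- windows$start[wi]; wend <- windows$end[wi]
    coreEnd <- windows$coreEnd[wi]
    contigSeq <- ref[[contig]]
    wseq <- as.character(Biostrings::subseq(contigSeq, wstart + 1L, wend))

    sel <- variants$contig == contig & variants$pos >= wstart &
      variants$pos < wend
    muts <- variants[sel, , drop = FALSE]
    ap <- applyMutations(wseq, wstart, muts, ploidy)

    if (config@keepHaplotypes) {
      coreHap <- vapply(seq_len(ploidy), function(h) {
        map <- ap$maps[[h]]
        hapEnd <- if (is.null(map)) coreEnd - wstart else {
          lastEnd <- map$ref0[nrow(map)] + map$len[nrow(map)]
          if (coreEnd >= lastEnd)
            nchar(ap$haps[h]) - (wend - coreEnd)
          else refToHap(map, coreEnd)
        }
        substr(ap$haps[h], 1L, hapEnd)
      }, character(1))
      hapAcc[[contig]][[length(hapAcc[[contig]]) + 1L]] <- coreHap
    }

    ## fragment planning
    plan <- planFragmentCount(contigSeq, contig, wstart, coreEnd, config,
                              sequencingModel@gcBias, targetTrack)
    if (plan$expected <= 0) next
    nFrag <- rpois(1L, plan$expected)
    if (nFrag == 0L) next
    coreLen <- coreEnd - wstart
    span <- wend - wstart
    flen <- if (paired)
      pmin(sampleFragmentLengths(sequencingModel@fragment, nFrag, rl), span)
    else rep(rl, nFrag)
    starts <- wstart +
      sample.int(coreLen, nFrag, replace = TRUE, prob = plan$weights) - 1L
    bad <- which(starts + flen > wend)
    for (j in bad) {
      maxIdx <- min(coreLen, wend - flen[j] - wstart + 1L)
      if (maxIdx < 1L) {
        starts[j] <- wstart; flen[j] <- span
      } else {
        starts[j] <- wstart +
          sample.int(maxIdx, 1L, prob = plan$weights[seq_len(maxIdx)]) - 1L
      }
    }
    copy <- sample.int(ploidy, nFrag, replace = TRUE)

    pos1 <- integer(nFrag); cigar1 <- character(nFrag)
    pos2 <- integer(nFrag); cigar2 <- character(nFrag)
    span2 <- integer(nFrag)
    seq1 <- character(nFrag); seq2 <- character(nFrag)
    for (h in seq_len(ploidy)) {
      sel <- which(copy == h)
      if (length(sel) == 0L) next
      hap <- ap$haps[h]; map <- ap$maps[[h]]
      hlen <- nchar(hap)
      hstart <- if (is.null(map)) starts[sel] - wstart
                else refToHap(map, starts[sel])
      fl <- flen[sel]
      fl <- pmin(fl, hlen - hstart)
      short <- fl < rl
      if (any(short)) {
        hstart[short] <- pmax(0L, hlen - rl)
        fl[short] <- pmin(rl, hlen - hstart[short])
      }
      seq1[sel] <- substring(hap, hstart + 1L,
                             pmin(hstart + rl + margin, hlen))
      if (paired) {
        e2 <- hstart + fl
        raw2 <- substring(hap, pmax(1L, e2 - rl - margin + 1L), e2)
        seq2[sel] <- revComp(raw2)
      }
      if (is.null(map)) {
        pos1[sel] <- starts[sel]
        cigar1[sel] <- paste0(rl, "M")
        if (paired) {
          pos2[sel] <- starts[sel] + fl - rl
          cigar2[sel] <- paste0(rl, "M")
          span2[sel] <- rl
        }
      } else {
        simple1 <- {
          i1 <- pmax(1L, findInterval(hstart, map$hap0))
          hstart >= map$hap0[i1] & hstart + rl <= map$hap0[i1] + map$len[i1]
        }
        for (k in seq_along(sel)) {
          j <- sel[k]
          if (simple1[k]) {
            i1 <- max(1L, findInterval(hstart[k], map$hap0))
            pos1[j] <- map$ref0[i1] + (hstart[k] - map$hap0[i1])
            cigar1[j] <- paste0(rl, "M")
          } else {
            bc <- buildCigarFromMap(map, hstart[k], rl)
            pos1[j] <- bc$pos; cigar1[j] <- bc$cigar
          }
          if (paired) {
            h2 <- hstart[k] + fl[k] - rl
            i2 <- max(1L, findInterval(h2, map$hap0))
            if (h2 >= map$hap0[i2] && h2 + rl <= map$hap0[i2] + map$len[i2]) {
              pos2[j] <- map$ref0[i2] + (h2 - map$hap0[i2])
              cigar2[j] <- paste0(rl, "M")
              span2[j] <- rl
            } else {
              bc2 <- buildCigarFromMap(map, h2, rl)
              pos2[j] <- bc2$pos; cigar2[j] <- bc2$cigar
              span2[j] <- bc2$refSpan
            }
          }
        }
      }
    }

    names_ <- encodeReadNames(readNamePrefix, serial + seq_len(nFrag),
                              contig, pos1 + 1L, "+", cigar1,
                              if (paired) pos2 + 1L else ".",
                              if (paired) "-" else ".",
                              if (paired) cigar2 else ".")
    serial <- serial + nFrag
    nFragments <- nFragments + nFrag

    ## qualities + errors
    if (config@writeFastq) {
      q1 <- sampleQualityStrings(qmF, nFrag, rl)
      er1 <- applySequencingErrors(seq1, q1, errm, rl)
      out1 <- er1$seqs
      qa1 <- qualsToAscii(q1)
      if (paired) {
        q2 <- sampleQualityStrings(qmR, nFrag, rl)
        er2 <- applySequencingErrors(seq2, q2, errm, rl)
        out2 <- er2$seqs
        qa2 <- qualsToAscii(q2)
      }
    } else {
      out1 <- substr(seq1, 1L, rl)
      if (paired) out2 <- substr(seq2, 1L, rl)
      er1 <- er2 <- NULL
      qa1 <- qa2 <- rep(paste(rep("I", rl), collapse = ""), nFrag)
    }

    ## emit FASTQ
    if (config@writeFastq) {
      writeFastqBlock(conF1, names_, out1, qa1, if (paired) 1L else NULL)
      if (paired) writeFastqBlock(conF2, names_, out2, qa2, 2L)
    }

    ## emit SAM (mate 2 stored in forward reference orientation)
    tags1 <- paste0("zp:i:", pos1 + 1L, "\tzs:A:+", "\tzc:Z:", cigar1,
                    "\tzh:i:", copy)
    if (paired) {
      tlen <- (pos2 + span2) - pos1
      rec1 <- paste(names_, 99L, contig, pos1 + 1L, 60L, cigar1, "=",
                    pos2 + 1L, tlen, out1, qa1, tags1, sep = "\t")
      tags2 <- paste0("zp:i:", pos2 + 1L, "\tzs:A:-", "\tzc:Z:", cigar2,
                      "\tzh:i:", copy)
      rec2 <- paste(names_, 147L, contig, pos2 + 1L, 60L, cigar2, "=",
                    pos1 + 1L, -tlen, revComp(out2),
                    reverseStrings(qa2), tags2, sep = "\t")
      writeLines(as.vector(rbind(rec1, rec2)), conSam)
    } else {
      rec1 <- paste(names_, 0L, contig, pos1 + 1L, 60L, cigar1, "*", 0L,
                    0L, out1, qa1, tags1, sep = "\t")
      writeLines(rec1, conSam)
    }

    if (config@returnReads) {
      rt <- data.frame(name = names_, contig = contig, copy = copy,
                       pos1 = pos1 + 1L, cigar1 = cigar1, seq1 = out1,
                       stringsAsFactors = FALSE)
      if (paired) {
        rt$pos2 <- pos2 + 1L; rt$cigar2 <- cigar2; rt$seq2 <- out2
      }
      readAcc[[length(readAcc) + 1L]] <- rt
      if (doErrors) {
        collectErr <- function(er, mate) {
          if (is.null(er) || nrow(er$errors) == 0L) return(NULL)
          e <- er$errors
          e$name <- names_[e$read]; e$mate <- mate
          e$read <- NULL
          e
        }
        errAcc[[length(errAcc) + 1L]] <-
          rbind(collectErr(er1, 1L), if (paired) collectErr(er2, 2L))
      }
    }
  }

  writeGoldenVcf(variants, ref, vcfPath)

  res <- list(paths = list(fastq1 = if (config@writeFastq) fq1Path,
                           fastq2 = if (config@writeFastq && paired) fq2Path,
                           sam = samPath, vcf = vcfPath),
              nFragments = nFragments,
              nReads = nFragments * (if (paired) 2L else 1L),
              variants = variants)
  if (config@keepHaplotypes)
    res$haplotypes <- lapply(hapAcc, function(parts) {
      if (length(parts) == 0L) return(character(0))
      vapply(seq_len(ploidy), function(h)
        paste(vapply(parts, `[[`, character(1), h), collapse = ""),
        character(1))
    })
  if (config@returnReads) {
    res$reads <- if (length(readAcc)) do.call(rbind, readAcc) else NULL
    res$errors <- if (length(errAcc)) do.call(rbind, errAcc) else NULL
  }
  class(res) <- "verisimSimulation"
  invisible(res)
}

#' @export
print.verisimSimulation <- function(x, ...) {
  cat("verisim simulation: ", x$nReads, " reads (", x$nFragments,
      " fragments), ", nrow(x$variants), " golden variants\n", sep = "")
  invisible(x)
}

## reverse each string in a character vector
reverseStrings <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

#' Simulate variants only (no reads)
#'
#' Runs the mutation engine over the reference and writes a golden VCF,
#' without generating any reads. Useful for mutation-model round trips.
#'
#' @param ref reference DNAStringSet.
#' @param model MutationModel.
#' @param vcfPath output VCF path (NULL to skip writing).
#' @param ploidy haplotype copies.
#' @param hetFraction heterozygous fraction.
#' @param rateTrack optional mutation-rate RegionTrack.
#' @param windowSize,windowOverlap reference tiling.
#' @param seed optional seed.
#' @return the golden variant table (data.frame).
#' @export
simulateVariants <- function(ref, model, vcfPath = NULL, ploidy = 2L,
                             hetFraction = 2 / 3, rateTrack = NULL,
                             windowSize = 10000L, windowOverlap = 100L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  windows <- tileWindows(ref, windowSize, windowOverlap)
  out <- list()
  for (wi in seq_len(nrow(windows))) {
    contig <- windows$contig[wi]
    wstart <- windows$start[wi]
    wseq <- as.character(Biostrings::subseq(ref[[contig]], wstart + 1L,
                                            windows$end[wi]))
    muts <- buildWindowMutations(contig, wseq, wstart, windows$coreEnd[wi],
                                 model, rateTrack, hetFraction, ploidy,
                                 NULL, headLimit = if (wstart > 0L)
                                   wstart + windowOverlap)
    if (nrow(muts))
      out[[length(out) + 1L]] <-
        cbind(data.frame(contig = contig, stringsAsFactors = FALSE), muts)
  }
  variants <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gt = character(0), origin = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(vcfPath)) writeGoldenVcf(variants, ref, vcfPath)
  variants
}
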