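## Sequencing-error sub-model: learning from alignments and application to
## simulated reads.

#' Construct an ErrorModel
#'
#' @param errorScale multiplier on the Phred-implied per-base error
#'   probability.
#' @param typeFractions named numeric `c(sub=, ins=, del=)`.
#' @param subMatrix 4x4 row-stochastic substitution matrix (rows = true
#'   base), zero diagonal.
#' @param indelLengths named distribution over indel-error lengths.
#' @param insBases named distribution over inserted bases (ACGT).
#' @return an \linkS4class{ErrorModel}.
#' @export
ErrorModel <- function(errorScale = 1,
                       typeFractions = c(sub = 0.99, ins = 0.005, del = 0.005),
                       subMatrix = NULL, indelLengths = NULL,
                       insBases = NULL) {
  if (is.null(subMatrix)) subMatrix <- uniformAltMatrix()
  if (is.null(indelLengths))
    indelLengths <- setNames(c(0.7, 0.15, 0.1, 0.05), 1:4)
  if (is.null(insBases)) insBases <- setNames(rep(0.25, 4), DNA_BASES)
  methods::new("ErrorModel", errorScale = errorScale,
               typeFractions = typeFractions[c("sub", "ins", "del")],
               subMatrix = subMatrix, indelLengths = indelLengths,
               insBases = insBases)
}

#' Default error model
#'
#' Substitution-dominated (as for Illumina chemistry), uniform substitution
#' targets, short geometric-tailed indels; scale 1 (errors exactly at the
#' Phred-implied rate).
#'
#' @return an \linkS4class{ErrorModel}.
#' @export
defaultErrorModel <- function() ErrorModel()

#' Error scale for a requested mean error rate
#'
#' @param rate requested mean per-base error rate.
#' @param qualityModel the QualityModel whose strings will carry the errors.
#' @param readLength simulated read length.
#' @return scalar multiplier such that the mean of
#'   `min(1, scale * 10^(-Q/10))` over simulated bases equals `rate`.
#' @export
errorScaleForRate <- function(rate, qualityModel, readLength = NULL) {
  stopifnot(rate >= 0)
  if (rate == 0) return(0)
  rate / expectedPhredErrorProb(qualityModel, readLength)
}

#' Apply sequencing errors to reads
#'
#' Per-position Bernoulli draws at `min(1, scale * 10^(-Q/10))`; error type,
#' substituted base, indel length and inserted bases follow the model's
#' distributions. Deletions pull downstream bases in (the sequence may carry
#' margin bases beyond `readLength` for this purpose); insertions push them
#' out; the result is re-truncated to `readLength`, padding with random
#' bases if the margin is exhausted. Indel likelihood is uniform along the
#' read. The sampled quality string is unchanged: per-cycle qualities belong
#' to the machine cycle, not the base identity.
#'
#' @param seqs character vector of read sequences (possibly with margin
#'   bases beyond `readLength`).
#' @param quals integer matrix `n x readLength` of Phred scores.
#' @param model ErrorModel.
#' @param readLength output read length (default `ncol(quals)`).
#' @return list with `seqs` (errored, truncated to `readLength`) and
#'   `errors`, a data.frame (`read`, `pos` 0-based read offset, `type`,
#'   `before`, `after`).
#' @export
applySequencingErrors <- function(seqs, quals, model,
                                  readLength = ncol(quals)) {
  n <- length(seqs)
  empty <- data.frame(read = integer(0), pos = integer(0),
                      type = character(0), before = character(0),
                      after = character(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(seqs = character(0), errors = empty))
  if (model@errorScale <= 0)
    return(list(seqs = substr(seqs, 1L, readLength), errors = empty))
  p <- qualityToErrorProb(quals, model@errorScale)
  hit <- matrix(runif(n * readLength) < p[, seq_len(readLength)], n)
  nHit <- rowSums(hit)
  outSeqs <- substr(seqs, 1L, readLength)
  errRows <- list()
  for (i in which(nHit > 0L)) {
    s <- seqs[i]
    positions <- which(hit[i, ])   # 1-based read offsets, pre-error coords
    shift <- 0L                    # net coordinate shift from earlier indels
    for (p0 in positions) {
      pos <- p0 + shift
      if (pos < 1L || pos > nchar(s)) next
      type <- c("sub", "ins", "del")[sampleRows(rbind(model@typeFractions), 1L)]
      base <- substr(s, pos, pos)
      if (type == "sub") {
        if (!base %in% DNA_BASES) next
        alt <- sample(DNA_BASES, 1L, prob = model@subMatrix[base, ])
        substr(s, pos, pos) <- alt
        errRows[[length(errRows) + 1L]] <-
          list(i, p0 - 1L, "sub", base, alt)
      } else if (type == "ins") {
        len <- as.integer(sample(names(model@indelLengths), 1L,
                                 prob = model@indelLengths))
        ins <- paste(sample(DNA_BASES, len, replace = TRUE,
                            prob = model@insBases), collapse = "")
        s <- paste0(substr(s, 1L, pos), ins, substr(s, pos + 1L, nchar(s)))
        shift <- shift + len
        errRows[[length(errRows) + 1L]] <-
          list(i, p0 - 1L, "ins", "", ins)
      } else {
        len <- as.integer(sample(names(model@indelLengths), 1L,
                                 prob = model@indelLengths))
        len <- min(len, nchar(s) - pos)
        if (len < 1L) next
        del <- substr(s, pos + 1L, pos + len)
        s <- paste0(substr(s, 1L, pos), substr(s, pos + len + 1L, nchar(s)))
        shift <- shift - len
        errRows[[length(errRows) + 1L]] <-
          list(i, p0 - 1L, "del", del, "")
      }
    }
    if (nchar(s) < readLength)
      s <- paste0(s, paste(sample(DNA_BASES, readLength - nchar(s),
                                  replace = TRUE), collapse = ""))
    outSeqs[i] <- substr(s, 1L, readLength)
  }
  errors <- if (length(errRows)) {
    m <- do.call(rbind, errRows)
    data.frame(read = unlist(m[, 1L]), pos = unlist(m[, 2L]),
               type = unlist(m[, 3L]), before = unlist(m[, 4L]),
               after = unlist(m[, 5L]), stringsAsFactors = FALSE)
  } else empty
  list(seqs = outSeqs, errors = errors)
}

## ---------------------------------------------------------------------------
## Learning from alignments
## ---------------------------------------------------------------------------

#' Learn an error model from a SAM alignment
#'
#' A read position is counted as a sequencing error iff it is a mismatch or
#' an indel of at most `maxIndelLen` bases, the site's variant allele
#' frequency is below `vafThreshold`, the base quality is below
#' `qThreshold`, the read's mapping quality is above `mapqThreshold`, and it
#' is not part of a larger event (adjacent to another mismatch or indel in
#' the same read). Qualifying events fill the type fractions, substitution
#' matrix, indel length and inserted-base distributions; the error scale is
#' fitted so that the Phred-implied expectation under the observed quality
#' profile reproduces the observed error rate.
#'
#' @param samPath SAM text file.
#' @param ref reference DNAStringSet.
#' @param qThreshold count only bases with quality strictly below this
#'   (default 10).
#' @param vafThreshold count only sites with VAF strictly below this
#'   (default 0.2).
#' @param mapqThreshold count only reads with MAPQ strictly above this
#'   (default 10).
#' @param maxIndelLen longest indel treated as a sequencing error (default 4).
#' @return an \linkS4class{ErrorModel}; if no qualifying errors are found,
#'   the default model is returned with a warning.
#' @export
learnErrorModel <- function(samPath, ref, qThreshold = 10L,
                            vafThreshold = 0.2, mapqThreshold = 10L,
                            maxIndelLen = 4L) {
  sam <- readSam(samPath)
  rec <- sam$records
  rec <- rec[!bitwAnd(rec$flag, 4L) & rec$cigar != "*" &
               rec$rname %in% names(ref), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no aligned reads in ", samPath)

  nOps <- vapply(rec$cigar, function(cg) length(parseCigar(cg)$op),
                 integer(1), USE.NAMES = FALSE)
  pureM <- nOps == 1L & grepl("^[0-9]+M$", rec$cigar)

  totalBases <- 0
  phredSum <- 0
  evList <- list()

  ## fast path: pure-M reads, compared base-by-base over concatenated
  ## strings (one raw-vector comparison for the whole file)
  for (cn in unique(rec$rname)) {
    sel <- which(pureM & rec$rname == cn)
    if (length(sel) == 0L) next
    rl <- nchar(rec$seq[sel])
    refStr <- as.character(ref[[cn]])
    refSl <- substring(refStr, rec$pos[sel], rec$pos[sel] + rl - 1L)
    a <- charToRaw(paste(rec$seq[sel], collapse = ""))
    b <- charToRaw(paste(refSl, collapse = ""))
    q <- as.integer(charToRaw(paste(rec$qual[sel], collapse = ""))) - 33L
    totalBases <- totalBases + length(a)
    phredSum <- phredSum + sum(10^(-q / 10))
    mism <- which(a != b)
    if (length(mism)) {
      cs <- cumsum(c(0L, rl))
      ri <- findInterval(mism - 1L, cs)   # read index within sel
      off <- mism - cs[ri]                # 1-based offset in read
      evList[[length(evList) + 1L]] <- data.frame(
        contig = cn, refpos = rec$pos[sel][ri] + off - 1L, type = "sub",
        refbase = rawToChar(b[mism], multiple = TRUE),
        readbase = rawToChar(a[mism], multiple = TRUE),
        q = q[mism], len = 1L, mapq = rec$mapq[sel][ri],
        read = sel[ri], stringsAsFactors = FALSE)
    }
  }

  ## slow path: reads with indels/clips
  for (i in which(!pureM)) {
    ops <- parseCigar(rec$cigar[i])
    cn <- rec$rname[i]
    refseq <- ref[[cn]]
    rpos <- rec$pos[i]; qpos <- 1L
    readSeq <- rec$seq[i]
    readQ <- as.integer(charToRaw(rec$qual[i])) - 33L
    ev <- list()
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        rs <- as.character(Biostrings::subseq(refseq, rpos, rpos + len - 1L))
        qs <- substr(readSeq, qpos, qpos + len - 1L)
        mism <- which(charToRaw(rs) != charToRaw(qs))
        for (m in mism)
          ev[[length(ev) + 1L]] <- list(rpos + m - 1L, "sub",
                                        substr(rs, m, m), substr(qs, m, m),
                                        readQ[qpos + m - 1L], 1L)
        totalBases <- totalBases + len
        phredSum <- phredSum + sum(10^(-readQ[qpos:(qpos + len - 1L)] / 10))
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        ev[[length(ev) + 1L]] <- list(rpos, "ins", "",
                                      substr(readSeq, qpos, qpos + len - 1L),
                                      readQ[qpos], len)
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        ev[[length(ev) + 1L]] <- list(rpos, "del",
          as.character(Biostrings::subseq(refseq, rpos, rpos + len - 1L)),
          "", readQ[min(qpos, length(readQ))], len)
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
    }
    if (length(ev)) {
      m <- do.call(rbind, ev)
      evList[[length(evList) + 1L]] <- data.frame(
        contig = cn, refpos = unlist(m[, 1L]), type = unlist(m[, 2L]),
        refbase = unlist(m[, 3L]), readbase = unlist(m[, 4L]),
        q = unlist(m[, 5L]), len = unlist(m[, 6L]), mapq = rec$mapq[i],
        read = i, stringsAsFactors = FALSE)
    }
  }

  useDefault <- function(msg) {
    warning("no qualifying sequencing errors in ", samPath, " (", msg,
            "); returning the default error model")
    defaultErrorModel()
  }
  if (length(evList) == 0L) return(useDefault("no mismatches"))
  ev <- do.call(rbind, evList)

  ## per-site depth (M spans; pure-M fast path + refSpan for the rest)
  depth <- lapply(setNames(names(ref), names(ref)), function(cn) {
    sel <- rec$rname == cn
    if (!any(sel)) return(integer(0))
    L <- length(ref[[cn]])
    starts <- rec$pos[sel]
    ends <- pmin(starts + cigarRefSpan(rec$cigar[sel]) - 1L, L)
    cumsum(tabulate(starts, L) - tabulate(ends + 1L, L))
  })

  ev$siteDepth <- vapply(seq_len(nrow(ev)), function(j) {
    d <- depth[[ev$contig[j]]]
    if (ev$refpos[j] <= length(d)) d[ev$refpos[j]] else 0L
  }, numeric(1))
  key <- paste(ev$contig, ev$refpos, ev$type, ev$readbase, ev$refbase)
  altCount <- table(key)
  ev$vaf <- as.numeric(altCount[key]) / pmax(ev$siteDepth, 1)

  ## larger-event exclusion: adjacent to another event in the same read
  ord <- order(ev$read, ev$refpos)
  ev <- ev[ord, , drop = FALSE]
  adj <- rep(FALSE, nrow(ev))
  if (nrow(ev) > 1L) {
    sameRead <- ev$read[-1L] == ev$read[-nrow(ev)]
    close <- abs(ev$refpos[-1L] - ev$refpos[-nrow(ev)]) <= 1L
    adj[-1L] <- adj[-1L] | (sameRead & close)
    adj[-nrow(ev)] <- adj[-nrow(ev)] | (sameRead & close)
  }
  keep <- ev$vaf < vafThreshold & ev$q < qThreshold &
    ev$mapq > mapqThreshold & ev$len <= maxIndelLen & !adj
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(useDefault("all events filtered"))

  tf <- normalizeProbs(c(sub = sum(ev$type == "sub"),
                         ins = sum(ev$type == "ins"),
                         del = sum(ev$type == "del")))
  sm <- uniformAltMatrix()
  subs <- ev[ev$type == "sub", , drop = FALSE]
  if (nrow(subs)) {
    t <- table(factor(subs$refbase, DNA_BASES),
               factor(subs$readbase, DNA_BASES))
    for (b in DNA_BASES) {
      row <- as.numeric(t[b, ]); row[DNA_BASES == b] <- 0
      if (sum(row) > 0) sm[b, ] <- row / sum(row)
    }
  }
  indel <- ev[ev$type != "sub", , drop = FALSE]
  il <- if (nrow(indel)) {
    t <- table(indel$len); setNames(as.numeric(t) / sum(t), names(t))
  } else NULL
  ib <- if (any(ev$type == "ins")) {
    bases <- unlist(strsplit(ev$readbase[ev$type == "ins"], ""))
    normalizeProbs(table(factor(bases, DNA_BASES)))
  } else NULL
  obsRate <- nrow(ev) / max(totalBases, 1)
  expRate <- phredSum / max(totalBases, 1)
  ErrorModel(errorScale = obsRate / max(expRate, 1e-12),
             typeFractions = tf, subMatrix = sm,
             indelLengths = il %||% setNames(c(0.7, 0.15, 0.1, 0.05), 1:4),
             insBases = if (is.null(ib)) setNames(rep(0.25, 4), DNA_BASES)
                        else setNames(as.numeric(ib), DNA_BASES))
}
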