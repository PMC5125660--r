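## GC-bias and fragment-length sub-models.

#' Learn GC coverage bias
#'
#' Slides non-overlapping windows of `windowSize` bases along the reference,
#' records each window's GC count and mean coverage, bins by integer GC
#' count, and divides each bin's mean coverage by the overall mean to yield
#' multipliers. Empty bins are interpolated from their neighbors;
#' multipliers are capped and then renormalized so the abundance-weighted
#' mean is exactly 1.
#'
#' @param coverage either a named list of per-contig numeric coverage
#'   vectors, or a SAM path from which coverage is computed.
#' @param ref reference DNAStringSet.
#' @param windowSize GC window size in bases (>= 10; default 100).
#' @param maxMultiplier cap on any single multiplier (default 5).
#' @return a \linkS4class{GcBiasModel}.
#' @export
learnGcBias <- function(coverage, ref, windowSize = 100L, maxMultiplier = 5) {
  stopifnot(windowSize >= 10L)
  if (is.character(coverage)) coverage <- samCoverage(coverage, ref)
  gcCount <- integer(0); covMean <- numeric(0)
  for (cn in names(ref)) {
    L <- length(ref[[cn]])
    nw <- L %/% windowSize
    if (nw == 0L) next
    starts <- (seq_len(nw) - 1L) * windowSize + 1L
    v <- Biostrings::Views(ref[[cn]], start = starts,
                           width = windowSize)
    gc <- Biostrings::letterFrequency(v, "GC")
    cv <- coverage[[cn]]
    if (length(cv) < nw * windowSize) cv <- c(cv, rep(0, nw * windowSize - length(cv)))
    cm <- colMeans(matrix(cv[seq_len(nw * windowSize)], nrow = windowSize))
    gcCount <- c(gcCount, as.integer(gc))
    covMean <- c(covMean, cm)
  }
  if (length(gcCount) == 0L) stop("reference shorter than one GC window")
  overall <- mean(covMean)
  if (overall <= 0) stop("alignment has zero coverage")
  bins <- 0:windowSize
  mult <- rep(NA_real_, windowSize + 1L)
  abun <- numeric(windowSize + 1L)
  for (g in bins) {
    sel <- gcCount == g
    abun[g + 1L] <- sum(sel)
    if (any(sel)) mult[g + 1L] <- mean(covMean[sel]) / overall
  }
  obs <- which(!is.na(mult))
  mult <- approx(bins[obs], mult[obs], xout = bins, rule = 2)$y
  mult <- pmin(mult, maxMultiplier)
  wm <- weighted.mean(mult, abun)
  mult <- mult / wm
  methods::new("GcBiasModel", windowSize = as.integer(windowSize),
               multipliers = mult, abundance = abun)
}

## per-position GC multiplier over a reference interval (0-based half-open),
## constant within each non-overlapping GC window of the contig
gcWeights <- function(gcBias, refseq, start, end) {
  if (is.null(gcBias)) return(rep(1, end - start))
  ws <- gcBias@windowSize
  wFirst <- start %/% ws
  wLast <- (end - 1L) %/% ws
  L <- length(refseq)
  mult <- vapply(wFirst:wLast, function(w) {
    a <- w * ws + 1L; b <- min((w + 1L) * ws, L)
    gc <- as.integer(Biostrings::letterFrequency(
      Biostrings::subseq(refseq, a, b), "GC"))
    ## partial terminal window: scale GC count to the full window size
    if (b - a + 1L < ws) gc <- as.integer(round(gc * ws / (b - a + 1L)))
    gcBias@multipliers[min(gc, ws) + 1L]
  }, numeric(1))
  out <- rep(mult, each = ws)
  off <- start - wFirst * ws
  out[(off + 1L):(off + end - start)]
}

#' Gaussian fragment model
#'
#' Fallback insert-size model for when no alignment is available to learn
#' from.
#'
#' @param mean,sd mean and standard deviation of the template length.
#' @return a \linkS4class{FragmentModel}.
#' @export
gaussianFragmentModel <- function(mean = 300, sd = 30) {
  methods::new("FragmentModel", kind = "gaussian", support = integer(0),
               probs = numeric(0), mean = mean, sd = sd)
}

#' Empirical fragment model
#'
#' @param support template lengths.
#' @param probs probabilities (normalized internally).
#' @return a \linkS4class{FragmentModel}.
#' @export
empiricalFragmentModel <- function(support, probs) {
  o <- order(support)
  methods::new("FragmentModel", kind = "empirical",
               support = as.integer(support[o]),
               probs = normalizeProbs(probs[o]), mean = NA_real_,
               sd = NA_real_)
}

#' Learn a fragment-length model from paired alignments
#'
#' Histograms |TLEN| of the leftmost mate of each pair (records with
#' positive template length); zero or absurd values (above `cap`) are
#' skipped.
#'
#' @param samPath SAM text file with paired alignments.
#' @param cap longest credible template length (default 2000).
#' @return an empirical \linkS4class{FragmentModel}.
#' @export
learnFragmentModel <- function(samPath, cap = 2000L) {
  sam <- readSam(samPath)
  tl <- sam$records$tlen
  tl <- tl[tl > 0L & tl <= cap]
  if (length(tl) == 0L) stop("no usable paired template lengths in ", samPath)
  t <- table(tl)
  empiricalFragmentModel(as.integer(names(t)), as.numeric(t))
}

#' Sample fragment lengths
#'
#' @param model FragmentModel.
#' @param n number of draws.
#' @param minLength smallest admissible fragment (the read length).
#' @return integer vector of length n.
#' @export
sampleFragmentLengths <- function(model, n, minLength = 1L) {
  if (n == 0L) return(integer(0))
  if (model@kind == "empirical") {
    f <- sample.int(length(model@support), n, replace = TRUE,
                    prob = model@probs)
    pmax(model@support[f], as.integer(minLength))
  } else {
    pmax(as.integer(round(rnorm(n, model@mean, model@sd))),
         as.integer(minLength))
  }
}
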