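## Position-dependent Markov chain over Phred quality scores.

#' Construct a QualityModel
#'
#' @param initDist distribution of the position-1 score (length qMax+1).
#' @param transitions array `c(L, qMax+1, qMax+1)`; slice p holds
#'   P(Q at p | Q at p-1). Rows that sum to zero are treated as unobserved
#'   and fall back to uniform at sampling time.
#' @param qMax highest quality score.
#' @return a \linkS4class{QualityModel}.
#' @export
QualityModel <- function(initDist, transitions, qMax = 41L) {
  methods::new("QualityModel", readLength = dim(transitions)[1L],
               qMax = as.integer(qMax), initDist = initDist,
               transitions = transitions)
}

#' Default quality model
#'
#' A synthetic but realistic Illumina-like profile: scores start around
#' Q37, decay slowly toward the 3' end, and are autocorrelated along the
#' read (next score regresses toward the positional mean with Gaussian
#' spread). Used when no FASTQ has been learned from.
#'
#' @param readLength model read length.
#' @param qMax highest quality score (41 for Phred+33).
#' @param startMean,endMean positional mean quality at the first and last
#'   cycle.
#' @param sd within-position Gaussian spread.
#' @param ar regression weight toward the previous score.
#' @return a \linkS4class{QualityModel}.
#' @export
defaultQualityModel <- function(readLength = 100L, qMax = 41L,
                                startMean = 37, endMean = 28, sd = 2.5,
                                ar = 0.6) {
  L <- as.integer(readLength); q1 <- qMax + 1L
  qv <- 0:qMax
  posMean <- startMean - (startMean - endMean) * ((seq_len(L) - 1) /
                                                  max(1L, L - 1L))^1.5
  disc <- function(mu) normalizeProbs(dnorm(qv, mu, sd))
  init <- disc(posMean[1])
  tr <- array(0, dim = c(L, q1, q1))
  for (p in seq_len(L)[-1L]) {
    mu <- ar * qv + (1 - ar) * posMean[p]
    for (qp in seq_len(q1))
      tr[p, qp, ] <- disc(mu[qp])
  }
  QualityModel(initDist = init, transitions = tr, qMax = qMax)
}

#' Learn a quality model from FASTQ
#'
#' The initial distribution comes from position-1 scores and each
#' transition row is the observed frequency of score changes at that
#' position: `transitions[P, Q', Q] = count(Q' -> Q at P) / count(Q' at
#' P-1)`. Reads shorter than the modal length are skipped and counted.
#'
#' @param fastqPath Phred+33 FASTQ path.
#' @param qMax highest quality score (default 41).
#' @return a \linkS4class{QualityModel} with attribute `"nSkipped"`.
#' @export
learnQualityModel <- function(fastqPath, qMax = 41L) {
  ## (suppress Biostrings' note about dropped FASTQ metadata columns)
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(fastqPath),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(qs) == 0L) stop("empty FASTQ: ", fastqPath)
  widths <- Biostrings::width(qs)
  L <- as.integer(names(sort(table(widths), decreasing = TRUE))[1L])
  keep <- widths == L
  nSkipped <- sum(!keep)
  qm <- matrix(unlist(as(Biostrings::quality(qs[keep]), "IntegerList"),
                      use.names = FALSE), ncol = L, byrow = TRUE)
  if (any(qm < 0L) || any(qm > qMax))
    stop("quality scores outside [0, ", qMax, "] in ", fastqPath)
  q1 <- qMax + 1L
  init <- normalizeProbs(tabulate(qm[, 1L] + 1L, q1))
  tr <- array(0, dim = c(L, q1, q1))
  for (p in seq_len(L)[-1L]) {
    idx <- qm[, p - 1L] * q1 + qm[, p] + 1L
    cnt <- matrix(tabulate(idx, q1 * q1), q1, q1, byrow = TRUE)
    rs <- rowSums(cnt)
    nz <- rs > 0
    cnt[nz, ] <- cnt[nz, ] / rs[nz]
    tr[p, , ] <- cnt
  }
  model <- QualityModel(initDist = init, transitions = tr,
                        qMax = as.integer(qMax))
  attr(model, "nSkipped") <- nSkipped
  model
}

## map target read positions onto model positions (linear stretch)
mapQualityPositions <- function(modelLength, targetLength) {
  if (targetLength == 1L) return(1L)
  p <- seq_len(targetLength)
  m <- round(1 + (p - 1) * (modelLength - 1) / (targetLength - 1))
  as.integer(pmin(pmax(m, 1L), modelLength))
}

## cumulative transition matrices with uniform fallback applied to
## unobserved rows, for the model positions actually used
prepareQualitySampler <- function(model, targetLength) {
  q1 <- model@qMax + 1L
  mp <- mapQualityPositions(model@readLength, targetLength)
  usedPos <- unique(mp[-1L])
  usedPos <- pmax(usedPos, 2L)   # position 1 has no transition slice
  cums <- vector("list", model@readLength)
  for (p in usedPos) {
    m <- model@transitions[p, , ]
    rs <- rowSums(m)
    if (any(rs <= 0)) m[rs <= 0, ] <- 1 / q1
    m <- m / rowSums(m)
    cums[[p]] <- t(apply(m, 1L, cumsum))
  }
  list(map = mp, cums = cums,
       initCum = cumsum(normalizeProbs(model@initDist)))
}

#' Sample quality strings
#'
#' Samples the Markov chain; reads of a length different from the model's
#' map each target position onto model position
#' `round(1 + (p-1)(L-1)/(targetLength-1))`, so learned profiles stretch to
#' arbitrary simulated read lengths.
#'
#' @param model QualityModel.
#' @param n number of strings.
#' @param targetLength read length to generate (default: model length).
#' @return integer matrix `n x targetLength` of Phred values.
#' @export
sampleQualityStrings <- function(model, n, targetLength = NULL) {
  targetLength <- as.integer(targetLength %||% model@readLength)
  stopifnot(targetLength >= 1L, n >= 0L)
  out <- matrix(0L, n, targetLength)
  if (n == 0L) return(out)
  sp <- prepareQualitySampler(model, targetLength)
  cur <- findInterval(runif(n), sp$initCum) # values 0..qMax
  out[, 1L] <- cur
  if (targetLength > 1L) for (p in 2L:targetLength) {
    mpos <- max(sp$map[p], 2L)
    cm <- sp$cums[[mpos]]
    r <- cm[cur + 1L, , drop = FALSE]
    cur <- as.integer(rowSums(r < runif(n)))
    out[, p] <- cur
  }
  out
}

#' Phred-implied error probability
#'
#' `min(1, errorScale * 10^(-Q/10))`: the Phred assumption with a single
#' scale factor reconciling it against a requested mean error rate.
#'
#' @param q quality scores.
#' @param errorScale non-negative multiplier.
#' @return error probabilities.
#' @export
qualityToErrorProb <- function(q, errorScale = 1) {
  stopifnot(all(q >= 0), errorScale >= 0)
  p <- errorScale * 10^(-q / 10)
  p[p > 1] <- 1    # (pmin would drop matrix dimensions)
  p
}

#' Expected Phred error probability under a quality model
#'
#' Propagates the chain's marginal distributions analytically and returns
#' the mean over positions of `E[10^(-Q/10)]`; used to convert a requested
#' mean error rate into an error scale.
#'
#' @param model QualityModel.
#' @param targetLength simulated read length (default model length).
#' @return scalar expected per-base Phred-implied error probability.
#' @export
expectedPhredErrorProb <- function(model, targetLength = NULL) {
  targetLength <- as.integer(targetLength %||% model@readLength)
  q1 <- model@qMax + 1L
  phred <- 10^(-(0:model@qMax) / 10)
  mp <- mapQualityPositions(model@readLength, targetLength)
  marg <- normalizeProbs(model@initDist)
  acc <- sum(marg * phred)
  if (targetLength > 1L) for (p in 2L:targetLength) {
    m <- model@transitions[max(mp[p], 2L), , ]
    rs <- rowSums(m)
    if (any(rs <= 0)) m[rs <= 0, ] <- 1 / q1
    m <- m / rowSums(m)
    marg <- as.numeric(marg %*% m)
    acc <- acc + sum(marg * phred)
  }
  acc / targetLength
}

## per-position marginal mean quality (used in round-trip checks)
qualityMarginalMeans <- function(model, targetLength = NULL) {
  targetLength <- as.integer(targetLength %||% model@readLength)
  q1 <- model@qMax + 1L
  qv <- 0:model@qMax
  mp <- mapQualityPositions(model@readLength, targetLength)
  marg <- normalizeProbs(model@initDist)
  out <- numeric(targetLength)
  out[1L] <- sum(marg * qv)
  if (targetLength > 1L) for (p in 2L:targetLength) {
    m <- model@transitions[max(mp[p], 2L), , ]
    rs <- rowSums(m)
    if (any(rs <= 0)) m[rs <= 0, ] <- 1 / q1
    m <- m / rowSums(m)
    marg <- as.numeric(marg %*% m)
    out[p] <- sum(marg * qv)
  }
  out
}
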