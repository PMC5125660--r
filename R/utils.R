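#' @importFrom stats runif rnorm rpois dnorm approx setNames weighted.mean
#' @importFrom utils read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stochastic rounding
#'
#' Rounds a non-negative expectation to an integer without bias: the floor is
#' kept and the fractional part becomes one extra count with matching
#' probability, so small windows are not systematically shorted.
#'
#' @param x numeric vector of non-negative expectations.
#' @return integer vector with `E[result] == x` elementwise.
#' @export
stochasticRound <- function(x) {
  stopifnot(all(x >= 0))
  fl <- floor(x)
  as.integer(fl + (runif(length(x)) < (x - fl)))
}

## reverse complement on plain character vectors (empty strings allowed)
revComp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- NULL
  out
}

## Phred integer matrix -> vector of ASCII(+33) strings, one per row
qualsToAscii <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  n <- nrow(q)
  if (n == 0L) return(character(0))
  long <- rawToChar(as.raw(as.integer(t(q)) + 33L))
  L <- ncol(q)
  substring(long, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

## ASCII(+33) strings (equal length) -> integer matrix of Phred values
asciiToQuals <- function(s) {
  L <- unique(nchar(s))
  stopifnot(length(L) == 1L)
  m <- matrix(as.integer(charToRaw(paste(s, collapse = ""))) - 33L,
              ncol = L, byrow = TRUE)
  m
}

## normalize a non-negative vector to a probability vector; zero-sum input
## returns the fallback (uniform unless given)
normalizeProbs <- function(x, fallback = NULL) {
  s <- sum(x)
  if (s <= 0) {
    if (is.null(fallback)) fallback <- rep(1 / length(x), length(x))
    fb <- fallback
    names(fb) <- names(x)
    return(fb)
  }
  x / s
}

## draw one index per row of a probability matrix (rows need not be visited
## equally); vectorized inverse-CDF
sampleRows <- function(probMatrix, rows, u = runif(length(rows))) {
  cm <- t(apply(probMatrix, 1L, cumsum))
  r <- cm[rows, , drop = FALSE]
  as.integer(rowSums(r < u) + 1L)
}

## split "0|1|0" genotype strings into an n x ploidy 0/1 integer matrix
gtToMatrix <- function(gt, ploidy) {
  if (length(gt) == 0L) return(matrix(integer(0), 0L, ploidy))
  parts <- strsplit(gt, "[|/]")
  m <- matrix(0L, length(gt), ploidy)
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.integer(parts[[i]]))
    v[is.na(v)] <- 0L
    if (length(v) < ploidy) v <- c(v, rep(0L, ploidy - length(v)))
    m[i, ] <- as.integer(v[seq_len(ploidy)] > 0L)
  }
  m
}

matrixToGt <- function(m) {
  apply(m, 1L, function(r) paste(r, collapse = "|"))
}

## trinucleotide context label "X_Z"
contextLabel <- function(before, after) paste0(before, "_", after)

## all 64 trinucleotides, lexicographic (matches Biostrings count order)
allTrinucs <- function() {
  b <- DNA_BASES
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}
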