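## Golden-truth reconstruction: rebuild the error-free read sequences from
## golden positions/CIGARs against haplotypes derived from the golden VCF.
## This is the consistency oracle for the simulator: with errors off, every
## emitted read must equal its reconstruction; with errors on, the recorded
## error list reconciles the two.

leadingSoftClip <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- parseCigar(cg)
    if (length(ops$op) && ops$op[1L] == "S") ops$len[1L] else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Reconstruct error-free reads from golden truth
#'
#' Applies the golden variants to the reference to rebuild the haplotypes,
#' then extracts each read's sequence from its haplotype copy at the
#' position implied by its golden coordinates. Returns what the simulator
#' must have emitted before sequencing errors.
#'
#' @param reads per-read truth table as returned by
#'   \code{\link{simulateReads}} with `returnReads = TRUE` (columns
#'   `contig`, `copy`, `pos1`, `cigar1` and, if paired, `pos2`, `cigar2`).
#' @param ref reference DNAStringSet.
#' @param variants golden variant table (`contig`, `pos` 0-based, `ref`,
#'   `alt`, `gt`).
#' @param ploidy haplotype copies.
#' @param readLength read length.
#' @return list with `exp1` and (when mate-2 columns are present) `exp2`:
#'   expected read sequences in read orientation.
#' @export
reconstructGoldenReads <- function(reads, ref, variants, ploidy,
                                   readLength) {
  n <- nrow(reads)
  exp1 <- character(n)
  paired <- !is.null(reads$pos2)
  exp2 <- if (paired) character(n)
  for (cn in unique(reads$contig)) {
    v <- variants[variants$contig == cn, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    ap <- applyMutations(as.character(ref[[cn]]), 0L, v, ploidy)
    for (h in seq_len(ploidy)) {
      sel <- which(reads$contig == cn & reads$copy == h)
      if (length(sel) == 0L) next
      hap <- ap$haps[h]; map <- ap$maps[[h]]
      toHap <- function(pos1based) {
        p0 <- pos1based - 1L
        if (is.null(map)) p0 else refToHap(map, p0)
      }
      h1 <- toHap(reads$pos1[sel]) - leadingSoftClip(reads$cigar1[sel])
      exp1[sel] <- substring(hap, h1 + 1L, h1 + readLength)
      if (paired) {
        h2 <- toHap(reads$pos2[sel]) - leadingSoftClip(reads$cigar2[sel])
        exp2[sel] <- revComp(substring(hap, h2 + 1L, h2 + readLength))
      }
    }
  }
  if (paired) list(exp1 = exp1, exp2 = exp2) else list(exp1 = exp1)
}
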