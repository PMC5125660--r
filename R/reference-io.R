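#' Read a reference genome from FASTA
#'
#' Sequences are uppercased, the contig name is the header token before the
#' first whitespace, and only the characters A, C, G, T, N (either case) are
#' accepted. Plain and gzip-compressed FASTA are supported.
#'
#' @param path path to a FASTA file with at least one record.
#' @return a \link[Biostrings]{DNAStringSet}, one element per contig.
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  if (length(ref) == 0L) stop("FASTA contains no records: ", path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (any(names(ref) == "")) stop("empty contig name in ", path)
  if (anyDuplicated(names(ref))) stop("duplicate contig names in ", path)
  bad <- Biostrings::letterFrequency(ref, "ACGTN")
  if (any(bad < Biostrings::width(ref)))
    stop("reference contains characters outside {A,C,G,T,N}")
  ref
}

#' Write a reference to FASTA
#'
#' @param ref DNAStringSet.
#' @param path output path.
#' @export
writeReference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, path)
  invisible(path)
}

#' Generate a random reference genome
#'
#' Bases are i.i.d. with P(G) + P(C) = `gcFraction`, split evenly within the
#' GC and AT pairs. Deterministic for a fixed seed.
#'
#' @param nContigs number of contigs.
#' @param length length of each contig (>= 3).
#' @param gcFraction GC content in [0, 1].
#' @param seed optional integer seed.
#' @return DNAStringSet named `contig1..contigN`.
#' @export
randomReference <- function(nContigs = 1L, length = 10000L, gcFraction = 0.5,
                            seed = NULL) {
  stopifnot(length >= 3L, gcFraction >= 0, gcFraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  seqs <- vapply(seq_len(nContigs), function(i)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = ""),
    character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("contig", seq_len(nContigs))
  ref
}

#' Trinucleotide census of a reference
#'
#' Counts every length-3 window over {A,C,G,T}; windows containing N are
#' skipped (N has no trinucleotide context).
#'
#' @param ref DNAStringSet.
#' @return named integer vector over the 64 trinucleotides.
#' @export
trinucCensus <- function(ref) {
  counts <- Biostrings::trinucleotideFrequency(ref)
  if (is.matrix(counts)) counts <- colSums(counts)
  storage.mode(counts) <- "integer"
  counts[allTrinucs()]
}

#' Tile a reference into sliding windows
#'
#' Windows of `windowSize` bases step by `windowSize - overlap`, so
#' consecutive windows share `overlap` bases; the final window is clamped to
#' the contig end, and contigs shorter than a window yield a single
#' whole-contig window. Each window owns a non-overlapping "core"
#' (`[start, coreEnd)`), the tail `overlap` bases belonging to the next
#' window's core; cores partition the contig.
#'
#' @param ref DNAStringSet (only the lengths and names are used).
#' @param windowSize window size in bases (> 2*overlap).
#' @param overlap shared bases between consecutive windows (> 0).
#' @return data.frame with columns `contig`, `start`, `end`, `coreEnd`
#'   (0-based half-open).
#' @export
tileWindows <- function(ref, windowSize = 10000L, overlap = 100L) {
  stopifnot(windowSize > 2L * overlap, overlap > 0L)
  out <- list()
  for (ci in seq_along(ref)) {
    len <- Biostrings::width(ref)[ci]
    s <- 0L
    starts <- integer(0); ends <- integer(0)
    repeat {
      e <- min(s + windowSize, len)
      starts <- c(starts, s); ends <- c(ends, e)
      if (e >= len) break
      s <- e - overlap
    }
    core <- c(if (length(starts) > 1L) starts[-1L], len)
    out[[ci]] <- data.frame(contig = names(ref)[ci], start = starts,
                            end = ends, coreEnd = core,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Construct a RegionTrack
#'
#' @param contig,start,end interval coordinates, 0-based half-open.
#' @param value per-interval scalar (mutation rate, or 1 for targets).
#' @param semantics `"target"` or `"mutation-rate"`.
#' @param onReference optional logical flag per interval.
#' @return a \linkS4class{RegionTrack}; overlaps are normalized (maximum
#'   value wins).
#' @export
regionTrack <- function(contig, start, end, value = 1,
                        semantics = c("target", "mutation-rate"),
                        onReference = TRUE) {
  semantics <- match.arg(semantics)
  stopifnot(all(start < end), all(value >= 0))
  gr <- GenomicRanges::GRanges(contig,
          IRanges::IRanges(start = start + 1L, end = end))
  gr$value <- rep_len(as.numeric(value), length(gr))
  gr$onReference <- rep_len(onReference, length(gr))
  gr <- normalizeTrackRegions(gr)
  methods::new("RegionTrack", regions = gr, semantics = semantics)
}

## disjoin overlapping intervals; the maximum value wins on overlap
normalizeTrackRegions <- function(gr) {
  if (length(gr) < 2L) return(sort(gr))
  dj <- GenomicRanges::disjoin(gr, with.revmap = TRUE)
  rv <- dj$revmap
  dj$value <- vapply(seq_along(dj),
                     function(i) max(gr$value[rv[[i]]]), numeric(1))
  dj$onReference <- vapply(seq_along(dj),
                           function(i) all(gr$onReference[rv[[i]]]), logical(1))
  dj$revmap <- NULL
  sort(dj)
}

#' Read a BED file into a RegionTrack
#'
#' Expects >= 3 tab-separated columns (contig, 0-based start, end). For
#' mutation-rate semantics the 4th column is the per-base rate; for target
#' semantics a missing 4th column defaults to value 1. Records on contigs
#' absent from `reference` are retained but flagged (`onReference == FALSE`).
#'
#' @param path BED file path.
#' @param semantics `"target"` or `"mutation-rate"`.
#' @param reference optional DNAStringSet used to flag unknown contigs.
#' @return a \linkS4class{RegionTrack}.
#' @export
readBedTrack <- function(path, semantics = c("target", "mutation-rate"),
                         reference = NULL) {
  semantics <- match.arg(semantics)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  start <- suppressWarnings(as.integer(df[[2L]]))
  end <- suppressWarnings(as.integer(df[[3L]]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates in ", path)
  if (any(start >= end)) stop("BED interval with start >= end in ", path)
  if (ncol(df) >= 4L && semantics == "mutation-rate") {
    value <- suppressWarnings(as.numeric(df[[4L]]))
    if (anyNA(value)) stop("non-numeric value column in ", path)
  } else value <- rep(1, nrow(df))
  onRef <- if (is.null(reference)) TRUE else df[[1L]] %in% names(reference)
  regionTrack(df[[1L]], start, end, value, semantics, onReference = onRef)
}

#' Per-position track values over an interval
#'
#' @param track RegionTrack or NULL.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param default value assigned to positions not covered by the track.
#' @return numeric vector of length `end - start`.
#' @export
trackValues <- function(track, contig, start, end, default = 0) {
  out <- rep(default, end - start)
  if (is.null(track)) return(out)
  gr <- track@regions
  sel <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  if (length(sel) == 0L) return(out)
  s0 <- GenomicRanges::start(sel) - 1L  # back to 0-based
  e0 <- GenomicRanges::end(sel)
  for (i in seq_along(sel)) {
    a <- max(s0[i], start); b <- min(e0[i], end)
    if (a < b) out[(a - start + 1L):(b - start)] <- sel$value[i]
  }
  out
}
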