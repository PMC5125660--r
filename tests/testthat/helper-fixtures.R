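## Fixture builders: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

makeRef <- function(...) {
  seqs <- c(...)
  ref <- Biostrings::DNAStringSet(unname(seqs))
  names(ref) <- if (is.null(names(seqs)))
    paste0("c", seq_along(seqs)) else names(seqs)
  ref
}

writeTestVcf <- function(df, path, sample = "S1") {
  con <- file(path, "w")
  on.exit(close(con))
  hasGt <- !is.null(df$gt)
  hdr <- c("##fileformat=VCFv4.1",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (hasGt) c("FORMAT", sample)), collapse = "\t"))
  writeLines(hdr, con)
  if (nrow(df)) {
    body <- paste(df$contig, df$pos + 1L, ".", df$ref, df$alt, ".", "PASS",
                  ".", sep = "\t")
    if (hasGt) body <- paste(body, "GT", df$gt, sep = "\t")
    writeLines(body, con)
  }
  path
}

## quals: single string reused, or a character vector (one per read)
writeTestFastq <- function(seqs, quals, path, names = NULL) {
  if (is.null(names)) names <- paste0("r", seq_along(seqs))
  quals <- rep_len(quals, length(seqs))
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), path)
  path
}

writeTestSam <- function(ref, rec, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
  body <- paste(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq,
                rec$cigar, rec$rnext, rec$pnext, rec$tlen, rec$seq,
                rec$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

## brute-force trinucleotide counter (oracle for the census)
bruteTrinuc <- function(seqs) {
  out <- setNames(rep(0L, 64), verisim:::allTrinucs())
  for (s in seqs) {
    if (nchar(s) < 3L) next
    for (i in seq_len(nchar(s) - 2L)) {
      w <- substr(s, i, i + 2L)
      if (grepl("^[ACGT]{3}$", w)) out[w] <- out[w] + 1L
    }
  }
  out
}

## total variation distance between two (possibly differently keyed)
## discrete distributions
tvDist <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- p[keys]; qv <- q[keys]
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  0.5 * sum(abs(pv - qv))
}

## random sequence string
randSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
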