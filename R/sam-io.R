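## Minimal SAM text reader/writer. The package's alignment contract is SAM
## text (BAM conversion is external tooling); records are plain
## tab-separated fields, parsed without any binary machinery.

#' Read a SAM text file
#'
#' @param path SAM file.
#' @return list with `header` (character vector of `@` lines) and `records`,
#'   a data.frame of the 11 mandatory fields plus `tags` (remaining fields,
#'   tab-joined).
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  isHeader <- startsWith(lines, "@")
  header <- lines[isHeader]
  body <- lines[!isHeader & nzchar(lines)]
  if (length(body) == 0L)
    return(list(header = header,
                records = data.frame(qname = character(0), flag = integer(0),
                                     rname = character(0), pos = integer(0),
                                     mapq = integer(0), cigar = character(0),
                                     rnext = character(0), pnext = integer(0),
                                     tlen = integer(0), seq = character(0),
                                     qual = character(0), tags = character(0),
                                     stringsAsFactors = FALSE)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) stop("truncated SAM record in ", path)
  f <- function(i) vapply(parts, `[[`, character(1), i)
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else "",
    character(1))
  list(header = header,
       records = data.frame(qname = f(1), flag = as.integer(f(2)),
                            rname = f(3), pos = as.integer(f(4)),
                            mapq = as.integer(f(5)), cigar = f(6),
                            rnext = f(7), pnext = as.integer(f(8)),
                            tlen = as.integer(f(9)), seq = f(10),
                            qual = f(11), tags = tags,
                            stringsAsFactors = FALSE))
}

## parse one CIGAR string into op/len vectors
parseCigar <- function(cigar) {
  if (cigar == "*") return(list(op = character(0), len = integer(0)))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

## reference-consuming span of each CIGAR (vectorized)
cigarRefSpan <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- parseCigar(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## read-consuming length of each CIGAR (vectorized)
cigarReadLen <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- parseCigar(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## merge adjacent same-op runs; equate H with S ("10S90M" == "10H90M")
normalizeCigar <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- parseCigar(cg)
    if (length(ops$op) == 0L) return("*")
    op <- ops$op; op[op == "H"] <- "S"; op[op %in% c("=", "X")] <- "M"
    len <- ops$len
    keep <- len > 0L
    op <- op[keep]; len <- len[keep]
    if (length(op) > 1L) {
      grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
      len <- as.integer(tapply(len, grp, sum))
      op <- op[!duplicated(grp)]
    }
    paste0(len, op, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## SAM header for a reference
samHeader <- function(ref, sortOrder = "unknown") {
  c(paste0("@HD\tVN:1.6\tSO:", sortOrder),
    paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)),
    "@PG\tID:verisim\tPN:verisim")
}

## coverage per contig from a SAM (CIGAR-aware: M/D/N span the reference)
samCoverage <- function(samPath, ref) {
  sam <- readSam(samPath)
  rec <- sam$records
  rec <- rec[!bitwAnd(rec$flag, 4L) & rec$cigar != "*", , drop = FALSE]
  out <- lapply(setNames(names(ref), names(ref)), function(cn) {
    L <- length(ref[[cn]])
    d <- numeric(L + 1L)
    sel <- rec$rname == cn
    if (any(sel)) {
      s <- rec$pos[sel]
      e <- s + cigarRefSpan(rec$cigar[sel]) - 1L
      e <- pmin(e, L)
      for (j in seq_along(s)) {
        d[s[j]] <- d[s[j]] + 1
        d[e[j] + 1L] <- d[e[j] + 1L] - 1
      }
    }
    cumsum(d)[seq_len(L)]
  })
  out
}
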