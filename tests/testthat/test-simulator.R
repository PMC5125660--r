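test_that("null-model single-end reads are exact reference substrings", {
  ref <- randomReference(1, 30000, seed = 30)
  out <- tempfile()
  res <- simulateReads(ref, out,
                       simConfig(coverage = 5, paired = FALSE,
                                 mutationRate = 0, errorRate = 0, seed = 1))
  sam <- readSam(res$paths$sam)
  rec <- sam$records
  expect_gt(nrow(rec), 100L)
  expect_true(all(rec$flag == 0L))
  expect_true(all(rec$cigar == "100M"))
  s <- as.character(ref[[1]])
  expect_identical(rec$seq, substring(s, rec$pos, rec$pos + 99L))
  ## FASTQ qualities stay within the Phred+33 band of the model
  fq <- readLines(res$paths$fastq1)
  qchars <- unlist(strsplit(fq[seq(4, length(fq), by = 4)], ""))
  expect_true(all(utf8ToInt(paste(qchars, collapse = "")) -
                    33L <= qMax(defaultQualityModel())))
})

test_that("identical seeds give byte-identical outputs", {
  ref <- randomReference(1, 20000, seed = 8)
  outs <- replicate(2, {
    o <- tempfile()
    simulateReads(ref, o, simConfig(coverage = 4, seed = 77,
                                    mutationRate = 0.002))
    o
  })
  for (suffix in c("_read1.fq", "_read2.fq", "_golden.sam", "_golden.vcf"))
    expect_identical(unname(tools::md5sum(paste0(outs[1], suffix))),
                     unname(tools::md5sum(paste0(outs[2], suffix))))
})

test_that("fragment planning yields the arithmetic expectation", {
  ref <- randomReference(1, 10000, seed = 2)
  cfg <- simConfig(readLength = 100L, coverage = 20, paired = TRUE)
  plan <- planFragmentCount(ref[[1]], "contig1", 0L, 10000L, cfg)
  expect_equal(plan$expected, 1000)
  expect_equal(plan$weights, rep(1, 10000))
  ## a window entirely off-target runs at the off-target fraction
  tr <- regionTrack("contig1", 90000L, 95000L, 1, "target")
  plan2 <- planFragmentCount(ref[[1]], "contig1", 0L, 10000L, cfg,
                             targetTrack = tr)
  expect_equal(plan2$expected, 20)
  ## N runs start nothing
  refN <- makeRef(c(n1 = paste0(randSeq(500), strrep("N", 200),
                                randSeq(300))))
  plan3 <- planFragmentCount(refN[[1]], "n1", 0L, 1000L, cfg)
  expect_equal(plan3$weights[501:700], rep(0, 200))
})

test_that("golden CIGARs follow the coordinate map", {
  s <- randSeq(300)
  ## no variants: plain match
  expect_equal(buildCigarFromMap(NULL, 17L, 100L),
               list(pos = 17L, cigar = "100M", refSpan = 100L))
  ## 3-base deletion after 10 read bases
  del <- data.frame(pos = 59L, ref = substr(s, 60, 63),
                    alt = substr(s, 60, 60), gt = "1")
  mapD <- applyMutations(s, 0L, del, 1L)$maps[[1]]
  expect_equal(buildCigarFromMap(mapD, 50L, 100L)$cigar, "10M3D90M")
  ## 2-base insertion after 10 read bases
  ins <- data.frame(pos = 59L, ref = substr(s, 60, 60),
                    alt = paste0(substr(s, 60, 60), "CA"), gt = "1")
  mapI <- applyMutations(s, 0L, ins, 1L)$maps[[1]]
  bc <- buildCigarFromMap(mapI, 50L, 100L)
  expect_equal(bc$cigar, "10M2I88M")
  expect_equal(bc$pos, 50L)
  expect_equal(bc$refSpan, 98L)
  ## a read starting inside the insertion is soft-clipped at its head
  bc2 <- buildCigarFromMap(mapI, 61L, 50L)
  expect_equal(bc2$cigar, "1S49M")
})

test_that("paired reads have FR orientation and SAM-consistent TLEN", {
  ref <- randomReference(1, 20000, seed = 3)
  out <- tempfile()
  res <- simulateReads(ref, out,
                       simConfig(coverage = 4, mutationRate = 0,
                                 errorRate = 0, seed = 5),
                       sequencingModel = sequencingModel(
                         fragment = gaussianFragmentModel(250, 10)))
  rec <- readSam(res$paths$sam)$records
  m1 <- rec[bitwAnd(rec$flag, 64L) > 0L, ]
  m2 <- rec[bitwAnd(rec$flag, 128L) > 0L, ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  expect_true(all(m1$flag == 99L) && all(m2$flag == 147L))
  expect_equal(m1$tlen, (m2$pos + 100L) - m1$pos)
  expect_equal(m1$tlen, -m2$tlen)
  expect_equal(m1$pnext, m2$pos)
  s <- as.character(ref[[1]])
  ## mate 1 forward, mate 2 stored reverse-complemented in reference
  ## orientation: both are reference substrings in an error-free run
  expect_identical(m1$seq, substring(s, m1$pos, m1$pos + 99L))
  expect_identical(m2$seq, substring(s, m2$pos, m2$pos + 99L))
  ## fully-overlapping mates when the fragment equals the read length
  res2 <- simulateReads(ref, tempfile(),
                        simConfig(coverage = 2, mutationRate = 0,
                                  errorRate = 0, seed = 6),
                        sequencingModel = sequencingModel(
                          fragment = gaussianFragmentModel(100, 0)))
  rec2 <- readSam(res2$paths$sam)$records
  p1 <- rec2[bitwAnd(rec2$flag, 64L) > 0L, ]
  p2 <- rec2[bitwAnd(rec2$flag, 128L) > 0L, ]
  p2 <- p2[match(p1$qname, p2$qname), ]
  expect_equal(p1$pos, p2$pos)
})

test_that("read names decode to the golden truth", {
  nm <- encodeReadNames("sim", 1:2, "ctg-7", c(100L, 200L), "+", "100M",
                        c(350L, 450L), "-", "90M10S")
  d <- decodeReadNames(paste0(nm, c("/1", "/2")))
  expect_true(all(d$ok))
  expect_equal(d$contig, rep("ctg-7", 2))
  expect_equal(d$pos1, c(100L, 200L))
  expect_equal(d$cigar2, rep("90M10S", 2))
  bad <- decodeReadNames("someRandomName")
  expect_false(bad$ok)
})

test_that("golden VCF writing round-trips and encodes ploidy", {
  ref <- makeRef(c(a = randSeq(500), b = randSeq(300)))
  v <- data.frame(contig = c("b", "a", "a"), pos = c(10L, 99L, 5L),
                  ref = c("A", "C", "G"), alt = c("T", "CAT", "G"),
                  gt = c("0|1", "1|1", "0|1"))
  p <- tempfile(fileext = ".vcf")
  writeGoldenVcf(v, ref, p)
  back <- readGoldenVcf(p)
  ## sorted by reference contig order then position
  expect_equal(back$contig, c("a", "a", "b"))
  expect_equal(back$pos, c(5L, 99L, 10L))
  expect_equal(back$gt, c("0|1", "1|1", "0|1"))
  expect_equal(back$ref, c("G", "C", "A"))
})

test_that("a tetraploid single-copy variant serializes as 0|1|0|0-style GT", {
  set.seed(40)
  ref <- randomReference(1, 15000, seed = 40)
  v <- simulateVariants(ref, defaultMutationModel(rate = 0.003), ploidy = 4L,
                        hetFraction = 1, seed = 41)
  expect_gt(nrow(v), 10L)
  parts <- strsplit(v$gt, "|", fixed = TRUE)
  expect_true(all(lengths(parts) == 4L))
  expect_true(all(vapply(parts, function(x) sum(x == "1"), integer(1)) == 1L))
  ## the default simulated ploidy is 2
  expect_equal(simConfig()@ploidy, 2L)
})

test_that("input VCF variants are inserted verbatim and win conflicts", {
  ref <- randomReference(1, 20000, seed = 15)
  s <- as.character(ref[[1]])
  iv <- data.frame(contig = "contig1", pos = c(5000L, 9000L),
                   ref = c(substr(s, 5001, 5001), substr(s, 9001, 9004)),
                   alt = c("A", substr(s, 9001, 9001)), gt = c("0|1", "1|1"))
  iv$alt[1] <- setdiff(c("A", "C", "G", "T"), iv$ref[1])[1]
  ivPath <- writeTestVcf(iv, tempfile(fileext = ".vcf"))
  out <- tempfile()
  res <- simulateReads(ref, out, simConfig(coverage = 3, mutationRate = 0.001,
                                           errorRate = 0, seed = 16),
                       inputVcf = ivPath)
  v <- res$variants
  got <- v[v$origin == "input-vcf", c("pos", "ref", "alt", "gt")]
  expect_equal(got$pos, iv$pos)
  expect_equal(got$ref, iv$ref)
  expect_equal(got$alt, iv$alt)
  expect_equal(got$gt, iv$gt)
  ## golden VCF includes them verbatim too
  back <- readGoldenVcf(res$paths$vcf)
  expect_true(all(paste(iv$pos, iv$ref, iv$alt) %in%
                    paste(back$pos, back$ref, back$alt)))
  ## and a reference mismatch aborts
  ivBad <- iv; ivBad$ref[1] <- "NOPE"
  expect_error(simulateReads(ref, tempfile(), simConfig(coverage = 1),
                             inputVcf = writeTestVcf(ivBad, tempfile())),
               "mismatch")
})

test_that("a heterozygous site is supported by about half the reads", {
  ref <- randomReference(1, 12000, seed = 18)
  s <- as.character(ref[[1]])
  pos0 <- 6000L
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, pos0 + 1L, pos0 + 1L))[1]
  iv <- writeTestVcf(data.frame(contig = "contig1", pos = pos0,
                                ref = substr(s, pos0 + 1L, pos0 + 1L),
                                alt = alt, gt = "0|1"),
                     tempfile(fileext = ".vcf"))
  out <- tempfile()
  res <- simulateReads(ref, out, simConfig(coverage = 150, mutationRate = 0,
                                           errorRate = 0, seed = 19),
                       inputVcf = iv)
  rec <- readSam(res$paths$sam)$records
  covers <- rec$pos <= pos0 + 1L & rec$pos + 99L >= pos0 + 1L &
    rec$cigar == "100M"
  rec <- rec[covers, ]
  base <- substr(rec$seq, pos0 + 2L - rec$pos, pos0 + 2L - rec$pos)
  expect_gt(nrow(rec), 100L)
  frac <- mean(base == alt)
  expect_gt(frac, 0.5 - 3 * 0.5 / sqrt(nrow(rec)))
  expect_lt(frac, 0.5 + 3 * 0.5 / sqrt(nrow(rec)))
})

test_that("realized coverage matches the request and avoids N runs", {
  ref <- makeRef(c(g = paste0(randSeq(20000), strrep("N", 1500),
                              randSeq(20000))))
  out <- tempfile()
  res <- simulateReads(ref, out, simConfig(coverage = 20, mutationRate = 0,
                                           errorRate = 0, seed = 20,
                                           writeFastq = FALSE))
  rec <- readSam(res$paths$sam)$records
  ## no fragment starts inside the N run
  expect_false(any(rec$pos > 20000L & rec$pos <= 21500L &
                     bitwAnd(rec$flag, 64L) > 0L))
  ## aligned bases / callable length = requested coverage within 5%
  cov <- nrow(rec) * 100 / 40000
  expect_lt(abs(cov - 20) / 20, 0.05)
  ## golden VCF never mutates N positions
  expect_true(all(substr(res$variants$ref, 1, 1) %in% c("A", "C", "G", "T")))
})

test_that("mutation-rate tracks steer sites into their intervals", {
  ref <- randomReference(1, 30000, seed = 22)
  tr <- regionTrack("contig1", 12000L, 12010L, 1.0, "mutation-rate")
  m <- defaultMutationModel()
  m@typeFractions <- c(sub = 1, ins = 0, del = 0)
  v <- simulateVariants(ref, m, rateTrack = tr, seed = 23)
  expect_gt(nrow(v), 5L)
  expect_true(all(v$pos >= 12000L & v$pos < 12010L))
})

test_that("golden reads reconstruct from the golden truth (with indels)", {
  ref <- randomReference(1, 40000, seed = 25)
  out <- tempfile()
  res <- simulateReads(ref, out,
                       simConfig(coverage = 10, mutationRate = 0.01,
                                 errorRate = 0, seed = 26,
                                 returnReads = TRUE, keepHaplotypes = TRUE))
  v <- res$variants
  expect_gt(sum(nchar(v$ref) > 1 | nchar(v$alt) > 1), 5L)  # indels present
  rec <- reconstructGoldenReads(res$reads, ref, v, 2L, 100L)
  expect_identical(res$reads$seq1, rec$exp1)
  expect_identical(res$reads$seq2, rec$exp2)
  ## the stitched internal haplotypes equal the VCF applied to the reference
  expect_identical(res$haplotypes$contig1,
                   buildHaplotypes(ref, v, 2L)$contig1)
  ## no two golden variants overlap in reference coordinates
  v <- v[order(v$pos), ]
  expect_true(all(v$pos[-1L] >= head(v$pos + nchar(v$ref), -1L)))
})

test_that("recorded sequencing errors reconcile reads with haplotypes", {
  ref <- randomReference(1, 20000, seed = 27)
  out <- tempfile()
  res <- simulateReads(ref, out,
                       simConfig(coverage = 8, mutationRate = 0,
                                 errorRate = 0.02, seed = 28,
                                 returnReads = TRUE))
  rec <- reconstructGoldenReads(res$reads, ref, res$variants, 2L, 100L)
  clean1 <- res$reads$seq1 == rec$exp1
  err1 <- res$errors[res$errors$mate == 1L, ]
  ## every read that differs from its reconstruction has a recorded error
  expect_true(all(res$reads$name[!clean1] %in% err1$name))
  expect_gt(sum(!clean1), 0L)
  ## single-substitution reads: recorded before/after match the sequences
  solo <- names(which(table(err1$name) == 1L))
  subs <- err1[err1$type == "sub" & err1$name %in% solo, ]
  i <- match(subs$name, res$reads$name)
  expect_identical(substr(rec$exp1[i], subs$pos + 1L, subs$pos + 1L),
                   subs$before)
  expect_identical(substr(res$reads$seq1[i], subs$pos + 1L, subs$pos + 1L),
                   subs$after)
})
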