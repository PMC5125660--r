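## one shared small simulation for the evaluation tests
evalFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- randomReference(1, 40000, seed = 50)
      out <- tempfile()
      res <- simulateReads(ref, out,
                           simConfig(coverage = 12, mutationRate = 0.002,
                                     errorRate = 0, seed = 51,
                                     writeFastq = FALSE))
      cache <<- list(ref = ref, out = out, res = res,
                     sam = res$paths$sam, vcf = res$paths$vcf)
    }
    cache
  }
})

test_that("self-comparison scores perfectly", {
  fx <- evalFixture()
  rep <- compareAlignments(fx$sam)
  expect_equal(rep@nCorrectPosition, rep@nReads)
  expect_equal(rep@nCorrectCigar, rep@nReads)
  expect_equal(rep@nUnmapped, 0L)
  expect_equal(rep@nUnknown, 0L)
  vrep <- compareVcfs(fx$vcf, fx$vcf, fx$ref)
  expect_equal(vrep@FP, 0L)
  expect_equal(vrep@FN, 0L)
  expect_equal(vrep@TP, vrep@nGolden)
  expect_equal(vrep@genotypeConcordance, 1)
})

test_that("known perturbations are recovered exactly", {
  fx <- evalFixture()
  lines <- readLines(fx$sam)
  body <- which(!startsWith(lines, "@"))
  set.seed(52)
  hit <- sample(body, 10)
  perturbed <- lines
  for (i in hit) {
    f <- strsplit(perturbed[i], "\t", fixed = TRUE)[[1]]
    f[4] <- as.character(as.integer(f[4]) + 7L)
    perturbed[i] <- paste(f, collapse = "\t")
  }
  testSam <- tempfile(fileext = ".sam")
  writeLines(perturbed, testSam)
  rep <- compareAlignments(testSam)
  expect_equal(rep@nReads - rep@nCorrectPosition, 10L)
  expect_equal(rep@nReads - rep@nCorrectCigar, 10L)
  expect_equal(nrow(rep@mismatches), 10L)
  ## within tolerance the perturbed positions pass again
  expect_equal(compareAlignments(testSam, posTolerance = 7L)@nCorrectPosition,
               rep@nReads)

  ## drop 10 variants from the test VCF: exactly 10 FN
  g <- readGoldenVcf(fx$vcf)
  expect_gt(nrow(g), 30L)
  set.seed(53)
  drop <- sample(nrow(g), 10)
  testVcf <- writeTestVcf(g[-drop, ], tempfile(fileext = ".vcf"))
  vrep <- compareVcfs(fx$vcf, testVcf, fx$ref)
  expect_equal(vrep@FN, 10L)
  expect_equal(vrep@FP, 0L)
  expect_equal(vrep@TP, nrow(g) - 10L)
  expect_equal(sort(vrep@fnRecords$pos), sort(g$pos[drop]))
  ## and 5 invented variants: exactly 5 FP
  fake <- data.frame(contig = "contig1", pos = c(11L, 222L, 3333L, 40L, 55L),
                     ref = "A", alt = "T", gt = "0|1")
  s <- as.character(fx$ref[[1]])
  fake$ref <- substring(s, fake$pos + 1L, fake$pos + 1L)
  fake$alt <- vapply(fake$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  fake <- fake[!paste(fake$pos, fake$ref) %in% paste(g$pos, g$ref), ]
  testVcf2 <- writeTestVcf(rbind(g, fake), tempfile(fileext = ".vcf"))
  vrep2 <- compareVcfs(fx$vcf, testVcf2, fx$ref)
  expect_equal(vrep2@FP, nrow(fake))
  expect_equal(vrep2@FN, 0L)
})

test_that("FP/FN residues are written as parseable VCFs", {
  fx <- evalFixture()
  g <- readGoldenVcf(fx$vcf)
  testVcf <- writeTestVcf(g[-(1:3), ], tempfile(fileext = ".vcf"))
  pre <- tempfile()
  vrep <- compareVcfs(fx$vcf, testVcf, fx$ref, outPrefix = pre)
  fn <- readGoldenVcf(paste0(pre, "_FN.vcf"))
  expect_equal(nrow(fn), 3L)
  expect_equal(sort(fn$pos), sort(g$pos[1:3]))
  expect_equal(nrow(readGoldenVcf(paste0(pre, "_FP.vcf"))), 0L)
})

test_that("equivalent representations are detected by haplotype identity", {
  ## the same single-A deletion written as TAA->TA and as TA->T
  ga <- data.frame(pos = 1L, ref = "TAA", alt = "TA")
  gb <- data.frame(pos = 1L, ref = "TA", alt = "T")
  expect_true(equivalentVariantGroups(ga, gb, "TTAAC", 0L))
  expect_true(equivalentVariantGroups(
    data.frame(pos = 2L, ref = "AA", alt = "A"),
    data.frame(pos = 3L, ref = "AA", alt = "A"), "TTAAACG", 0L))
  expect_false(equivalentVariantGroups(
    data.frame(pos = 2L, ref = "A", alt = "C"),
    data.frame(pos = 2L, ref = "A", alt = "G"), "TTAAACG", 0L))
  ## an identical SNP on both sides is trivially equivalent
  snp <- data.frame(pos = 4L, ref = "A", alt = "G")
  expect_true(equivalentVariantGroups(snp, snp, "TTAAACG", 0L))
  ## overlapping variants within one group are an error
  bad <- data.frame(pos = c(2L, 3L), ref = c("AAA", "A"), alt = c("A", "C"))
  expect_error(equivalentVariantGroups(bad, snp, "TTAAACG", 0L),
               "overlapping")
})

test_that("homopolymer shifts are equivalent by brute-force application", {
  ## property: deleting one base anywhere inside a homopolymer run spells
  ## the same haplotype; the group checker must agree with direct string
  ## surgery on windows <= 200 bases
  set.seed(54)
  for (rep_i in 1:10) {
    left <- randSeq(sample(20:80, 1))
    run <- strrep(sample(c("A", "C", "G", "T"), 1), sample(4:9, 1))
    right <- randSeq(sample(20:80, 1))
    w <- paste0(left, run, right)
    runStart <- nchar(left)          # 0-based
    i <- sample(nchar(run) - 1L, 1)  # deletion anchored inside the run
    a <- data.frame(pos = runStart - 1L,
                    ref = substr(w, runStart, runStart + 1L),
                    alt = substr(w, runStart, runStart))
    b <- data.frame(pos = runStart + i - 1L,
                    ref = substr(w, runStart + i, runStart + i + 1L),
                    alt = substr(w, runStart + i, runStart + i))
    ## direct string surgery oracle
    apply1 <- function(v) paste0(substr(w, 1, v$pos + 1L),
                                 substring(w, v$pos + nchar(v$ref) + 1L))
    expect_identical(apply1(a), apply1(b))
    expect_true(equivalentVariantGroups(a, b, w, 0L))
  }
})

test_that("equivalence mode turns matched clusters into TPs", {
  ref <- makeRef(c(q = paste0("TTAAC", randSeq(60))))
  golden <- data.frame(contig = "q", pos = 1L, ref = "TAA", alt = "TA",
                       gt = "1|1")
  test <- data.frame(contig = "q", pos = 1L, ref = "TA", alt = "T",
                     gt = "1|1")
  gv <- writeTestVcf(golden, tempfile(fileext = ".vcf"))
  tv <- writeTestVcf(test, tempfile(fileext = ".vcf"))
  plain <- compareVcfs(gv, tv, ref)
  expect_equal(c(plain@TP, plain@FP, plain@FN), c(0L, 1L, 1L))
  eq <- compareVcfs(gv, tv, ref, equivalence = TRUE)
  expect_equal(c(eq@TP, eq@FP, eq@FN), c(1L, 0L, 0L))
  expect_equal(eq@nEquivalentGroups, 1L)
})

test_that("mappability flags unique and repeated k-mers", {
  set.seed(55)
  uniq <- randSeq(1000)
  mp <- computeMappability(makeRef(c(u = uniq)), 25L)
  expect_true(all(mp$u))
  expect_length(mp$u, 1000L - 24L)
  mp2 <- computeMappability(makeRef(c(h = strrep("A", 200))), 25L)
  expect_false(any(mp2$h))
  ## a duplicated 100-base block is non-unique in both copies
  block <- randSeq(100)
  dup <- paste0(randSeq(300), block, randSeq(300), block, randSeq(100))
  mp3 <- computeMappability(makeRef(c(d = dup)), 50L)
  expect_false(any(mp3$d[301:351]))
  expect_false(any(mp3$d[701:751]))
  expect_true(all(mp3$d[1:200]))
  ## the reverse complement of a k-mer counts as an occurrence
  rcdup <- paste0(randSeq(200), block, randSeq(200),
                  verisim:::revComp(block), randSeq(100))
  mp4 <- computeMappability(makeRef(c(r = rcdup)), 50L)
  expect_false(any(mp4$r[201:251]))
})

test_that("false negatives are categorized by mappability then depth", {
  set.seed(56)
  block <- randSeq(300)
  ref <- makeRef(c(d = paste0(randSeq(600), block, randSeq(400), block,
                              randSeq(300))))
  L <- Biostrings::width(ref)[1]
  ## fabricate a golden alignment: depth ~20 on [1, 1200], none beyond
  pos <- sample(1100, 250, replace = TRUE)
  sam <- writeTestSam(ref, data.frame(qname = paste0("r", 1:250), flag = 0L,
                                      rname = "d", pos = pos, mapq = 60L,
                                      cigar = "100M", rnext = "*",
                                      pnext = 0L, tlen = 0L,
                                      seq = strrep("A", 100),
                                      qual = strrep("I", 100)),
                      tempfile(fileext = ".sam"))
  fn <- data.frame(contig = "d",
                   pos = c(300L,    # unique, covered -> other
                           1650L,   # unique, uncovered -> low-coverage
                           700L))   # inside the repeat -> unmappable
  cats <- diagnoseFalseNegatives(fn, sam, ref, readLength = 100L,
                                 dpThreshold = 10L)
  expect_equal(attr(cats, "labels"),
               c("other", "low-coverage", "unmappable"))
  expect_equal(unname(cats[c("unmappable", "low-coverage", "other")]),
               c(1L, 1L, 1L))
  expect_equal(sum(cats), nrow(fn))
})

test_that("normalized CIGARs equate clips and merge runs", {
  nc <- verisim:::normalizeCigar
  expect_equal(nc("10S90M"), nc("10H90M"))
  expect_equal(nc("50M50M"), "100M")
  expect_equal(nc("10M0I90M"), "100M")
  expect_false(nc("10M1D90M") == nc("100M"))
})
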