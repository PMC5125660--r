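test_that("learning tallies variant types, contexts and indel lengths", {
  ## reference containing an AGA context at a known place
  s <- paste0("TTTTT", "AGA", "TTTTT", "ACA", "TTTTTTTTTT")
  ref <- makeRef(c(chr = s))
  ## two SNPs + one insertion: type fractions (2/3, 1/3, 0)
  vcf <- tempfile(fileext = ".vcf")
  writeTestVcf(data.frame(contig = "chr",
                          pos = c(6L, 14L, 20L),   # 0-based
                          ref = c("G", "C", "T"),
                          alt = c("C", "T", "TAA")), vcf)
  m <- learnMutationModel(vcf, ref)
  expect_equal(unname(typeFractions(m)), c(2 / 3, 1 / 3, 0))
  ## the AGA->ACA substitution fills row G, column C of the A_A matrix
  expect_equal(trinucMatrices(m)[["A_A"]]["G", "C"], 1)
  expect_equal(sum(trinucMatrices(m)[["A_A"]]["G", ]), 1)
  ## insertion length 2 recorded
  expect_equal(indelLengths(m)$ins, c(`2` = 1))
  ## deletion distribution untrained: uniform-ish fallback still sums to 1
  expect_equal(sum(indelLengths(m)$del), 1)
  ## overall rate = usable records / callable length
  expect_equal(overallRate(m), 3 / nchar(s))
})

test_that("learning skips records that contradict the reference", {
  ref <- makeRef(c(chr = strrep("ACGT", 20)))
  vcf <- tempfile(fileext = ".vcf")
  writeTestVcf(data.frame(contig = c("chr", "chr", "nope"),
                          pos = c(4L, 9L, 2L),
                          ref = c("A", "T", "A"),   # pos 9 is really C
                          alt = c("G", "G", "G")), vcf)
  m <- learnMutationModel(vcf, ref)
  st <- attr(m, "stats")
  expect_equal(unname(st[["used"]]), 1L)
  expect_equal(unname(st[["refMismatch"]]), 2L)
  ## a VCF with nothing usable is an error
  writeTestVcf(data.frame(contig = "zz", pos = 0L, ref = "A", alt = "C"), vcf)
  expect_error(learnMutationModel(vcf, ref), "no usable")
})

test_that("a lone deletion trains the deletion length distribution", {
  ref <- makeRef(c(chr = "TTTTTACGGGTTTTT"))
  vcf <- tempfile(fileext = ".vcf")
  writeTestVcf(data.frame(contig = "chr", pos = 5L, ref = "ACGG", alt = "A"),
               vcf)
  m <- learnMutationModel(vcf, ref)
  expect_equal(indelLengths(m)$del, c(`3` = 1))
  expect_equal(unname(typeFractions(m)), c(0, 0, 1))
})

test_that("rate rescaling changes only the overall rate", {
  m <- randomMutationModel(rate = 0.001, seed = 5)
  m2 <- rescaleMutationRate(m, 0.01)
  expect_equal(overallRate(m2), 0.01)
  expect_equal(trinucMatrices(m2), trinucMatrices(m))
  expect_equal(typeFractions(m2), typeFractions(m))
  expect_equal(overallRate(rescaleMutationRate(m, 0)), 0)
  expect_equal(rescaleMutationRate(m, overallRate(m)), m)
  expect_error(rescaleMutationRate(m, -1))
})

test_that("site sampling respects rate, tracks and N masking", {
  m <- defaultMutationModel(rate = 0)
  expect_length(sampleMutationSites("c", 0L, 1000L, strrep("A", 1000), m),
                0L)
  ## track concentrated on 10 bases: every site inside
  set.seed(3)
  tr <- regionTrack("c", 500L, 510L, 1, "mutation-rate")
  m2 <- defaultMutationModel(rate = 0.001)
  sites <- sampleMutationSites("c", 0L, 1000L, randSeq(1000), m2,
                               rateTrack = tr)
  expect_true(all(sites >= 500L & sites < 510L))
  expect_gt(length(sites), 5L)  # expected count 10, without replacement
  ## no sites on N
  sN <- sampleMutationSites("c", 0L, 1000L,
                            paste0(strrep("N", 500), randSeq(500)),
                            defaultMutationModel(rate = 0.05))
  expect_true(all(sN >= 500L))
})

test_that("sampled site counts match the expected rate", {
  set.seed(11)
  m <- defaultMutationModel(rate = 0.01)
  s <- randSeq(20000)
  counts <- vapply(1:30, function(i)
    length(sampleMutationSites("c", 0L, 20000L, s, m)), numeric(1))
  ## mean of 30 draws of ~Binomial(20000, 0.01): 3 sigma band
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 30))
})

test_that("mutation payloads follow the conditional distributions", {
  set.seed(4)
  ## degenerate SNP model: G always becomes C
  tm <- list("A_A" = matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                                     c("A","C","G","T"))))
  tm[["A_A"]]["G", "C"] <- 1
  tm[["A_A"]]["A", "C"] <- 1; tm[["A_A"]]["C", "G"] <- 1
  tm[["A_A"]]["T", "G"] <- 1
  m <- MutationModel(typeFractions = c(sub = 1, ins = 0, del = 0),
                     trinucMatrices = tm)
  for (i in 1:5) {
    p <- sampleMutation(m, "G", "A_A", "GAAA")
    expect_equal(p[c("type", "ref", "alt")],
                 list(type = "sub", ref = "G", alt = "C"))
  }
  ## forced deletion of 2 bases at the first C of AACCT: VCF form ACC -> A
  md <- MutationModel(typeFractions = c(sub = 0, ins = 0, del = 1),
                      delLengths = setNames(1, "2"))
  pd <- sampleMutation(md, "C", "A_C", "CCT", maxLen = 10L, upstream = "A")
  expect_equal(pd, list(type = "del", ref = "ACC", alt = "A",
                        posShift = -1L))
  ## N context falls back to a uniform alternate
  pN <- sampleMutation(m, "G", "N_N", "GAAA")
  expect_equal(pN$type, "sub")
  expect_true(pN$alt %in% setdiff(c("A", "C", "G", "T"), "G"))
})

test_that("sampled alternates reproduce the matrix frequencies", {
  set.seed(8)
  m <- randomMutationModel(rate = 0.01, seed = 8)
  m@typeFractions <- c(sub = 1, ins = 0, del = 0)
  draws <- vapply(1:4000, function(i)
    sampleMutation(m, "A", "C_G", "AAAA")$alt, character(1))
  emp <- table(factor(draws, c("A", "C", "G", "T"))) / 4000
  expect_lt(max(abs(as.numeric(emp) - trinucMatrices(m)[["C_G"]]["A", ])),
            0.03)
})

test_that("genotype assignment obeys ploidy and the het fraction", {
  set.seed(2)
  expect_equal(assignGenotype(3L, 1L), matrix(1L, 3, 1))
  gHet <- assignGenotype(200L, 2L, hetFraction = 1)
  expect_true(all(rowSums(gHet) == 1L))
  gHom <- assignGenotype(50L, 2L, hetFraction = 0)
  expect_true(all(rowSums(gHom) == 2L))
  g4 <- assignGenotype(100L, 4L, hetFraction = 1)
  expect_true(all(rowSums(g4) == 1L))
  ## every sampled genotype carries at least one alternate
  gAny <- assignGenotype(300L, 3L, hetFraction = 0.5)
  expect_true(all(rowSums(gAny) >= 1L))
})

test_that("mutation application edits the right copies and maps indels", {
  muts <- data.frame(pos = 1L, ref = "A", alt = "C", gt = "0|1")
  ap <- applyMutations("AAAA", 0L, muts, 2L)
  expect_equal(ap$haps, c("AAAA", "ACAA"))
  expect_null(ap$maps[[2]])
  ## 3-base deletion: haplotype shorter, map skips ref 11..13
  s <- strrep("ACGTT", 6)
  del <- data.frame(pos = 10L, ref = substr(s, 11, 14), alt = substr(s, 11, 11),
                    gt = "1")
  apd <- applyMutations(s, 0L, del, 1L)
  expect_equal(nchar(apd$haps[1]), nchar(s) - 3L)
  map <- apd$maps[[1]]
  expect_equal(map$ref0, c(0L, 14L))
  expect_equal(map$hap0, c(0L, 11L))
  expect_equal(verisim:::refToHap(map, c(10L, 12L, 14L)), c(10L, 11L, 11L))
})

test_that("mutation models survive a JSON round trip", {
  m <- randomMutationModel(rate = 0.004, seed = 13)
  p <- tempfile(fileext = ".json")
  writeMutationModel(m, p)
  m2 <- readMutationModel(p)
  expect_equal(overallRate(m2), overallRate(m))
  expect_equal(typeFractions(m2), typeFractions(m))
  expect_equal(trinucMatrices(m2), trinucMatrices(m))
  expect_equal(indelLengths(m2), indelLengths(m))
})

test_that("region-stratified learning recovers the rate ordering", {
  ## construct data with a higher rate outside "CDS" blocks, as for
  ## coding/noncoding stratification
  set.seed(21)
  ref <- randomReference(1, 120000, seed = 21)
  blocks <- seq(0L, 110000L, by = 20000L)
  cds <- regionTrack(rep("contig1", length(blocks)), blocks, blocks + 8000L,
                     1, "target")
  gaps <- regionTrack(rep("contig1", length(blocks)), blocks + 8000L,
                      pmin(blocks + 20000L, 120000L), 1, "target")
  rates <- regionTrack(rep("contig1", 2 * length(blocks)),
                       c(blocks, blocks + 8000L),
                       c(blocks + 8000L, pmin(blocks + 20000L, 120000L)),
                       rep(c(0.002, 0.01), each = length(blocks)),
                       "mutation-rate")
  v <- simulateVariants(ref, defaultMutationModel(), rateTrack = rates,
                        seed = 22)
  vcf <- tempfile(fileext = ".vcf")
  writeGoldenVcf(v, ref, vcf)
  mCds <- learnMutationModel(vcf, ref, regions = cds)
  mNon <- learnMutationModel(vcf, ref, regions = gaps)
  expect_gt(overallRate(mNon), overallRate(mCds))
  expect_lt(abs(overallRate(mCds) - 0.002), 0.001)
  expect_lt(abs(overallRate(mNon) - 0.01), 0.002)
})
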