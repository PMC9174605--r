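# Synthetic-data generators: determinism and calibration

test_that("generators are pure functions of their seed", {
  g1 <- genGenome(1000, 0.5, seed = 42)
  g2 <- genGenome(1000, 0.5, seed = 42)
  expect_equal(as.character(genomeSeq(g1)), as.character(genomeSeq(g2)))
  expect_false(identical(as.character(genomeSeq(genGenome(1000, 0.5, seed = 43))),
                         as.character(genomeSeq(g1))))

  cp1 <- genCodonPair(100, 0.05, 0.01, seed = 7)
  cp2 <- genCodonPair(100, 0.05, 0.01, seed = 7)
  expect_identical(cp1, cp2)

  sp1 <- genSharedPair(5000, 0.3, 0.02, seed = 9)
  sp2 <- genSharedPair(5000, 0.3, 0.02, seed = 9)
  expect_equal(as.character(genomeSeq(sp1$g2)), as.character(genomeSeq(sp2$g2)))

  dp1 <- genDepthProfiles(n_query_genes = 10, seed = 3)
  dp2 <- genDepthProfiles(n_query_genes = 10, seed = 3)
  expect_identical(dp1$queries, dp2$queries)
})

test_that("base composition hits the target GC", {
  g <- genGenome(2000, 1.0, seed = 5)
  expect_false(grepl("[AT]", as.character(genomeSeq(g))))
  g <- genGenome(1e6, 0.506, seed = 6)
  freq <- Biostrings::alphabetFrequency(genomeSeq(g))
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_lt(abs(gc - 0.506), 0.003)
})

test_that("planted repeat families honour their K2P target", {
  g <- genGenome(20000, 0.5, seed = 1)
  pl <- plantRepeatFamily(g, 3, 200, 0, seed = 2, strands = c("+", "+", "+"))
  seqchr <- as.character(genomeSeq(pl$genome))
  copies <- substring(seqchr, pl$truth$start + 1, pl$truth$end)
  expect_equal(copies[1], copies[2])  # target 0 -> identical copies
  expect_equal(copies[1], copies[3])
  expect_true(all(pl$truth$n_ts == 0 & pl$truth$n_tv == 0))

  # calibration at 0.05 over replicates, measured between planted copies
  ests <- numeric(20)
  for (i in 1:20) {
    pli <- plantRepeatFamily(g, 2, 1000, 0.05, seed = 100 + i,
                             strands = c("+", "+"))
    s <- as.character(genomeSeq(pli$genome))
    ests[i] <- k2pDistance(substring(s, pli$truth$start[1] + 1, pli$truth$end[1]),
                           substring(s, pli$truth$start[2] + 1, pli$truth$end[2]))
  }
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.05), 3 * se + 1e-9)

  expect_error(plantRepeatFamily(g, 50, 500, 0, seed = 1), "too large")
})

test_that("an inverted planted pair is found as one minus-strand hit", {
  g <- genGenome(8000, 0.5, seed = 12)
  pl <- plantRepeatFamily(g, 2, 300, 0, seed = 13, strands = c("+", "-"))
  h <- hitTable(findDispersedRepeats(pl$genome))
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
})

test_that("shared-pair generator spans its fraction range", {
  sp <- genSharedPair(4000, 1, 0, seed = 31)
  expect_equal(as.character(genomeSeq(sp$g1)), as.character(genomeSeq(sp$g2)))

  sp0 <- genSharedPair(4000, 0, 0, seed = 32)
  expect_equal(nrow(sp0$truth), 0L)
  expect_false(as.character(genomeSeq(sp0$g1)) == as.character(genomeSeq(sp0$g2)))

  sp6 <- genSharedPair(30000, 0.6, 0.02, seed = 33)
  expect_equal(sum(sp6$truth$length), 18000)
  sf <- sharedFraction(sp6$g1, sp6$g2)
  expect_gte(sf$pct_mean, 55)
  expect_lte(sf$pct_mean, 65)
})

test_that("depth generator separates classes and degrades with overdispersion", {
  dp <- genDepthProfiles(n_query_genes = 30, seed = 40)
  expect_equal(length(dp$panel@mito), 32L)
  meds <- vapply(dp$queries, median, 1.0)
  expect_true(all(meds[dp$truth$label == "plastid"] >
                  meds[dp$truth$label == "nuclear"]))

  acc_at_disp <- function(disp, seeds = 1:10) {
    mean(vapply(seeds, function(s) {
      dp <- genDepthProfiles(n_query_genes = 90,
                             class_means = c(nuclear = 15, mitochondrial = 45,
                                             plastid = 135),
                             mito_spread = 1.2, dispersion = disp,
                             seed = 800 + s)
      mean(classifyOrigin(dp$queries, dp$panel)$label == dp$truth$label)
    }, 1.0))
  }
  accs <- vapply(c(0, 0.5, 2, 8), acc_at_disp, 1.0)
  expect_true(all(diff(accs) <= 0.01))  # non-increasing up to MC jitter
})

test_that("codon-pair generator respects its targets and limits", {
  cp <- genCodonPair(300, 0, 0, seed = 50)
  expect_identical(cp$codons1, cp$codons2)
  expect_true(all(cp$truth$n_syn == 0) && all(cp$truth$n_nonsyn == 0))
  expect_error(genCodonPair(100, 0.6, 0.01, seed = 1), "saturation")
  # no stop codons anywhere
  cp <- genCodonPair(500, 0.2, 0.1, seed = 51)
  codons <- substring(cp$codons1, seq(1, nchar(cp$codons1), 3),
                      seq(3, nchar(cp$codons1), 3))
  expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
})
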