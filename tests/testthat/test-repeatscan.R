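# Dispersed-repeat discovery: seed extension, K2P, classification,
# overlap-once accounting and planted-repeat recovery

test_that("seed extension handles the canonical constructions", {
  p <- scanParams()
  # hostile flanks on both sides: every flank column mismatches
  seed7 <- "ACGTGCA"
  q <- paste0(strrep("C", 30), seed7, strrep("C", 30))
  s <- paste0(strrep("G", 30), seed7, strrep("G", 30))
  h <- extendSeed(q, s, 30, 30, p)
  expect_equal(h$score, 14L)
  expect_equal(h$q_end - h$q_start, 7L)

  # two identical 50-mers in anti-matching flanks -> exactly 50 bp, identity 1
  set.seed(11)
  core <- rand_seq(50)
  q <- paste0(strrep("C", 40), core, strrep("C", 40))
  s <- paste0(strrep("G", 40), core, strrep("G", 40))
  h <- extendSeed(q, s, 60, 60, p)
  expect_equal(h$q_end - h$q_start, 50L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$score, 100L)

  # 21 bp duplication with one central mismatch: score 2*20 - 3 = 37
  copy1 <- "ACGTGCATTGCACTGAACGTA"
  copy2 <- copy1
  substr(copy2, 11, 11) <- "T"
  q <- paste0(strrep("C", 25), copy1, strrep("C", 25))
  s <- paste0(strrep("G", 25), copy2, strrep("G", 25))
  h <- extendSeed(q, s, 25, 25, p)
  expect_equal(h$q_end - h$q_start, 21L)
  expect_equal(h$score, 37L)
  expect_equal(nchar(h$aligned_q), 21L)
})

test_that("K2P distance matches the closed form and its domain", {
  expect_equal(k2pDistance("ACGT", "ACGT"), 0)
  # 100 columns: 10 transitions, 5 transversions -> P=0.1, Q=0.05
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(k2pDistance(a, b), -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
  expect_equal(round(k2pDistance(a, b), 5), 0.17018)
  # saturation: transversions at half the sites
  b2 <- paste0(strrep("C", 50), strrep("A", 50))
  expect_identical(k2pDistance(strrep("A", 100), b2), Inf)
  # symmetry and gap-column exclusion
  set.seed(5)
  for (i in 1:25) {
    x <- rand_seq(60); y <- rand_seq(60)
    expect_identical(k2pDistance(x, y), k2pDistance(y, x))
  }
  expect_equal(k2pDistance("AC-GT", "ACCGT"), 0)  # gap column dropped
  expect_error(k2pDistance("----", "----"), "ungapped")
  expect_error(k2pDistance("AC", "ACG"), "equal length")
})

test_that("size and age classes use the stated thresholds", {
  expect_equal(classifySize(c(99, 100, 999, 1000, 5000)),
               c("small", "medium", "medium", "large", "large"))
  expect_equal(classifyAge(c(0, 0.005, 0.1, 0.199, 0.2, 0.25)),
               c("recent", "recent", "intermediate", "intermediate",
                 "ancient", "ancient"))
})

test_that("planted exact duplications are recovered with clean E-values", {
  g <- genGenome(5000, 0.5, seed = 42)
  pl <- plantRepeatFamily(g, 2, 500, 0, seed = 7, strands = c("+", "+"))
  hits <- findDispersedRepeats(pl$genome)
  h <- hitTable(hits)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_true(all(h$evalue <= 1e-6))
  # the planted loci are inside the reported intervals
  expect_lte(h$q_start, pl$truth$start[1])
  expect_gte(h$q_end, pl$truth$end[1])
  expect_lte(h$s_start, pl$truth$start[2])
  expect_gte(h$s_end, pl$truth$end[2])
  expect_equal(h$size_class, "medium")
  expect_equal(h$age_class, "recent")
})

test_that("inverted duplications are reported on the minus strand", {
  g <- genGenome(5000, 0.5, seed = 10)
  pl <- plantRepeatFamily(g, 2, 300, 0, seed = 3, strands = c("+", "-"))
  h <- hitTable(findDispersedRepeats(pl$genome))
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_gte(h$length, 300L - 2L)
})

test_that("degenerate inputs are handled: homopolymers and tiny genomes", {
  hA <- findDispersedRepeats(GenomeSeq("a", strrep("A", 1000)))
  expect_equal(length(hA), 0L)
  expect_warning(h <- findDispersedRepeats(GenomeSeq("t", "ACG")), "word size")
  expect_equal(length(h), 0L)
})

test_that("100% recall of planted duplications across seeded fixtures", {
  found <- 0L
  n_fix <- 200L
  for (i in seq_len(n_fix)) {
    g <- genGenome(5000, 0.5, seed = 10000 + i)
    len <- sample(c(50L, 120L, 300L), 1L)
    pl <- plantRepeatFamily(g, 2, len, 0, seed = 20000 + i)
    h <- hitTable(findDispersedRepeats(pl$genome))
    tr <- pl$truth[order(pl$truth$start), ]  # hits are canonically ordered
    covered <- any(h$q_start <= tr$start[1] & h$q_end >= tr$end[1] &
                   h$s_start <= tr$start[2] & h$s_end >= tr$end[2])
    if (covered) found <- found + 1L
    expect_true(all(h$evalue <= 1e-6))
  }
  expect_equal(found, n_fix)
})

test_that("merged repetitive bp equals the per-base bitmap oracle", {
  g <- genGenome(30000, 0.5, seed = 77)
  pl1 <- plantRepeatFamily(g, 6, 400, 0.02, seed = 78)
  hits <- findDispersedRepeats(pl1$genome)
  h <- hitTable(hits)
  expect_gt(nrow(h), 5)
  m <- mergedRepetitiveBp(hits)
  expect_identical(m$total_bp,
                   bitmap_total(c(h$q_start, h$s_start), c(h$q_end, h$s_end),
                                genomeLength(pl1$genome)))
  expect_lte(m$total_bp, genomeLength(pl1$genome))
})

test_that("planted K2P families are recovered within tolerance", {
  g <- genGenome(50000, 0.5, seed = 1)
  fam <- plantRepeatFamily(g, 10, 1000, 0.05, seed = 2)
  s <- summarizeRepeats(fam$genome, findDispersedRepeats(fam$genome))
  # x-drop termination can split a divergent 1 kb pair into shorter hits, so
  # pool the medium and large multisets
  k2p <- c(s@k2pByClass$medium, s@k2pByClass$large)
  expect_gte(length(k2p), 30L)  # 45 pairs planted
  expect_gte(median(k2p), 0.03)
  expect_lte(median(k2p), 0.07)
  expect_equal(s@nPairs[["total"]],
               s@nPairs[["small"]] + s@nPairs[["medium"]] + s@nPairs[["large"]])
})

test_that("simulated pair K2P is unbiased within 3 SE over replicates", {
  set.seed(99)
  n_rep <- 100L; L <- 1000L; d <- 0.05
  ests <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    src <- rand_seq(L)
    a <- mutateSequenceK2P(src, d / 2)$seq
    b <- mutateSequenceK2P(src, d / 2)$seq
    ests[i] <- k2pDistance(a, b)
  }
  se <- sd(ests) / sqrt(n_rep)
  expect_lt(abs(mean(ests) - d), 3 * se + 1e-9)
})

test_that("random genomes yield at most ~1 spurious hit under the E filter", {
  n_hits <- 0L
  for (i in 1:3) {
    a <- genGenome(100000, 0.5, seed = 500 + i, id = "a")
    b <- genGenome(100000, 0.5, seed = 600 + i, id = "b")
    sf <- sharedFraction(a, b)
    n_hits <- n_hits + (sf$shared_bp_1to2 > 0) + (sf$shared_bp_2to1 > 0)
  }
  # i.i.d. pairs: mean reported hits per genome bounded by the E cutoff
  expect_lte(n_hits / 3, 1)
})

test_that("circular genomes find seeds across the origin", {
  # plant a repeat whose second copy spans the origin
  set.seed(33)
  core <- rand_seq(120)
  bg <- rand_seq(3000)
  circ_seq <- paste0(substr(core, 61, 120), substr(bg, 61, 2400),
                     core, substr(bg, 2531, 3000), substr(core, 1, 60))
  g <- GenomeSeq("circ", circ_seq, circular = TRUE)
  h <- hitTable(findDispersedRepeats(g))
  expect_gte(nrow(h), 1L)
  L <- genomeLength(g)
  wraps <- h$s_end > L | h$q_end > L
  expect_true(any(wraps))
  m <- mergedRepetitiveBp(findDispersedRepeats(g))
  expect_lte(m$total_bp, L)
})
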