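# Shared-DNA quantification and decay regression

test_that("a genome shares 100% with itself regardless of repeat content", {
  g <- genGenome(20000, 0.5, seed = 3)
  pl <- plantRepeatFamily(g, 4, 500, 0, seed = 4)  # repeat-rich
  sf <- sharedFraction(pl$genome, pl$genome)
  expect_equal(sf$pct_1, 100)
  expect_equal(sf$pct_2, 100)
  expect_equal(sf$pct_mean, 100)
})

test_that("independent random genomes share essentially nothing", {
  a <- genGenome(50000, 0.5, seed = 11, id = "a")
  b <- genGenome(50000, 0.5, seed = 12, id = "b")
  expect_lt(sharedFraction(a, b)$pct_mean, 1)
})

test_that("swapping the arguments swaps the roles", {
  sp <- genSharedPair(20000, 0.3, 0.05, seed = 21)
  f12 <- sharedFraction(sp$g1, sp$g2)
  f21 <- sharedFraction(sp$g2, sp$g1)
  expect_equal(f12$shared_bp_1to2, f21$shared_bp_2to1)
  expect_equal(f12$shared_bp_2to1, f21$shared_bp_1to2)
  expect_equal(f12$pct_mean, f21$pct_mean)
  expect_equal(f12$species1, f21$species2)
})

test_that("planted shared fractions are recovered within 5 points", {
  for (frac in c(0.10, 0.30, 0.60)) {
    for (div in c(0, 0.05, 0.10)) {
      seed <- round(1000 * frac + 100 * div * 100)
      sp <- genSharedPair(40000, frac, div, seed = seed)
      sf <- sharedFraction(sp$g1, sp$g2)
      expect_lt(abs(sf$pct_mean - 100 * frac), 5,
                label = sprintf("fraction %.0f%% at %.0f%% divergence (got %.1f)",
                                100 * frac, 100 * div, sf$pct_mean))
    }
  }
})

test_that("decay regression matches its closed form and a permutation oracle", {
  # three collinear points: |r| = 1
  fit <- decayRegression(data.frame(t_mya = c(10, 20, 30),
                                    pct_mean = c(30, 20, 10)))
  expect_equal(fit$pearson_r, -1)
  expect_equal(fit$slope, -1)
  expect_error(decayRegression(data.frame(t_mya = 1:2, pct_mean = 2:1)),
               "at least 3")
  # degenerate variance flagged
  dg <- decayRegression(data.frame(t_mya = c(1, 1, 1), pct_mean = c(1, 2, 3)))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$pearson_r))

  # t-test p-value vs permutation oracle on the bundled pair table
  tab <- readTypedTable(mitocompFixture("shared_dna_pairs.tsv"),
                        tableSpec(t_mya = "numeric", pct_mean = "numeric"))
  fit <- decayRegression(tab)
  set.seed(1234)
  n_perm <- 4000L
  robs <- abs(fit$pearson_r)
  exceed <- mean(replicate(n_perm,
    abs(cor(tab$t_mya, sample(tab$pct_mean))) >= robs))
  expect_lt(abs(exceed - fit$p_value), 0.02)
})
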