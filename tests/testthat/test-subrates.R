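# Absolute substitution rates, fold/clade summaries, NG86 estimator

test_that("absolute rate is the divergence-time quotient and is linear", {
  expect_equal(signif(absoluteRate(0.002997, 87), 6), 3.44483e-11)
  expect_equal(signif(absoluteRate(0.126746, 112), 6), 1.13166e-09)
  expect_equal(absoluteRate(0, 50), 0)
  d <- runif(10); t <- runif(10, 1, 300)
  expect_equal(absoluteRate(2 * d, t), 2 * absoluteRate(d, t))
  expect_error(absoluteRate(0.1, 0), "positive")
  expect_error(absoluteRate(0.1, -5), "positive")
})

test_that("fold ranges use terminal rows, round half-up, and scale-cancel", {
  df <- data.frame(taxon = c("a", "b", "c", "clade"),
                   clade = c("X", "X", "Y", "X"),
                   is_terminal = c(TRUE, TRUE, TRUE, FALSE),
                   is_clade_summary = c(FALSE, FALSE, FALSE, TRUE),
                   ds = c(0.01, 0.0045, 0.031, 99), dn = c(1, 1, 1, 99),
                   rs = c(2, 1, 9, 99), rn = c(3, 1, 4.4, 99))
  f <- foldRange(df, "ds")
  expect_equal(f$fold, 7L)  # 0.031/0.0045 = 6.889 -> 7
  expect_equal(f$max_taxon, "c")
  expect_equal(f$min_taxon, "b")
  expect_equal(foldRange(df, "dn")$fold, 1L)       # equal values
  expect_equal(foldRange(df, "rn")$fold, 4L)       # 4.4 rounds down
  expect_equal(foldRange(df, "rs", scope = "X")$fold, 2L)
  # invariant under uniform scaling
  df2 <- df; df2$ds <- df$ds * 1e6
  expect_equal(foldRange(df2, "ds")$fold, f$fold)
  df3 <- df; df3$ds[1] <- 0
  expect_error(foldRange(df3, "ds"), "zero")
})

test_that("clade ratios read summary rows and fail on missing clades", {
  rates <- readBranchRates(mitocompFixture("branch_rates.tsv"))
  expect_equal(cladeRatio(rates, "Cupressophytes", "Cupressophytes", "ds"), 1)
  expect_error(cladeRatio(rates, "Bryophytes", "Pinaceae", "ds"), "Bryophytes")
  # internal-branch rows are not clade summaries
  expect_error(cladeRatio(rates, "Cupressaceae", "Pinaceae", "ds"), "Cupressaceae")
})

test_that("NG86 matches hand-computed site counts and the pathway oracle", {
  r <- ng86Pairwise("TTTGGG", "TTTGGG")
  expect_equal(r$ds, 0)
  expect_equal(r$dn, 0)

  # TTT GGG vs TTC GGG: one synonymous third-position change
  r <- ng86Pairwise("TTTGGG", "TTCGGG")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 4 / 3, tolerance = 1e-12)  # (1/3 + 1) averaged over both
  expect_equal(r$N, 6 - 4 / 3, tolerance = 1e-12)

  # multi-difference codons against the exhaustive-pathway oracle
  pairs <- list(c("TTT", "GTA"), c("ATG", "CGG"), c("AAA", "ACC"),
                c("TGG", "TGT"), c("CAT", "GCA"), c("TCA", "AGT"))
  for (p in pairs) {
    r <- ng86Pairwise(p[1], p[2])
    o <- path_oracle(p[1], p[2])
    expect_equal(r$Sd, o[["sd"]], tolerance = 1e-12, label = paste(p, collapse = "/"))
    expect_equal(r$Nd, o[["nd"]], tolerance = 1e-12, label = paste(p, collapse = "/"))
  }

  # symmetry
  set.seed(8)
  cp <- genCodonPair(200, 0.1, 0.05, seed = 88)
  a <- ng86Pairwise(cp$codons1, cp$codons2)
  b <- ng86Pairwise(cp$codons2, cp$codons1)
  expect_equal(a$ds, b$ds)
  expect_equal(a$dn, b$dn)

  expect_error(ng86Pairwise("TTTT", "TTTT"), "divisible")
  expect_error(ng86Pairwise("TAATTT", "TAATTT"), "stop codon")
})

test_that("NG86 recovers simulated targets within 3 standard errors", {
  cp <- genCodonPair(5000, 0.05, 0.01, seed = 5)
  est <- ng86Pairwise(cp$codons1, cp$codons2)
  se_jc <- function(p, n) sqrt(p * (1 - p) / n) / (1 - 4 * p / 3)
  expect_lt(abs(est$ds - 0.05), 3 * se_jc(est$ps, est$S))
  expect_lt(abs(est$dn - 0.01), 3 * se_jc(est$pn, est$N))
})

test_that("recomputed absolute rates agree with the given table to 6 sig figs", {
  rates <- readBranchRates(mitocompFixture("branch_rates.tsv"))
  expect_equal(signif(rates$rs, 6), rates$rs_given)
  expect_equal(signif(rates$rn, 6), rates$rn_given)
})
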