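# Depth-based genome-of-origin classification

make_panel <- function(nuclear = 15, plastid = 14395, mito = c(275, 600, 1169),
                       len = 50) {
  ReferencePanel(nuclear = rep(nuclear, len), plastid = rep(plastid, len),
                 mito = lapply(mito, rep, times = len))
}

test_that("median depth follows the stated convention", {
  expect_equal(medianDepth(c(10, 20, 30)), 20)
  expect_equal(medianDepth(c(0, 0, 100, 100)), 50)
  expect_error(medianDepth(numeric()), "empty")
  expect_error(medianDepth(c(1, -2)), "non-negative")
  set.seed(14)
  m <- medianDepth(rpois(1000, 15))
  expect_gte(m, 12); expect_lte(m, 18)
})

test_that("classification follows the nearest anchor in log2 space", {
  panel <- make_panel()
  a <- panelAnchors(panel)
  expect_equal(unname(a), c(15, 600, 14395))

  call <- classifyOrigin(rep(15, 40), panel)
  expect_equal(call$label, "nuclear")

  call <- classifyOrigin(rep(600, 40), panel)  # exactly the mito anchor
  expect_equal(call$label, "mitochondrial")
  expect_gt(call$margin, 0)

  call <- classifyOrigin(rep(0, 40), panel)
  expect_equal(call$label, "ambiguous")
  expect_equal(call$flag, "no coverage")

  # geometric midpoint between nuclear and mito anchors -> ambiguous
  mid <- sqrt(15 * 600)
  call <- classifyOrigin(rep(mid, 40), panel)
  expect_equal(call$label, "ambiguous")
  expect_equal(call$flag, "ambiguous margin")

  # multi-copy nuclear insertion flagged but still nuclear
  call <- classifyOrigin(rep(60, 40), panel)
  expect_equal(call$label, "nuclear")
  expect_match(call$flag, "multi-copy")
})

test_that("labels are scale-invariant and length-invariant", {
  dp <- genDepthProfiles(n_query_genes = 30, seed = 9)
  base <- classifyOrigin(dp$queries, dp$panel)
  scaled_panel <- ReferencePanel(dp$panel@nuclear * 8, dp$panel@plastid * 8,
                                 lapply(dp$panel@mito, `*`, 8))
  scaled <- classifyOrigin(lapply(dp$queries, `*`, 8), scaled_panel)
  expect_equal(scaled$label, base$label)

  long_gene <- rep(c(14, 16), 500)   # same distribution, different length
  short_gene <- rep(c(14, 16), 10)
  panel <- make_panel()
  expect_equal(classifyOrigin(long_gene, panel)$label,
               classifyOrigin(short_gene, panel)$label)
})

test_that("synthetic panels are classified accurately at realistic anchors", {
  dp <- genDepthProfiles(n_query_genes = 200, seed = 9)
  calls <- classifyOrigin(dp$queries, dp$panel)
  expect_gte(mean(calls$label == dp$truth$label), 0.99)
})

test_that("accuracy is high at 8-fold separation and decays towards 1-fold", {
  acc_at_ratio <- function(ratio, seeds = 1:5) {
    mean(vapply(seeds, function(s) {
      dp <- genDepthProfiles(n_query_genes = 60,
                             class_means = c(nuclear = 15,
                                             mitochondrial = 15 * ratio,
                                             plastid = 15 * ratio^2),
                             mito_spread = 1.2, seed = 700 + s)
      calls <- classifyOrigin(dp$queries, dp$panel)
      mean(calls$label == dp$truth$label)
    }, 1.0))
  }
  accs <- vapply(c(8, 4, 2, 1), acc_at_ratio, 1.0)
  expect_gte(accs[1], 0.95)
  expect_true(all(diff(accs) <= 1e-9))  # monotonically non-increasing
})

test_that("the depth report carries the mitochondrial reference range", {
  panel <- make_panel(mito = seq(275, 1169, length.out = 32))
  calls <- classifyOrigin(list(gene1 = rep(16, 30), gene2 = rep(500, 30),
                               gene3 = rep(0, 30)), panel)
  rep_ <- depthReport(calls, panel)
  expect_equal(rep_$mito_depth_range_label, "275-1169")
  expect_equal(nrow(rep_$table), 3L)
  expect_equal(sum(rep_$table$label == "ambiguous"), 1L)
  single <- depthReport(classifyOrigin(rep(15, 10), panel), panel)
  expect_equal(nrow(single$table), 1L)
})
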