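# RNA-editing-site set statistics

toy_table <- function() {
  data.frame(species = c("A", "A", "A", "B", "B"),
             gene = c("nad1", "nad1", "cox1", "nad1", "atp4"),
             column = c(5L, 9L, 2L, 5L, 7L))
}

test_that("site counts collapse duplicates and reject unknown species", {
  tab <- toy_table()
  expect_equal(countSites(tab, "A"), 3L)
  expect_equal(countSites(rbind(tab, tab), "A"), 3L)
  expect_error(countSites(tab, "Z"), "unknown species")
  big <- genEditSites(c(Platycladus = 1068L), seed = 55)
  expect_equal(countSites(big, "Platycladus"), 1068L)
})

test_that("unique fractions follow the shared-column definition", {
  tab <- toy_table()
  # A shares nad1:5 with B; nad1:9 and cox1:2 are unique
  u <- uniqueFraction(tab, "A")
  expect_equal(u$n_unique, 2L)
  expect_equal(u$pct, 100 * 2 / 3)

  disjoint <- data.frame(species = c("A", "B"), gene = "g", column = c(1L, 2L))
  expect_equal(uniqueFraction(disjoint, "A")$pct, 100)
  expect_equal(uniqueFraction(disjoint, "B")$pct, 100)

  same <- data.frame(species = c("A", "B"), gene = "g", column = c(3L, 3L))
  expect_equal(uniqueFraction(same, "A")$pct, 0)

  expect_error(uniqueFraction(data.frame(species = "A", gene = "g", column = 1L),
                              "A"), "2 species")
})

test_that("a planted 25%-unique construction is recovered exactly", {
  # species A: 40 sites, 10 of them at columns no other species touches
  shared <- data.frame(species = "A", gene = "g", column = 1:30)
  uniq <- data.frame(species = "A", gene = "g", column = 101:110)
  others <- rbind(data.frame(species = "B", gene = "g", column = 1:30),
                  data.frame(species = "C", gene = "g", column = 15:40))
  tab <- rbind(shared, uniq, others)
  u <- uniqueFraction(tab, "A")
  expect_equal(u$n_unique, 10L)
  expect_equal(u$pct, 25)
})

test_that("validation overlap reports the predicted-set percentage", {
  pred <- data.frame(gene = "g", column = seq_len(1007))
  obs <- data.frame(gene = "g", column = c(seq_len(745), 2000L + seq_len(323)))
  vo <- validationOverlap(pred, obs)
  expect_equal(vo$n_overlap, 745L)
  expect_equal(vo$pct_of_predicted, 74L)

  expect_equal(validationOverlap(pred, pred)$pct_of_predicted, 100L)
  none <- data.frame(gene = "g", column = 5000:5100)
  expect_equal(validationOverlap(pred, none)$pct_of_predicted, 0L)
  vo0 <- validationOverlap(pred[0, ], obs)
  expect_true(is.na(vo0$pct_of_predicted))
  expect_equal(vo0$flag, "empty predicted set")

  # count symmetric, percentage not
  a <- data.frame(gene = "g", column = 1:10)
  b <- data.frame(gene = "g", column = 6:25)
  expect_equal(validationOverlap(a, b)$n_overlap, validationOverlap(b, a)$n_overlap)
  expect_false(validationOverlap(a, b)$pct_of_predicted ==
               validationOverlap(b, a)$pct_of_predicted)
})

test_that("editing summary invariants hold on random tables", {
  set.seed(66)
  for (rep in 1:10) {
    tab <- genEditSites(c(A = 80L, B = 120L, C = 40L), genes = c("g1", "g2"),
                        max_column = 150L, seed = 660 + rep)
    summ <- editingSummary(tab)
    key <- paste(tab$gene, tab$column)
    expect_lte(sum(summ$n_unique), length(unique(key)))
    # permuting uninvolved species labels leaves A's uniqueness unchanged
    tab2 <- tab
    tab2$species[tab2$species == "B"] <- "tmp"
    tab2$species[tab2$species == "C"] <- "B"
    tab2$species[tab2$species == "tmp"] <- "C"
    expect_equal(uniqueFraction(tab2, "A"), uniqueFraction(tab, "A"))
  }
})
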