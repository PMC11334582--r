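test_that("Shannon and ENS reproduce hand-worked values", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(5, 3, 2)), 1.02965, tolerance = 1e-5)
  expect_equal(ens(0), 1)
  expect_equal(ens(log(4)), 4)
  expect_equal(ens(1.02965), 2.8001, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(ens(-0.1), ">= 0")
})

test_that("Shannon agrees with the vegan implementation", {
  set.seed(21)
  m <- matrix(rpois(60, 20), nrow = 6)
  ours <- apply(m, 1, shannon)
  theirs <- vegan::diversity(m, index = "shannon")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("rarefaction at exactly the sample total returns the plain metric", {
  m <- matrix(c(1500L, 900L, 600L,
                4000L, 0L, 2000L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  ct <- count_table(m)
  res <- rarefied_metric(ct, depth = 3000, iterations = 5, metric = "H_shannon",
                         seed = 1)
  expect_equal(res$value[res$sample_id == "a"], shannon(m["a", ]),
               tolerance = 1e-12)
})

test_that("rarefied ENS of a balanced two-taxon community is about 2", {
  ct <- count_table(matrix(c(3000L, 3000L), nrow = 1,
                           dimnames = list("s", c("t1", "t2"))))
  res <- rarefied_metric(ct, depth = 3000, iterations = 100, metric = "ENS_ASV",
                         seed = 2)
  expect_lt(abs(res$value - 2), 0.01)
})

test_that("samples below depth are dropped with a warning", {
  m <- matrix(c(5000L, 100L), ncol = 1, dimnames = list(c("deep", "shallow"), "t1"))
  expect_warning(res <- rarefied_metric(count_table(m), depth = 3000,
                                        iterations = 2, seed = 1),
                 "below rarefaction depth")
  expect_identical(res$sample_id, "deep")
  expect_error(rarefied_metric(count_table(m), depth = 0), "depth must be > 0")
})

test_that("rarefied richness is unbiased for the hypergeometric closed form", {
  x <- c(500L, 300L, 120L, 50L, 20L, 8L, 2L)
  depth <- 200
  sub <- rarefy_counts(x, depth, iterations = 3000)
  rich <- rowSums(sub > 0)
  expected <- crossdiv:::expected_rarefied_richness(x, depth)
  mc_se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 2 * mc_se)
  # and never exceeds the full-sample richness
  expect_true(all(rich <= sum(x > 0)))
  expect_true(all(rowSums(sub) == depth))
})

test_that("Bray-Curtis reproduces hand values and matches vegan", {
  expect_equal(bray_curtis(rbind(a = c(1, 2, 3), b = c(1, 2, 3)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(1, 0, 2), b = c(0, 3, 0)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))["a", "b"],
               1 / 3, tolerance = 1e-12)
  set.seed(31)
  m <- matrix(rpois(50, 15), nrow = 5)
  rownames(m) <- paste0("s", 1:5)
  ours <- bray_curtis(m)
  theirs <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
  expect_true(all(ours >= 0 & ours <= 1))
  expect_equal(ours, t(ours))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("ENS is bounded by richness with equality only for uniform communities", {
  set.seed(41)
  for (i in 1:50) {
    x <- rpois(12, 8)
    if (sum(x) == 0) next
    e <- ens(shannon(x))
    rich <- sum(x > 0)
    expect_gte(e, 1 - 1e-12)
    expect_lte(e, rich + 1e-9)
    if (length(unique(x[x > 0])) > 1) expect_lt(e, rich)
  }
  expect_equal(ens(shannon(c(4, 4, 4, 4, 0))), 4, tolerance = 1e-12)
})

test_that("taxonomic aggregation conserves totals and separates unclassified bins", {
  ct <- toy_count_table()
  for (rk in c("genus", "family", "order", "class")) {
    agg <- aggregate_taxonomy(ct, rk)
    expect_equal(rowSums(agg$counts), rowSums(ct$counts))
  }
  expect_error(aggregate_taxonomy(ct, "phylum"), "'arg' should be one of")

  tax <- toy_taxonomy()
  tax$genus <- c("unclassified", "unclassified", "g3")
  tax$family <- c("f1", "f2", "f2")
  ct2 <- count_table(toy_counts(), tax)
  agg <- aggregate_taxonomy(ct2, "genus")
  # unclassified genera under different families stay distinct bins
  expect_equal(ncol(agg$counts), 3L)
})

test_that("CLPP profiles blank-correct, clamp and flag degenerate plates", {
  absorb <- setNames(c(rep(0.55, 4), rep(0.05, 27)), sprintf("s%02d", 1:31))
  pl <- clpp_plate(absorb, blank = 0.05)
  expect_equal(clpp_profile(pl)$ens_clpp, 4, tolerance = 1e-9)

  v <- setNames(c(0.45, 0.45, 0.25, rep(0.01, 28)), sprintf("s%02d", 1:31))
  pr <- clpp_profile(clpp_plate(v, blank = 0.05))
  expect_equal(pr$ens_clpp, 2.8719, tolerance = 1e-4)  # profile (0.4, 0.4, 0.2)

  low <- clpp_profile(clpp_plate(setNames(rep(0.01, 31), sprintf("s%02d", 1:31)),
                                 blank = 0.05))
  expect_false(low$defined)
  expect_true(is.na(low$ens_clpp))
})
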