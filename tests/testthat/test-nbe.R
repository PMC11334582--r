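nbe_design <- function() {
  full_factorial_design(species = c("S1", "S2", "S3"),
                        origins = c("O1", "O2", "O3"), replicates = 1L)
}

test_that("NBE subtracts the mean of the component monoculture means", {
  design <- nbe_design()
  mono <- design[design$diversity_level == "mono", ]
  vals <- data.frame(culture_id = mono$culture_id, value = 0)
  strains <- vapply(crossdiv:::split_strains(mono$strains), `[[`, character(1), 1)
  vals$value <- ifelse(strains %in% c("S1.O1", "S2.O1", "S3.O1"),
                       c("S1.O1" = 8, "S2.O1" = 10, "S3.O1" = 12)[strains], 5)
  sp_poly <- design$culture_id[design$treatment == "S1.O1+S2.O1+S3.O1"]
  vals <- rbind(vals, data.frame(culture_id = sp_poly, value = 12))
  r <- nbe(design, vals, "biomass")
  expect_equal(r$nbe[r$culture_id == sp_poly], 2)
  # a polyculture exactly at the expectation has NBE 0
  vals$value[vals$culture_id == sp_poly] <- 10
  r2 <- nbe(design, vals, "biomass")
  expect_equal(r2$nbe[r2$culture_id == sp_poly], 0)
})

test_that("NBE errors name a missing component monoculture", {
  design <- nbe_design()
  keep <- design$diversity_level != "mono" |
    !vapply(crossdiv:::split_strains(design$strains), `[[`, character(1), 1) %in% "S2.O2"
  vals <- data.frame(culture_id = design$culture_id[keep], value = 1)
  expect_error(nbe(design, vals, "biomass"), "no monoculture values for strain S2.O2")
})

test_that("NBE is affine-equivariant: shifts cancel, scales carry through", {
  design <- full_factorial_design(replicates = 2L)
  set.seed(91)
  vals <- data.frame(culture_id = design$culture_id,
                     value = runif(nrow(design), 50, 150))
  base <- nbe(design, vals, "v")
  shifted <- vals; shifted$value <- shifted$value + 17.3
  scaled <- vals; scaled$value <- scaled$value * 2.5
  expect_equal(nbe(design, shifted, "v")$nbe, base$nbe, tolerance = 1e-10)
  expect_equal(nbe(design, scaled, "v")$nbe, 2.5 * base$nbe, tolerance = 1e-10)
})

test_that("t confidence intervals match the hand calculation and flag degeneracy", {
  x <- data.frame(culture_id = c("a", "b", "c"), treatment = "T",
                  diversity_level = "species_poly", variable = "v",
                  observed = 1:3, expected = 0, nbe = c(1, 2, 3))
  s <- nbe_summary(x, by = "diversity_level")
  expect_equal(s$nbe_mean, 2)
  expect_equal(s$ci_low, -0.484, tolerance = 1e-3)
  expect_equal(s$ci_high, 4.484, tolerance = 1e-3)
  expect_false(s$significant)

  x$nbe <- c(2, 2, 2)
  s2 <- nbe_summary(x, by = "diversity_level")
  expect_equal(s2$ci_low, 2)
  expect_equal(s2$ci_high, 2)
  expect_true(s2$significant)
})

test_that("BCa bootstrap intervals are reproducible and bracket the mean", {
  x <- data.frame(culture_id = paste0("c", 1:9), treatment = "T",
                  diversity_level = "species_poly", variable = "v",
                  observed = 0, expected = 0,
                  nbe = c(1.2, 0.8, 2.1, 1.7, 0.4, 1.1, 1.9, 0.6, 1.4))
  s1 <- nbe_summary(x, by = "diversity_level", ci = "bca", seed = 1)
  s2 <- nbe_summary(x, by = "diversity_level", ci = "bca", seed = 1)
  expect_equal(s1$ci_low, s2$ci_low)
  expect_lt(s1$ci_low, s1$nbe_mean)
  expect_gt(s1$ci_high, s1$nbe_mean)
  expect_true(s1$significant)
})

test_that("strong complementarity is detected at every polyculture level", {
  design <- full_factorial_design()
  ok <- logical(200)
  for (i in seq_len(200)) {
    cfg <- simulation_config(seed = 50000 + i, delta_ce = 0.3, sigma_b = 0.02)
    bm <- simulate_biomass(cfg, design)
    vals <- data.frame(culture_id = bm$biomass$culture_id,
                       value = bm$biomass$biomass_carbon)
    s <- nbe_summary(nbe(design, vals, "biomass"), by = "diversity_level")
    ok[i] <- all(s$significant & s$nbe_mean > 0)
  }
  expect_gte(mean(ok), 0.95)
})

test_that("the additive partition reproduces hand-worked cases", {
  p1 <- lh_partition(m = c(10, 20), y_o = c(6, 12))
  expect_equal(c(p1$delta_y, p1$ce, p1$se), c(3, 3, 0), tolerance = 1e-12)
  p2 <- lh_partition(m = c(10, 20), y_o = c(4, 14))
  expect_equal(c(p2$delta_y, p2$ce, p2$se), c(3, 1.5, 1.5), tolerance = 1e-12)
  # a null mixture partitions to all zeros
  p3 <- lh_partition(m = c(10, 20), y_o = c(5, 10))
  expect_equal(c(p3$delta_y, p3$ce, p3$se), c(0, 0, 0), tolerance = 1e-12)
  expect_error(lh_partition(c(10, 0), c(1, 1)), "> 0")
  expect_error(lh_partition(c(10, 20), c(1, 1), ry_e = c(0.3, 0.3)), "sum to 1")
})

test_that("maximum specific growth rate recovers exponential and logistic rates", {
  t <- 0:3
  expect_equal(max_specific_growth_rate(t, 10 * exp(0.5 * t)), 0.5,
               tolerance = 1e-10)
  expect_equal(max_specific_growth_rate(0:5, rep(7, 6)), 0, tolerance = 1e-12)
  expect_error(max_specific_growth_rate(0:4, rep(0, 5)), "positive RFU")
  expect_error(max_specific_growth_rate(c(0, 1), c(1, 2)), "at least 3")

  # logistic growth sampled daily, K/X0 = 1000: slope window hits the
  # early exponential phase within 5 percent of the true rate
  r_true <- 0.6
  rfu <- crossdiv:::logistic_rfu(0:14, x0 = 0.3, r = r_true, k = 300)
  est <- max_specific_growth_rate(0:14, rfu)
  expect_lt(abs(est - r_true) / r_true, 0.05)
})

test_that("per-culture growth rates line up with the generator's rates", {
  cfg <- simulation_config(seed = 12, sigma_rfu = 0)
  design <- full_factorial_design(replicates = 1L)
  mono <- design[design$diversity_level == "mono", ]
  bm <- simulate_biomass(cfg, mono)
  gr <- growth_rates(bm$growth)
  strains <- vapply(crossdiv:::split_strains(mono$strains), `[[`, character(1), 1)
  r_true <- cfg$growth_r[strains]
  est <- gr$growth_rate[match(mono$culture_id, gr$culture_id)]
  expect_true(all(abs(est - r_true) / r_true < 0.2))
})
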