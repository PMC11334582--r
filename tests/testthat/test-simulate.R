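test_that("identical config and seed give identical bundles; new seed, same shapes", {
  cfg <- simulation_config(seed = 3, n_taxa = 40, depth_range = c(800L, 1200L),
                           rarefaction_depth = 500L)
  b1 <- simulate_experiment(cfg)
  b2 <- simulate_experiment(cfg)
  expect_identical(b1$cultures$biomass_carbon, b2$cultures$biomass_carbon)
  expect_identical(b1$counts$attached$counts, b2$counts$attached$counts)
  expect_identical(b1$growth$rfu, b2$growth$rfu)

  cfg2 <- simulation_config(seed = 4, n_taxa = 40, depth_range = c(800L, 1200L),
                            rarefaction_depth = 500L)
  b3 <- simulate_experiment(cfg2)
  expect_false(identical(b1$counts$attached$counts, b3$counts$attached$counts))
  expect_identical(dim(b1$counts$attached$counts), dim(b3$counts$attached$counts))
  expect_equal(nrow(b1$design), 48L)
  expect_equal(nrow(b1$asv_samples), 96L)
  expect_equal(length(b1$clpp), 48L)
})

test_that("zero-effect, zero-noise config makes every NBE exactly zero", {
  cfg <- simulation_config(seed = 5, sigma_b = 0, delta_ce = 0, delta_se = 0)
  design <- full_factorial_design()
  bm <- simulate_biomass(cfg, design)
  vals <- data.frame(culture_id = bm$biomass$culture_id,
                     value = bm$biomass$biomass_carbon)
  r <- nbe(design, vals, "biomass")
  expect_equal(max(abs(r$nbe)), 0)
  expect_equal(max(abs(bm$truth$treatments$expected_delta_y)), 0)
})

test_that("negative-biomass complementarity is rejected", {
  expect_error(simulation_config(seed = 1, delta_ce = -1.2), "negative biomass")
})

test_that("observed mean NBE matches the analytic expectation (Monte Carlo)", {
  design <- full_factorial_design()
  full_tr <- design$treatment[design$diversity_level == "full_poly"][1]
  obs <- numeric(200)
  cfg <- simulation_config(seed = 1, delta_ce = 0.2, sigma_b = 0.05)
  truth <- NULL
  for (i in seq_len(200)) {
    cfg_i <- simulation_config(seed = 40000 + i, delta_ce = 0.2, sigma_b = 0.05)
    bm <- simulate_biomass(cfg_i, design)
    vals <- data.frame(culture_id = bm$biomass$culture_id,
                       value = bm$biomass$biomass_carbon)
    r <- nbe(design, vals, "biomass")
    obs[i] <- mean(r$nbe[r$treatment == full_tr])
    truth <- bm$truth$treatments
  }
  expected <- truth$expected_delta_y[truth$treatment == full_tr]
  mc_se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * mc_se)
})

test_that("pure host-specific compositions are recovered at extreme depth", {
  # w = 1, no Dirichlet noise, no fraction shift, huge depth: the empirical
  # monoculture composition converges to the strain profile (TV < 0.02)
  cfg <- simulation_config(seed = 6, host_specificity = 1, dirichlet_alpha = Inf,
                           fraction_shift = 0, depth_range = c(100000L, 100000L),
                           replicates = 1L)
  design <- full_factorial_design(replicates = 1L)
  mono <- design[design$diversity_level == "mono", ][1:3, ]
  mb <- simulate_microbiome(cfg, mono, seed = 6, fractions = "attached")
  prof <- crossdiv:::taxa_profiles(cfg)
  for (i in seq_len(nrow(mono))) {
    emp <- mb$tables$attached$counts[i, ] / sum(mb$tables$attached$counts[i, ])
    strain <- mono$strains[i]
    tv <- 0.5 * sum(abs(emp - prof$pi_strain[strain, ]))
    expect_lt(tv, 0.02)
  }
})

test_that("mixing distinct host-specific compositions raises expected diversity", {
  cfg <- simulation_config(seed = 7, host_specificity = 1, dirichlet_alpha = Inf,
                           fraction_shift = 0, replicates = 1L)
  design <- full_factorial_design(replicates = 1L)
  mb <- simulate_microbiome(cfg, design, seed = 7, fractions = "attached")
  e <- mb$expected_composition$attached
  mono_rows <- which(design$diversity_level == "mono")
  sp_poly <- which(design$diversity_level == "species_poly")[1]
  comp <- crossdiv:::split_strains(design$strains[sp_poly])[[1]]
  mono_for_comp <- mono_rows[design$strains[mono_rows] %in% comp]
  mix_ens <- ens(shannon(e[sp_poly, ]))
  for (i in mono_for_comp) {
    expect_gt(mix_ens, ens(shannon(e[i, ])))
  }
})

test_that("CLPP simulation honours degenerate and replicate-identical profiles", {
  design <- full_factorial_design(replicates = 3L)
  mono <- design[design$diversity_level == "mono", ][1:6, ]

  cfg_flat <- simulation_config(seed = 8, clpp_base_profile = rep(0.5, 31),
                                clpp_sigma = 0, clpp_specificity = 0)
  plates <- simulate_clpp(cfg_flat, mono, seed = 8)
  expect_equal(clpp_profile(plates[[1]])$ens_clpp, 31, tolerance = 1e-9)

  cfg_zero <- simulation_config(seed = 8, clpp_base_profile = rep(0, 31),
                                clpp_sigma = 0)
  p0 <- clpp_profile(simulate_clpp(cfg_zero, mono, seed = 8)[[1]])
  expect_false(p0$defined)
  expect_true(is.na(p0$ens_clpp))

  # identical use probabilities + small noise: processed profiles nearly equal
  cfg_noise <- simulation_config(seed = 9, clpp_sigma = 0.02, clpp_specificity = 0)
  same_strain <- design[design$strains == "S1.O1", ]
  reps <- do.call(rbind, lapply(1:34, function(i) {
    pl <- simulate_clpp(cfg_noise, same_strain, seed = 900 + i)
    t(vapply(pl, function(p) clpp_profile(p)$profile, numeric(31)))
  }))
  d <- bray_curtis(reps)
  expect_lt(mean(d[upper.tri(d)]), 0.05)
})

test_that("single-replicate designs degrade gracefully downstream", {
  cfg <- simulation_config(seed = 10, replicates = 1L)
  design <- full_factorial_design(replicates = 1L)
  bm <- simulate_biomass(cfg, design)
  vals <- data.frame(culture_id = bm$biomass$culture_id,
                     value = bm$biomass$biomass_carbon)
  s <- nbe_summary(nbe(design, vals, "biomass"), by = "treatment")
  expect_true(all(is.na(s$ci_low[s$n == 1])))
  expect_true(all(is.na(s$significant[s$n == 1])))
})
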