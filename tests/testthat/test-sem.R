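fig4_spec <- function(extra_edge = NULL, name = "hypothesized") {
  edges <- c("species_richness -> biomass", "strain_richness -> biomass",
             "species_richness -> ens_free", "strain_richness -> ens_free",
             "species_richness -> ens_attached", "strain_richness -> ens_attached")
  path_spec(c(edges, extra_edge), correlations = "biomass ~~ ens_attached",
            name = name)
}

test_that("a (near-)perfect linear relationship gives a standardized coefficient of 1", {
  set.seed(100)
  x <- seq(-3, 3, length.out = 50)
  dat <- data.frame(x = x, y = 2 * x + rnorm(50, 0, 1e-8))
  pm <- fit_path_model(dat, path_spec("x -> y"))
  expect_equal(pm$coefficients$std_estimate, 1, tolerance = 1e-8)
  expect_lt(pm$coefficients$p_value, 1e-20)
})

test_that("the 4-point fixture gives slope 0.9 and beta* equal to Pearson r", {
  dat <- data.frame(x = 1:4, y = c(1, 2, 2, 4))
  pm <- fit_path_model(dat, path_spec("x -> y"))
  expect_equal(pm$coefficients$estimate, 0.9, tolerance = 1e-12)
  expect_equal(pm$coefficients$std_estimate, 0.9 * sd(1:4) / sd(c(1, 2, 2, 4)),
               tolerance = 1e-12)
  expect_equal(pm$coefficients$std_estimate, cor(dat$x, dat$y), tolerance = 1e-12)
})

test_that("univariate standardized coefficients equal Pearson correlations", {
  set.seed(101)
  for (i in 1:20) {
    dat <- data.frame(x = rnorm(30), e = rnorm(30))
    dat$y <- runif(1, -2, 2) * dat$x + dat$e
    pm <- fit_path_model(dat, path_spec("x -> y"))
    expect_equal(abs(pm$coefficients$std_estimate), abs(cor(dat$x, dat$y)),
                 tolerance = 1e-12)
  }
})

test_that("independent noise rarely produces a large standardized coefficient", {
  set.seed(102)
  ok <- 0
  for (i in 1:200) {
    dat <- data.frame(x = rnorm(200), y = rnorm(200))
    pm <- fit_path_model(dat, path_spec("x -> y"))
    ok <- ok + (abs(pm$coefficients$std_estimate) < 0.2 &&
                  pm$coefficients$p_value > 0.05)
  }
  expect_gte(ok, 180)
})

test_that("the d-separation basis set covers textbook cases", {
  chain <- path_spec(c("x -> y", "y -> z"))
  claims <- dsep_basis_set(chain)
  expect_length(claims, 1)
  expect_equal(claims[[1]]$x, "x")
  expect_equal(claims[[1]]$y, "z")
  expect_equal(claims[[1]]$given, "y")

  complete <- path_spec(c("x -> y", "x -> z", "y -> z"))
  expect_length(dsep_basis_set(complete), 0)
})

test_that("the basis set matches brute-force enumeration and ignores spec order", {
  spec <- fig4_spec()
  claims <- dsep_basis_set(spec)
  # oracle: enumerate all non-adjacent, non-correlated unordered pairs
  vars <- spec$vars
  adj <- spec$adjacency
  expected_pairs <- list()
  for (u in vars) for (v in vars) {
    if (u >= v) next
    directed <- any((adj$from == u & adj$to == v) | (adj$from == v & adj$to == u))
    correlated <- any(spec$correlations$a == u & spec$correlations$b == v)
    if (!directed && !correlated) expected_pairs[[length(expected_pairs) + 1]] <- c(u, v)
  }
  got_pairs <- lapply(claims, function(cl) sort(c(cl$x, cl$y)))
  expect_setequal(lapply(expected_pairs, sort), got_pairs)

  # rewriting the same model in a different order yields the same claims
  spec2 <- path_spec(rev(c("species_richness -> biomass",
                           "strain_richness -> biomass",
                           "species_richness -> ens_free",
                           "strain_richness -> ens_free",
                           "species_richness -> ens_attached",
                           "strain_richness -> ens_attached")),
                     correlations = "ens_attached ~~ biomass")
  expect_identical(dsep_basis_set(spec2), claims)
})

test_that("spec validation rejects cycles, duplicate edges and clashing correlations", {
  expect_error(path_spec(c("x -> y", "y -> x")), "cycle")
  expect_error(path_spec(c("x -> y", "x -> y")), "duplicated edge")
  expect_error(path_spec("x -> y", correlations = "x ~~ y"), "also a directed edge")
})

test_that("Fisher's C follows the closed form and flags saturation", {
  expect_equal(fishers_c(c(1, 1))$C, 0)
  expect_equal(fishers_c(c(1, 1))$p_value, 1)
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p_value, 0.596, tolerance = 1e-3)
  sat <- fishers_c(numeric(0))
  expect_true(sat$saturated)
  expect_equal(sat$df, 0L)
  expect_error(fishers_c(c(0.5, 0)), "degenerate")
})

test_that("AICc comparison breaks ties by order and flags infeasible candidates", {
  set.seed(103)
  spec <- path_spec(c("x -> y"), name = "a")
  spec_b <- path_spec(c("x -> y"), name = "b")
  dat <- data.frame(x = rnorm(30))
  dat$y <- 0.5 * dat$x + rnorm(30)
  cmp <- compare_path_models(dat, list(spec, spec_b))
  expect_equal(cmp$AICc[1], cmp$AICc[2])
  expect_equal(cmp$model[cmp$best], "a")

  tiny <- dat[1:4, ]  # n = 4 <= K + 1 = 5
  cmp2 <- compare_path_models(tiny, list(spec))
  expect_true(cmp2$infeasible[1])
  expect_false(any(cmp2$best))
})

test_that("collinear parents are rejected", {
  set.seed(104)
  dat <- data.frame(x = rnorm(40))
  dat$x2 <- 2 * dat$x
  dat$y <- dat$x + rnorm(40)
  expect_error(fit_path_model(dat, path_spec(c("x -> y", "x2 -> y"))),
               "collinear")
})

test_that("interaction terms are products of centered parents", {
  set.seed(105)
  dat <- data.frame(a = rnorm(120), b = rnorm(120))
  dat$y <- 0.5 * dat$a + 0.8 * (dat$a - mean(dat$a)) * (dat$b - mean(dat$b)) +
    rnorm(120, 0, 0.3)
  pm <- fit_path_model(dat, path_spec(c("a -> y", "b -> y", "a:b -> y")))
  est <- pm$coefficients$estimate[pm$coefficients$predictor == "a:b"]
  expect_equal(est, 0.8, tolerance = 0.15)
})

test_that("residual correlations recover the latent coupling sign", {
  spec <- fig4_spec()
  dat <- simulate_path_data(spec, 300, corr_strength = 0.8, seed = 9)
  pm <- fit_path_model(dat, spec)
  expect_equal(nrow(pm$correlations), 1L)
  expect_gt(pm$correlations$r, 0.2)
  expect_lt(pm$correlations$p_value, 0.01)
})
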