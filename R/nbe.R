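#' Per-sample net biodiversity effects
#'
#' For every polyculture sample, the expected value under the null of no
#' diversity effect is the unweighted mean, over the component strains, of
#' each strain's monoculture replicate mean; the net biodiversity effect
#' is observed minus expected. Using the mean of replicate means (rather
#' than pooling replicates) keeps unequal replication from weighting
#' component strains unevenly.
#'
#' @param design An [experiment_design()].
#' @param values Data frame with columns `culture_id` and `value`, or a
#'   numeric vector named by culture id. Missing values are skipped.
#' @param variable Name recorded in the output.
#' @return Data frame, one row per polyculture sample: `culture_id`,
#'   `treatment`, `diversity_level`, `variable`, `observed`, `expected`,
#'   `nbe`.
#' @export
nbe <- function(design, values, variable = "value") {
  if (is.numeric(values)) {
    values <- data.frame(culture_id = names(values), value = unname(values),
                         stringsAsFactors = FALSE)
  }
  v <- stats::setNames(values$value, values$culture_id)
  sets <- split_strains(design$strains)
  mono <- design$diversity_level == "mono"
  mono_strain <- vapply(sets[mono], `[[`, character(1), 1L)
  mono_vals <- v[design$culture_id[mono]]
  mono_means <- tapply(mono_vals, mono_strain, mean, na.rm = TRUE)
  poly_idx <- which(!mono)
  rows <- lapply(poly_idx, function(ci) {
    obs <- v[design$culture_id[ci]]
    if (is.na(obs)) return(NULL)
    comp <- sets[[ci]]
    comp_means <- mono_means[comp]
    if (any(is.na(comp_means))) {
      cd_stop("no monoculture values for strain ",
              comp[which(is.na(comp_means))[1]],
              " (needed by polyculture ", design$culture_id[ci], ")")
    }
    expected <- mean(comp_means)
    data.frame(culture_id = design$culture_id[ci],
               treatment = design$treatment[ci],
               diversity_level = design$diversity_level[ci],
               variable = variable, observed = unname(obs),
               expected = unname(expected), nbe = unname(obs - expected),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# bias-corrected and accelerated bootstrap interval for a mean
bca_ci <- function(x, conf = 0.95, n_boot = 2000L, seed = NULL) {
  set_local_seed(seed)
  n <- length(x)
  theta <- mean(x)
  boots <- vapply(seq_len(n_boot), function(i) mean(x[sample.int(n, replace = TRUE)]),
                  numeric(1))
  if (stats::sd(boots) == 0) return(c(theta, theta))
  z0 <- stats::qnorm(mean(boots < theta) + 0.5 * mean(boots == theta))
  jack <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
  dj <- mean(jack) - jack
  accel <- sum(dj^3) / (6 * sum(dj^2)^1.5)
  if (!is.finite(accel)) accel <- 0
  alpha <- (1 - conf) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  unname(stats::quantile(boots, adj, type = 7))
}

#' Treatment- or level-wise summary of net biodiversity effects
#'
#' Mean NBE with a 95 percent confidence interval per group; `significant`
#' is TRUE when the interval excludes zero. The default interval is the
#' Student-t interval `mean +/- t_{0.975, n-1} s/sqrt(n)`; a seedable BCa
#' bootstrap is available. Groups with a single sample get an undefined
#' (NA) interval.
#'
#' @param x Per-sample NBE table from [nbe()].
#' @param by `"diversity_level"` or `"treatment"`.
#' @param ci `"t"` or `"bca"`.
#' @param conf Confidence level.
#' @param n_boot,seed Bootstrap controls (BCa only).
#' @return Data frame: `treatment`, `diversity_level`, `variable`,
#'   `nbe_mean`, `ci_low`, `ci_high`, `n`, `significant`.
#' @export
nbe_summary <- function(x, by = c("diversity_level", "treatment"),
                        ci = c("t", "bca"), conf = 0.95,
                        n_boot = 2000L, seed = NULL) {
  by <- match.arg(by)
  ci <- match.arg(ci)
  groups <- split(x, x[[by]])
  rows <- lapply(names(groups), function(g) {
    gx <- groups[[g]]
    n <- nrow(gx)
    m <- mean(gx$nbe)
    if (n >= 2L) {
      if (ci == "t") {
        half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(gx$nbe) / sqrt(n)
        lo <- m - half; hi <- m + half
      } else {
        b <- bca_ci(gx$nbe, conf, n_boot,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, g))
        lo <- b[1]; hi <- b[2]
      }
      signif <- lo > 0 || hi < 0
    } else {
      lo <- NA_real_; hi <- NA_real_; signif <- NA
    }
    data.frame(
      treatment = if (by == "treatment") g else "(all)",
      diversity_level = if (by == "diversity_level") g else gx$diversity_level[1],
      variable = gx$variable[1], nbe_mean = m, ci_low = lo, ci_high = hi,
      n = n, significant = signif, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Additive partition of the net biodiversity effect
#'
#' Loreau-Hector partition: with observed per-component yields in mixture
#' `Y_O,i`, monoculture yields `M_i` and expected relative yields
#' `RY_E,i` (default 1/N), the deviations `dRY_i = Y_O,i/M_i - RY_E,i`
#' give `deltaY = sum Y_O,i - sum RY_E,i M_i`, the complementarity effect
#' `CE = N mean(dRY) mean(M)` and the selection effect `SE = N
#' cov_pop(dRY, M)` (population covariance, so `CE + SE = deltaY`
#' exactly).
#'
#' @param m Monoculture yields `M_i` (all > 0).
#' @param y_o Observed per-component yields in the mixture.
#' @param ry_e Expected relative yields (default equal shares, sum 1).
#' @return Object of class `lh_partition`: `delta_y`, `ce`, `se`, `n`.
#' @export
lh_partition <- function(m, y_o, ry_e = NULL) {
  n <- length(m)
  if (n < 2L) cd_stop("partition needs >= 2 components")
  if (length(y_o) != n) cd_stop("m and y_o differ in length")
  if (any(m <= 0)) cd_stop("monoculture yields must be > 0")
  if (is.null(ry_e)) ry_e <- rep(1 / n, n)
  if (abs(sum(ry_e) - 1) > 1e-8) cd_stop("expected relative yields must sum to 1")
  dry <- y_o / m - ry_e
  delta_y <- sum(y_o) - sum(ry_e * m)
  ce <- n * mean(dry) * mean(m)
  se <- sum((dry - mean(dry)) * (m - mean(m)))  # N * population covariance
  structure(list(delta_y = delta_y, ce = ce, se = se, n = n),
            class = "lh_partition")
}

#' @export
print.lh_partition <- function(x, ...) {
  cat(sprintf("Net effect deltaY = %.4g = CE %.4g + SE %.4g (%d components)\n",
              x$delta_y, x$ce, x$se, x$n))
  invisible(x)
}

#' Maximum specific growth rate from an RFU time series
#'
#' The maximum, over all windows of `window` consecutive time points with
#' positive RFU, of the least-squares slope of log(RFU) against time.
#'
#' @param day Strictly increasing time points (days).
#' @param rfu Nonnegative fluorescence values.
#' @param window Number of consecutive points per regression window.
#' @return Growth rate in day^-1.
#' @export
max_specific_growth_rate <- function(day, rfu, window = 3L) {
  if (length(day) != length(rfu)) cd_stop("day and rfu differ in length")
  if (length(day) < window) cd_stop("need at least ", window, " time points")
  if (any(diff(day) <= 0)) cd_stop("days must be strictly increasing")
  slopes <- c()
  for (i in seq_len(length(day) - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (any(rfu[idx] <= 0)) next
    t <- day[idx]; y <- log(rfu[idx])
    slopes <- c(slopes, sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2))
  }
  if (!length(slopes)) cd_stop("no window of ", window, " consecutive positive RFU values")
  max(slopes)
}

#' Maximum specific growth rates for every culture in a growth table
#'
#' @param growth Long-format growth series (`culture_id`, `day`, `rfu`).
#' @param window Window length passed to [max_specific_growth_rate()].
#' @return Data frame: `culture_id`, `growth_rate`.
#' @export
growth_rates <- function(growth, window = 3L) {
  by_cult <- split(growth, growth$culture_id)
  data.frame(
    culture_id = names(by_cult),
    growth_rate = vapply(by_cult, function(g) {
      max_specific_growth_rate(g$day, g$rfu, window)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
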