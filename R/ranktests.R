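#' Holm step-down adjustment of p-values
#'
#' Sorted p-values are multiplied by `m, m-1, ..., 1`, monotonicity is
#' enforced by a running maximum, and results are capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
p_adjust_holm <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1L)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Sorted p-values are multiplied by `m/rank`, monotonicity is enforced by
#' a running minimum from the largest p down, and results are capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
p_adjust_bh <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1L)))
  out <- numeric(m)
  out[o] <- adj
  out
}

rank_tie_stats <- function(values) {
  r <- rank(values)  # average ranks for ties
  tab <- table(values)
  list(ranks = r, tie_sum = sum(tab^3 - tab), n = length(values))
}

#' Kruskal-Wallis rank-sum test (tie-corrected)
#'
#' H = `[12/(N(N+1))] sum R_g^2/n_g - 3(N+1)` on average ranks, divided by
#' the tie correction `1 - sum(t^3 - t)/(N^3 - N)`; p-value from the
#' chi-squared distribution with `a - 1` df.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return Object of class `rank_test`: `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.vector(groups))
  if (length(values) != length(groups)) cd_stop("values and groups differ in length")
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) cd_stop("need >= 2 groups")
  if (length(unique(values)) < 2L) cd_stop("all ties: every value identical")
  ts <- rank_tie_stats(values)
  n <- ts$n
  rank_sums <- tapply(ts$ranks, groups, sum)
  sizes <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  correction <- 1 - ts$tie_sum / (n^3 - n)
  h <- h / correction
  df <- nlevels(groups) - 1L
  structure(list(statistic = h, df = df,
                 p_value = stats::pchisq(h, df, lower.tail = FALSE),
                 n = n, method = "Kruskal-Wallis"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Dunn post-hoc tests with Holm adjustment
#'
#' For each unordered group pair, `z = (Rbar_g - Rbar_h) / sqrt([N(N+1)/12
#' - tie term] (1/n_g + 1/n_h))` on the pooled average ranks, with the tie
#' term `sum(t^3 - t) / (12 (N - 1))`; two-sided normal p-values, adjusted
#' by the Holm step-down procedure.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"holm"`, `"bh"` or `"none"`.
#' @return Data frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_holm <- function(values, groups, adjust = c("holm", "bh", "none")) {
  adjust <- match.arg(adjust)
  groups <- droplevels(as.factor(as.vector(groups)))
  if (nlevels(groups) < 3L) cd_stop("Dunn post-hoc tests need >= 3 groups")
  if (length(unique(values)) < 2L) cd_stop("all ties: every value identical")
  ts <- rank_tie_stats(values)
  n <- ts$n
  mean_ranks <- tapply(ts$ranks, groups, mean)
  sizes <- tabulate(groups)
  tie_term <- ts$tie_sum / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g <- match(pairs[1, k], levels(groups))
    h <- match(pairs[2, k], levels(groups))
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[g] + 1 / sizes[h]))
    z <- (mean_ranks[g] - mean_ranks[h]) / se
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k], z = unname(z),
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjust,
                           holm = p_adjust_holm(out$p_value),
                           bh = p_adjust_bh(out$p_value),
                           none = out$p_value)
  out
}

# Spearman rho via ranked Pearson correlation (average ranks for ties),
# two-sided p from the t approximation.
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3L) cd_stop("Spearman correlation needs n >= 3")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Taxon-response Spearman screens with BH control within taxonomic levels
#'
#' Relative abundances are aggregated at each requested taxonomic level
#' and correlated (Spearman) against a per-sample response; BH adjustment
#' is applied separately within each level. Zero-variance taxa are
#' flagged and excluded from the number of tests.
#'
#' @param table A [count_table()] with taxonomy.
#' @param response Named numeric vector (names = sample ids) or data frame
#'   with columns `sample_id` and `value`.
#' @param levels Taxonomic levels to screen.
#' @return Data frame: `level`, `taxon`, `n`, `rho`, `p_value`,
#'   `p_adjusted`, `constant` flag.
#' @export
spearman_bh <- function(table, response,
                        levels = c("genus", "family", "order", "class")) {
  if (is.data.frame(response)) {
    response <- stats::setNames(response$value, response$sample_id)
  }
  ids <- intersect(rownames(table$counts), names(response))
  if (length(ids) < 3L) cd_stop("need >= 3 samples with both abundances and response")
  y <- response[ids]
  out <- lapply(levels, function(lev) {
    agg <- aggregate_taxonomy(table, lev)$counts[ids, , drop = FALSE]
    rel <- agg / rowSums(agg)
    res <- lapply(colnames(rel), function(tx) {
      v <- rel[, tx]
      if (stats::sd(v) == 0) {
        data.frame(level = lev, taxon = tx, n = length(ids), rho = NA_real_,
                   p_value = NA_real_, constant = TRUE, stringsAsFactors = FALSE)
      } else {
        st <- spearman_test(v, y)
        data.frame(level = lev, taxon = tx, n = length(ids), rho = st$rho,
                   p_value = st$p_value, constant = FALSE, stringsAsFactors = FALSE)
      }
    })
    df <- do.call(rbind, res)
    df$p_adjusted <- NA_real_
    tested <- !df$constant
    df$p_adjusted[tested] <- p_adjust_bh(df$p_value[tested])
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
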