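as_dist_matrix <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) cd_stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) cd_stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) cd_stop("distance matrix must have a zero diagonal")
  m
}

ss_within <- function(d2, idx) {
  s <- 0
  for (ix in idx) s <- s + sum(d2[ix, ix]) / (2 * length(ix))
  s
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components: `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and tests the
#' pseudo-F ratio `(SS_A/(a-1)) / (SS_W/(N-a))` by whole-sample label
#' permutation. The permutation p-value includes the observed statistic:
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`, so the attainable floor
#' with 999 permutations is 0.001.
#'
#' @param d Distance matrix (`dist` or square symmetric matrix).
#' @param groups Group labels, one per sample.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `permanova`: `pseudo_F`, `R2`, `p_value`,
#'   `df_between`, `df_within`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  m <- as_dist_matrix(d)
  groups <- as.factor(as.vector(groups))
  n <- nrow(m)
  if (length(groups) != n) cd_stop("groups length must match the distance matrix")
  if (any(table(groups) == 0L)) groups <- droplevels(groups)
  a <- nlevels(groups)
  if (a < 2L) cd_stop("need >= 2 groups")
  if (n <= a) cd_stop("need more samples than groups")
  d2 <- m^2
  idx <- split(seq_len(n), groups)
  sizes <- lengths(idx)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- ss_within(d2, idx)
  ss_a <- ss_tot - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (n - a))
  set_local_seed(seed)
  grp_of <- rep(seq_len(a), sizes)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    idx_p <- split(perm, grp_of)
    ss_w_p <- ss_within(d2, idx_p)
    ss_a_p <- ss_tot - ss_w_p
    f_p <- (ss_a_p / (a - 1)) / (ss_w_p / (n - a))
    if (f_p >= f_obs - 1e-12) ge <- ge + 1L
  }
  structure(list(
    pseudo_F = f_obs, R2 = ss_a / ss_tot,
    p_value = (ge + 1) / (n_perm + 1),
    df_between = a - 1L, df_within = n - a, n_perm = as.integer(n_perm),
    ss_total = ss_tot, ss_between = ss_a, ss_within = ss_w
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA with multiple-testing adjustment
#'
#' One subset test per unordered group pair, each re-permuting within its
#' own pair of groups. The per-pair seed is derived from `seed` and the
#' pair label, so any single pair can be reproduced by calling
#' [permanova()] on the sub-matrix with the derived seed.
#'
#' @inheritParams permanova
#' @param adjust `"bonferroni"` (adjusted p = min(1, p * n_pairs)),
#'   `"holm"` or `"none"`.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999L,
                               adjust = c("bonferroni", "holm", "none"),
                               seed = NULL) {
  adjust <- match.arg(adjust)
  m <- as_dist_matrix(d)
  groups <- as.factor(as.vector(groups))
  levs <- levels(groups)
  if (length(levs) < 3L) cd_stop("pairwise comparisons need >= 3 groups")
  pairs <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- groups %in% c(g1, g2)
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste(g1, g2, sep = "|"))
    res <- permanova(m[sel, sel, drop = FALSE], droplevels(groups[sel]),
                     n_perm = n_perm, seed = sub_seed)
    data.frame(group1 = g1, group2 = g2, pseudo_F = res$pseudo_F, R2 = res$R2,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjust,
    bonferroni = pmin(1, out$p_value * nrow(out)),
    holm = p_adjust_holm(out$p_value),
    none = out$p_value)
  out
}
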