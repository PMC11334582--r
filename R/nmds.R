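lower_tri <- function(m) m[lower.tri(m)]

config_dist_vec <- function(x) {
  as.vector(stats::dist(x))
}

# Kruskal stress-1 given configuration distances and disparities
stress1 <- function(dvec, dhat) {
  sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
}

# monotone (isotonic) regression of configuration distances on the
# dissimilarity order; "primary" tie handling (ties broken by current
# configuration distance, i.e. unconstrained within ties)
disparities <- function(delta, dvec) {
  o <- order(delta, dvec)
  fit <- stats::isoreg(dvec[o])$yf
  out <- numeric(length(dvec))
  out[o] <- fit
  out
}

nmds_single <- function(delta, x0, max_iter, tol) {
  n <- nrow(x0)
  x <- scale(x0, scale = FALSE)
  dvec <- config_dist_vec(x)
  dhat <- disparities(delta, dvec)
  s <- stress1(dvec, dhat)
  trace <- s
  for (it in seq_len(max_iter)) {
    # Guttman transform towards the current disparities
    dm <- matrix(0, n, n)
    dm[lower.tri(dm)] <- dvec
    dm <- dm + t(dm)
    ratio <- matrix(0, n, n)
    pos <- dm > 0
    dhm <- matrix(0, n, n)
    dhm[lower.tri(dhm)] <- dhat
    dhm <- dhm + t(dhm)
    ratio[pos] <- dhm[pos] / dm[pos]
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x_new <- b %*% x / n
    x_new <- scale(x_new, scale = FALSE)
    dvec_new <- config_dist_vec(x_new)
    dhat_new <- disparities(delta, dvec_new)
    s_new <- stress1(dvec_new, dhat_new)
    if (s_new > s + 1e-12) break  # guard: never accept a stress increase
    x <- x_new; dvec <- dvec_new; dhat <- dhat_new
    improved <- s - s_new
    s <- s_new
    trace <- c(trace, s)
    if (improved < tol) break
  }
  list(points = x, stress = s, trace = trace,
       converged = length(trace) < max_iter + 1L || s < tol)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1 `sqrt(sum((d - dhat)^2) / sum(d^2))`, where
#' `dhat` is the monotone (isotonic) regression of the configuration
#' distances on the input dissimilarities, by iterated Guttman transforms.
#' The first start is the metric (classical) MDS solution; remaining
#' starts are random. The best configuration over all starts is returned,
#' centered; within a run the reported stress sequence is non-increasing
#' by construction.
#'
#' @param d Dissimilarity matrix (`dist` or square symmetric matrix).
#' @param k Target dimensionality (default 2).
#' @param restarts Total number of starts (1 metric + `restarts - 1`
#'   random; default 50).
#' @param max_iter Iteration cap per start.
#' @param tol Stress-improvement convergence tolerance.
#' @param seed Optional RNG seed for the random starts.
#' @return Object of class `nmds`: `points` (n x k), `stress`,
#'   `converged`, `restarts`, `stress_trace` (best run) and
#'   `metric_init_stress` (stress of the metric-MDS start).
#' @export
nmds <- function(d, k = 2L, restarts = 50L, max_iter = 500L, tol = 1e-7,
                 seed = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  if (n < k + 1L) cd_stop("need at least k + 1 samples")
  delta <- lower_tri(m)
  degenerate <- stats::sd(delta) == 0
  set_local_seed(seed)
  x0 <- suppressWarnings(stats::cmdscale(m, k = k))
  if (ncol(x0) < k) {
    x0 <- cbind(x0, matrix(stats::rnorm(n * (k - ncol(x0)), sd = 1e-4), n))
  }
  scale0 <- mean(delta)
  best <- NULL
  init_stress <- NA_real_
  for (r in seq_len(max(1L, restarts))) {
    start <- if (r == 1L) x0 else matrix(stats::rnorm(n * k, sd = scale0), n, k)
    run <- nmds_single(delta, start, max_iter, tol)
    if (r == 1L) init_stress <- run$trace[1]
    if (is.null(best) || run$stress < best$stress) best <- run
    if (best$stress < 1e-10) break
  }
  structure(list(
    points = structure(best$points, dimnames = list(rownames(m), paste0("NMDS", seq_len(k)))),
    stress = best$stress,
    converged = !degenerate && best$converged,
    degenerate = degenerate,
    restarts = as.integer(restarts),
    stress_trace = best$trace,
    metric_init_stress = init_stress
  ), class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS (%d points, k = %d): stress-1 = %.5f, converged = %s\n",
              nrow(x$points), ncol(x$points), x$stress, x$converged))
  invisible(x)
}
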