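term_constituents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Specify a piecewise path model
#'
#' Directed edges are `"cause -> effect"` strings (interactions of
#' mean-centered parents as `"a:b -> y"`); free correlations between
#' variables (double-headed arrows) are `"a ~~ b"` strings. The directed
#' part must be acyclic; a correlated pair may not also be a directed
#' edge.
#'
#' @param edges Character vector of directed edges.
#' @param correlations Character vector of correlated-error pairs.
#' @param name Optional model label.
#' @return Object of class `path_spec`.
#' @export
path_spec <- function(edges, correlations = character(), name = NULL) {
  parse_arrow <- function(s, sep) {
    parts <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(parts == "")) cd_stop("cannot parse: '", s, "'")
    parts
  }
  ed <- t(vapply(edges, parse_arrow, character(2), sep = "->"))
  edges_df <- data.frame(from = ed[, 1], to = ed[, 2], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(edges_df$from, edges_df$to))) cd_stop("duplicated edge")
  if (any(grepl(":", edges_df$to))) cd_stop("an interaction cannot be an effect")
  corr_df <- if (length(correlations)) {
    co <- t(vapply(correlations, parse_arrow, character(2), sep = "~~"))
    data.frame(a = pmin(co[, 1], co[, 2]), b = pmax(co[, 1], co[, 2]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }
  vars <- unique(c(unlist(lapply(edges_df$from, term_constituents)), edges_df$to,
                   corr_df$a, corr_df$b))
  # directed adjacency between plain variables (interactions expanded)
  adj <- unique(do.call(rbind, lapply(seq_len(nrow(edges_df)), function(i) {
    data.frame(from = term_constituents(edges_df$from[i]), to = edges_df$to[i],
               stringsAsFactors = FALSE)
  })))
  for (i in seq_len(nrow(corr_df))) {
    pair <- c(corr_df$a[i], corr_df$b[i])
    hit <- (adj$from %in% pair) & (adj$to %in% pair)
    if (any(hit)) cd_stop("correlated-error pair ", corr_df$a[i], " ~~ ",
                          corr_df$b[i], " is also a directed edge")
  }
  spec <- structure(list(vars = vars, edges = edges_df, adjacency = adj,
                         correlations = corr_df, name = name),
                    class = "path_spec")
  topo_order(spec)  # errors on a cycle
  spec
}

# Kahn topological sort with alphabetical tie-break, so the order (and the
# basis set built from it) is invariant to how the spec was written down.
topo_order <- function(spec) {
  vars <- sort(spec$vars)
  adj <- spec$adjacency
  order_out <- character(0)
  indeg <- vapply(vars, function(v) sum(adj$to == v), integer(1))
  avail <- sort(vars[indeg == 0])
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order_out <- c(order_out, v)
    kids <- adj$to[adj$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(order_out) != length(vars)) cd_stop("directed edges contain a cycle")
  order_out
}

parent_vars <- function(spec, v) {
  terms <- spec$edges$from[spec$edges$to == v]
  unique(unlist(lapply(terms, term_constituents)))
}

#' d-separation basis set of a path specification
#'
#' One independence claim per non-adjacent pair of variables not declared
#' as a correlated-error pair, conditioned on the union of both variables'
#' parents; the pair is ordered topologically and claims are returned in a
#' deterministic order independent of how the spec was written.
#'
#' @param spec A [path_spec()].
#' @return List of claims, each `list(x, y, given)` with `x` topologically
#'   before `y`.
#' @export
dsep_basis_set <- function(spec) {
  topo <- topo_order(spec)
  adj <- spec$adjacency
  corr <- spec$correlations
  claims <- list()
  nv <- length(topo)
  if (nv < 2L) return(claims)
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      u <- topo[i]; v <- topo[j]
      directed <- any((adj$from == u & adj$to == v) | (adj$from == v & adj$to == u))
      correlated <- any(corr$a == min(u, v) & corr$b == max(u, v))
      if (directed || correlated) next
      given <- sort(setdiff(union(parent_vars(spec, u), parent_vars(spec, v)),
                            c(u, v)))
      claims[[length(claims) + 1L]] <- list(x = u, y = v, given = given)
    }
  }
  claims
}

# build the regression frame for a set of parent terms; interaction terms
# are products of mean-centered constituents
term_frame <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- term_constituents(tm)
    if (length(parts) == 1L) {
      data[[tm]]
    } else {
      Reduce(`*`, lapply(parts, function(p) data[[p]] - mean(data[[p]])))
    }
  })
  df <- as.data.frame(cols)
  names(df) <- gsub(":", "_x_", terms, fixed = TRUE)
  df
}

claim_p_value <- function(data, claim) {
  df <- data.frame(.y = data[[claim$y]], .x = data[[claim$x]])
  if (length(claim$given)) df <- cbind(df, data[claim$given])
  fit <- stats::lm(.y ~ ., data = df)
  ct <- summary(fit)$coefficients
  if (!".x" %in% rownames(ct)) cd_stop("claim test degenerate for ",
                                       claim$x, " _||_ ", claim$y)
  ct[".x", 4]
}

#' Combine independence-claim p-values into Fisher's C
#'
#' `C = -2 sum log p_i` with `df = 2k` and a global p-value from the
#' upper chi-squared tail. A saturated model (no claims) has C = 0 and a
#' vacuously perfect fit, flagged.
#'
#' @param p Vector of claim p-values in (0, 1].
#' @return List: `C`, `df`, `p_value`, `saturated`.
#' @export
fishers_c <- function(p) {
  if (length(p) == 0L) {
    return(list(C = 0, df = 0L, p_value = 1, saturated = TRUE))
  }
  if (any(p <= 0)) cd_stop("claim test degenerate: p-value of 0")
  if (any(p > 1)) cd_stop("p-values must be in (0, 1]")
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p_value = stats::pchisq(C, df, lower.tail = FALSE),
       saturated = FALSE)
}

#' Fit a piecewise path model
#'
#' Each endogenous variable is regressed on its parent terms by ordinary
#' least squares; coefficients are standardized as `b * sd(x)/sd(y)` (for
#' a one-predictor equation the standardized coefficient equals the
#' Pearson correlation). Correlated-error pairs are reported as Pearson
#' correlations of the two variables' residuals (raw variables when
#' exogenous). Global fit is Fisher's C over the d-separation basis set,
#' and `AICc = C + 2 K n / (n - K - 1)` with K the number of estimated
#' parameters (slopes, intercepts, error variances and residual
#' correlations).
#'
#' @param data Data frame containing every spec variable.
#' @param spec A [path_spec()].
#' @param kappa_max Condition-number threshold for collinear parents.
#' @return Object of class `path_model`.
#' @export
fit_path_model <- function(data, spec, kappa_max = 1e8) {
  miss <- setdiff(spec$vars, names(data))
  if (length(miss)) cd_stop("data missing variables: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[spec$vars])
  if (!all(cc)) {
    cd_warn("dropping ", sum(!cc), " incomplete case(s)")
    data <- data[cc, , drop = FALSE]
  }
  n <- nrow(data)
  endo <- unique(spec$edges$to)
  k_params <- nrow(spec$correlations)
  fits <- list()
  coef_rows <- list()
  resids <- list()
  for (v in endo) {
    terms <- spec$edges$from[spec$edges$to == v]
    if (n < length(terms) + 2L) {
      cd_stop("too few cases for the equation of ", v, ": need n >= ",
              length(terms) + 2L)
    }
    tf <- term_frame(data, terms)
    x_mat <- as.matrix(cbind(1, tf))
    if (kappa(scale(x_mat[, -1, drop = FALSE]), exact = TRUE) > kappa_max &&
        ncol(x_mat) > 2L) {
      cd_stop("collinear parents in equation for ", v)
    }
    df_eq <- cbind(data.frame(.y = data[[v]]), tf)
    fit <- stats::lm(.y ~ ., data = df_eq)
    ct <- summary(fit)$coefficients
    sdy <- stats::sd(data[[v]])
    for (ti in seq_along(terms)) {
      cn <- names(tf)[ti]
      coef_rows[[length(coef_rows) + 1L]] <- data.frame(
        response = v, predictor = terms[ti],
        estimate = unname(ct[cn, 1]),
        std_estimate = unname(ct[cn, 1]) * stats::sd(tf[[cn]]) / sdy,
        p_value = unname(ct[cn, 4]), stringsAsFactors = FALSE)
    }
    k_params <- k_params + length(terms) + 2L  # slopes + intercept + error variance
    fits[[v]] <- fit
    resids[[v]] <- stats::residuals(fit)
  }
  corr_rows <- lapply(seq_len(nrow(spec$correlations)), function(i) {
    a <- spec$correlations$a[i]; b <- spec$correlations$b[i]
    xa <- if (a %in% endo) resids[[a]] else data[[a]]
    xb <- if (b %in% endo) resids[[b]] else data[[b]]
    ct <- stats::cor.test(xa, xb)
    data.frame(a = a, b = b, r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  claims <- dsep_basis_set(spec)
  claim_p <- vapply(claims, function(cl) claim_p_value(data, cl), numeric(1))
  fc <- fishers_c(claim_p)
  aicc <- if (n > k_params + 1L) {
    fc$C + 2 * k_params * n / (n - k_params - 1)
  } else {
    NA_real_
  }
  structure(list(
    spec = spec,
    coefficients = do.call(rbind, coef_rows),
    correlations = do.call(rbind, corr_rows),
    claims = claims, claim_p = claim_p,
    C = fc$C, df = fc$df, global_p = fc$p_value, saturated = fc$saturated,
    K = k_params, n = n, AICc = aicc
  ), class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Piecewise path model: %d equations, Fisher's C = %.3f (df %d, p = %.3g), K = %d, n = %d, AICc = %.2f\n",
              length(unique(x$coefficients$response)), x$C, x$df, x$global_p,
              x$K, x$n, x$AICc))
  print(x$coefficients, row.names = FALSE)
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Compare candidate path models by AICc
#'
#' Candidates are fitted on the same data and ranked by AICc; ties are
#' broken by smaller K, then by candidate order. Candidates with
#' `n <= K + 1` are flagged infeasible and never ranked best.
#'
#' @param data Data frame.
#' @param specs List of [path_spec()] candidates.
#' @return Data frame with one row per candidate (`model`, `K`, `C`, `df`,
#'   `global_p`, `AICc`, `infeasible`, `best`) plus the fitted models in
#'   `attr(, "fits")`.
#' @export
compare_path_models <- function(data, specs) {
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_path_model(data, sp), error = function(e) e)
  })
  rows <- lapply(seq_along(specs), function(i) {
    f <- fits[[i]]
    nm <- specs[[i]]$name %||% paste0("model_", i)
    if (inherits(f, "error")) {
      data.frame(model = nm, K = NA_integer_, C = NA_real_, df = NA_integer_,
                 global_p = NA_real_, AICc = NA_real_, infeasible = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model = nm, K = f$K, C = f$C, df = f$df, global_p = f$global_p,
                 AICc = f$AICc, infeasible = is.na(f$AICc),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ord <- order(out$infeasible, out$AICc, out$K, seq_len(nrow(out)))
  out <- out[ord, ]
  out$best <- FALSE
  if (!out$infeasible[1]) out$best[1] <- TRUE
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  out
}

#' Simulate Gaussian data from a path specification
#'
#' Exogenous variables are standard normal; each endogenous variable is
#' the linear combination of its parent terms plus Gaussian error.
#' Correlated-error pairs are induced by a shared latent term.
#'
#' @param spec A [path_spec()].
#' @param n Sample size.
#' @param coefs Named numeric vector of edge coefficients keyed as
#'   `"from->to"`; unnamed edges default to 0.5.
#' @param sd_resid Residual standard deviation of endogenous variables.
#' @param corr_strength Loading of the shared latent term for correlated
#'   pairs.
#' @param seed Optional RNG seed.
#' @return Data frame with one column per variable.
#' @export
simulate_path_data <- function(spec, n, coefs = NULL, sd_resid = 1,
                               corr_strength = 0.5, seed = NULL) {
  set_local_seed(seed)
  topo <- topo_order(spec)
  data <- as.data.frame(stats::setNames(
    replicate(length(topo), numeric(n), simplify = FALSE), topo))
  shared <- list()
  for (i in seq_len(nrow(spec$correlations))) {
    z <- stats::rnorm(n)
    shared[[spec$correlations$a[i]]] <- c(shared[[spec$correlations$a[i]]], list(z))
    shared[[spec$correlations$b[i]]] <- c(shared[[spec$correlations$b[i]]], list(z))
  }
  for (v in topo) {
    terms <- spec$edges$from[spec$edges$to == v]
    mu <- 0
    for (tm in terms) {
      key <- paste0(tm, "->", v)
      beta <- if (!is.null(coefs) && key %in% names(coefs)) coefs[[key]] else 0.5
      parts <- term_constituents(tm)
      val <- Reduce(`*`, lapply(parts, function(p) data[[p]] - mean(data[[p]])))
      mu <- mu + beta * val
    }
    eps <- stats::rnorm(n, 0, if (length(terms)) sd_resid else 1)
    for (z in shared[[v]] %||% list()) eps <- eps + corr_strength * z
    data[[v]] <- mu + eps
  }
  data
}
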