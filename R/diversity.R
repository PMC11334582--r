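#' Shannon diversity index (natural log)
#'
#' H' = -sum p_i log p_i over the positive proportions of a count or
#' abundance vector. Natural logs throughout, so ENS = exp(H').
#'
#' @param x Nonnegative numeric vector with at least one positive entry.
#' @return H' in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0)) cd_stop("negative abundances")
  tot <- sum(x)
  if (tot == 0) cd_stop("Shannon index undefined for an all-zero vector")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Effective number of species from a Shannon index
#'
#' @param h Shannon index H' (nats), >= 0.
#' @return ENS = exp(H').
#' @export
ens <- function(h) {
  if (any(h < 0)) cd_stop("Shannon index must be >= 0")
  exp(h)
}

#' Rarefy one count vector by repeated subsampling without replacement
#'
#' Draws `iterations` multivariate-hypergeometric subsamples of size
#' `depth` (sequential conditional hypergeometric draws, vectorized over
#' iterations).
#'
#' @param x Nonnegative integer count vector with `sum(x) >= depth`.
#' @param depth Subsample size.
#' @param iterations Number of independent subsamples.
#' @return Integer matrix, `iterations` rows x `length(x)` columns.
#' @export
rarefy_counts <- function(x, depth, iterations = 100L) {
  if (depth <= 0) cd_stop("depth must be > 0")
  if (any(x < 0) || any(x != round(x))) cd_stop("counts must be nonnegative integers")
  n_total <- sum(x)
  if (n_total < depth) cd_stop("sample total ", n_total, " below depth ", depth)
  k <- length(x)
  out <- matrix(0, nrow = iterations, ncol = k)
  remaining <- rep(n_total, iterations)
  to_draw <- rep(depth, iterations)
  for (j in seq_len(k)) {
    nj <- x[j]
    take <- stats::rhyper(iterations, m = nj, n = remaining - nj, k = to_draw)
    out[, j] <- take
    remaining <- remaining - nj
    to_draw <- to_draw - take
  }
  colnames(out) <- names(x)
  out
}

#' Rarefied alpha-diversity per sample
#'
#' For each sample with total count at or above `depth`, the metric is
#' computed on each of `iterations` subsamples of size `depth` drawn
#' without replacement, and averaged across iterations (the metric is
#' averaged, not the counts). Samples below `depth` are dropped with a
#' warning.
#'
#' @param table A [count_table()].
#' @param depth Rarefaction depth (default 3000 reads).
#' @param iterations Number of subsampling iterations (default 100).
#' @param metric One of `"H_shannon"`, `"ENS_ASV"`, `"richness"`.
#' @param seed Optional RNG seed.
#' @return Data frame: `sample_id`, `metric`, `value`, `depth`,
#'   `iterations`.
#' @export
rarefied_metric <- function(table, depth = 3000L, iterations = 100L,
                            metric = c("ENS_ASV", "H_shannon", "richness"),
                            seed = NULL) {
  metric <- match.arg(metric)
  if (depth <= 0) cd_stop("depth must be > 0")
  set_local_seed(seed)
  m <- table$counts
  totals <- rowSums(m)
  keep <- totals >= depth
  if (any(!keep)) {
    cd_warn(sum(!keep), " sample(s) below rarefaction depth ", depth,
            " dropped: ", paste(rownames(m)[!keep], collapse = ", "))
  }
  fun <- switch(metric,
                H_shannon = function(v) shannon(v),
                ENS_ASV = function(v) ens(shannon(v)),
                richness = function(v) sum(v > 0))
  ids <- rownames(m)[keep]
  vals <- vapply(ids, function(sid) {
    sub <- rarefy_counts(m[sid, ], depth, iterations)
    mean(apply(sub, 1, fun))
  }, numeric(1))
  data.frame(sample_id = ids, metric = metric, value = unname(vals),
             depth = depth, iterations = iterations, stringsAsFactors = FALSE)
}

# closed-form expectation of rarefied richness (hypergeometric)
expected_rarefied_richness <- function(x, depth) {
  n_total <- sum(x)
  sum(1 - exp(lchoose(n_total - x, depth) - lchoose(n_total, depth)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over taxa.
#'
#' @param x A [count_table()] or a samples-x-taxa nonnegative matrix.
#' @return Symmetric `dist`-convertible matrix with zero diagonal and
#'   values in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2L) cd_stop("need >= 2 samples")
  if (any(m < 0)) cd_stop("negative abundances")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    cd_stop("Bray-Curtis undefined for all-zero sample(s): ",
            paste(rownames(m)[zero], collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  tot <- rowSums(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- sum(abs(m[i, ] - m[j, ]))
      d[i, j] <- d[j, i] <- num / (tot[i] + tot[j])
    }
  }
  d
}

#' Aggregate a count table at a higher taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label. `"unclassified"`
#' labels are kept as distinct bins per parent lineage rather than pooled
#' into one global bin.
#'
#' @param table A [count_table()] with taxonomy.
#' @param rank One of `"genus"`, `"family"`, `"order"`, `"class"`.
#' @return A [count_table()] (no taxonomy) with one column per bin.
#' @export
aggregate_taxonomy <- function(table, rank = c("genus", "family", "order", "class")) {
  rank <- match.arg(rank)
  tax <- table$taxonomy
  if (is.null(tax)) cd_stop("count table has no taxonomy")
  above <- TAX_RANKS[seq_len(match(rank, TAX_RANKS) - 1L)]
  label <- tax[[rank]]
  uncl <- label == "unclassified"
  if (any(uncl)) {
    lineage <- do.call(paste, c(tax[above], list(sep = "|")))
    label[uncl] <- paste0(lineage[uncl], "|unclassified")
  }
  groups <- factor(label, levels = unique(label))
  agg <- t(rowsum(t(table$counts), groups))
  count_table(agg)
}

#' Substrate-use profile and functional diversity of a CLPP plate
#'
#' Absorbances are blank-corrected (negatives clamped to zero); the
#' effective number of substrates utilized is exp of the Shannon index of
#' the corrected profile. A plate with no substrate above blank has an
#' undefined ENS and is flagged.
#'
#' @param plate A [clpp_plate()].
#' @return List with `profile` (corrected absorbances), `ens_clpp`
#'   (NA when undefined) and `defined` flag.
#' @export
clpp_profile <- function(plate) {
  if (!inherits(plate, "clpp_plate")) cd_stop("not a clpp_plate")
  corrected <- pmax(plate$absorbance - plate$blank, 0)
  if (all(corrected == 0)) {
    return(list(profile = corrected, ens_clpp = NA_real_, defined = FALSE))
  }
  list(profile = corrected, ens_clpp = ens(shannon(corrected)), defined = TRUE)
}
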