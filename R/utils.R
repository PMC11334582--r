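`%||%` <- function(a, b) if (is.null(a)) b else a

cd_stop <- function(...) stop(paste0(...), call. = FALSE)

cd_warn <- function(...) warning(paste0(...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' All stochastic stages of a run draw from sub-seeds derived from one
#' master seed by a fixed label, so partial re-runs of a stage reproduce
#' exactly. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.double(seed)) %% 2147000000 + h * 1009) %% 2147483647)
}

set_local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# deterministic checksum of an R object (config provenance in manifests)
config_checksum <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
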