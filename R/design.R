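#' Build a strain code from species and origin codes
#'
#' Strains are identified as `species.origin`, e.g. `"S1.O2"`.
#'
#' @param species,origin Character code vectors.
#' @return Character vector of strain codes.
#' @export
strain_code <- function(species, origin) paste(species, origin, sep = ".")

split_strains <- function(strains) {
  strsplit(strains, "+", fixed = TRUE)
}

strain_species <- function(strain_set) {
  vapply(strsplit(strain_set, ".", fixed = TRUE), `[[`, character(1), 1L)
}

strain_origin <- function(strain_set) {
  vapply(strsplit(strain_set, ".", fixed = TRUE), `[[`, character(1), 2L)
}

#' Classify the diversity level of a strain set
#'
#' Levels follow the factorial design: `mono` (one strain),
#' `intraspecific_poly` (one species, several strains),
#' `species_poly` (several species, one strain each) and `full_poly`
#' (several species, several strains per species).
#'
#' @param strain_set Character vector of strain codes (`"S1.O1"` style).
#' @return One of `"mono"`, `"intraspecific_poly"`, `"species_poly"`,
#'   `"full_poly"`.
#' @export
classify_diversity_level <- function(strain_set) {
  if (length(strain_set) == 0L) cd_stop("empty strain set")
  if (anyDuplicated(strain_set)) cd_stop("duplicate strains in strain set")
  sp <- strain_species(strain_set)
  n <- length(strain_set)
  ns <- length(unique(sp))
  if (n == 1L) {
    "mono"
  } else if (ns == 1L) {
    "intraspecific_poly"
  } else if (ns == n) {
    "species_poly"
  } else {
    "full_poly"
  }
}

#' Construct a validated experiment design table
#'
#' @param df Data frame with columns `culture_id`, `treatment`, `strains`
#'   (strain codes joined by `+`), `replicate` and optionally
#'   `diversity_level` (recomputed from `strains`; a contradictory stated
#'   level is an error).
#' @param species,origins Allowed code universes.
#' @return A data frame of class `experiment_design` with the
#'   `diversity_level` column recomputed from the strain sets.
#' @export
experiment_design <- function(df,
                              species = NULL,
                              origins = NULL) {
  req <- c("culture_id", "treatment", "strains", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) cd_stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$culture_id)) cd_stop("duplicate culture_id in design")
  sets <- split_strains(df$strains)
  all_strains <- unique(unlist(sets))
  sp <- strain_species(all_strains)
  or <- strain_origin(all_strains)
  if (!is.null(species) && !all(sp %in% species)) {
    cd_stop("unknown species code: ", paste(setdiff(sp, species), collapse = ", "))
  }
  if (!is.null(origins) && !all(or %in% origins)) {
    cd_stop("unknown origin code: ", paste(setdiff(or, origins), collapse = ", "))
  }
  level <- vapply(sets, classify_diversity_level, character(1))
  if (!is.null(df$diversity_level)) {
    bad <- which(df$diversity_level != level)
    if (length(bad)) {
      cd_stop("diversity_level mismatch for culture ", df$culture_id[bad[1]],
              ": stated '", df$diversity_level[bad[1]], "' but strain set implies '",
              level[bad[1]], "'")
    }
  }
  df$diversity_level <- level
  df$n_strains <- lengths(sets)
  class(df) <- c("experiment_design", "data.frame")
  df
}

#' Enumerate the full factorial species-by-origin design
#'
#' With 3 species and 3 origins this yields the canonical 16 treatment
#' combinations: 9 monocultures, 3 intraspecific polycultures (one species,
#' all origins), 3 species polycultures (all species, one origin) and the
#' full polyculture of all 9 strains, each replicated.
#'
#' @param species,origins Character code vectors.
#' @param replicates Number of replicate cultures per treatment.
#' @return An `experiment_design` data frame.
#' @export
full_factorial_design <- function(species = c("S1", "S2", "S3"),
                                  origins = c("O1", "O2", "O3"),
                                  replicates = 3L) {
  if (replicates < 1L) cd_stop("replicates must be >= 1")
  strains <- as.vector(outer(species, origins, strain_code))
  treatments <- c(
    as.list(strains),
    lapply(species, function(s) strain_code(s, origins)),
    lapply(origins, function(o) strain_code(species, o)),
    list(strains)
  )
  labels <- vapply(treatments, function(x) paste(sort(x), collapse = "+"), character(1))
  df <- data.frame(
    culture_id = paste0(rep(labels, each = replicates), "_r",
                        rep(seq_len(replicates), length(labels))),
    treatment = rep(labels, each = replicates),
    strains = rep(labels, each = replicates),
    replicate = rep(seq_len(replicates), length(labels)),
    stringsAsFactors = FALSE
  )
  experiment_design(df, species = species, origins = origins)
}
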