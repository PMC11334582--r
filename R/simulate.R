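#' Configuration for a synthetic factorial diversity experiment
#'
#' Encodes the statistical structure the analysis assumes: lognormal
#' monoculture biomass around per-strain means, a proportional
#' complementarity boost `delta_ce` and a selection tilt `delta_se` in
#' polycultures, host-specific microbiomes mixed with a shared core
#' composition (host-specificity weight `w`), Dirichlet-multinomial
#' sequencing noise, logistic growth curves, substrate-use plates and
#' lognormal free-living bacterial abundances.
#'
#' @param seed Integer master seed; fixes all randomness of a bundle.
#' @param species,origins Code universes for the factorial design.
#' @param replicates Replicate cultures per treatment.
#' @param biomass_mu Named vector of monoculture biomass means (carbon
#'   units) per strain; default spreads species and origin effects.
#' @param sigma_b Lognormal biomass noise (sd on the log scale).
#' @param delta_ce Complementarity effect: proportional boost (>= -1) of
#'   each strain's expected yield in polyculture.
#' @param delta_se Selection tilt: weighting of high-biomass strains in
#'   the initial polyculture proportions.
#' @param n_taxa Number of synthetic bacterial taxa.
#' @param host_specificity Weight `w` in `[0, 1]` of the strain-specific
#'   composition relative to the shared core.
#' @param dirichlet_alpha Dirichlet concentration of per-sample
#'   compositional noise (`Inf` = none).
#' @param depth_range Integer sequencing depth range (uniform draw).
#' @param fraction_shift Strength of the deterministic compositional shift
#'   separating attached from free-living base compositions.
#' @param rarefaction_depth Depth the analysis will rarefy to; depths
#'   below it are flagged at validation.
#' @param clpp_base_profile Baseline substrate-use probabilities (31 values).
#' @param clpp_specificity Weight of per-strain deviations from the
#'   baseline substrate profile (0 = functionally redundant communities).
#' @param clpp_blank,clpp_signal,clpp_sigma Plate blank level, signal gain
#'   and Gaussian absorbance noise.
#' @param growth_r Named per-strain intrinsic growth rates (day^-1).
#' @param growth_k Monoculture carrying capacity (RFU).
#' @param growth_days Sampling days for growth series.
#' @param sigma_rfu Multiplicative (log-scale) RFU noise.
#' @param abundance_mu,abundance_sigma Lognormal free-living bacterial
#'   abundance parameters.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              species = c("S1", "S2", "S3"),
                              origins = c("O1", "O2", "O3"),
                              replicates = 3L,
                              biomass_mu = NULL,
                              sigma_b = 0.1,
                              delta_ce = 0.2,
                              delta_se = 0,
                              n_taxa = 60L,
                              host_specificity = 0.75,
                              dirichlet_alpha = 200,
                              depth_range = c(5000L, 20000L),
                              fraction_shift = 1,
                              rarefaction_depth = 3000L,
                              clpp_base_profile = NULL,
                              clpp_specificity = 0,
                              clpp_blank = 0.05,
                              clpp_signal = 1,
                              clpp_sigma = 0.05,
                              growth_r = NULL,
                              growth_k = 300,
                              growth_days = 0:14,
                              sigma_rfu = 0.05,
                              abundance_mu = 1.5e6,
                              abundance_sigma = 0.2) {
  strains <- as.vector(outer(species, origins, strain_code))
  if (is.null(biomass_mu)) {
    sp_base <- stats::setNames(seq(180, 300, length.out = length(species)), species)
    or_fact <- stats::setNames(seq(0.9, 1.1, length.out = length(origins)), origins)
    biomass_mu <- stats::setNames(
      sp_base[strain_species(strains)] * or_fact[strain_origin(strains)], strains)
  }
  if (is.null(growth_r)) {
    sp_base <- stats::setNames(seq(0.5, 0.7, length.out = length(species)), species)
    or_fact <- stats::setNames(seq(0.95, 1.05, length.out = length(origins)), origins)
    growth_r <- stats::setNames(
      sp_base[strain_species(strains)] * or_fact[strain_origin(strains)], strains)
  }
  if (is.null(clpp_base_profile)) {
    clpp_base_profile <- 0.05 + 0.9 * ((seq_len(31) * 13L) %% 31L) / 30
  }
  cfg <- structure(list(
    seed = as.integer(seed), species = species, origins = origins,
    strains = strains, replicates = as.integer(replicates),
    biomass_mu = biomass_mu, sigma_b = sigma_b,
    delta_ce = delta_ce, delta_se = delta_se,
    n_taxa = as.integer(n_taxa), host_specificity = host_specificity,
    dirichlet_alpha = dirichlet_alpha, depth_range = as.integer(depth_range),
    fraction_shift = fraction_shift, rarefaction_depth = as.integer(rarefaction_depth),
    clpp_base_profile = clpp_base_profile, clpp_specificity = clpp_specificity,
    clpp_blank = clpp_blank, clpp_signal = clpp_signal, clpp_sigma = clpp_sigma,
    growth_r = growth_r, growth_k = growth_k, growth_days = growth_days,
    sigma_rfu = sigma_rfu,
    abundance_mu = abundance_mu, abundance_sigma = abundance_sigma
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$delta_ce < -1) cd_stop("delta_ce < -1 implies negative biomass")
  if (cfg$sigma_b < 0 || cfg$sigma_rfu < 0 || cfg$clpp_sigma < 0) {
    cd_stop("noise parameters must be >= 0")
  }
  if (cfg$host_specificity < 0 || cfg$host_specificity > 1) {
    cd_stop("host_specificity must be in [0, 1]")
  }
  if (any(cfg$biomass_mu <= 0)) cd_stop("biomass means must be positive")
  if (length(cfg$depth_range) != 2L || cfg$depth_range[1] > cfg$depth_range[2]) {
    cd_stop("depth_range must be (min, max) with min <= max")
  }
  if (length(cfg$clpp_base_profile) != 31L) cd_stop("clpp_base_profile must have 31 entries")
  if (any(cfg$clpp_base_profile < 0 | cfg$clpp_base_profile > 1)) {
    cd_stop("substrate-use probabilities must lie in [0, 1]")
  }
  if (cfg$depth_range[1] < cfg$rarefaction_depth) {
    cd_warn("minimum sequencing depth ", cfg$depth_range[1],
            " is below the rarefaction depth ", cfg$rarefaction_depth,
            "; some samples may be dropped at rarefaction")
  }
  invisible(cfg)
}

# Deterministic per-strain composition profiles, fraction-shift loadings,
# substrate profiles and a synthetic 6-rank taxonomy. No randomness here:
# profiles are part of the model, not of the noise.
taxa_profiles <- function(cfg) {
  n <- cfg$n_taxa
  strains <- cfg$strains
  n_sp <- length(cfg$species)
  n_st <- length(strains)
  n_core <- max(4L, round(0.25 * n))
  n_spb <- max(2L, (n - n_core) * 3L %/% (5L * n_sp))
  n_stb <- max(1L, (n - n_core - n_spb * n_sp) %/% n_st)
  used <- n_core + n_spb * n_sp + n_stb * n_st
  if (used > n) cd_stop("n_taxa too small for the design (need >= ", used, ")")
  taxa <- sprintf("ASV_%03d", seq_len(n))
  geo <- function(k, r = 0.75) {
    w <- r^(seq_len(k) - 1)
    w / sum(w)
  }
  core_idx <- seq_len(n_core)
  sp_idx <- lapply(seq_len(n_sp), function(s) n_core + (s - 1L) * n_spb + seq_len(n_spb))
  st_idx <- lapply(seq_len(n_st), function(i) n_core + n_spb * n_sp + (i - 1L) * n_stb + seq_len(n_stb))
  pi_core <- rep(0.1 / n, n)
  pi_core[core_idx] <- pi_core[core_idx] + 0.9 * geo(n_core)
  pi_strain <- matrix(0, nrow = n_st, ncol = n, dimnames = list(strains, taxa))
  sp_of <- match(strain_species(strains), cfg$species)
  for (i in seq_len(n_st)) {
    p <- rep(0.10 / n, n)
    p[core_idx] <- p[core_idx] + 0.15 * geo(n_core)
    p[sp_idx[[sp_of[i]]]] <- p[sp_idx[[sp_of[i]]]] + 0.45 * geo(n_spb)
    p[st_idx[[i]]] <- p[st_idx[[i]]] + 0.30 * geo(n_stb, 0.6)
    pi_strain[i, ] <- p / sum(p)
  }
  lambda <- (((seq_len(n) * 37L) %% 21L) - 10L) / 10
  gid <- ceiling(seq_len(n) / 2)
  fid <- ceiling(gid / 2); oid <- ceiling(fid / 2)
  cid <- ceiling(oid / 2); pid <- ceiling(cid / 2)
  genus <- ifelse(seq_len(n) %% 10L == 0L, "unclassified", sprintf("g%02d", gid))
  taxonomy <- data.frame(
    taxon_id = taxa, domain = "Bacteria",
    phylum = sprintf("p%02d", pid), class = sprintf("c%02d", cid),
    order = sprintf("o%02d", oid), family = sprintf("f%02d", fid),
    genus = genus, stringsAsFactors = FALSE
  )
  clpp_strain <- matrix(0, nrow = n_st, ncol = 31L, dimnames = list(strains, NULL))
  for (i in seq_len(n_st)) {
    rot <- ((seq_len(31) + 3L * i - 1L) %% 31L) + 1L
    clpp_strain[i, ] <- cfg$clpp_base_profile[rot]
  }
  list(taxa = taxa, pi_core = pi_core / sum(pi_core), pi_strain = pi_strain,
       lambda = lambda, taxonomy = taxonomy, clpp_strain = clpp_strain)
}

# Initial strain proportions of a culture, tilted towards high-biomass
# strains when delta_se != 0.
strain_proportions <- function(cfg, strain_set) {
  mu <- cfg$biomass_mu[strain_set]
  w <- 1 + cfg$delta_se * (mu - mean(mu)) / mean(mu)
  w <- pmax(w, 1e-6)
  stats::setNames(w / sum(w), strain_set)
}

logistic_rfu <- function(t, x0, r, k) {
  e <- exp(r * t)
  k * x0 * e / (k + x0 * (e - 1))
}

#' Simulate biomass, growth series and analytic ground truth
#'
#' Monoculture biomass of strain i is LogNormal(log mu_i, sigma_b);
#' polyculture expected biomass is `sum(p_i mu_i) (1 + delta_ce)` with
#' `p_i` the (possibly selection-tilted) initial proportions. Growth
#' series follow per-strain logistic curves (initial total 10 RFU split by
#' the proportions) with multiplicative noise. The truth records, per
#' polyculture treatment, the expected net biodiversity effect and its
#' complementarity/selection split computed in closed form from the model
#' (including the lognormal mean factor exp(sigma_b^2/2)).
#'
#' @param cfg A [simulation_config()].
#' @param design An [experiment_design()] table.
#' @param seed Optional seed (defaults to the config seed).
#' @return List with `biomass` (per-culture carbon), `growth` (long RFU
#'   series), and `truth` (treatment-level expectations, per-culture strain
#'   proportions and per-strain observed yields).
#' @export
simulate_biomass <- function(cfg, design, seed = cfg$seed) {
  validate_simulation_config(cfg)
  set_local_seed(seed)
  phi <- exp(cfg$sigma_b^2 / 2)
  sets <- split_strains(design$strains)
  n_cult <- nrow(design)
  biomass <- numeric(n_cult)
  prop_rows <- vector("list", n_cult)
  yield_rows <- vector("list", n_cult)
  growth_rows <- vector("list", n_cult)
  mean_mu_all <- mean(cfg$biomass_mu)
  for (ci in seq_len(n_cult)) {
    comp <- sets[[ci]]
    k <- length(comp)
    p <- strain_proportions(cfg, comp)
    mu <- cfg$biomass_mu[comp]
    boost <- if (k > 1L) 1 + cfg$delta_ce else 1
    expected <- sum(p * mu) * boost
    obs <- expected * exp(stats::rnorm(1, 0, cfg$sigma_b))
    biomass[ci] <- obs
    prop_rows[[ci]] <- data.frame(culture_id = design$culture_id[ci],
                                  strain = comp, proportion = unname(p),
                                  stringsAsFactors = FALSE)
    yield_rows[[ci]] <- data.frame(culture_id = design$culture_id[ci],
                                   strain = comp,
                                   yield = obs * unname(p * mu) / sum(p * mu),
                                   stringsAsFactors = FALSE)
    r <- cfg$growth_r[comp]
    kcap <- cfg$growth_k * (cfg$biomass_mu[comp] / mean_mu_all) * p * boost
    curve <- rowSums(vapply(seq_len(k), function(i) {
      logistic_rfu(cfg$growth_days, 10 * p[i], r[i], kcap[i])
    }, numeric(length(cfg$growth_days))))
    noisy <- curve * exp(stats::rnorm(length(curve), 0, cfg$sigma_rfu))
    growth_rows[[ci]] <- data.frame(culture_id = design$culture_id[ci],
                                    day = cfg$growth_days, rfu = noisy,
                                    stringsAsFactors = FALSE)
  }
  # closed-form expectations per polyculture treatment
  treats <- unique(design[design$diversity_level != "mono",
                          c("treatment", "diversity_level")])
  truth_rows <- lapply(seq_len(nrow(treats)), function(i) {
    comp <- split_strains(treats$treatment[i])[[1]]
    k <- length(comp)
    p <- strain_proportions(cfg, comp)
    mu <- cfg$biomass_mu[comp]
    m_i <- mu * phi
    dry <- unname(p) * (1 + cfg$delta_ce) - 1 / k
    ce <- k * mean(dry) * mean(m_i)
    se <- sum((dry - mean(dry)) * (m_i - mean(m_i)))
    data.frame(treatment = treats$treatment[i],
               diversity_level = treats$diversity_level[i],
               expected_delta_y = ce + se, expected_ce = ce, expected_se = se,
               stringsAsFactors = FALSE)
  })
  truth <- list(
    treatments = do.call(rbind, truth_rows),
    proportions = do.call(rbind, prop_rows),
    yields = do.call(rbind, yield_rows)
  )
  growth <- do.call(rbind, growth_rows)
  rownames(growth) <- NULL
  class(growth) <- c("growth_series", "data.frame")
  list(
    biomass = data.frame(culture_id = design$culture_id,
                         biomass_carbon = biomass, stringsAsFactors = FALSE),
    growth = growth,
    truth = truth
  )
}

#' Simulate attached and free-living microbiome count tables
#'
#' Each culture's community composition is the proportion-weighted mixture
#' `sum_i p_i [(1 - w) pi_core + w pi_i]` of its strains' host-specific
#' compositions, deterministically shifted between the attached and
#' free-living fractions, perturbed by a Dirichlet draw with concentration
#' `alpha`, and multinomially sampled at a uniform random depth.
#'
#' @param cfg A [simulation_config()].
#' @param design An [experiment_design()].
#' @param proportions Data frame `culture_id`, `strain`, `proportion`
#'   (as produced by [simulate_biomass()]).
#' @param seed Optional seed.
#' @param fractions Which size fractions to simulate.
#' @return List with one [count_table()] per fraction, a `samples` map and
#'   the expected (noise-free) compositions per sample.
#' @export
simulate_microbiome <- function(cfg, design, proportions = NULL,
                                seed = cfg$seed,
                                fractions = c("attached", "free_living")) {
  validate_simulation_config(cfg)
  set_local_seed(seed)
  prof <- taxa_profiles(cfg)
  w <- cfg$host_specificity
  sets <- split_strains(design$strains)
  out <- list()
  sample_rows <- list()
  expected <- list()
  for (fr in fractions) {
    shift_sign <- if (fr == "attached") 0.5 else -0.5
    mult <- exp(shift_sign * cfg$fraction_shift * prof$lambda)
    m <- matrix(0, nrow = nrow(design), ncol = cfg$n_taxa,
                dimnames = list(paste0(design$culture_id, "__",
                                       if (fr == "attached") "att" else "free"),
                                prof$taxa))
    emat <- m
    for (ci in seq_len(nrow(design))) {
      comp <- sets[[ci]]
      p <- if (is.null(proportions)) {
        strain_proportions(cfg, comp)
      } else {
        pr <- proportions[proportions$culture_id == design$culture_id[ci], ]
        stats::setNames(pr$proportion, pr$strain)[comp]
      }
      if (abs(sum(p) - 1) > 1e-8) cd_stop("strain proportions must sum to 1")
      mix <- (1 - w) * prof$pi_core +
        w * colSums(prof$pi_strain[comp, , drop = FALSE] * unname(p))
      if (abs(sum(mix) - 1) > 1e-8) cd_stop("compositions must sum to 1")
      comp_f <- mix * mult
      comp_f <- comp_f / sum(comp_f)
      q <- if (is.finite(cfg$dirichlet_alpha)) {
        g <- stats::rgamma(cfg$n_taxa, shape = cfg$dirichlet_alpha * comp_f)
        if (sum(g) == 0) comp_f else g / sum(g)
      } else {
        comp_f
      }
      depth <- cfg$depth_range[1] +
        sample.int(cfg$depth_range[2] - cfg$depth_range[1] + 1L, 1L) - 1L
      m[ci, ] <- stats::rmultinom(1, depth, q)[, 1]
      emat[ci, ] <- comp_f
    }
    out[[fr]] <- count_table(m, prof$taxonomy)
    expected[[fr]] <- emat
    sample_rows[[fr]] <- data.frame(sample_id = rownames(m),
                                    culture_id = design$culture_id,
                                    fraction = fr, stringsAsFactors = FALSE)
  }
  list(tables = out,
       samples = do.call(rbind, sample_rows),
       expected_composition = expected)
}

#' Simulate substrate-utilization (CLPP) plates
#'
#' Absorbance is `blank + use_probability * signal + Gaussian noise` for
#' each of the 31 substrates; the community use probability is the
#' proportion-weighted mixture of per-strain profiles (identical profiles
#' when `clpp_specificity = 0`).
#'
#' @inheritParams simulate_microbiome
#' @return Named list of [clpp_plate()] objects, one per culture.
#' @export
simulate_clpp <- function(cfg, design, proportions = NULL, seed = cfg$seed) {
  validate_simulation_config(cfg)
  set_local_seed(seed)
  prof <- taxa_profiles(cfg)
  sets <- split_strains(design$strains)
  plates <- vector("list", nrow(design))
  names(plates) <- design$culture_id
  for (ci in seq_len(nrow(design))) {
    comp <- sets[[ci]]
    p <- if (is.null(proportions)) {
      strain_proportions(cfg, comp)
    } else {
      pr <- proportions[proportions$culture_id == design$culture_id[ci], ]
      stats::setNames(pr$proportion, pr$strain)[comp]
    }
    u_strain <- (1 - cfg$clpp_specificity) *
      matrix(cfg$clpp_base_profile, nrow = length(comp), ncol = 31L, byrow = TRUE) +
      cfg$clpp_specificity * prof$clpp_strain[comp, , drop = FALSE]
    u <- colSums(u_strain * unname(p))
    absorb <- cfg$clpp_blank + u * cfg$clpp_signal +
      stats::rnorm(31L, 0, cfg$clpp_sigma)
    plates[[ci]] <- clpp_plate(
      stats::setNames(absorb, sprintf("substrate_%02d", 1:31)),
      blank = cfg$clpp_blank, culture_id = design$culture_id[ci])
  }
  plates
}

#' Simulate a complete experiment bundle
#'
#' Runs the factorial design through all sub-simulators (biomass + growth,
#' microbiome per fraction, CLPP plates, bacterial abundance) using
#' sub-seeds derived from the config seed, and optionally writes the
#' bundle to disk in the package's plain-text formats.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Optional output directory (written via [write_bundle()]).
#' @return Object of class `crossdiv_bundle`.
#' @export
simulate_experiment <- function(cfg, out_dir = NULL) {
  validate_simulation_config(cfg)
  design <- full_factorial_design(cfg$species, cfg$origins, cfg$replicates)
  bm <- simulate_biomass(cfg, design, seed = derive_seed(cfg$seed, "biomass"))
  mb <- simulate_microbiome(cfg, design, bm$truth$proportions,
                            seed = derive_seed(cfg$seed, "microbiome"))
  plates <- simulate_clpp(cfg, design, bm$truth$proportions,
                          seed = derive_seed(cfg$seed, "clpp"))
  set_local_seed(derive_seed(cfg$seed, "abundance"))
  abundance <- data.frame(
    culture_id = design$culture_id,
    bacterial_abundance = exp(stats::rnorm(nrow(design), log(cfg$abundance_mu),
                                           cfg$abundance_sigma)),
    stringsAsFactors = FALSE
  )
  cultures <- merge(merge(design, bm$biomass, by = "culture_id"),
                    abundance, by = "culture_id", sort = FALSE)
  bundle <- structure(list(
    config = cfg, design = design, cultures = cultures,
    counts = mb$tables, asv_samples = mb$samples,
    clpp = plates, growth = bm$growth, truth = c(bm$truth, list(
      expected_composition = mb$expected_composition))
  ), class = "crossdiv_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.crossdiv_bundle <- function(x, ...) {
  cat("crossdiv_bundle:", nrow(x$design), "cultures,",
      nrow(x$asv_samples), "ASV samples,", length(x$clpp), "CLPP plates\n")
  invisible(x)
}

#' Write a simulated bundle to a directory of plain-text tables
#'
#' @param bundle A `crossdiv_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  for (fr in names(bundle$counts)) {
    write_table(bundle$counts[[fr]], fp(paste0("counts_", fr, ".tsv")))
  }
  tax <- bundle$counts[[1]]$taxonomy
  if (!is.null(tax)) {
    utils::write.table(tax, fp("taxonomy.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cult <- bundle$cultures
  meas <- data.frame(sample_id = paste0(cult$culture_id, "__culture"),
                     culture_id = cult$culture_id, fraction = "none",
                     biomass_carbon = cult$biomass_carbon,
                     bacterial_abundance = cult$bacterial_abundance,
                     stringsAsFactors = FALSE)
  asv <- bundle$asv_samples
  asv$biomass_carbon <- NA_real_
  asv$bacterial_abundance <- NA_real_
  samples <- rbind(meas, asv[names(meas)])
  samples <- merge(samples,
                   cult[c("culture_id", "treatment", "strains", "replicate",
                          "diversity_level")],
                   by = "culture_id", sort = FALSE)
  samples <- samples[order(samples$sample_id),
                     c("sample_id", "culture_id", "treatment", "strains",
                       "replicate", "diversity_level", "fraction",
                       "biomass_carbon", "bacterial_abundance")]
  write_table(samples, fp("samples.tsv"))
  write_table(as.data.frame(bundle$growth), fp("growth.tsv"))
  write_clpp(bundle$clpp, fp("clpp.csv"))
  write_table(bundle$truth$treatments, fp("truth_treatments.tsv"))
  write_table(bundle$truth$proportions, fp("truth_proportions.tsv"))
  write_table(bundle$truth$yields, fp("truth_yields.tsv"))
  manifest <- list(seed = bundle$config$seed,
                   config_checksum = config_checksum(unclass(bundle$config)),
                   package_version = as.character(utils::packageVersion("crossdiv")))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `design`, `samples`, `counts` (per fraction),
#'   `cultures`, `growth`, `clpp` and any truth tables present.
#' @export
read_bundle <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  ds <- read_design_and_samples(fp("samples.tsv"))
  tax_path <- if (file.exists(fp("taxonomy.tsv"))) fp("taxonomy.tsv")
  counts <- list()
  for (fr in c("attached", "free_living")) {
    f <- fp(paste0("counts_", fr, ".tsv"))
    if (file.exists(f)) counts[[fr]] <- read_count_table(f, tax_path)
  }
  meas <- ds$samples[ds$samples$fraction == "none", ]
  cultures <- merge(ds$design,
                    meas[c("culture_id", "biomass_carbon", "bacterial_abundance")],
                    by = "culture_id", sort = FALSE)
  truth <- NULL
  if (file.exists(fp("truth_treatments.tsv"))) {
    truth <- list(treatments = read_result_table(fp("truth_treatments.tsv")),
                  proportions = read_result_table(fp("truth_proportions.tsv")),
                  yields = read_result_table(fp("truth_yields.tsv")))
  }
  list(design = ds$design, samples = ds$samples, counts = counts,
       cultures = cultures, growth = read_growth_series(fp("growth.tsv")),
       clpp = read_clpp(fp("clpp.csv")), truth = truth)
}
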