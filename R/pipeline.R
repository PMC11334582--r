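default_sem_specs <- function() {
  additive <- path_spec(
    edges = c("species_richness -> biomass",
              "strain_richness -> biomass",
              "species_richness -> ens_free_living",
              "strain_richness -> ens_free_living",
              "species_richness -> ens_attached",
              "strain_richness -> ens_attached"),
    correlations = c("biomass ~~ bacterial_abundance",
                     "bacterial_abundance ~~ ens_attached"),
    name = "additive")
  interaction <- path_spec(
    edges = c(
      "species_richness -> biomass",
      "strain_richness -> biomass",
      "species_richness:strain_richness -> biomass",
      "species_richness -> ens_free_living",
      "strain_richness -> ens_free_living",
      "species_richness -> ens_attached",
      "strain_richness -> ens_attached"),
    correlations = c("biomass ~~ bacterial_abundance",
                     "bacterial_abundance ~~ ens_attached"),
    name = "interaction")
  list(additive, interaction)
}

pipeline_defaults <- function(config) {
  defaults <- list(
    rarefaction_depth = 3000L, rarefaction_iterations = 100L,
    n_perm = 999L, nmds_restarts = 20L, nmds_k = 2L,
    ci = "t", cor_levels = c("genus", "family", "order", "class"),
    alpha = 0.05
  )
  utils::modifyList(defaults, config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cd_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full cross-domain biodiversity analysis pipeline
#'
#' Consumes a simulated bundle (or a bundle directory of the same layout)
#' and writes the full set of result tables: monoculture PERMANOVA with
#' pairwise comparisons and NMDS coordinates per fraction, monoculture
#' Kruskal-Wallis/Dunn diversity contrasts, per-sample and summarized net
#' biodiversity effects for biomass, growth rate, bacterial ENS per
#' fraction, bacterial abundance and CLPP diversity, the
#' complementarity/selection partition where per-strain yields are
#' available, AICc-compared path models, and taxon-biomass correlation
#' screens per taxonomic level and fraction. A JSON manifest records the
#' seed and a config checksum.
#'
#' @param config Named list (or path to a YAML file): either `simulation`
#'   (arguments for [simulation_config()]) or `input_dir` (a bundle
#'   directory), plus `out_dir`, `seed`, and optional settings
#'   `rarefaction_depth`, `rarefaction_iterations`, `n_perm`,
#'   `nmds_restarts`, `ci`, `cor_levels`.
#' @return Invisibly, a named list of all result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- pipeline_defaults(config)
  if (is.null(config$seed)) cd_stop("config must set a seed")
  if (is.null(config$out_dir)) cd_stop("config must set out_dir")
  seed <- as.integer(config$seed)

  bundle <- stage("input", {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
      cfg <- do.call(simulation_config, sim_args)
      b <- simulate_experiment(cfg)
      list(design = b$design, cultures = b$cultures, counts = b$counts,
           asv_map = b$asv_samples, clpp = b$clpp, growth = b$growth,
           truth = b$truth)
    } else if (!is.null(config$input_dir)) {
      b <- read_bundle(config$input_dir)
      asv_map <- b$samples[b$samples$fraction != "none",
                           c("sample_id", "culture_id", "fraction")]
      list(design = b$design, cultures = b$cultures, counts = b$counts,
           asv_map = asv_map, clpp = b$clpp, growth = b$growth,
           truth = b$truth)
    } else {
      cd_stop("config needs either 'simulation' or 'input_dir'")
    }
  })
  design <- bundle$design
  cultures <- bundle$cultures
  fractions <- names(bundle$counts)
  out <- list()

  # --- rarefied diversity per ASV sample, carried to the culture level
  ens_tables <- stage("rarefied_diversity", {
    lapply(stats::setNames(fractions, fractions), function(fr) {
      rm <- rarefied_metric(bundle$counts[[fr]],
                            depth = config$rarefaction_depth,
                            iterations = config$rarefaction_iterations,
                            metric = "ENS_ASV",
                            seed = derive_seed(seed, paste0("rarefy_", fr)))
      map <- bundle$asv_map[bundle$asv_map$fraction == fr, ]
      merge(rm, map, by = "sample_id")
    })
  })
  out$diversity_samples <- do.call(rbind, lapply(ens_tables, function(x) {
    x[c("sample_id", "culture_id", "fraction", "metric", "value",
        "depth", "iterations")]
  }))
  rownames(out$diversity_samples) <- NULL

  clpp_ens <- stage("clpp_diversity", {
    data.frame(
      culture_id = names(bundle$clpp),
      ens_clpp = vapply(bundle$clpp, function(p) clpp_profile(p)$ens_clpp,
                        numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  })

  grates <- stage("growth_rates", growth_rates(bundle$growth))

  # per-culture response table used by NBE, the path models and the screens
  per_culture <- stage("merge_culture_values", {
    pc <- cultures[c("culture_id", "treatment", "strains", "replicate",
                     "diversity_level", "biomass_carbon", "bacterial_abundance")]
    for (fr in fractions) {
      e <- ens_tables[[fr]][c("culture_id", "value")]
      names(e)[2] <- paste0("ens_", fr)
      pc <- merge(pc, e, by = "culture_id", all.x = TRUE)
    }
    pc <- merge(pc, clpp_ens, by = "culture_id", all.x = TRUE)
    merge(pc, grates, by = "culture_id", all.x = TRUE)
  })

  # --- monoculture community structure: PERMANOVA + pairwise + NMDS
  mono_ids <- design$culture_id[design$diversity_level == "mono"]
  mono_strain <- stats::setNames(
    vapply(split_strains(design$strains[design$diversity_level == "mono"]),
           `[[`, character(1), 1L), mono_ids)
  perm_rows <- list(); pair_rows <- list(); nmds_rows <- list()
  stage("monoculture_permanova", {
    for (fr in fractions) {
      map <- bundle$asv_map[bundle$asv_map$fraction == fr &
                              bundle$asv_map$culture_id %in% mono_ids, ]
      m <- bundle$counts[[fr]]$counts[map$sample_id, , drop = FALSE]
      rel <- m / rowSums(m)
      d <- bray_curtis(rel)
      strains <- mono_strain[map$culture_id]
      for (fac in c("species", "origin")) {
        g <- if (fac == "species") strain_species(strains) else strain_origin(strains)
        res <- permanova(d, g, n_perm = config$n_perm,
                         seed = derive_seed(seed, paste("permanova", fr, fac)))
        perm_rows[[length(perm_rows) + 1L]] <- data.frame(
          fraction = fr, factor = fac, pseudo_F = res$pseudo_F, R2 = res$R2,
          p_value = res$p_value, df_between = res$df_between,
          df_within = res$df_within, stringsAsFactors = FALSE)
        pw <- pairwise_permanova(d, g, n_perm = config$n_perm,
                                 adjust = "bonferroni",
                                 seed = derive_seed(seed, paste("pairwise", fr, fac)))
        pw <- cbind(fraction = fr, factor = fac, pw)
        pair_rows[[length(pair_rows) + 1L]] <- pw
      }
      ord <- nmds(d, k = config$nmds_k, restarts = config$nmds_restarts,
                  seed = derive_seed(seed, paste("nmds", fr)))
      nmds_rows[[length(nmds_rows) + 1L]] <- data.frame(
        fraction = fr, sample_id = rownames(ord$points),
        NMDS1 = ord$points[, 1], NMDS2 = ord$points[, 2],
        stress = ord$stress, stringsAsFactors = FALSE)
    }
  })
  # CLPP profiles of monocultures analysed the same way
  stage("monoculture_clpp_permanova", {
    prof <- t(vapply(bundle$clpp[mono_ids],
                     function(p) clpp_profile(p)$profile, numeric(31)))
    keep <- rowSums(prof) > 0
    if (sum(keep) >= 4L) {
      d <- bray_curtis(prof[keep, , drop = FALSE])
      strains <- mono_strain[mono_ids[keep]]
      for (fac in c("species", "origin")) {
        g <- if (fac == "species") strain_species(strains) else strain_origin(strains)
        res <- permanova(d, g, n_perm = config$n_perm,
                         seed = derive_seed(seed, paste("permanova clpp", fac)))
        perm_rows[[length(perm_rows) + 1L]] <- data.frame(
          fraction = "clpp", factor = fac, pseudo_F = res$pseudo_F, R2 = res$R2,
          p_value = res$p_value, df_between = res$df_between,
          df_within = res$df_within, stringsAsFactors = FALSE)
      }
    }
  })
  out$permanova <- do.call(rbind, perm_rows)
  out$permanova_pairwise <- do.call(rbind, pair_rows)
  out$nmds <- do.call(rbind, nmds_rows)

  # --- monoculture diversity contrasts (Kruskal-Wallis + Dunn)
  kw_rows <- list(); dunn_rows <- list()
  stage("monoculture_rank_tests", {
    mono_pc <- per_culture[per_culture$diversity_level == "mono", ]
    strains <- mono_strain[mono_pc$culture_id]
    vars <- intersect(c(paste0("ens_", fractions), "ens_clpp",
                        "bacterial_abundance"), names(mono_pc))
    for (vn in vars) {
      vals <- mono_pc[[vn]]
      ok <- !is.na(vals)
      for (fac in c("species", "origin")) {
        g <- if (fac == "species") strain_species(strains[ok]) else strain_origin(strains[ok])
        kw <- kruskal_wallis(vals[ok], g)
        kw_rows[[length(kw_rows) + 1L]] <- data.frame(
          variable = vn, factor = fac, statistic = kw$statistic, df = kw$df,
          p_value = kw$p_value, n = kw$n, stringsAsFactors = FALSE)
        dn <- dunn_holm(vals[ok], g)
        dunn_rows[[length(dunn_rows) + 1L]] <- cbind(variable = vn, factor = fac, dn)
      }
    }
  })
  out$kruskal <- do.call(rbind, kw_rows)
  out$dunn <- do.call(rbind, dunn_rows)

  # --- net biodiversity effects for every response variable
  stage("nbe", {
    nbe_vars <- c(biomass = "biomass_carbon", growth_rate = "growth_rate",
                  stats::setNames(paste0("ens_", fractions),
                                  paste0("ens_", fractions)),
                  ens_clpp = "ens_clpp", abundance = "bacterial_abundance")
    samp_rows <- list(); summ_rows <- list()
    for (vn in names(nbe_vars)) {
      col <- nbe_vars[[vn]]
      if (!col %in% names(per_culture)) next
      vals <- data.frame(culture_id = per_culture$culture_id,
                         value = per_culture[[col]], stringsAsFactors = FALSE)
      res <- nbe(design, vals, variable = vn)
      samp_rows[[vn]] <- res
      for (by in c("diversity_level", "treatment")) {
        summ_rows[[paste(vn, by)]] <-
          cbind(grouping = by,
                nbe_summary(res, by = by, ci = config$ci,
                            seed = derive_seed(seed, paste("nbe", vn, by))))
      }
    }
    out$nbe_samples <- do.call(rbind, samp_rows)
    out$nbe_summary <- do.call(rbind, summ_rows)
    rownames(out$nbe_samples) <- NULL
    rownames(out$nbe_summary) <- NULL
  })

  # --- complementarity/selection partition (needs per-strain yields)
  out$partition <- stage("partition", {
    if (is.null(bundle$truth) || is.null(bundle$truth$yields)) {
      NULL
    } else {
      yields <- bundle$truth$yields
      mono_pc <- per_culture[per_culture$diversity_level == "mono", ]
      mono_means <- tapply(mono_pc$biomass_carbon,
                           mono_strain[mono_pc$culture_id], mean, na.rm = TRUE)
      polys <- design[design$diversity_level != "mono", ]
      rows <- lapply(seq_len(nrow(polys)), function(i) {
        y <- yields[yields$culture_id == polys$culture_id[i], ]
        p <- lh_partition(m = unname(mono_means[y$strain]), y_o = y$yield)
        data.frame(culture_id = polys$culture_id[i],
                   treatment = polys$treatment[i],
                   diversity_level = polys$diversity_level[i],
                   delta_y = p$delta_y, ce = p$ce, se = p$se,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    }
  })

  # --- path models
  stage("path_models", {
    sem_df <- per_culture
    n_sp <- vapply(split_strains(sem_df$strains),
                   function(s) length(unique(strain_species(s))), integer(1))
    sem_df$species_richness <- n_sp
    sem_df$strain_richness <- lengths(split_strains(sem_df$strains)) / n_sp
    sem_df$biomass <- sem_df$biomass_carbon
    specs <- if (!is.null(config$sem_specs)) {
      lapply(config$sem_specs, function(s) {
        path_spec(s$edges, s$correlations %||% character(), name = s$name)
      })
    } else {
      default_sem_specs()
    }
    cmp <- compare_path_models(sem_df, specs)
    out$sem_comparison <- cmp
    best <- attr(cmp, "fits")[[1]]
    if (!inherits(best, "error")) {
      out$sem_coefficients <- best$coefficients
      out$sem_correlations <- best$correlations
    }
  })

  # --- taxon-biomass correlation screens per fraction and taxonomic level
  stage("correlation_screens", {
    rows <- list()
    for (fr in fractions) {
      map <- bundle$asv_map[bundle$asv_map$fraction == fr, ]
      biomass <- stats::setNames(per_culture$biomass_carbon, per_culture$culture_id)
      resp <- stats::setNames(unname(biomass[map$culture_id]), map$sample_id)
      resp <- resp[!is.na(resp)]
      sc <- spearman_bh(bundle$counts[[fr]], resp, levels = config$cor_levels)
      rows[[fr]] <- cbind(fraction = fr, sc)
    }
    out$correlations <- do.call(rbind, rows)
    rownames(out$correlations) <- NULL
  })

  # --- write everything
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out)) {
    if (!is.null(out[[nm]])) {
      write_table(as.data.frame(out[[nm]]), file.path(config$out_dir, paste0(nm, ".tsv")))
    }
  }
  manifest <- list(seed = seed,
                   config_checksum = config_checksum(config),
                   package_version = as.character(utils::packageVersion("crossdiv")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   tables = names(out)[!vapply(out, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
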