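TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a validated count table
#'
#' The central container for ASV count data: an integer matrix with samples
#' as rows and taxa as columns, optionally carrying a six-rank taxonomy
#' (`domain` to `genus`; missing assignments are the explicit string
#' `"unclassified"`).
#'
#' @param counts Nonnegative integer matrix, samples x taxa, with unique
#'   dimnames.
#' @param taxonomy Optional data frame with columns `taxon_id` and the six
#'   ranks, covering every taxon.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) cd_stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    cd_stop("counts must have sample (row) and taxon (column) names")
  }
  if (anyDuplicated(rownames(counts))) cd_stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) cd_stop("duplicate taxon ids")
  if (any(!is.finite(counts))) cd_stop("counts contain non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    cd_stop("negative count at taxon ", colnames(counts)[bad[2]],
            ", sample ", rownames(counts)[bad[1]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    cd_stop("non-integer count at taxon ", colnames(counts)[bad[2]],
            ", sample ", rownames(counts)[bad[1]])
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max totals
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    need <- c("taxon_id", TAX_RANKS)
    miss <- setdiff(need, names(taxonomy))
    if (length(miss)) cd_stop("taxonomy missing columns: ", paste(miss, collapse = ", "))
    uncovered <- setdiff(colnames(counts), taxonomy$taxon_id)
    if (length(uncovered)) {
      cd_stop("taxonomy missing taxon: ", uncovered[1])
    }
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), need]
    rownames(taxonomy) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa",
      if (is.null(x$taxonomy)) "(no taxonomy)" else "(with taxonomy)", "\n")
  invisible(x)
}

#' Read a tab-separated count table (taxa as rows, samples as columns)
#'
#' Counts are accepted from integer-literal text only; any other cell is a
#' validation error naming the offending taxon and sample.
#'
#' @param path Count TSV: first column taxon ids, remaining columns samples.
#' @param taxonomy_path Optional taxonomy TSV with columns `taxon_id` and
#'   the six ranks `domain`..`genus`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) cd_stop("count table needs a taxon column and >= 1 sample column")
  taxa <- raw[[1]]
  samples <- names(raw)[-1]
  if (anyDuplicated(taxa)) cd_stop("duplicate taxon ids in ", path)
  if (anyDuplicated(samples)) cd_stop("duplicate sample ids in ", path)
  m <- matrix(0, nrow = length(samples), ncol = length(taxa),
              dimnames = list(samples, taxa))
  for (j in seq_along(samples)) {
    cells <- trimws(raw[[j + 1L]])
    ok <- grepl("^-?[0-9]+$", cells)
    if (!all(ok)) {
      i <- which(!ok)[1]
      cd_stop("non-integer count at taxon ", taxa[i], ", sample ", samples[j],
              " (value '", cells[i], "')")
    }
    m[j, ] <- as.numeric(cells)
  }
  taxonomy <- if (!is.null(taxonomy_path)) {
    utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
  }
  count_table(m, taxonomy)
}

#' Write any result table as deterministic TSV
#'
#' Columns are written in their given order; doubles at fixed 9-decimal
#' precision so a write/read round trip is exact to 1e-9.
#'
#' @param x Data frame (or count_table counts written taxa-as-rows).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  UseMethod("write_table")
}

#' @export
write_table.data.frame <- function(x, path) {
  df <- as.data.frame(x)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.double(col)) df[[nm]] <- sprintf("%.9f", col)
    if (is.logical(col)) df[[nm]] <- ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
  }
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    cd_stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.count_table <- function(x, path) {
  m <- t(x$counts)  # taxa as rows on disk
  fm <- matrix(formatC(m, format = "d"), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(taxon_id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read experiment metadata into a design and a sample table
#'
#' The metadata TSV has one row per sample with columns `sample_id`,
#' `culture_id`, `treatment`, `strains`, `replicate`, `fraction`
#' (`attached`/`free_living` for ASV samples, `none` for culture-level
#' measurements), `biomass_carbon` and `bacterial_abundance`. The
#' diversity level is always recomputed from the strain set; a stated
#' `diversity_level` column is cross-checked.
#'
#' @param path Metadata TSV.
#' @param species,origins Allowed code universes (NULL = unchecked).
#' @param expected_replicates If given, a warning is logged when any
#'   treatment has fewer replicates (lost samples).
#' @return List with elements `design` (one row per culture) and
#'   `samples` (one row per sample).
#' @export
read_design_and_samples <- function(path, species = NULL, origins = NULL,
                                    expected_replicates = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "culture_id", "treatment", "strains", "replicate", "fraction")
  miss <- setdiff(req, names(df))
  if (length(miss)) cd_stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) cd_stop("duplicate sample_id in metadata")
  bad_frac <- setdiff(unique(df$fraction), c("attached", "free_living", "none"))
  if (length(bad_frac)) cd_stop("unknown fraction: ", bad_frac[1])

  cult_cols <- intersect(c("culture_id", "treatment", "strains", "replicate",
                           "diversity_level"), names(df))
  cultures <- unique(df[cult_cols])
  if (anyDuplicated(cultures$culture_id)) {
    cd_stop("inconsistent culture metadata for culture_id ",
            cultures$culture_id[duplicated(cultures$culture_id)][1])
  }
  rownames(cultures) <- NULL
  design <- experiment_design(cultures, species = species, origins = origins)
  if (!is.null(expected_replicates)) {
    n_rep <- table(design$treatment)
    short <- names(n_rep)[n_rep < expected_replicates]
    if (length(short)) {
      cd_warn("treatments with lost replicates: ", paste(short, collapse = ", "))
    }
  }
  samples <- df[c("sample_id", "culture_id", "fraction",
                  intersect(c("biomass_carbon", "bacterial_abundance"), names(df)))]
  list(design = design, samples = samples)
}

#' Read a long-format growth series table
#'
#' @param path TSV with columns `culture_id`, `day`, `rfu`.
#' @return Data frame of class `growth_series`, days strictly increasing
#'   within each culture.
#' @export
read_growth_series <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("culture_id", "day", "rfu"), names(df))
  if (length(miss)) cd_stop("growth table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$rfu < 0)) cd_stop("negative RFU value")
  for (cid in unique(df$culture_id)) {
    d <- df$day[df$culture_id == cid]
    if (any(diff(d) <= 0)) cd_stop("days not strictly increasing for culture ", cid)
  }
  class(df) <- c("growth_series", "data.frame")
  df
}

#' Construct a CLPP plate record
#'
#' @param absorbance Named numeric vector of absorbances for the 31 carbon
#'   substrates.
#' @param blank Blank-well absorbance.
#' @param culture_id Culture identifier.
#' @return Object of class `clpp_plate`.
#' @export
clpp_plate <- function(absorbance, blank, culture_id = NA_character_) {
  if (length(absorbance) != 31L) {
    cd_stop("CLPP plate must have exactly 31 substrate entries, got ",
            length(absorbance))
  }
  if (!is.numeric(absorbance) || !is_scalar_number(blank)) {
    cd_stop("CLPP absorbances must be numeric")
  }
  if (is.null(names(absorbance))) names(absorbance) <- sprintf("substrate_%02d", 1:31)
  structure(list(culture_id = culture_id, absorbance = absorbance, blank = blank),
            class = "clpp_plate")
}

#' Read CLPP plates from a long CSV
#'
#' @param path CSV with columns `culture_id`, `substrate`, `absorbance`;
#'   one `blank` substrate row per culture.
#' @return Named list of [clpp_plate()] objects.
#' @export
read_clpp <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("culture_id", "substrate", "absorbance"), names(df))
  if (length(miss)) cd_stop("CLPP table missing columns: ", paste(miss, collapse = ", "))
  plates <- lapply(split(df, df$culture_id), function(p) {
    blank <- p$absorbance[p$substrate == "blank"]
    if (length(blank) != 1L) cd_stop("culture ", p$culture_id[1], " needs exactly one blank row")
    subs <- p[p$substrate != "blank", ]
    clpp_plate(stats::setNames(subs$absorbance, subs$substrate), blank,
               culture_id = p$culture_id[1])
  })
  plates[unique(df$culture_id)]
}

write_clpp <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    data.frame(culture_id = p$culture_id,
               substrate = c(names(p$absorbance), "blank"),
               absorbance = c(unname(p$absorbance), p$blank),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$absorbance <- sprintf("%.9f", df$absorbance)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
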