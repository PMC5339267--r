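# Readers and writers for the documented tab-separated formats, plus the
# YAML run configuration. All tables are plain TSV with headers; read and
# write round-trip bit-exactly.

#' Read a gradient fraction table
#'
#' Tab-separated file with header columns `fraction`, `refractive_index`
#' (optional), `density` (optional; at least one of the two required),
#' `copies`, `copies_sd` (optional); one file per gradient. Densities are
#' filled from refractive index where absent and fractions are sorted by
#' decreasing density.
#'
#' @param path File path.
#' @param treatment,depth Labels attached to the profile.
#' @return A [gradient_profile()].
#' @export
read_fraction_table <- function(path, treatment = "12C",
                                depth = "surface") {
  df <- .read_tsv(path)
  need <- "fraction" %in% names(df) && "copies" %in% names(df)
  if (!need || !any(c("density", "refractive_index") %in% names(df))) {
    stop("`", path, "`: needs columns `fraction`, `copies`, and at least ",
         "one of `density`/`refractive_index`", call. = FALSE)
  }
  for (col in intersect(c("density", "refractive_index", "copies",
                          "copies_sd"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0L) {
      stop("`", path, "`: non-numeric `", col, "` at row ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  gradient_profile(
    fraction = df$fraction,
    density = if ("density" %in% names(df)) df$density else NULL,
    refractive_index = if ("refractive_index" %in% names(df))
      df$refractive_index else NULL,
    copies = df$copies,
    copies_sd = if ("copies_sd" %in% names(df)) df$copies_sd else NULL,
    treatment = treatment, depth = depth
  )
}

#' Write a gradient fraction table
#'
#' @param profile A [gradient_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(profile, path) {
  stopifnot(inherits(profile, "gradient_profile"))
  out <- profile[, c("fraction", "density", "copies", "copies_sd")]
  .write_tsv(out, path)
}

#' Read a taxon x fraction read-count table
#'
#' Tab-separated matrix: first column `taxon`, second column `rank`
#' (uniform, `class` or `genus`), remaining columns one per fraction
#' identifier; values are integer read counts.
#'
#' @param path File path.
#' @return A [fraction_taxon_table()].
#' @export
read_taxon_table <- function(path) {
  df <- .read_tsv(path)
  if (!identical(names(df)[1:2], c("taxon", "rank"))) {
    stop("`", path, "`: first two columns must be `taxon`, `rank`",
         call. = FALSE)
  }
  rank <- unique(df$rank)
  if (length(rank) != 1L) {
    stop("`", path, "`: `rank` must be uniform within one table",
         call. = FALSE)
  }
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  mode(counts) <- "numeric"
  if (any(is.na(counts))) {
    stop("`", path, "`: non-numeric read counts", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("`", path, "`: negative read counts", call. = FALSE)
  }
  colnames(counts) <- sub("^X", "", colnames(counts))
  fraction_taxon_table(counts, taxa = df$taxon, rank = rank)
}

#' Write a taxon x fraction table
#'
#' @param table A [fraction_taxon_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(table, path) {
  stopifnot(inherits(table, "fraction_taxon_table"))
  df <- data.frame(taxon = table$taxa, rank = table$rank,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read an incubation time series (long format)
#'
#' Tab-separated long format with columns `treatment`, `depth`,
#' `replicate`, `time_h`, `analyte`, `value`. The analyte vocabulary is
#' `peptide`, the free amino acids `A`, `V`, `F`, the fragments `AV`,
#' `VF`, `FA`, `VFA`, plus `NH4`, `Pi` and `cells`.
#'
#' @param path File path.
#' @return A data.frame in the same long format, `time_h` and `value`
#'   numeric.
#' @export
read_incubation_series <- function(path) {
  df <- .read_tsv(path)
  need <- c("treatment", "depth", "replicate", "time_h", "analyte", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("`", path, "`: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$time_h <- as.numeric(df$time_h)
  df$value <- as.numeric(df$value)
  if (any(is.na(df$value)) || any(df$value < 0)) {
    stop("`", path, "`: concentrations must be non-negative numbers",
         call. = FALSE)
  }
  df[, need]
}

#' Write an incubation time series
#'
#' @param series Long-format data.frame (see [read_incubation_series()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incubation_series <- function(series, path) {
  .write_tsv(series, path)
}

#' Write an enrichment report
#'
#' Tab-separated file with the per-taxon report columns; `NA` marks the
#' undefined enrichment (unlabeled relative copy number zero).
#'
#' @param report An `enrichment_report` from [enrichment_analysis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  .write_tsv(as.data.frame(report), path)
}

#' Read a run configuration
#'
#' YAML file with any of the keys `heavy_window` (list `density_min`,
#' `density_max`), `threshold_method`, `abundance_floor`, `constants`
#' (passed to [conversion_constants()]), `simulation` (passed to
#' [sim_config()]), `seed`. Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list of resolved settings with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("heavy_window", "threshold_method", "abundance_floor",
             "constants", "simulation", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("`", path, "`: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list(
    heavy_window = if (!is.null(cfg$heavy_window))
      heavy_window(cfg$heavy_window$density_min,
                   cfg$heavy_window$density_max),
    threshold_method = if (is.null(cfg$threshold_method)) "ci_mean"
      else match.arg(cfg$threshold_method, c("ci_mean", "percentile")),
    abundance_floor = if (is.null(cfg$abundance_floor)) 0.001
      else cfg$abundance_floor,
    constants = do.call(conversion_constants,
                        if (is.null(cfg$constants)) list()
                        else cfg$constants),
    simulation = do.call(sim_config,
                         if (is.null(cfg$simulation)) list()
                         else cfg$simulation),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
  out
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
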