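# The core SIP statistic: per-taxon relative 16S gene copy numbers inside
# the heavy-density window, percentage enrichment of the labeled gradient
# over the unlabeled one, and the confidence-interval noise threshold used
# to call taxa as active incorporators.

#' Taxon x fraction read-count table
#'
#' Read counts per taxon and gradient fraction, with per-fraction (column)
#' proportions. Columns whose read total is zero are flagged and their
#' proportions left `NA` rather than silently zero-filled.
#'
#' @param counts Non-negative integer matrix, taxa in rows, fractions in
#'   columns; column names are fraction identifiers matching a
#'   [gradient_profile()]'s `fraction` column.
#' @param taxa Taxon labels (default: rownames of `counts`); must be unique
#'   within a rank.
#' @param rank Single rank label for the table, `"class"` or `"genus"`.
#' @return A `fraction_taxon_table`: list with `counts`, `proportions`,
#'   `taxa`, `rank`, `fractions`, `empty_fractions`.
#' @export
fraction_taxon_table <- function(counts, taxa = rownames(counts),
                                 rank = c("genus", "class")) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("`counts` needs column names (fraction identifiers)", call. = FALSE)
  }
  if (is.null(taxa)) stop("taxon labels are required", call. = FALSE)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label within rank: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  rownames(counts) <- taxa
  totals <- colSums(counts)
  props <- sweep(counts, 2, totals, "/")
  props[, totals == 0] <- NA_real_
  structure(
    list(
      counts = counts, proportions = props, taxa = taxa, rank = rank,
      fractions = colnames(counts), empty_fractions = colnames(counts)[totals == 0]
    ),
    class = "fraction_taxon_table"
  )
}

#' @export
print.fraction_taxon_table <- function(x, ...) {
  cat("<fraction_taxon_table> ", length(x$taxa), " ", x$rank, "-level taxa x ",
      length(x$fractions), " fractions (", sum(x$counts), " reads)\n", sep = "")
  invisible(x)
}

#' Sum genus-level counts into class-level counts
#'
#' Class-level results are computed by summing genus read counts within each
#' class before proportions are taken, not by averaging genus-level
#' enrichments.
#'
#' @param table A genus-rank [fraction_taxon_table()].
#' @param class_of Named character vector mapping each genus label to its
#'   class.
#' @return A class-rank `fraction_taxon_table`.
#' @export
aggregate_to_class <- function(table, class_of) {
  stopifnot(inherits(table, "fraction_taxon_table"))
  if (table$rank != "genus") {
    stop("`table` must be genus-rank to aggregate to class", call. = FALSE)
  }
  missing <- setdiff(table$taxa, names(class_of))
  if (length(missing) > 0L) {
    stop("no class mapping for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- factor(class_of[table$taxa])
  agg <- rowsum(table$counts, group = cls)
  fraction_taxon_table(agg, taxa = rownames(agg), rank = "class")
}

#' Per-taxon 16S gene copy numbers within a density window
#'
#' For each taxon, the proportion of its reads in each window fraction is
#' multiplied by that fraction's total 16S gene copy number and summed over
#' the window: copies_taxon = sum_f proportion[taxon, f] * copies[f].
#' Fractions are matched between the read table and the gradient profile by
#' fraction identifier.
#'
#' @param table A [fraction_taxon_table()].
#' @param profile The matching [gradient_profile()].
#' @param window A [heavy_window()].
#' @return Named numeric vector of copies per taxon.
#' @export
taxon_copy_numbers <- function(table, profile, window) {
  stopifnot(inherits(table, "fraction_taxon_table"),
            inherits(profile, "gradient_profile"),
            inherits(window, "heavy_window"))
  heavy <- select_heavy(profile, window)
  ids <- as.character(heavy$fraction)
  unmatched <- setdiff(ids, table$fractions)
  if (length(unmatched) > 0L) {
    stop("window fractions missing from the taxon table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  props <- table$proportions[, ids, drop = FALSE]
  props[is.na(props)] <- 0  # empty fractions contribute no copies
  out <- as.vector(props %*% heavy$copies)
  names(out) <- table$taxa
  out
}

#' Relative copy numbers within the window
#'
#' Each taxon's window copy number divided by the summed copies of all taxa
#' in the same window, so values sum to 1. This normalization corrects for
#' the slight difference in total DNA between the labeled and unlabeled
#' gradients.
#'
#' @param taxon_copies Named numeric vector from [taxon_copy_numbers()].
#' @return Named numeric vector summing to 1.
#' @export
relative_copy_numbers <- function(taxon_copies) {
  tot <- sum(taxon_copies)
  if (!is.finite(tot) || tot <= 0) {
    stop("total copy number in the window must be positive", call. = FALSE)
  }
  taxon_copies / tot
}

#' Percentage enrichment of the labeled gradient over the unlabeled
#'
#' The per-taxon activity statistic:
#' `100 * (rel_13C - rel_12C) / rel_12C`, where the relative copy numbers
#' are summed over the same heavy-density window in each gradient. 100%
#' enrichment means the taxon's heavy-window relative copy number is twice
#' as abundant in the labeled treatment. Where `rel_12C` is zero with
#' `rel_13C` positive the statistic is undefined and returned as `NA` (never
#' infinity, never dropped).
#'
#' @param rel_13c,rel_12c Named numeric vectors from
#'   [relative_copy_numbers()]; taxa are outer-joined, a side's missing
#'   taxon treated as relative copy number 0.
#' @return Named numeric vector of percent enrichment (may be negative; `NA`
#'   marks undefined).
#' @export
percent_enrichment <- function(rel_13c, rel_12c) {
  taxa <- union(names(rel_13c), names(rel_12c))
  if (is.null(taxa)) {  # unnamed scalars / vectors: positional
    stopifnot(length(rel_13c) == length(rel_12c))
    r13 <- as.numeric(rel_13c)
    r12 <- as.numeric(rel_12c)
  } else {
    r13 <- ifelse(taxa %in% names(rel_13c), rel_13c[taxa], 0)
    r12 <- ifelse(taxa %in% names(rel_12c), rel_12c[taxa], 0)
  }
  out <- ifelse(r12 > 0, 100 * (r13 - r12) / r12, NA_real_)
  # rel12 = rel13 = 0: no signal on either side, defined as 0 change
  out[r12 == 0 & r13 == 0] <- 0
  names(out) <- taxa
  out
}

#' Noise threshold from positive enrichment values
#'
#' Estimates the error/noise level of the percentage-enrichment statistic
#' from all strictly positive enrichment values among taxa, and turns it
#' into a calling threshold. Two methods:
#' \describe{
#'   \item{`ci_mean`}{upper limit of the two-sided 95% confidence interval
#'     of the mean of the positive values (t-distribution); the reported
#'     `noise` is the interval half-width.}
#'   \item{`percentile`}{the 97.5th percentile of the positive values
#'     (`noise` equals the threshold).}
#' }
#'
#' @param enrichments Numeric vector of per-taxon percent enrichments
#'   (negatives and `NA`s are ignored by definition).
#' @param method `"ci_mean"` or `"percentile"`.
#' @param conf Confidence level (default 0.95).
#' @return List with `threshold`, `noise`, `n_positive`, `method`, `conf`.
#' @export
noise_threshold <- function(enrichments, method = c("ci_mean", "percentile"),
                            conf = 0.95) {
  method <- match.arg(method)
  pos <- enrichments[!is.na(enrichments) & enrichments > 0]
  n <- length(pos)
  if (n < 2L) {
    stop("need at least 2 positive enrichment values to estimate noise",
         call. = FALSE)
  }
  if (method == "ci_mean") {
    m <- mean(pos)
    se <- stats::sd(pos) / sqrt(n)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * se
    list(threshold = m + half, noise = half, n_positive = n,
         method = method, conf = conf)
  } else {
    q <- unname(stats::quantile(pos, probs = 1 - (1 - conf) / 2, type = 7))
    list(threshold = q, noise = q, n_positive = n,
         method = method, conf = conf)
  }
}

#' Flag taxa above the enrichment threshold and abundance floor
#'
#' A taxon is called enriched when its percentage enrichment is strictly
#' greater than the threshold. The abundance filter requires the taxon's
#' community-wide mean relative abundance to reach the floor (default 0.1%
#' of the community).
#'
#' @param report An `enrichment_report` data.frame (see
#'   [enrichment_analysis()]).
#' @param threshold Percent threshold, non-negative.
#' @param abundance_floor Minimum community relative abundance (default
#'   0.001).
#' @return The report with `threshold_used`, `above_threshold` and
#'   `abundance_filter_passed` filled in.
#' @export
flag_enriched <- function(report, threshold, abundance_floor = 0.001) {
  stopifnot(is.data.frame(report), threshold >= 0)
  report$threshold_used <- threshold
  report$above_threshold <- !is.na(report$percent_enrichment) &
    report$percent_enrichment > threshold
  report$abundance_filter_passed <- report$abundance >= abundance_floor
  report
}

#' Full enrichment analysis for one paired-gradient comparison
#'
#' Runs the whole statistic: heavy-window copy numbers per taxon in each
#' gradient, within-window relative copy numbers, percentage enrichment,
#' the noise threshold from positive values, and the flags.
#'
#' @param table_12c,table_13c [fraction_taxon_table()]s for the unlabeled
#'   and labeled gradients.
#' @param profile_12c,profile_13c Matching [gradient_profile()]s.
#' @param window A [heavy_window()]; if `NULL`, [default_heavy_window()] is
#'   used.
#' @param threshold_method Passed to [noise_threshold()]; set to `NA` to
#'   skip thresholding (e.g. fewer than 2 positive values expected).
#' @param abundance_floor Passed to [flag_enriched()].
#' @return An `enrichment_report` data.frame with one row per taxon:
#'   `taxon`, `rank`, `rel_copies_12C`, `rel_copies_13C`,
#'   `percent_enrichment`, `abundance`, `threshold_used`,
#'   `above_threshold`, `abundance_filter_passed`; the window and threshold
#'   details are attached as attributes.
#' @export
enrichment_analysis <- function(table_12c, table_13c, profile_12c,
                                profile_13c, window = NULL,
                                threshold_method = "ci_mean",
                                abundance_floor = 0.001) {
  if (is.null(window)) {
    window <- default_heavy_window(profile_12c, profile_13c)
  }
  rel12 <- relative_copy_numbers(
    taxon_copy_numbers(table_12c, profile_12c, window))
  rel13 <- relative_copy_numbers(
    taxon_copy_numbers(table_13c, profile_13c, window))
  enr <- percent_enrichment(rel13, rel12)
  taxa <- names(enr)
  # community relative abundance pooled over both gradients' reads
  tot <- rep(0, length(taxa))
  names(tot) <- taxa
  for (tb in list(table_12c, table_13c)) {
    rs <- rowSums(tb$counts)
    tot[names(rs)] <- tot[names(rs)] + rs
  }
  report <- data.frame(
    taxon = taxa,
    rank = table_13c$rank,
    rel_copies_12C = unname(rel12[taxa]),
    rel_copies_13C = unname(rel13[taxa]),
    percent_enrichment = unname(enr),
    abundance = unname(tot / sum(tot)),
    threshold_used = NA_real_,
    above_threshold = NA,
    abundance_filter_passed = NA,
    stringsAsFactors = FALSE
  )
  thr <- NULL
  if (!is.na(threshold_method)) {
    thr <- tryCatch(noise_threshold(enr, method = threshold_method),
                    error = function(e) {
                      warning("noise threshold unavailable: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(thr)) {
      report <- flag_enriched(report, thr$threshold, abundance_floor)
    } else {
      report$abundance_filter_passed <- report$abundance >= abundance_floor
    }
  }
  report <- report[order(-replace(report$percent_enrichment,
                                  is.na(report$percent_enrichment), -Inf)), ]
  rownames(report) <- NULL
  attr(report, "window") <- window
  attr(report, "threshold") <- thr
  class(report) <- c("enrichment_report", "data.frame")
  report
}
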