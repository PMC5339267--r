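# Zero-order decay kinetics for peptide incubation time series:
# concentration declines linearly with time, so the rate is the negated OLS
# slope. Post-depletion observations are excluded, except that the first
# observation below the quantitation floor is retained to anchor the
# depletion time.

#' Fit a zero-order decay rate to a concentration time series
#'
#' Ordinary least-squares fit of concentration against time using the
#' points up to and including the first observation below the quantitation
#' floor; later points are discarded (once the substrate bottoms out the
#' series is flat and would bias the slope). The rate constant is
#' `k = -slope`, in concentration units per hour.
#'
#' @param time Times in hours, strictly increasing.
#' @param conc Concentrations in uM, same length, non-negative.
#' @param floor Quantitation floor in uM below which an observation counts
#'   as depleted (default 0.01, a typical LC-MS floor).
#' @return A `rate_estimate` list: `k` (uM/h, positive = loss), `intercept`
#'   (uM), `n_points_used`, `depletion_time` (h; first time below the
#'   floor, or `NA` if never depleted), `r_squared`.
#' @examples
#' t <- c(0, 8, 13)
#' fit_zero_order(t, 0.40 - 0.02 * t)$k  # 0.02
#' @export
fit_zero_order <- function(time, conc, floor = 0.01) {
  stopifnot(length(time) == length(conc), length(time) >= 2L)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  below <- which(conc < floor)
  if (length(below) > 0L) {
    use <- seq_len(below[1L])
    depletion_time <- time[below[1L]]
  } else {
    use <- seq_along(time)
    depletion_time <- NA_real_
  }
  if (sum(conc[use] >= floor) < 2L) {
    stop("fewer than 2 observations above the quantitation floor",
         call. = FALSE)
  }
  fit <- stats::lm(conc[use] ~ time[use])
  co <- unname(stats::coef(fit))
  tss <- sum((conc[use] - mean(conc[use]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(
      k = -co[2L],
      intercept = co[1L],
      n_points_used = length(use),
      depletion_time = depletion_time,
      r_squared = r2
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> k = %.4g uM/h (n = %d%s)\n", x$k,
              x$n_points_used,
              if (is.na(x$depletion_time)) ""
              else sprintf(", depleted by %g h", x$depletion_time)))
  invisible(x)
}

#' Cell-specific decomposition rate
#'
#' Bulk rate normalized to the initial bacterial abundance.
#'
#' @param k Zero-order rate, uM/h.
#' @param initial_cells Initial abundance, cells/mL, positive.
#' @return Rate in uM/h per cell/mL (uM h^-1 cell^-1 mL).
#' @export
cell_specific_rate <- function(k, initial_cells) {
  if (any(initial_cells <= 0)) {
    stop("`initial_cells` must be positive", call. = FALSE)
  }
  k / initial_cells
}

#' Compare two groups of rates
#'
#' Ratio of group means plus a Welch two-sample t-test; standard plumbing
#' for statements like "decomposition was twice as fast in the bottom
#' water".
#'
#' @param rates_a,rates_b Numeric vectors of rates (uM/h), at least 2 each.
#' @return List with `ratio_of_means` (a over b), `mean_a`, `mean_b`,
#'   `t_statistic`, `df`, `p_value`, `degenerate` (TRUE when a group has
#'   zero variance, in which case the test statistics are `NA` rather than
#'   an error).
#' @export
compare_rates <- function(rates_a, rates_b) {
  stopifnot(length(rates_a) >= 2L, length(rates_b) >= 2L)
  out <- list(
    ratio_of_means = mean(rates_a) / mean(rates_b),
    mean_a = mean(rates_a), mean_b = mean(rates_b),
    t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    degenerate = stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0
  )
  if (!out$degenerate) {
    tt <- stats::t.test(rates_a, rates_b)
    out$t_statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
  }
  out
}

#' Check that a killed control stayed flat
#'
#' Flags a poisoned-control series whose peptide concentration moved by more
#' than a tolerance (default 20% of the initial value); a flat killed
#' control demonstrates that decomposition is microbial.
#'
#' @param conc Concentration series, uM.
#' @param tol Allowed relative change from the initial value (default 0.2).
#' @return `TRUE` when the series stayed within tolerance.
#' @export
killed_control_ok <- function(conc, tol = 0.2) {
  stopifnot(length(conc) >= 2L, conc[1L] > 0)
  all(abs(conc - conc[1L]) <= tol * conc[1L])
}

#' Fit peptide decay rates across an incubation set
#'
#' Fits [fit_zero_order()] to the peptide series of every
#' treatment/depth/replicate combination in a long-format incubation table
#' and summarizes replicates as mean plus or minus absolute error (half the
#' absolute difference for duplicates).
#'
#' @param series Long-format data.frame with columns `treatment`, `depth`,
#'   `replicate`, `time_h`, `analyte`, `value` (see
#'   [read_incubation_series()]); the peptide analyte is `"peptide"`.
#' @param floor Quantitation floor passed to [fit_zero_order()].
#' @return A data.frame with one row per fit (`treatment`, `depth`,
#'   `replicate`, `k`, `intercept`, `n_points_used`, `depletion_time`), and
#'   attribute `summary`: per treatment/depth mean k and absolute error.
#' @export
fit_peptide_rates <- function(series, floor = 0.01) {
  stopifnot(all(c("treatment", "depth", "replicate", "time_h", "analyte",
                  "value") %in% names(series)))
  pep <- series[series$analyte == "peptide", , drop = FALSE]
  keys <- unique(pep[, c("treatment", "depth", "replicate")])
  fits <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(keys[i, , drop = FALSE], pep)
    sub <- sub[order(sub$time_h), ]
    est <- fit_zero_order(sub$time_h, sub$value, floor = floor)
    cbind(keys[i, , drop = FALSE],
          k = est$k, intercept = est$intercept,
          n_points_used = est$n_points_used,
          depletion_time = est$depletion_time)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  agg <- stats::aggregate(k ~ treatment + depth, data = out, FUN = mean)
  names(agg)[names(agg) == "k"] <- "k_mean"
  err <- stats::aggregate(k ~ treatment + depth, data = out,
                          FUN = function(v) diff(range(v)) / 2)
  agg$k_abs_error <- err$k
  attr(out, "summary") <- agg
  out
}
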