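# CsCl gradient fractions: refractive-index -> buoyant-density conversion,
# ratio-of-quantities normalization, heavy-window selection, and the
# density-shift -> %13C incorporation conversion.

# Published linear CsCl calibration at 20 degrees C relating refractive
# index to solution density (g/mL).
.default_ri_slope <- 10.8601
.default_ri_intercept <- -13.4974

# Densities are compared at 4-decimal precision everywhere a window or
# monotonicity check is made, to keep fraction selection stable against
# float-boundary noise.
.round_density <- function(x) round(x, 4)

#' Buoyant density from refractive index
#'
#' Linear map `density = slope * RI + intercept` using the standard CsCl
#' calibration at 20 degrees C by default. Refractometer readings outside
#' the plausible CsCl working range are rejected.
#'
#' @param refractive_index Numeric vector of refractometer readings
#'   (dimensionless), each in `[1.34, 1.42]`.
#' @param slope,intercept Calibration line coefficients.
#' @return Densities in g/mL.
#' @examples
#' density_from_ri(1.4000)  # 1.70674 g/mL under the default calibration
#' @export
density_from_ri <- function(refractive_index,
                            slope = .default_ri_slope,
                            intercept = .default_ri_intercept) {
  bad <- !is.na(refractive_index) &
    (refractive_index < 1.34 | refractive_index > 1.42)
  if (any(bad)) {
    stop("refractive index outside plausible CsCl range [1.34, 1.42]: ",
         paste(refractive_index[bad], collapse = ", "), call. = FALSE)
  }
  slope * refractive_index + intercept
}

#' Refractive index from buoyant density (inverse calibration)
#'
#' @param density Densities in g/mL.
#' @inheritParams density_from_ri
#' @return Refractive indices.
#' @export
ri_from_density <- function(density,
                            slope = .default_ri_slope,
                            intercept = .default_ri_intercept) {
  if (slope == 0) stop("calibration slope of 0 cannot be inverted",
                       call. = FALSE)
  (density - intercept) / slope
}

#' Gradient profile for one treatment
#'
#' Represents the ordered fractions of one CsCl gradient (one treatment and
#' depth): fraction index, density (computed from refractive index where
#' absent), 16S rRNA gene copies per fraction, and the ratio of quantities —
#' copies normalized so the gradient maximum equals 1.
#'
#' @param fraction Integer fraction identifiers (1 = densest end, collection
#'   order).
#' @param density Densities in g/mL (optional if `refractive_index` given).
#' @param copies 16S gene copies per reaction, non-negative.
#' @param refractive_index Optional refractometer readings used to fill
#'   missing densities via [density_from_ri()].
#' @param copies_sd Optional qPCR standard deviations, same units as
#'   `copies`.
#' @param treatment Label, conventionally `"12C"` or `"13C"`.
#' @param depth Label, e.g. `"surface"` or `"bottom"`.
#' @param normalize Compute `ratio_of_quantities` immediately (default)?
#' @return A `gradient_profile`: a data.frame with columns `fraction`,
#'   `density`, `copies`, `copies_sd`, `below_detection`,
#'   `ratio_of_quantities`, rows sorted by decreasing density, with
#'   attributes `treatment` and `depth`.
#' @export
gradient_profile <- function(fraction, density = NULL, copies,
                             refractive_index = NULL, copies_sd = NULL,
                             treatment = "12C", depth = "surface",
                             normalize = TRUE) {
  n <- length(fraction)
  if (anyDuplicated(fraction)) {
    stop("duplicated fraction identifier(s): ",
         paste(unique(fraction[duplicated(fraction)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(density)) {
    if (is.null(refractive_index)) {
      stop("at least one of `density` or `refractive_index` is required",
           call. = FALSE)
    }
    density <- density_from_ri(refractive_index)
  } else if (!is.null(refractive_index)) {
    density <- ifelse(is.na(density), density_from_ri(refractive_index),
                      density)
  }
  if (length(density) != n || length(copies) != n) {
    stop("`fraction`, `density` and `copies` must have equal length",
         call. = FALSE)
  }
  if (any(is.na(density)) ||
      any(density < 1.60) || any(density > 1.85)) {
    stop("density outside CsCl sanity bounds [1.60, 1.85] g/mL",
         call. = FALSE)
  }
  if (any(is.na(copies)) || any(copies < 0)) {
    stop("`copies` must be non-negative", call. = FALSE)
  }
  df <- data.frame(
    fraction = fraction,
    density = density,
    copies = as.numeric(copies),
    copies_sd = if (is.null(copies_sd)) NA_real_ else as.numeric(copies_sd),
    below_detection = copies == 0,
    ratio_of_quantities = NA_real_
  )
  df <- df[order(-df$density, df$fraction), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "treatment") <- treatment
  attr(df, "depth") <- depth
  class(df) <- c("gradient_profile", "data.frame")
  if (normalize) df <- normalize_quantities(df)
  df
}

#' Ratio of quantities: normalize copies to the gradient maximum
#'
#' Per-fraction 16S copy numbers divided by the largest copy number in the
#' same gradient, so the most DNA-rich fraction has ratio exactly 1. This is
#' the within-gradient normalization that makes labeled and unlabeled
#' gradients comparable on one axis.
#'
#' @param profile A [gradient_profile()].
#' @return The profile with `ratio_of_quantities` filled in.
#' @export
normalize_quantities <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  mx <- max(profile$copies)
  if (mx <= 0) {
    stop("all fractions have zero copies; nothing to normalize",
         call. = FALSE)
  }
  profile$ratio_of_quantities <- profile$copies / mx
  profile
}

#' Heavy-density window
#'
#' The density range over which the enrichment statistic is summed; a closed
#' interval `[density_min, density_max]` in g/mL.
#'
#' @param density_min,density_max Window bounds, g/mL, `density_min <
#'   density_max`.
#' @return A `heavy_window` object.
#' @export
heavy_window <- function(density_min, density_max) {
  stopifnot(is.numeric(density_min), is.numeric(density_max),
            length(density_min) == 1L, length(density_max) == 1L)
  if (!(density_min < density_max)) {
    stop("`density_min` must be strictly less than `density_max`",
         call. = FALSE)
  }
  structure(list(density_min = density_min, density_max = density_max),
            class = "heavy_window")
}

#' @export
print.heavy_window <- function(x, ...) {
  cat(sprintf("<heavy_window> [%.4f, %.4f] g/mL\n",
              x$density_min, x$density_max))
  invisible(x)
}

#' Select the fractions inside a heavy window
#'
#' Closed on both ends; densities are compared at 4-decimal precision.
#' An empty selection is legal and returned with a warning.
#'
#' @param profile A [gradient_profile()].
#' @param window A [heavy_window()].
#' @return The subset of profile rows whose density lies in the window,
#'   order preserved.
#' @export
select_heavy <- function(profile, window) {
  stopifnot(inherits(profile, "gradient_profile"),
            inherits(window, "heavy_window"))
  d <- .round_density(profile$density)
  keep <- d >= .round_density(window$density_min) &
    d <= .round_density(window$density_max)
  out <- profile[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("heavy window selects no fractions", call. = FALSE)
  }
  out
}

#' Default heavy window from a paired gradient comparison
#'
#' Reproduces the visual rule used to place heavy-window bars on paired
#' gradient plots: the densest contiguous run of fractions in which the
#' labeled gradient's ratio of quantities exceeds the unlabeled one's.
#' Fractions are matched by fraction identifier. Three guards keep the rule
#' stable under qPCR noise: both ratio profiles are smoothed with a
#' 3-fraction running mean before comparison, runs shorter than `min_run`
#' fractions are ignored, and only fractions where the (smoothed) labeled
#' ratio is at least `ratio_floor` (i.e., real DNA is present) are
#' considered. The window is
#' capped at `max_width` g/mL, keeping the densest portion of the run, so
#' that it stays a heavy range rather than swallowing the unlabeled
#' community's band region when the crossing run is long.
#'
#' @param profile_12c,profile_13c Paired [gradient_profile()]s with matching
#'   fraction identifiers.
#' @param min_run Minimum run length in fractions (default 2).
#' @param ratio_floor Minimum labeled-gradient ratio of quantities
#'   (default 0.05).
#' @param max_width Maximum window width in g/mL (default 0.015).
#' @return A [heavy_window()] spanning the selected fractions' densities.
#' @export
default_heavy_window <- function(profile_12c, profile_13c,
                                 min_run = 2L, ratio_floor = 0.05,
                                 max_width = 0.015) {
  stopifnot(inherits(profile_12c, "gradient_profile"),
            inherits(profile_13c, "gradient_profile"))
  m <- match(profile_13c$fraction, profile_12c$fraction)
  if (any(is.na(m))) {
    stop("fraction identifiers do not match between the paired gradients",
         call. = FALSE)
  }
  smooth3 <- function(r) {
    n <- length(r)
    if (n < 3L) return(r)
    (r + c(r[1L], r[-n]) + c(r[-1L], r[n])) / 3
  }
  r13 <- smooth3(profile_13c$ratio_of_quantities)
  r12 <- smooth3(profile_12c$ratio_of_quantities[m])
  dens <- profile_13c$density  # sorted decreasing
  eligible <- r13 > r12 & r13 >= ratio_floor
  # contiguous runs over fractions ordered dense -> light
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= min_run)
  if (length(ok) == 0L) {
    stop("no contiguous run of >= ", min_run,
         " fractions with labeled ratio above unlabeled; ",
         "supply an explicit heavy_window", call. = FALSE)
  }
  i <- ok[1L]  # first run in dense -> light order is the densest
  idx <- starts[i]:ends[i]
  # keep the densest portion when the crossing run is wider than max_width
  top <- max(dens[idx])
  idx <- idx[top - dens[idx] <= max_width]
  heavy_window(min(dens[idx]), max(dens[idx]))
}

#' Percent 13C incorporation from a buoyant-density shift
#'
#' Converts an observed DNA buoyant-density shift into percent 13C
#' incorporation, as `100 * delta_density / full_label_shift`. The default
#' full-label shift of 0.036 g/mL is the standard CsCl value for fully
#' (100 atom%) 13C-labeled DNA; a shift of 0.01 g/mL then corresponds to
#' about 28% incorporation.
#'
#' @param delta_density Observed density shift, g/mL, non-negative.
#' @param full_label_shift Density shift of fully labeled DNA, g/mL,
#'   positive (default 0.036).
#' @return A list with `percent_raw` (real) and `percent` (rounded to the
#'   nearest integer percent).
#' @examples
#' incorporation_from_shift(0.01)$percent  # 28
#' @export
incorporation_from_shift <- function(delta_density, full_label_shift = 0.036) {
  if (!is.numeric(full_label_shift) || length(full_label_shift) != 1L ||
      full_label_shift <= 0) {
    stop("`full_label_shift` must be a positive density shift in g/mL",
         call. = FALSE)
  }
  if (any(delta_density < 0)) {
    stop("`delta_density` must be non-negative", call. = FALSE)
  }
  raw <- 100 * delta_density / full_label_shift
  list(percent_raw = raw, percent = round(raw))
}
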