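# Nitrogen mass balance of decomposed peptide: how much of the consumed
# peptide nitrogen shows up as extracellularly hydrolyzed fragments, as
# remineralized ammonium, and as new bacterial biomass; the remainder is
# closed into a residual dissolved-organic-nitrogen (DON) pool. Plus the
# phosphorus demand implied by an observed cell increase.

#' Conversion constants for the nitrogen budget and phosphorus demand
#'
#' Defaults follow the standard marine bacterioplankton conversion factors:
#' 20 fg C per cell, a bacterial C/N of 4, 0.2 pg dry mass per cell and a
#' cellular P content of 1.3% of dry mass. Nominal atomic masses (N = 14,
#' P = 31 g/mol) match the precision of these constants. The C/N ratio is
#' applied on a mass basis: biomass N (g) = biomass C (g) / CN.
#'
#' @param fg_C_per_cell Carbon per cell, fg (default 20).
#' @param bacterial_CN Bacterial carbon-to-nitrogen ratio (default 4).
#' @param cell_dry_mass Dry mass per cell, pg (default 0.2).
#' @param P_content P mass fraction of dry mass (default 0.013).
#' @param N_per_peptide N atoms per peptide molecule (default 4, the AVFA
#'   tetrapeptide).
#' @param mass_N,mass_P Atomic masses, g/mol.
#' @return A `conversion_constants` list.
#' @export
conversion_constants <- function(fg_C_per_cell = 20, bacterial_CN = 4,
                                 cell_dry_mass = 0.2, P_content = 0.013,
                                 N_per_peptide = 4, mass_N = 14,
                                 mass_P = 31) {
  vals <- c(fg_C_per_cell, bacterial_CN, cell_dry_mass, P_content,
            N_per_peptide, mass_N, mass_P)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all conversion constants must be strictly positive", call. = FALSE)
  }
  structure(
    list(fg_C_per_cell = fg_C_per_cell, bacterial_CN = bacterial_CN,
         cell_dry_mass = cell_dry_mass, P_content = P_content,
         N_per_peptide = N_per_peptide, mass_N = mass_N, mass_P = mass_P),
    class = "conversion_constants"
  )
}

#' Fraction of consumed peptide that was extracellularly hydrolyzed
#'
#' Estimated from the amino acid F (phenylalanine) and the F-containing
#' peptide fragments, each carrying one F per molecule, because bacterial
#' uptake of free F is negligible over the incubation: the summed molar
#' concentration of F-containing products divided by the peptide consumed.
#'
#' @param F_products uM of F plus F-containing fragments at the reference
#'   time (scalar or vector to be summed).
#' @param peptide_consumed uM of peptide consumed, positive.
#' @return Dimensionless fraction.
#' @examples
#' hydrolysis_fraction(0.17, 0.425)  # 0.40
#' @export
hydrolysis_fraction <- function(F_products, peptide_consumed) {
  .check_consumed(peptide_consumed)
  if (any(F_products < 0)) stop("`F_products` must be non-negative",
                                call. = FALSE)
  sum(F_products) / peptide_consumed
}

#' Fraction of consumed peptide N remineralized to ammonium
#'
#' The ammonium increase in the peptide treatment beyond the control,
#' relative to the nitrogen delivered by the consumed peptide (assuming
#' nitrification is negligible). Small negative results from measurement
#' noise are returned as-is with a `flag` attribute.
#'
#' @param delta_nh4_treatment,delta_nh4_control Ammonium change over the
#'   interval, uM, in the treatment and control bottles.
#' @param peptide_consumed uM of peptide consumed, positive.
#' @param n_per_molecule N atoms per peptide molecule (default 4).
#' @return Dimensionless fraction (attribute `flag` = "negative" when below
#'   zero).
#' @export
remineralization_fraction <- function(delta_nh4_treatment, delta_nh4_control,
                                      peptide_consumed, n_per_molecule = 4) {
  .check_consumed(peptide_consumed)
  out <- (delta_nh4_treatment - delta_nh4_control) /
    (peptide_consumed * n_per_molecule)
  if (out < 0) attr(out, "flag") <- "negative"
  out
}

#' Fraction of consumed peptide N incorporated into bacterial biomass
#'
#' New biomass N from the observed cell increase:
#' `mol N / L = delta_cells * fg_C_per_cell / CN / mass_N`, with fg/mL
#' converted to g/L. Divided by the nitrogen delivered by the consumed
#' peptide.
#'
#' @param delta_cells Cell increase, cells/mL, non-negative.
#' @param peptide_consumed uM of peptide consumed, positive.
#' @param constants A [conversion_constants()].
#' @return Dimensionless fraction, with attribute `biomass_N_uM` (the new
#'   biomass nitrogen in uM).
#' @export
biomass_n_fraction <- function(delta_cells, peptide_consumed,
                               constants = conversion_constants()) {
  .check_consumed(peptide_consumed)
  if (any(delta_cells < 0)) stop("`delta_cells` must be non-negative",
                                 call. = FALSE)
  # fg C/mL -> g C/L (x 1e-15 g/fg x 1e3 mL/L), then mass CN, then mol N
  g_C_per_L <- delta_cells * constants$fg_C_per_cell * 1e-15 * 1e3
  mol_N_per_L <- g_C_per_L / constants$bacterial_CN / constants$mass_N
  biomass_N_uM <- mol_N_per_L * 1e6
  out <- biomass_N_uM / (peptide_consumed * constants$N_per_peptide)
  attr(out, "biomass_N_uM") <- biomass_N_uM
  out
}

#' Close the peptide nitrogen budget
#'
#' Residual DON is the closure term: whatever fraction of consumed peptide
#' nitrogen is not accounted for by hydrolysis products, ammonium or new
#' biomass. The four fractions therefore sum to exactly 1. Inputs summing
#' to more than 1.05 are flagged as over-closure but still returned.
#'
#' @param hydrolysis,remineralization,biomass Fractions in `[-0.05, 1.05]`
#'   (small negatives from measurement noise are allowed and flagged).
#' @param reference_time Optional reference time, h, carried through.
#' @return A `nitrogen_budget` list: the four fractions, `reference_time`,
#'   and `flags` (character vector, possibly empty).
#' @examples
#' close_budget(0.40, 0.06, 0.05)$residual_DON_fraction  # 0.49
#' @export
close_budget <- function(hydrolysis, remineralization, biomass,
                         reference_time = NA_real_) {
  ins <- c(hydrolysis = hydrolysis, remineralization = remineralization,
           biomass = biomass)
  if (any(ins < -0.05) || any(ins > 1.05)) {
    stop("budget fractions must lie in [-0.05, 1.05]; got ",
         paste(signif(ins, 3), collapse = ", "), call. = FALSE)
  }
  flags <- character(0)
  if (any(ins < 0)) flags <- c(flags, "negative_input")
  if (sum(ins) > 1.05) flags <- c(flags, "over_closure")
  structure(
    list(
      hydrolysis_fraction = unname(ins[1L]),
      remineralization_fraction = unname(ins[2L]),
      biomass_fraction = unname(ins[3L]),
      residual_DON_fraction = 1 - sum(ins),
      reference_time = reference_time,
      flags = flags
    ),
    class = "nitrogen_budget"
  )
}

#' @export
print.nitrogen_budget <- function(x, ...) {
  cat(sprintf(paste0(
    "<nitrogen_budget> hydrolysis %.2g | remineralization %.2g | ",
    "biomass %.2g | residual DON %.2g%s\n"),
    x$hydrolysis_fraction, x$remineralization_fraction,
    x$biomass_fraction, x$residual_DON_fraction,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Phosphorus demand of an observed cell increase
#'
#' Phosphorus required to build the new cells:
#' `delta_cells * cell_dry_mass * P_content`, converted from pg/mL to mol/L
#' with the atomic mass of P, expressed in uM. A bloom of 9e5 cells/mL at
#' the default constants demands about 0.08 uM Pi.
#'
#' @param delta_cells Cell increase, cells/mL, non-negative.
#' @param constants A [conversion_constants()].
#' @return Demand in uM P (raw; round to two decimals for reporting).
#' @examples
#' round(phosphorus_demand(9.0e5), 2)  # 0.08
#' @export
phosphorus_demand <- function(delta_cells,
                              constants = conversion_constants()) {
  if (any(delta_cells < 0)) stop("`delta_cells` must be non-negative",
                                 call. = FALSE)
  # pg P/mL -> g P/L (x 1e-12 x 1e3), then mol/L, then uM
  g_P_per_L <- delta_cells * constants$cell_dry_mass * constants$P_content *
    1e-12 * 1e3
  g_P_per_L / constants$mass_P * 1e6
}

.check_consumed <- function(peptide_consumed) {
  if (length(peptide_consumed) != 1L || !is.finite(peptide_consumed) ||
      peptide_consumed <= 0) {
    stop("`peptide_consumed` must be a positive concentration (uM)",
         call. = FALSE)
  }
}
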