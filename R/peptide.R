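# Elemental composition and isotope-labeling accounting for peptides.
#
# A peptide given as a one-letter residue string is "condensed": the summed
# free amino-acid formulas lose one water per peptide bond, so a k-mer keeps
# k - 1 fewer H2O than the free residues.

# Free amino-acid molecular formulas (C, H, N, O, S) for the 20 standard
# residues, indexed by one-letter code.
.aa_formula <- local({
  m <- rbind(
    A = c(3, 7, 1, 2, 0),
    R = c(6, 14, 4, 2, 0),
    N = c(4, 8, 2, 3, 0),
    D = c(4, 7, 1, 4, 0),
    C = c(3, 7, 1, 2, 1),
    E = c(5, 9, 1, 4, 0),
    Q = c(5, 10, 2, 3, 0),
    G = c(2, 5, 1, 2, 0),
    H = c(6, 9, 3, 2, 0),
    I = c(6, 13, 1, 2, 0),
    L = c(6, 13, 1, 2, 0),
    K = c(6, 14, 2, 2, 0),
    M = c(5, 11, 1, 2, 1),
    F = c(9, 11, 1, 2, 0),
    P = c(5, 9, 1, 2, 0),
    S = c(3, 7, 1, 3, 0),
    T = c(4, 9, 1, 3, 0),
    W = c(11, 12, 2, 2, 0),
    Y = c(9, 11, 1, 3, 0),
    V = c(5, 11, 1, 2, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Nominal (integer) and monoisotopic atomic masses used for m/z.
.nominal_mass <- c(C = 12, H = 1, N = 14, O = 16, S = 32)
.monoisotopic_mass <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)

#' Elemental composition of a condensed peptide
#'
#' Builds a `peptide_spec` from a one-letter residue string: the summed free
#' amino-acid formulas minus one water per peptide bond. For the tetrapeptide
#' AVFA this gives C20 H30 N4 O5.
#'
#' @param sequence One-letter residue string using the 20 standard amino
#'   acid codes (case-insensitive).
#' @return An object of class `peptide_spec`: a list with `sequence`,
#'   `residues` (character vector), `composition` (named integer vector over
#'   C, H, N, O, S), `n_residues`, and `residue_carbons` (carbon count per
#'   residue position, side chain plus backbone).
#' @examples
#' avfa <- compose_peptide("AVFA")
#' avfa$composition[["C"]]  # 20
#' @export
compose_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  residues <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(unique(residues), rownames(.aa_formula))
  if (length(unknown) > 0L) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  k <- length(residues)
  comp <- colSums(.aa_formula[residues, , drop = FALSE])
  # one water lost per peptide bond
  comp[["H"]] <- comp[["H"]] - 2L * (k - 1L)
  comp[["O"]] <- comp[["O"]] - 1L * (k - 1L)
  comp <- as.integer(round(comp))
  names(comp) <- colnames(.aa_formula)
  structure(
    list(
      sequence = paste(residues, collapse = ""),
      residues = residues,
      composition = comp,
      n_residues = k,
      residue_carbons = unname(.aa_formula[residues, "C"])
    ),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  comp <- x$composition[x$composition > 0]
  cat("<peptide_spec> ", x$sequence, " (", x$n_residues, " residues): ",
      paste0(names(comp), comp, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Count 13C-labeled carbons under a per-residue labeling scheme
#'
#' The scheme gives, per residue position, how many of that residue's
#' carbons are 13C. The scheme used for 13C-AVFA labels all three carbons of
#' each alanine, all five of valine, and the six aromatic-ring carbons of
#' phenylalanine: 17 of the 20 carbons.
#'
#' @param spec A [compose_peptide()] result.
#' @param scheme Numeric vector of labeled-carbon counts, one per residue
#'   position (same length as the sequence). Each entry must not exceed that
#'   residue's total carbon count.
#' @return Integer total of labeled carbons.
#' @examples
#' count_labeled_carbons(compose_peptide("AVFA"), c(3, 5, 6, 3))  # 17
#' @export
count_labeled_carbons <- function(spec, scheme) {
  stopifnot(inherits(spec, "peptide_spec"))
  if (length(scheme) == 0L) return(0L)
  if (length(scheme) != spec$n_residues) {
    stop("`scheme` must have one entry per residue (", spec$n_residues, ")",
         call. = FALSE)
  }
  if (any(scheme < 0) || any(scheme != round(scheme))) {
    stop("labeled-carbon counts must be non-negative integers", call. = FALSE)
  }
  over <- which(scheme > spec$residue_carbons)
  if (length(over) > 0L) {
    stop("labeled count exceeds residue carbons at position(s): ",
         paste(over, collapse = ", "), " (residue ",
         paste(spec$residues[over], collapse = ", "), ")", call. = FALSE)
  }
  as.integer(sum(scheme))
}

#' The AVFA labeling scheme
#'
#' Per-position labeled-carbon counts for 13C-labeled
#' alanine-valine-phenylalanine-alanine: both alanines fully labeled (3
#' carbons each), valine fully labeled (5), and the six aromatic-ring
#' carbons of phenylalanine — 17 of 20 carbons in total.
#'
#' @return Numeric vector `c(3, 5, 6, 3)`.
#' @export
avfa_label_scheme <- function() c(A = 3, V = 5, F = 6, A = 3)

#' Nominal SIM m/z of a singly protonated peptide
#'
#' Nominal (integer-mass) `[M+H]+` m/z for selective ion monitoring on a
#' quadrupole: the sum of element counts times nominal atomic masses, plus 1
#' for the proton, plus one unit per 13C (each heavy carbon adds one
#' neutron). Unlabeled AVFA gives 407; with the 17-carbon labeling scheme,
#' 424.
#'
#' @param spec A [compose_peptide()] result.
#' @param n_labeled Number of 13C positions, between 0 and the total carbon
#'   count.
#' @return Integer m/z.
#' @seealso [monoisotopic_mass()] for the exact neutral monoisotopic mass.
#' @examples
#' sim_mz(compose_peptide("AVFA"), 0)   # 407
#' sim_mz(compose_peptide("AVFA"), 17)  # 424
#' @export
sim_mz <- function(spec, n_labeled = 0L) {
  stopifnot(inherits(spec, "peptide_spec"))
  n_c <- spec$composition[["C"]]
  if (length(n_labeled) != 1L || is.na(n_labeled) || n_labeled < 0 ||
      n_labeled > n_c || n_labeled != round(n_labeled)) {
    stop("`n_labeled` must be an integer in [0, ", n_c, "]", call. = FALSE)
  }
  as.integer(sum(spec$composition * .nominal_mass[names(spec$composition)]) +
               1L + n_labeled)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Exact monoisotopic mass of the condensed (all-12C) peptide. Provided as a
#' secondary output; the SIM channel contract uses nominal integer masses.
#'
#' @param spec A [compose_peptide()] result.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  sum(spec$composition * .monoisotopic_mass[names(spec$composition)])
}
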