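# Small in-code fixtures shared across test files.

# A gradient profile over an evenly spaced density grid.
make_profile <- function(copies, d_top = 1.75, d_bottom = 1.69,
                         treatment = "12C") {
  n <- length(copies)
  gradient_profile(
    fraction = seq_len(n),
    density = seq(d_top, d_bottom, length.out = n),
    copies = copies,
    treatment = treatment
  )
}

# A taxon table whose fraction identifiers match make_profile's.
make_taxa <- function(counts, taxa = NULL, rank = "genus") {
  counts <- as.matrix(counts)
  colnames(counts) <- as.character(seq_len(ncol(counts)))
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(nrow(counts)))
  fraction_taxon_table(counts, taxa = taxa, rank = rank)
}

# Brute-force double-loop oracle for the window copy-number sum.
oracle_taxon_copies <- function(table, profile, window) {
  out <- numeric(length(table$taxa))
  names(out) <- table$taxa
  for (ti in seq_along(table$taxa)) {
    acc <- 0
    for (fi in seq_len(nrow(profile))) {
      d <- round(profile$density[fi], 4)
      if (d >= round(window$density_min, 4) &&
          d <= round(window$density_max, 4)) {
        id <- as.character(profile$fraction[fi])
        p <- table$proportions[ti, id]
        if (!is.na(p)) acc <- acc + p * profile$copies[fi]
      }
    }
    out[ti] <- acc
  }
  out
}
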