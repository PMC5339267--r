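---
title: "Quantitative DNA-SIP enrichment analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DNA-SIP enrichment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipenrich)
```

## The problem

DNA stable isotope probing (SIP) identifies which members of a microbial
community assimilate a particular substrate. A community is incubated with
a ¹³C-labeled substrate (here, a model tetrapeptide) alongside an
unlabeled ¹²C control; organisms that build DNA from the labeled carbon
produce denser DNA, which bands deeper in an isopycnic CsCl gradient. Each
gradient is fractionated (~30 fractions spanning roughly 1.66–1.77 g/mL),
each fraction is assayed by 16S rRNA gene qPCR and amplicon sequencing,
and per-taxon activity is quantified by comparing the dense ("heavy") end
of the labeled gradient against the same density range of the control.

`sipenrich` implements that whole chain as composable functions, together
with the kinetics and element-budget calculations that accompany such a
peptide-amendment experiment, and a seeded synthetic-data generator so
every stage is testable without external data.

## The enrichment statistic

For one paired comparison, with a heavy-density window $W$ (a closed
density interval):

1. **Ratio of quantities.** Within each gradient, per-fraction 16S copy
   numbers are divided by the gradient's maximum, so the most DNA-rich
   fraction scores 1 (`normalize_quantities()`). This puts the two
   gradients on one axis without assuming equal DNA recovery.
2. **Window copy numbers.** For each taxon $i$,
   $c_i = \sum_{f \in W} p_{if} \, q_f$, where $p_{if}$ is the taxon's
   read proportion in fraction $f$ and $q_f$ the fraction's total copy
   number (`taxon_copy_numbers()`).
3. **Relative copy numbers.** $r_i = c_i / \sum_j c_j$ within each
   treatment's window, correcting for the slight difference in total DNA
   between gradients (`relative_copy_numbers()`). By construction
   $\sum_i r_i = 1$.
4. **Percentage enrichment.**
   $E_i = 100 \,(r_i^{13C} - r_i^{12C}) / r_i^{12C}$
   (`percent_enrichment()`). $E_i = 100$ means the taxon's heavy-window
   relative copy number doubled under labeling. Where $r_i^{12C} = 0$ with
   $r_i^{13C} > 0$ the statistic is undefined and reported `NA` — never
   infinity, never dropped.
5. **Noise threshold.** The error level of the statistic is estimated
   from all strictly positive enrichments (`noise_threshold()`), either as
   the upper limit of the two-sided 95% t-interval of their mean
   (`ci_mean`) or as their 97.5th percentile (`percentile`). Both are
   offered, with all intermediate quantities reported, because the mapping
   from a confidence interval to a calling threshold admits more than one
   reading; neither is asserted as canonical. Taxa are flagged when
   $E_i$ strictly exceeds the threshold and their community-wide relative
   abundance reaches the floor (default 0.1%).

Because the $r_i$ sum to one, enrichment is a zero-sum comparison: one
taxon's gain in window share is other taxa's loss. In a two-taxon system
the enrichments can never both be positive; in realistic communities a
strong incorporator drives most non-incorporators negative. Class-level
results sum genus read counts within class *before* proportions are taken
(`aggregate_to_class()`), not by averaging genus enrichments.

### Choosing the heavy window

The window is a required analysis parameter. When it is not supplied,
`default_heavy_window()` reproduces the visual rule used to place
heavy-window bars on paired gradient plots: the densest contiguous run of
fractions where the labeled gradient's ratio of quantities exceeds the
unlabeled one's. Three guards make this rule stable under qPCR noise,
each chosen for a specific failure mode observed with the raw rule:

* both ratio profiles are smoothed with a 3-fraction running mean, since
  near the crossover the excess is small and multiplicative noise flips
  individual fractions;
* runs shorter than `min_run = 2` fractions and fractions where the
  smoothed labeled ratio is below `ratio_floor = 0.05` are ignored,
  because the sparse dense tail (both ratios near zero) otherwise
  produces spurious crossings;
* the window is capped at `max_width = 0.015` g/mL, keeping the densest
  portion, so a long crossing run cannot swallow the unlabeled
  community's band region — a window that overlaps a taxon's unlabeled
  band cannot attribute that taxon's density shift.

Densities are compared at 4-decimal precision throughout window
selection, and the window is closed on both ends, so a fraction exactly
at a bound is included deterministically.

## Refractive index to density

Fraction densities are measured by refractometry and converted with the
linear CsCl calibration at 20 °C,
$\rho = 10.8601 \times \mathrm{RI} - 13.4974$ (g/mL), the standard line
for CsCl gradients in SIP work; both slope and intercept are
configurable, readings outside [1.34, 1.42] are rejected, and the map is
exactly invertible (`ri_from_density()`). A density shift converts to
percent ¹³C incorporation as
$100\,\Delta\rho / \Delta\rho_{\mathrm{full}}$ with
$\Delta\rho_{\mathrm{full}} = 0.036$ g/mL, the standard full-label shift
of 100 atom% ¹³C DNA; a shift of 0.01 g/mL is thus ~28% incorporation.

## Decay kinetics

Peptide disappearance in these incubations is zero-order: concentration
falls linearly until the substrate is exhausted, so `fit_zero_order()`
estimates the rate as the negated OLS slope of concentration on time. Two
conventions matter:

* **Truncation.** Only points up to and including the first observation
  below the quantitation floor (default 0.01 μM, a typical LC-MS floor)
  enter the fit; once the series bottoms out, further near-zero points
  would bias the slope toward zero. The first sub-floor point is retained
  to anchor the depletion time. A consequence worth knowing: if the
  sampling grid is sparse, the first sub-floor point can sit well past
  the true depletion time and pull the slope down; rate-recovery
  simulations in the test suite therefore use an initial concentration
  (0.47 μM, the top of the realistic amendment range) under which the
  series stays quantifiable throughout the sampled times, so they measure
  estimator noise rather than censoring. The truncation behavior itself
  is covered by a separate test.
* **Replication.** Replicates are fit separately and summarized as mean ±
  absolute error (`fit_peptide_rates()`), matching how duplicate bottles
  are usually reported.

`cell_specific_rate()` divides a bulk rate by initial cell abundance;
`compare_rates()` wraps a Welch two-sample t-test plus a ratio of means —
standard plumbing, no bespoke statistics. `killed_control_ok()` checks
that a poisoned control stayed within 20% of its initial value, the
operational meaning of "unchanged".

## Nitrogen mass balance and phosphorus demand

For a consumed amount of peptide (μM), the fate of its nitrogen is
partitioned into:

* **hydrolysis** — moles of phenylalanine and F-containing fragments per
  mole of peptide consumed (free F uptake is negligible on the incubation
  timescale, making F a conserved tracer of extracellular cleavage);
* **remineralization** — the treatment-minus-control ammonium increase
  over the peptide nitrogen consumed (nitrification neglected);
* **biomass incorporation** — new cells × 20 fg C per cell, divided by a
  bacterial C/N of 4 and the atomic mass of N. The C/N ratio is applied
  on a mass basis (g C per g N), i.e. mol N/L = g C/L ÷ CN ÷ 14; with
  the default constants a 3.3 × 10⁵ cells/mL increase is ≈ 0.118 μM N;
* **residual DON** — the closure term, $1 -$ the other three. It is
  never measured; the four fractions sum to exactly 1 by construction.

Fractions are reported unclipped: measurement noise can produce small
negatives (flagged, accepted down to −0.05), and inputs summing past 1.05
are flagged as over-closure but still returned. Nominal atomic masses
(N = 14, P = 31 g/mol) match the precision of the conversion constants;
reported values are conventionally rounded to two significant figures.

Phosphorus demand of an observed bloom is
cells × 0.2 pg dry mass × 1.3% P, converted to μM via the atomic mass of
P: increases of 8.1 × 10⁴ and 9.0 × 10⁵ cells/mL demand 0.01 and 0.08 μM
phosphate respectively.

## The synthetic-data generator

`simulate_gradient_pair()` builds a paired ¹²C/¹³C experiment from a
community definition:

* each taxon's unlabeled band centers at $\rho = 1.660 + 0.098 \times$
  GC, the standard CsCl GC–density relation;
* labeling shifts the center by atom fraction × 0.036 g/mL;
* per-fraction DNA mass is an abundance-weighted Gaussian kernel
  (σ = 0.006 g/mL) over a 30-fraction grid spanning 1.66–1.77 g/mL,
  normalized over the grid so total mass is conserved before noise, mixed
  with a 2% uniform background that emulates the smearing/tailing real
  gradients show — without it, a taxon whose band lies outside the heavy
  window would have *exactly* zero control-window copies and an undefined
  enrichment, which real data do not produce;
* qPCR copies are per-fraction totals scaled to 10⁷ with multiplicative
  lognormal noise (sdlog 0.15, mean-one); reads are multinomial draws of
  5000 per fraction from the within-fraction taxon masses.

All draws flow from one seed in a documented order (per gradient: the
lognormal vector over fractions, then one multinomial per fraction in
density order), so equal seeds give bit-identical outputs. Since no draw
is per-taxon — band placement is deterministic — a single stream meets
the reproducibility contract without per-taxon substreams.

`synthetic_community()` defaults encode the experimental regime this
method was designed for: 10 taxa, 3 of them incorporators with ¹³C atom
fractions drawn from 0.25–0.40 — bracketing the ~28% incorporation that a
density shift just above 0.01 g/mL corresponds to, and comfortably above
the ~20% usually quoted as the minimum separable labeling — and with GC
contents drawn from the community's upper range (0.55–0.65 versus
0.35–0.65 overall), reflecting that peptide-responsive marine
copiotrophs (Rhodobacteraceae and relatives) are high-GC organisms
whose labeled DNA moves *beyond* the community's unlabeled dense edge.
Incorporators also get a 1.5× growth multiplier, applied in both
treatments (substrate is added in both; only the isotope differs), so
paired gradients differ only by density shifts.

What the generator deliberately does **not** emulate: 16S copy-number
variation between genomes, PCR amplification bias, chimeras, and
gradient-to-gradient differences in DNA recovery beyond the lognormal
qPCR noise. Passing end-to-end tests therefore demonstrate the
statistic's behavior under its own assumptions, not robustness to those
real-data artifacts.

`simulate_incubation()` produces long-format time series for labeled,
unlabeled and killed treatments in duplicate: linear peptide decline to
depletion, a flat killed control, a produce-then-consume hump for
F-containing fragments, ammonium accumulating after depletion, and cells
rising during decomposition; additive Gaussian noise (σ = 0.01 μM)
truncated at zero.

## Known limitations

* **GC–label confound.** A single heavy window cannot separate labeling
  from GC content. An incorporator whose GC is low relative to the
  community will, at ~28% labeling, band *inside* the unlabeled
  community bulk and be undetectable by any window; conversely a high-GC
  non-incorporator contributes unlabeled DNA to the window in both
  gradients. The generator's defaults place incorporators at the high-GC
  edge precisely because that is the regime in which the method works;
  synthetic experiments outside that regime (easily constructed by
  passing a custom community) show the method failing, which is a
  property of the statistic, not a bug.
* **Window-top boundary.** Percent enrichment is monotone in a taxon's
  atom fraction only while its labeled band stays below the window's
  dense end; with a window top inside the gradient, a strongly labeled
  band eventually crosses above it and the statistic genuinely falls.
  Monotonicity tests therefore use windows reaching the gradient top.
* **Few positive enrichments.** With a strong single incorporator the
  zero-sum statistic can leave fewer than two positive values, making
  the noise threshold undefined; `noise_threshold()` rejects, and
  `enrichment_analysis()` degrades to an un-thresholded report with a
  warning. With only 2–3 positives the t-interval is honest but very
  wide.
* **Undefined enrichment.** `NA` marks a taxon absent from the control
  window; downstream tables preserve it.

## Problem sizes and numerical choices

The test suite and the reproduction script run synthetic experiments at
the scale of the emulated design — 30 fractions, 10 taxa, 5000 reads per
fraction — with 50-seed ensembles for rank-recovery properties and
500-replicate ensembles for rate-estimator bias, sizes at which the
binomial noise on a 95%-level property check is a few percent.
Oracle-equivalence checks (window sums versus a brute-force double loop)
use 100 random small instances at relative tolerance 10⁻¹².

## A worked example

```{r example, eval = FALSE}
set.seed(1)
comm <- synthetic_community(seed = 42)
sim <- simulate_gradient_pair(comm, sim_config(), seed = 42)
report <- enrichment_analysis(sim$table_12C, sim$table_13C,
                              sim$profile_12C, sim$profile_13C)
head(report, 4)          # taxa sorted by percent_enrichment
attr(report, "window")   # the automatically selected heavy window
```

The three simulated incorporators occupy the top three enrichment ranks;
the window lands on the dense shoulder the labeled bands created. See the
README for the printed output of this exact run.
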