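# sipenrich

Quantitative analysis for DNA stable isotope probing (SIP) experiments on
CsCl buoyant-density gradients, built around a peptide-amendment design:
a microbial community is incubated with a ¹³C-labeled model tetrapeptide
(AVFA, 17 of its 20 carbons labeled) next to an unlabeled ¹²C control,
each gradient is fractionated and assayed by 16S rRNA gene qPCR and
amplicon sequencing, and taxa that assimilated the labeled carbon are
identified by how much denser their DNA bands.

It is aimed at microbial ecologists running (or simulating) SIP
incubations who want the gradient arithmetic, the per-taxon enrichment
statistic with its noise threshold, the substrate decay kinetics and the
element budgets in one tested, scriptable package.

## The core statistic

With a heavy-density window *W* (a closed density interval at the dense
end of the gradient), for each taxon *i*:

* window copy number: `c_i = Σ_{f∈W} p_if × q_f`, read proportion times
  fraction total 16S copies, summed over the window;
* relative copy number: `r_i = c_i / Σ_j c_j` within each treatment;
* **percentage enrichment**: `E_i = 100 × (r_i^13C − r_i^12C) / r_i^12C`.

`E_i = 100` means the taxon's heavy-window relative copy number is twice
as abundant under labeling. The error level of the statistic is estimated
from the positive enrichments (95% t-interval of the mean, or a
percentile), and taxa are called enriched when `E_i` strictly exceeds the
threshold and the taxon is at least 0.1% of the community.

Around that core: refractive-index → density conversion
(ρ = 10.8601·RI − 13.4974, CsCl at 20 °C), ratio-of-quantities
normalization, density-shift → %¹³C incorporation
(Δρ / 0.036 g mL⁻¹), peptide elemental composition with SIM *m/z*
accounting, zero-order decay-rate fitting, a peptide nitrogen mass
balance (hydrolysis / remineralization / biomass / residual DON closure)
with phosphorus demand, and a fully seeded synthetic-data generator that
emulates the paired-gradient and incubation structure.

## Worked example

Simulate a paired ¹²C/¹³C experiment for a 10-taxon community with three
¹³C-incorporating taxa, then run the full enrichment analysis:

```r
library(sipenrich)

comm <- synthetic_community(seed = 42)   # 3 labeled taxa: t01, t02, t03
sim  <- simulate_gradient_pair(comm, sim_config(), seed = 42)
report <- enrichment_analysis(sim$table_12C, sim$table_13C,
                              sim$profile_12C, sim$profile_13C)
cols <- c("taxon", "rel_copies_12C", "rel_copies_13C", "percent_enrichment")
print(head(report, 4)[, cols], digits = 3)
#>   taxon rel_copies_12C rel_copies_13C percent_enrichment
#> 1   t03         0.0506        0.16663              229.3
#> 2   t01         0.4142        0.74007               78.7
#> 3   t02         0.0808        0.06727              -16.7
#> 4   t05         0.0182        0.00131              -92.8
attr(report, "window")
#> <heavy_window> [1.7359, 1.7472] g/mL
```

The three simulated incorporators occupy the top three ranks: t03's
relative copy number in the heavy window more than tripled (+229%), t01's
rose 79%, while every unlabeled taxon lost window share (the relative
copy numbers sum to 1, so enrichment is zero-sum). The automatically
chosen window sits on the dense shoulder that the labeled DNA created.
With only two positive enrichment values the t-interval threshold is very
wide (≈1100%), so nothing is flagged `above_threshold` here — honest
behavior for a two-positive comparison; `noise_threshold(...,
method = "percentile")` is the alternative.

Decay kinetics on simulated incubations (rates in μM h⁻¹; the generator
runs the bottom-water incubation 1.5× faster than the surface):

```r
series <- simulate_incubation(sim_config(decay_k = 0.018,
                                         initial_peptide = 0.47,
                                         times = c(0, 4, 8, 12, 16)),
                              seed = 42)
fits <- fit_peptide_rates(series)
print(attr(fits, "summary"), digits = 3)
#>   treatment   depth    k_mean k_abs_error
#> 1       12C  bottom  0.026419    0.000162
#> 2       13C  bottom  0.026669    0.000225
#> 3    killed  bottom -0.000704    0.000529
#> 4       12C surface  0.018507    0.000747
#> 5       13C surface  0.018055    0.000129
#> 6    killed surface  0.000291    0.000442
```

Live treatments recover their true rates (0.027 bottom, 0.018 surface);
the poisoned controls fit to zero. Element bookkeeping uses the same
conversion constants throughout:

```r
close_budget(hydrolysis = 0.40, remineralization = 0.06, biomass = 0.05)
#> <nitrogen_budget> hydrolysis 0.4 | remineralization 0.06 | biomass 0.05 | residual DON 0.49
round(phosphorus_demand(9.0e5), 2)   # μM P for a 9e5 cells/mL bloom
#> [1] 0.08
```

See `vignettes/sip-enrichment-analysis.Rmd` for the models, parameter
choices and known limitations, and `inst/scripts/sip-enrich` for a thin
command-line wrapper (`simulate | enrich | kinetics | massbalance`).

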