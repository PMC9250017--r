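# clockvar

Transcriptional variability analysis of the zebrafish segmentation clock
genes *her1* and *her7*, for researchers quantifying gene-expression noise
in single-molecule FISH (smFISH) count data and interpreting it with
stochastic models of bursty transcription.

During somitogenesis, *her1* and *her7* oscillate every ~30 minutes in the
presomitic mesoderm, are expressed at low copy number (mean total ≈ 49
molecules per cell), and are strongly co-regulated. Across a population of
cells at the same oscillation phase (a single-cell-wide
posterior-to-anterior slice), cell-to-cell variability of the paired
transcripts decomposes as in dual-reporter noise analysis:

    uncorrelated = 1/2 < ( x/<x> − y/<y> )² >          (intrinsic-like)
    correlated   = ( <xy> − <x><y> ) / ( <x><y> )      (extrinsic-like)
    total        = correlated + uncorrelated = ( CV²x + CV²y ) / 2

with `x`, `y` the per-cell *her1*, *her7* counts and `< >` plain population
averages. The package provides:

* **Variability curves** — per-slice decomposition, optional cell-volume
  normalization, and 5-bin variability-versus-mean curves
  (`slice_statistics()`, `volume_correct()`, `bin_curve()`).
* **Genotype comparison** — bootstrap resampling of slices (100×), area
  under the variability curve over the genotypes' overlapping expression
  range, percent difference and a calibrated paired test
  (`bootstrap_auc_compare()`), plus Kolmogorov-Smirnov and Shapiro-Wilk
  helpers.
* **Stochastic clock model** — exact Gillespie simulation (compiled core)
  of a delayed negative-feedback oscillator with correlated
  transcriptional bursting: co-firing fraction α, geometric burst sizes
  with Hill repression of burst size by the Her1·Her7 heterodimer, and
  10-step Erlang delay chains (`sim_params()`, `simulate_population()`,
  `sim_variability_curve()`, `deletion_mutant()`, `dosage_comparison()`).
* **Synthetic smFISH generator** — Poisson-lognormal mixture with
  kinematic-wave spatial profiles, lognormal cell volumes and closed-form
  expected statistics, so every estimator is testable against ground truth
  (`synth_config()`, `generate_cells()`, `make_genotype_pair()`).
* **I/O and CLI** — canonical CSV cell tables, a column-mapping importer
  for published spreadsheets, JSON results files, and a command-line
  interface (`clockvar_cli()`; `inst/cli/clockvar.R`) with `analyze`,
  `compare`, `simulate` and `synth` subcommands.

See the methods vignette (`vignettes/clockvar-methods.Rmd`) for the model,
parameter defaults and numerical choices.

## Worked example

Generate a wild-type-like dataset and a matched mutant with 23% lower
expression and 38% lower correlated variability (the kind of effect a
heterozygous deletion of the locus produces), then compare them:

```r
library(clockvar)

cfg  <- synth_config(seed = 7)                    # 6 embryos, 30 slices/half
pair <- make_genotype_pair(cfg, level_scale = 0.77,
                           correlated_scale = 0.62, genotype_b = "del_het")

pts_wt  <- slice_statistics(volume_correct(pair$a))
pts_mut <- slice_statistics(volume_correct(pair$b))
bin_curve(pts_wt)
#>   bin bin_mean_her mean_correlated mean_uncorrelated mean_total
#> 1   1       0.0066          0.1216            0.3609     0.4825
#> 2   2       0.0143          0.1373            0.1473     0.2846
#> 3   3       0.0270          0.1487            0.0793     0.2280
#> 4   4       0.0392          0.1431            0.0500     0.1931
#> 5   5       0.0499          0.1669            0.0367     0.2036

bootstrap_auc_compare(pts_wt, pts_mut, "correlated", seed = 1)
#> <auc_comparison> correlated variability: -34.7% (bootstrap mean, n = 100) / -34.4% (full data)
#>   paired t = -6.453, p = 4.08e-09
```

Reading the curve: `bin_mean_her` is mean total her per µm³ (counts were
volume-corrected), uncorrelated variability falls as 1/mean (counting
noise) while correlated variability stays near its extrinsic floor
(expected `exp(0.62 · 0.25) − 1 ≈ 0.17` after volume correction removes
the volume-coupled share). The comparison recovers the injected −38%
correlated effect to within its bootstrap error and rejects equality.

Simulating the clock model instead:

```r
snaps <- simulate_population(sim_params(), n_cells = 60, seed = 1)
sim_variability_curve(snaps)           # binned curve from the model
dosage_comparison(sim_params(), seeds = 1:10)  # wild type vs Bmax/2 mutant
```

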