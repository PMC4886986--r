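# dosewedge

Dose-resolved radiation-damage analysis for room-temperature serial
crystallography on multiple small crystals.

## What it does, and for whom

Room-temperature protein crystals tolerate orders of magnitude less X-ray
dose than cryo-cooled ones. The standard way to quantify this is to
collect consecutive rotation frames from several crystals, track the
absorbed dose per frame, and model how the merged intensity statistics
decay with cumulative dose. `dosewedge` is for methods developers and
beamline scientists who want that analysis as reproducible, tested code:

* Miller-index symmetry machinery for cubic point group 23 (the
  rotational point group of space group I2₁3): asymmetric-unit mapping,
  resolution calculation, a plain-text unmerged reflection format;
* a synthetic multi-crystal experiment generator with known ground truth
  (Wilson-statistics intensities, per-crystal exponential dose decay,
  Poisson counting noise, hidden two-state indexing modes);
* indexing-ambiguity resolution by Pearson-correlation maximization over
  common reflections;
* relative K/B scaling of dose wedges against the first wedge;
* exponential dose-decay fitting with derived damage metrics;
* merging statistics: R_merge, R_meas, CC½, CC*, completeness,
  multiplicity, mean I/σ.

The decay model for the normalized mean intensity is

    I(D) = I0 · exp(−β_tot · D) + I1

with absorbed dose D (kGy). Derived metrics: the specific dose
D\* = 1/β_tot, the half dose D_1/2 = D\*·ln[2·I0/(I0 − I1)], and the
undamaged fraction I1/(I0 + I1).

## Worked example

Derived metrics from a published per-crystal fit (I0 = 1.04, I1 = 0.236,
D\* = 149.1 kGy):

```r
library(dosewedge)
derived_doses(i0 = 1.04, i1 = 0.236, d_star = 149.1)
#> $d_star
#> [1] 149.1
#> $d_half
#> [1] 141.7226
#> $undamaged_fraction
#> [1] 0.1849530
```

The half dose says this crystal's mean intensity halves after ~142 kGy;
18.5% of its initial diffracting power appears dose-insensitive.

A full synthetic experiment — 5 crystals × 700 frames at 0.808 kGy/frame,
decay parameters per crystal, random hidden indexing modes — analysed end
to end (about half a minute):

```r
report <- run_pipeline(default_config(), seed = 11)
print(report$cohort)
#> cohort of 5 crystals:
#>   D*      = 153.0 +/- 22.2 kGy
#>   D_1/2   = 141.8 +/- 19.9 kGy
#>   undamaged fraction = 17.2% +/- 2.6%
#>   tolerable dose vs cryo reference (43000 kGy): 1/303
```

The cohort mean specific dose (153.0 kGy here) recovers the generator's
ground truth; the last line compares the cohort mean half dose with a
configured cryogenic reference half dose of 43 MGy — at room temperature
these crystals tolerate roughly 1/300 of the cryo dose. `report$modes`
carries the resolved indexing modes (meaningful up to a global flip),
`report$subset_stats` the per-wedge means, I/σ in the 2.4–1.9 Å shell,
and relative K/B scales, `report$merging` the per-wedge merging
statistics.

There is also a CLI:

```sh
Rscript -e 'dosewedge::pipeline_cli()' run --seed 11 --out out/
```

with subcommands `simulate`, `resolve`, `analyze`, `stats`, `run` and
flags `--config PATH` (JSON), `--seed INT`, `--out DIR`,
`--subset-size INT`, `--dose-per-frame FLOAT`.

## Documentation

The methods vignette (`vignettes/dose-decay-analysis.Rmd`) documents the
model and its assumptions, what the synthetic generator does and does not
emulate, the uncertainty estimator used for the decay fit, and known
limitations.
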