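# opticlear

Quantitative transparency assessment for optically cleared tissue, plus a
light-sheet image-stack processing chain, in R.

Optical tissue clearing (CUBIC, BABB, TDE, …) renders tissue transparent so
that light-sheet and confocal microscopes can image deep into intact samples.
Judging a clearing protocol "by eye" is unreliable; `opticlear` implements the
standard quantitative alternative: paired bright-field transmitted-light
images — a blank illumination image `I0` acquired without the sample and a
sample image `I` — are related by the Beer–Lambert law

    I = I0 · exp(−µ L)

where `L` is the sample thickness (mm) and `µ` the attenuation coefficient
(mm⁻¹): higher `µ` means more opaque tissue. The package estimates

    µ = ln( mean(I0_region) / mean(I_region) ) / L

over small randomly placed regions, following a hierarchical resampling
protocol: **3 regions per run × 15 runs per image × 3 images per sample =
135 individual measurements**, averaged into one value (mean ± SEM) per
sample. Clearing conditions are then compared by one-way ANOVA with
Bonferroni-corrected pairwise post-tests.

The package is aimed at microscopy/clearing labs that want a reproducible,
scriptable version of this protocol, and ships with:

* `phantom` generators with known ground truth (`transmittance_phantom_spec()`,
  `generate_transmittance_pair()`, `stack_phantom_spec()`,
  `generate_fluorescence_stack()`) — every estimator in the package is
  validated against them;
* the measurement protocol (`region_mu()`, `sample_regions()`,
  `run_protocol()`, `simulate_experiment()`, `measure_experiment()`);
* group statistics (`one_way_anova()`, `bonferroni_pairwise()`,
  `summarize_groups()`, `compare_conditions()`);
* a light-sheet stack chain (`median_filter_3x3()`, `remove_stripes()`,
  `adjust_contrast_linear()`, `max_intensity_projection()`,
  `export_volume()`);
* I/O for TIFF (built-in baseline codec: 8/16-bit, 32-bit float, multi-page),
  PNG and NRRD, and a CLI (`otc_cli()` / `inst/cli/opticlear`) with
  `simulate`, `measure`, `compare` and `process-stack` subcommands.

## Worked example

Simulate a three-condition clearing comparison (uncleared µ = 4.0 mm⁻¹,
BABB-like 1.5 mm⁻¹, CUBIC-like 0.5 mm⁻¹; L = 2 mm; Gaussian read noise with
sd = 2 % of the illumination level; 3 samples × 3 images each), run the full
135-measurement protocol on every sample, and compare:

```r
library(opticlear)

samples  <- simulate_experiment(default_conditions(), seed = 1)
measured <- measure_experiment(samples, protocol_params(seed = 1))
compare_conditions(measured$measurements, unit = "sample")
```

```
<group_comparison_result> one-way ANOVA + Bonferroni post-test
  unit of replication: sample
  F(2, 6) = 7964, p = 5.339e-11
  per-condition mean +/- SEM (mm^-1):
    BABB         1.4997 +/- 0.0004 (n = 3)
    CUBIC        0.5000 +/- 0.0001 (n = 3)
    uncleared    4.0029 +/- 0.0350 (n = 3)
  pairwise (Bonferroni-adjusted):
    BABB vs CUBIC: t = 34.960, p_adj = 1.09e-07 (*)
    BABB vs uncleared: t = -87.540, p_adj = 4.49e-10 (*)
    CUBIC vs uncleared: t = -122.500, p_adj = 5.99e-11 (*)
```

Each condition's recovered mean tracks its generating attenuation to well
under 1 %, and every Bonferroni-adjusted pairwise p-value is far below the
0.001 significance level such comparisons are reported at (`*`).

The same pipeline is available from the shell:

```sh
Rscript inst/cli/opticlear simulate --out-dir sim --seed 1
Rscript inst/cli/opticlear measure  --manifest sim/manifest.csv --out-dir meas --seed 1
Rscript inst/cli/opticlear compare  --measurements meas/measurements.csv --out-dir cmp
Rscript inst/cli/opticlear process-stack --input stack.tif --output out.nrrd \
        --destripe-axis x --format nrrd
```

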