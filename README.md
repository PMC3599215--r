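# ivimsim

B-value scheme sensitivity analysis for diffusion-weighted MRI (DWI) with
synthetic intravoxel incoherent motion (IVIM) phantoms.

## The science

The apparent diffusion coefficient (ADC) reported in clinical DWI is the
slope of a monoexponential fit,

    S(b) = S0 · exp(−b · ADC),

but in perfused tissue the signal decay is biexponential (the IVIM model):

    S(b) = S0 · [ (1 − fp) · exp(−b·D) + fp · exp(−b·D*) ],

where `D` is the tissue diffusion coefficient, `D*` the capillary
pseudodiffusion coefficient (`D* ≫ D`), and `fp` the perfusion fraction.
The pseudodiffusion term decays within the first tens of s/mm², so the
*choice of b values* entering the monoexponential fit determines how much
perfusion inflates the ADC above `D`. Combinations that include low b
values (0–100 s/mm²) are flow-sensitive; combinations restricted to high b
values approach `D` from above.

`ivimsim` quantifies this in a fully controlled setting:

* **Signal models** — closed-form mono-/biexponential signals and the exact
  two-point ADC (`mono_signal()`, `biexp_signal()`, `two_point_adc()`).
* **Scheme registry** — 13 monoexponential b-value combinations `B0`–`B12`
  plus the full biexponential fit `B0_biexp`, all subsets of a five-point
  acquisition at b = 0, 50, 100, 250, 800 s/mm² (`builtin_schemes()`).
* **Synthetic phantom** — seed-deterministic 3-D digital phantoms with
  homogeneous spherical lesions, known ground-truth parameter maps, and
  Rician magnitude noise (`phantom_spec()`, `generate_phantom()`); NIfTI
  round trip via `write_dataset()` / `read_dataset()`.
* **Voxel fitting** — Levenberg–Marquardt fits of both models with a
  deterministic multi-start for the biexponential, goodness-of-fit QC, and
  broom-style `tidy()`/`glance()` methods (`fit_mono()`, `fit_biexp()`,
  `compute_maps()`, `qc_filter()`).
* **Cohort statistics** — per-lesion ROI medians, pairwise
  percent-deviation matrices, exact-under-ties Wilcoxon signed-rank tests
  and Spearman correlations (`summarize_roi()`, `deviation_matrix()`,
  `paired_compare()`, `cohort_report()`).
* **CLI** — a config-file pipeline `simulate → fit → report`
  (`inst/scripts/dwi-pipeline.R`).

Everything is tidyverse-native: tibbles in, tibbles out, ggplot2
`autoplot()`/`plot_*()` graphics.

## Worked example

Simulate a noisy 8-lesion phantom, fit four schemes, and compare them at
cohort level. (Output below is from a real run.)

```r
library(ivimsim)

ph <- generate_phantom(phantom_spec(n_lesions = 8, snr = 50, seed = 42))
ph
#> <dwi_phantom> 21x21x7 grid, 5 b values (0, 50, 100, 250, 800), 8 lesions, 264 lesion voxels; seed 42

reg <- builtin_schemes()
maps <- compute_maps(
  ph, reg[reg$scheme_id %in% c("B0", "B1", "B6", "B0_biexp"), ],
  thresholds = qc_thresholds(r2_min = 0, chi2_max = Inf))  # convergence-only QC
maps
#> # A tibble: 1,056 × 17
#>   voxel_id     x     y     z lesion scheme_id model n_points   si0     adc     d
#>      <int> <int> <int> <int>  <int> <chr>     <chr>    <int> <dbl>   <dbl> <dbl>
#> 1      508     4     4     2      1 B0        mono         5  863. 6.38e-3    NA
#> 2      515    11     4     2      2 B0        mono         5  975. 1.82e-3    NA
#> 3      522    18     4     2      3 B0        mono         5  848. 8.90e-4    NA
#> 4      655     4    11     2      4 B0        mono         5  838. 2.14e-3    NA
#> # ℹ 1,052 more rows
#> # ℹ 6 more variables: d_star <dbl>, fp <dbl>, r_squared <dbl>,
#> #   chi_squared <dbl>, converged <lgl>, qc_pass <lgl>

rep <- cohort_report(summarize_roi(maps),
                     scheme_ids = c("B0", "B1", "B6", "B0_biexp"),
                     maps = maps)
rep$descriptives
#> # A tibble: 6 × 10
#>   scheme_id model parameter   mean     sd median    min    max n_lesions unit
#>   <chr>     <chr> <chr>      <dbl>  <dbl>  <dbl>  <dbl>  <dbl>     <int> <chr>
#> 1 B0        mono  adc        3.18   2.46   1.97   0.992  7.09          8 x10^-3…
#> 2 B1        mono  adc        1.70   0.540  1.76   1.01   2.51          8 x10^-3…
#> 3 B6        mono  adc        1.09   0.434  1.17   0.438  1.59          8 x10^-3…
#> 4 B0_biexp  biexp d          1.07   0.422  1.18   0.413  1.55          8 x10^-3…
#> 5 B0_biexp  biexp d_star    47.5   15.5   46.9   24.9   71.9           8 x10^-3…
#> 6 B0_biexp  biexp fp         0.373  0.180  0.416  0.118  0.542         8 dimens…

rep$deviations
#> <deviation_matrix> 4 schemes, method = group_median
#>          B0      B1      B6     B0_biexp
#> B0       0       12.1*   68.0** 66.8**
#> B1       -10.8*  0       49.8** 48.8**
#> B6       -40.5** -33.3** 0      -0.7
#> B0_biexp -40.1** -32.8** 0.7    0

dplyr::filter(tidy(rep$deviations), scheme_a == "B0", scheme_b == "B0_biexp")
#> # A tibble: 1 × 4
#>   scheme_a scheme_b deviation_pct p_value
#>   <chr>    <chr>            <dbl>   <dbl>
#> 1 B0       B0_biexp          66.8 0.00781
```

The expected physics is visible directly: the flow-sensitive all-b ADC
(`B0`) exceeds the biexponential `D` by tens of percent, the high-b
two-point ADC (`B6`, b = 250/800) nearly coincides with `D` (−0.7 %), and
every deviation pair satisfies the reciprocity identity
`(1 + d_ab/100)(1 + d_ba/100) = 1`. Stars mark paired signed-rank
significance (`*` p < 0.05, `**` p < 0.01), computed exactly even under
tied differences.

A note on QC: the default thresholds (`r2_min = 0.98`) are a noise screen
for map cleaning. For mono fits spanning low and high b they also flag
*model misspecification* in strongly perfused lesions, which would exclude
exactly the lesions the scheme comparison is about — hence the
convergence-only thresholds in cohort comparisons. See the vignette
(`vignettes/bvalue-scheme-bias.Rmd`) for the full methods discussion.

## Command-line pipeline

```sh
Rscript inst/scripts/dwi-pipeline.R simulate --config run.yaml --out data/
Rscript inst/scripts/dwi-pipeline.R fit      --config run.yaml --data data/ --out maps/
Rscript inst/scripts/dwi-pipeline.R report   --config run.yaml --maps maps/ --out report/
```

The YAML/JSON config controls the phantom, scheme subset, QC thresholds and
seed; outputs are NIfTI maps with JSON sidecars plus CSV/JSON report tables.

## Tests

```sh
Rscript -e 'devtools::test()'
# or against the installed package:
Rscript -e 'testthat::test_dir("tests/testthat", package = "ivimsim", load_package = "installed")'
```

The suite (~600 assertions) validates every numerical route against an
independent oracle: closed-form chord ADCs, a profile-likelihood
least-squares oracle for multi-point fits, full 2^n enumeration for the
signed-rank test, and analytic Rician/Rayleigh noise moments.

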