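# lipocoloc

Quantification toolkit for membrane binding of cholesterol-modified DNA and
DNA origami nanostructures, from two complementary readouts:

1. **Two-channel fluorescence colocalization** (TIRF-style imaging of
   surface-tethered liposomes). Liposome pixels are identified with a single
   per-condition intensity threshold — two standard deviations above the mean
   pixel intensity of the liposome channel pooled over *all* images of an
   experimental condition — and the binding score is the ratiometric
   colocalization ratio

   ```
   C_R = F_DNA,lipid / F_DNA,background
   ```

   the mean DNA-channel intensity over liposome-mask pixels divided by the
   mean over background pixels. `C_R = 1` means the DNA is distributed
   independently of the liposomes; `C_R > 1` means membrane enrichment.
   Whole-image Pearson correlation and Manders coefficients are computed
   alongside, together with an area-bias diagnostic that regresses each
   metric on liposome coverage (C_R should be flat; Pearson is not).

2. **Gel-shift densitometry** (agarose gel electrophoresis). Unbound tiles
   migrate as a band while liposome-bound material stays in the well, so the
   membrane-bound percentage is

   ```
   T = (1 − B/U) × 100%
   ```

   with `B` and `U` the background-corrected tile-band integrals of the lane
   with and without liposomes (always paired within a single gel). Band
   integration uses flanking-box median background correction. The package
   also normalizes reporter-fluorophore bands to a total-DNA stain and
   estimates anchor-handle occupancy by inverse regression of band intensity
   on handle count, with t-based 95% confidence intervals.

Because raw microscopy and gel data for such studies are rarely deposited,
the package ships fully seeded synthetic generators for both assay types with
exact ground truth (true liposome masks, true DNA enrichment, true bound
fraction), so every stage of the analysis is testable end to end. Condition
level statistics (regression-slope trend calls, exact/approximate Wilcoxon
rank-sum comparisons, pooled summaries) round out the analysis layer.

The audience is membrane nanotechnology / DNA nanostructure labs who want a
scripted, reproducible replacement for ad-hoc ImageJ macros and gel vendor
software.

## Worked example

Simulate one imaging condition with a true DNA enrichment of 1.9×, run the
full threshold → mask → C_R pipeline, and summarize:

```r
library(lipocoloc)

sim <- simulate_imaging_condition(imaging_scenario(
  n_images = 6, enrichment_rho = 1.9, seed = 11, condition_id = "chol_dna"
))
res <- coloc_condition(sim$condition)
summarize_coloc(res)
#> # A tibble: 1 × 4
#>   condition_id mean_C_R   sd_C_R n_images
#>   <chr>           <dbl>    <dbl>    <int>
#> 1 chol_dna         1.89 0.000740        6
```

The condition mean C_R of 1.89 recovers the generator's enrichment of 1.9 to
within about half a percent; per-image values (in `res`) sit near 1.89 with
coverages of 8–10% and Pearson correlations near 0.95.

Gel side — render a gel whose sample lane is depleted by a true bound
fraction of 55%, integrate the annotated bands, and form T:

```r
gel <- simulate_gel_image(gel_scenario(bound_fraction_true = 0.55, seed = 11))
bound_fraction_table(measure_gel(gel$image, gel$lanes))
#> # A tibble: 1 × 5
#>   gel_id pair          B        U T_pct
#>   <chr>  <chr>     <dbl>    <dbl> <dbl>
#> 1 gel_1  pair_1 2843358. 6398683.  55.6
```

`T_pct = 55.6` estimates the true 55% bound; the residual error comes from
the default 2% per-lane loading variation and pixel noise.

Occupancy — given stain-normalized band intensities at 0–4 handles and a
nominal 16-handle design:

```r
d <- data.frame(handle_count = c(0, 1, 2, 4, 16),
                intensity = c(0.02, 0.98, 2.05, 4.1, 11.2))
occupancy_regression(d, nominal_n = 16)
#> <occupancy_fit>
#>   slope 1.025 per handle; nominal n = 16 -> 10.93 occupied (68.3%)
#>   95% CI on the count: [10.47, 11.40]
```

A full simulate → segment → colocalize → gel → stats run from one YAML
config is available through `run_pipeline()`; see `?run_pipeline` and the
methods vignette (`vignettes/quantifying-dna-liposome-binding.Rmd`).

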