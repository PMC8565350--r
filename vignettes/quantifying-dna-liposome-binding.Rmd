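---
title: "Quantifying DNA–liposome binding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA–liposome binding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipocoloc)
```

# The measurement problem

Cholesterol-anchored DNA strands and DNA origami tiles bind lipid membranes.
Two assays quantify that binding at very different scales, and this package
implements the quantification layer for both:

* **Imaging.** Surface-tethered liposomes are imaged in one fluorescence
  channel (a rhodamine-labelled lipid), the DNA in a second (a far-red dye).
  The question per field of view is: how much brighter is the DNA channel on
  liposome pixels than elsewhere?
* **Gel shift.** Tiles incubated with liposomes are run on an agarose gel
  next to a liposome-free control. Unbound tiles migrate as a discrete band;
  liposome-bound tiles stay in the well. Band depletion measures binding.

# Colocalization model

## Segmentation rule

Liposome pixels are identified by a single intensity threshold per
experimental condition:

$$\theta = \mu + 2\sigma$$

where $\mu$ and $\sigma$ are the mean and standard deviation of the lipid
channel pooled over **all** pixels of **all** images in the condition. Two
details are fixed deliberately:

* $\sigma$ is the *population* SD (denominator $N$). At $10^5$–$10^6$ pixels
  the difference from the sample SD is negligible, but fixing it makes the
  threshold an exact function of the pooled pixel multiset — invariant to
  image order and to splitting images into tiles — which the oracle tests
  exploit.
* A pixel is liposome iff its intensity is **strictly** greater than
  $\theta$. "Above the threshold" is resolved deterministically: ties go to
  background, so a perfectly uniform condition yields an empty mask rather
  than an arbitrary one.

No morphological clean-up is applied by default, because the measurement is
a pooled-intensity ratio, not an object count; `binarize(min_size = )`
offers an optional connected-component size filter for visibly speckled
data.

## The colocalization ratio

$$C_R = \frac{F_{\mathrm{DNA,lipid}}}{F_{\mathrm{DNA,background}}}$$

with both numerator and denominator arithmetic means of *raw* DNA-channel
intensities over the mask and its complement. The design is ratiometric on
purpose: multiplying the DNA channel by any $k > 0$ (exposure, gain) leaves
$C_R$ unchanged, which is tested as an invariant. An *additive* offset does
change $C_R$; that too is tested, as documentation of a real limitation —
cameras with a large dark offset should be offset-corrected upstream.

$C_R$ is computed per image and summarized per condition as mean ± SD over
images. Per-image values are the natural unit: each field of view is an
independent draw of liposomes, and per-image reporting is what makes the
rank-sum and trend machinery downstream honest about $n$.

Pearson correlation over all pixel pairs and Manders fractions are emitted
alongside as comparison metrics, not as primary statistics.

## The area-bias diagnostic

A colocalization score used to compare conditions with different liposome
densities must not itself depend on density. `area_bias_check()` regresses
each metric on per-image coverage and reports the slope with a 95% CI.
`simulate_bias_suite()` builds the standard input: images identical in
everything but liposome count (default 5–80), analyzed as **one** condition
with one shared threshold — which is exactly how the threshold rule is
defined, and also what keeps the diagnostic clean. With a single shared
threshold the blurred rim of every disk is cut at the same intensity level
regardless of how many disks an image holds, so the per-disk mask geometry is
density-independent and $C_R$ carries no mechanical coverage trend. (Had the
threshold been recomputed per image, the pooled statistics — and with them
the cut level on the disk edge — would drift with coverage, imprinting a
spurious trend that says nothing about the statistic itself.) The suite's
default disk radius (4 px) keeps even the densest image's coverage low
enough that the pooled threshold stays below the half-rise of the blurred
edge; masks are then marginally dilated, and the background region remains
pure background for every density. Under this suite, the $C_R$-vs-coverage
slope CI should contain 0 while the Pearson-vs-coverage CI should not —
Pearson's coverage dependence is structural, since the fraction of
signal-bearing pixels enters its variance terms directly.

# The synthetic imaging generator

`simulate_imaging_condition()` renders what the analysis needs and nothing
more:

* **Liposomes** are non-overlapping hard disks (rejection-sampled, radii
  truncated-normal, fully inside the frame) at `lipid_fg_mean` over
  `lipid_bg_mean`, convolved with a Gaussian of `blur_sigma` (default 1 px)
  so that thresholding has a genuine partial-intensity edge to cut through —
  the simplest model that makes segmentation non-trivial.
* **DNA enrichment** is a sharp step on the *true* disk mask: mean
  `dna_bg_mean` outside, `enrichment_rho × dna_bg_mean` inside. Enrichment
  is defined on mean intensity — the same quantity $C_R$ estimates — so
  `enrichment_rho` is the exact ground truth for $C_R$, and
  `enrichment_rho = 1` renders a DNA channel statistically independent of
  liposome positions.
* **Noise** is additive Gaussian with SD 5% of each channel's background
  mean by default (EMCCD images at moderate illumination are approximately
  Gaussian at this level); Poisson shot noise is available. Pixels are
  clipped to the bit grid (16-bit default, intensities far from saturation)
  and the clipping fraction is reported; an 8-bit saturation stress case is
  exercised in the tests but is not a default.
* Everything is a pure function of the scenario, seed included.

Default geometry — 256×256 px, 30 disks of radius 8 ± 2 px, foreground
12000 over background 1000 — gives ~9% coverage and a threshold that lands
high on the blurred disk edge, i.e. slightly *eroded* masks containing only
true liposome pixels. That choice makes the default condition a faithful
estimator of `enrichment_rho` (the tests require recovery within 5% for
$\rho \in \{1.5, 2, 3\}$ and $|C_R - 1| < 0.02$ at $\rho = 1$), with the
small residual bias coming from enriched edge pixels that the eroded mask
relegates to the background mean. Liposome surface density is a free
parameter throughout: it is not a quantity the assay measures.

What the generator does **not** emulate: diffraction physics beyond a fixed
Gaussian blur, evanescent-field depth, liposome size–intensity correlation,
uneven illumination, camera offset/read-structure, or aggregation. Passing
tests therefore demonstrate the correctness and calibration of the
*quantification* given its stated image model — not robustness to every
artefact of real microscopes, which is what the area-bias diagnostic and
ratiometric design address only in part.

# Gel model and densitometry

`simulate_gel_image()` renders paired lanes: a control lane with the full
tile band (Gaussian along the migration axis, flat across the lane) and a
sample lane whose band amplitude is scaled by $(1 - f)$ for true bound
fraction $f$, with the bound signal deposited in the well region near the
top. Each lane's signal is multiplied by a lognormal loading factor (mean 1,
CV 2% by default — the scale of pipetting variation the replicate-gel design
exists to absorb). The rendered image is kept in floating point; values are
quantized only when written to TIFF.

`integrate_band()` sums the annotated band box and subtracts a per-pixel
background taken as the **median of two flanking boxes** of equal size
directly above and below the band. Vendor software does not disclose its
background model; the flanking median is simple, robust to a stray speck,
and exactly testable. Corrected integrals are floored at zero and flagged
when negative.

$$T = \left(1 - \frac{B}{U}\right) \times 100\%$$

is formed **only within a gel** (the API refuses cross-gel pairs), and
replicate gels are summarized as mean ± SD of per-gel $T$. Because sample
and control boxes truncate the same ±3σ band profile, the truncation cancels
in $B/U$ and a noiseless render recovers $T = 100f$ exactly — the generator
and quantifier are adjoint by construction, which is the point of keeping
the gel image unquantized. $B > U$ (negative $T$) is reported with a warning
rather than censored; silently clipping at 0 would bias replicate means
upward at low binding.

## Occupancy by inverse regression

Reporter intensity per attachment handle is taken as linear at low handle
counts ($n = 0$–4, where self-quenching and detector non-linearity are
negligible). An OLS line over the low-count points maps the observed
intensity of the nominal-$n$ design back to an effective occupied count
$\hat n = (y^* - a)/b$, with the classical calibration standard error

$$\mathrm{SE}(\hat n) = \frac{s}{|b|}\sqrt{\frac{1}{m_{obs}} +
\frac{1}{m_{fit}} + \frac{(\hat n - \bar n)^2}{S_{nn}}}$$

and a $t_{m_{fit}-2}$ quantile for the 95% CI. The intercept is fitted (it
is pinned by the $n = 0$ measurement) rather than forced to zero, so a
non-zero blank does not corrupt the slope. A non-positive slope is an error:
occupancy is undefined without signal growth. A 200-replicate simulation at
true occupancy 0.7 verifies ≥90% CI coverage in the test suite.

# Inference layer

* **Trend calls** are read off the t-based 95% CI of an OLS gradient:
  `increasing` iff the lower bound exceeds 0, `decreasing` iff the upper
  bound is below 0. A numerically perfect fit gets a degenerate CI rather
  than a spurious one. Per-image values are the default regression unit;
  condition means can be passed instead when images are strongly clustered.
* **Rank-sum comparisons** use exact enumeration when both groups have ≤ 20
  observations and no ties, and the tie-corrected normal approximation with
  continuity correction otherwise. Exact small-sample p-values are discrete:
  3-vs-3 groups can never go below $p = 0.1$, and calibration simulations in
  the tests use 18 per group, where the achievable test size (≈0.045) sits
  close to the nominal 0.05. Unadjusted p-values are primary (matching how
  pairwise condition tests are conventionally reported); Holm adjustment is
  available behind a flag.
* **Pooled summaries** are means over per-image values, never means of
  condition means, with named or predicate-based condition exclusion so
  that sensitivity analyses (e.g. dropping an extreme-pH condition) are one
  argument, not a data edit.

Batch effects (e.g. different liposome preparations) are deliberately out of
scope for modelling; they surface only as grouping columns, and the
within-gel pairing rule is the gel-side expression of the same caution.

# Reproducibility plumbing

`run_pipeline()` drives simulate → segment → colocalize → gel → stats from
one YAML config. Every stage derives its seed deterministically from the
master seed and the stage name, so runs are pure functions of the config;
the run report carries an MD5 checksum per artifact and a hash of the
config's scientific content (paths excluded). Conditions are written as one
multi-page TIFF each (channels as interleaved pages, order declared in a
flat CSV manifest) with a JSON ground-truth sidecar; mixed bit depths within
a condition are rejected rather than rescaled, because the threshold pools
raw intensities. Frame averaging of repeated acquisitions is available in
principle upstream of the loader but is off by default: averaging changes
the pooled noise term and therefore the threshold, so it must be an explicit
choice.

# Problem sizes

The test suite and the acceptance script run everything at desk scale by
design: 96–256 px images, 1–10 images per condition, single-figure disk
counts for unit tests and the default 30 for calibration checks, 200–1000
replicate simulations for CI coverage and test-size calibration. These sizes
give Monte-Carlo standard errors comfortably inside every asserted
tolerance while keeping the full suite in the tens of seconds; all of them
are scenario parameters, so scaling any of them up is a config change, not a
code change.

# Known limitations

* The image model is a two-level step world; $C_R$ on real data inherits
  sensitivity to additive offsets and to background structure the generator
  does not render.
* Lane boxes are user-supplied; there is no automatic band finding, no
  molecular-weight calibration, and no treatment of aggregation smears.
* The occupancy estimate leans on the low-count linearity assumption; if
  quenching already bites below $n = 4$, the extrapolated count is a lower
  bound rather than an estimate.
* No per-liposome instance segmentation or tracking: all statements are
  pixel-population statements.
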