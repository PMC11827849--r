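---
title: "Methods: quantifying enhancer activity, allelic expression, and cardiomyocyte mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enhancer activity, allelic expression, and cardiomyocyte mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinreg)
```

titinreg implements the quantitative procedures used to dissect a cardiac
enhancer of the titin (*TTN*) gene: pooled reporter-assay (MPRA)
quantification with a saturation-mutagenesis effect map, allele-specific
expression (ASE) estimation with cis/trans testing, micropillar
contractility tracking, and sarcomere filament metrology, together with the
statistics these analyses rely on. Every stage has a seeded synthetic-data
generator that emulates its data-generating process and records ground
truth, so each estimator can be validated by parameter recovery.

## MPRA activity quantification

A pooled MPRA measures the transcriptional activity of each reporter
construct as the ratio of its RNA barcode abundance to its plasmid DNA
abundance. Counts are first normalized per technical replicate to counts
per million (CPM), so each replicate's normalized sum is exactly $10^6$.
The activity of construct $c$ in replicate $r$ is

$$a_{cr} = \frac{\mathrm{CPM}^{\mathrm{RNA}}_{cr}}{\mathrm{CPM}^{\mathrm{DNA}}_{cr}}.$$

The experimental layout is three independently cloned plasmid libraries,
each transfected into four wells, giving twelve technical replicates.
Two quality-control rules are applied before analysis:

* **Representation filter.** A (construct, replicate) cell whose DNA CPM is
  below `min_norm_count` (default 100) is excluded — the construct is too
  poorly represented in the plasmid pool for its ratio to be meaningful.
  Cells exactly at the threshold are retained. The filter is applied to the
  DNA assay by default because DNA abundance is the representation
  measurement; `filter_assay = "both"` extends it to RNA.
* **Wild-type replicate rule.** A whole technical replicate is excluded
  when the wild-type construct's activity in it deviates from the mean
  wild-type activity across its library's replicates by at least
  `wt_sd_k` (default 1) standard deviations. The rule is scoped within a
  library because libraries differ systematically in composition; both the
  scope and $k$ are exposed.

No pseudocount is used anywhere: a zero-DNA cell is marked undefined and
excluded rather than imputed, which avoids fabricating activity for absent
constructs.

The mutagenesis effect map projects activities onto genomic positions
(1-based, inclusive intervals): each position's profile value is the mean
over all included cells of constructs whose mutated interval covers the
position, reported separately for deletion and point-mutation construct
categories. Positions covered by no construct are gaps, never zeros.
Group-versus-wild-type comparisons use Welch's unpaired two-tailed t test
with Benjamini–Hochberg adjustment across the groups tested in one call;
families are never pooled across calls.

The synthetic generator draws DNA counts negative-binomially around a
construct-by-library abundance (lognormal with log-scale SD 0.25 around the
mean depth, representing clone-representation drift between libraries) and
RNA counts around abundance × activity, with variance
$\mu + \alpha\mu^2$ ($\alpha = 0$ degrades to Poisson). Because total RNA
output depends on the activity mix, raw ratios are estimates of activity up
to a common scale; `construct_activity(act, relative_to = "WT")` removes
that scale. Recovery tests use 40 constructs at activities
{0.2, 0.4, 1.0, 2.0}, mean depth $10^3$, dispersion 0.1 over 20 seeds and
require Spearman $\rho \ge 0.9$ between true and estimated activities.

## Allele-specific expression

In animals heterozygous for an enhancer deletion on a hybrid strain
background, transcribed strain-distinguishing SNPs report which allele each
read came from. If the deleted element acts in *cis*, only the deleted
allele's transcription falls, so the mutant-linked/WT-linked read ratio
drops below 1 in heterozygotes while remaining at 1 in wild-type-genotype
animals; a *trans* factor would depress both alleles and leave the ratio
at 1 in both groups.

The per-sample ratio estimator is pooled by default — total mutant-linked
counts over total WT-linked counts across SNPs — which weights SNPs by
depth; `mean_of_snps` averages per-SNP ratios instead, and the two coincide
exactly when all SNPs share depth and ratio. Undefined ratios (zero
denominator) propagate as missing, never as 0 or infinity. Group
comparison is Welch's t on per-sample ratios.

The generator draws the mutant-allele count at each SNP binomially with
success probability $r/(1+r)$ for true ratio $r$; with dispersion
$\delta > 0$ the per-SNP probability is beta-distributed with that mean and
concentration $1/\delta$, capturing SNP-to-SNP variability from mapping and
local coverage effects. The pooled estimator has a small positive Jensen
bias (the ratio is a convex function of the pooled proportion) that is
negligible at the tested depths; the null-recovery suite (200 seeds at
depth $10^4$) requires the grand mean to sit within 0.01 of 1.

qPCR relative expression uses the standard $\Delta\Delta C_t$ method with
HPRT as the housekeeping gene: per-sample
$\Delta C_t = C_t(\mathrm{target}) - C_t(\mathrm{HPRT})$,
$\Delta\Delta C_t$ relative to the reference-group mean, fold
$= 2^{-\Delta\Delta C_t}$. The fold is invariant to any per-sample constant
shift in $C_t$ since the housekeeping subtraction cancels it. Mendelian
genotype ratios are tested by the asymptotic $\chi^2$ goodness of fit
(df = categories − 1), matching the test the field reports for lethal
genotype classes.

## Micropillar contractility

Cardiac microtissues suspended between two elastic pillars bend the
pillars when they contract; pillar deflection times the calibrated spring
constant $k = 2.68\ \mu\mathrm{N}/\mu\mathrm{m}$ gives twitch force, and
force over the tissue cross-sectional area gives stress
($1\ \mu\mathrm{N} / 1\ \mathrm{m}^2 = 10^{-6}$ Pa, so a 13.4 μN force
over $10^{-6}\ \mathrm{m}^2$ is 13.4 Pa). The area is user-supplied and
echoed in outputs because devices differ; it is not estimated from images.

Tracking is two-stage, per frame, always against the reference-frame
template (no drift update, so errors cannot accumulate):

1. **Integer stage.** Normalized cross-correlation of the cap template
   over a search window; the argmax gives a whole-pixel offset. A peak on
   the window boundary flags the frame and its deflection is missing.
2. **Subpixel stage.** A 3-point parabola through the correlation values
   around the peak, independently per axis; the correction is clamped to
   ±0.5 px by construction.

Deflection is the displacement from the resting position projected onto
the inter-pillar axis (the contraction direction). The resting position is
the per-axis median over frames in the lowest decile of displacement
magnitude — a robust diastolic baseline that tolerates a recording
starting mid-twitch — with `baseline = "first_frame"` as the simpler
alternative. On synthetic stacks with smooth logistic-edged caps (edge
softness 2 px, emulating slight defocus) the tracker is accurate to well
under 0.1 px, and a programmed 1.0 μm twitch yields a maximum force within
5% of $k \times 1\ \mu\mathrm{m} = 2.68\ \mu\mathrm{N}$.

The generator paces one cap along the inter-pillar axis with a
raised-cosine twitch at 1 Hz (period 30 frames at 30 frames/s). Fractional
shortening, the echocardiographic analogue used for whole-animal
contractility, is $(\mathrm{LVEDD} - \mathrm{LVESD}) / \mathrm{LVEDD}
\times 100\%$ with strict input validation (end-systolic cannot exceed
end-diastolic).

## Sarcomere filament metrology

Titin-GFP labels the sarcomere Z-disc region, so a striated cardiomyocyte
appears as strings of short bright stripes. Segmentation
illumination-corrects the image (subtracting a Gaussian background with a
15 px kernel, much wider than a stripe), denoises with a 1 px Gaussian,
thresholds globally (Otsu by default; fixed thresholds supported), labels
connected components, and discards components under `min_area_px`.

Per-filament metrics come from the second central moments of the pixel set
(with the 1/12 per-pixel integration term): the eigen-decomposition gives
the equivalent ellipse, whose full axis lengths are
$\lambda = 4\sqrt{\text{eigenvalue}}$ pixels — for a solid ellipse this
returns exactly the programmed axes. The orientation is the major
eigenvector's angle from the image vertical, clockwise-positive, in
[−90, 90); it is reported missing for isotropic components where the
direction is meaningless. $\lambda_2$ is floored at one pixel so
single-row components keep a positive width.

The striation repeat $d$ is measured center-to-center between a filament
and its nearest neighbor **along the string direction** — perpendicular to
the filament's major axis, since Z-disc stripes stack side-by-side along
the myofibril. (A search along the major axis would contradict the
geometry that lets neighboring stripes stay disjoint whenever their
spacing exceeds the stripe thickness $\lambda_2$.) The search is limited
to an angular cone (default half-angle 30°) and a distance cap (default
3 μm, above the ~1.8–2 μm physiological repeat), and each unordered pair
is recorded once.

The generator renders each filament as a logistic-edged ellipse (edge
0.75 px) so half-maximum thresholding recovers the programmed ellipse;
defaults $\lambda_1 = 2.0$ μm, $\lambda_2 = 0.6$ μm, $d = 1.8$ μm at
0.1625 μm/px (a 6.5 μm camera pixel through a 40× objective) are typical
cardiomyocyte striation scales. With the filament amplitude at 0.6
intensity units, SNR is defined as amplitude/noise SD; recovery suites run
at SNR 5 (noise 0.12) and require exact counts within 2%, spacing within
5%, and rotation equivariance of the recovered field orientation within 2°
under literal image rotation. Per-filament orientations of *independently*
generated noisy images scatter by a couple of degrees at SNR 5 — that is
estimator noise, not an equivariance failure, and the per-filament 2°
bound is asserted on noiseless images.

Flow-cytometry fluorescence is standardized by an affine least-squares fit
of rainbow-bead reference MEFL values against measured bead peak
intensities; the fitted map converts arbitrary units to MEFL and removes
day-to-day instrument drift. Gating happens upstream; this package only
consumes exported intensity tables.

## Statistical primitives

All group comparisons use Welch's unpaired two-tailed t test
(Welch–Satterthwaite degrees of freedom); goodness of fit uses the
asymptotic $\chi^2$; variant enrichment uses the exact binomial upper tail
(one-sided by default because the enrichment claim is directional, with a
capped two-sided option); multiple testing uses Benjamini–Hochberg within
one call's family. Calibration suites check type-I error at
$\alpha = 0.05$ over $10^4$ null simulations (±0.7% for Welch, ±1% for
$\chi^2$) and BH against brute-force step-up enumeration.

## Numerical and design choices

* Count noise is negative-binomial parameterized by mean and dispersion
  $\alpha$ (variance $\mu + \alpha\mu^2$); the assays' papers do not state
  a count model, and this is the standard sequencing choice.
* Generators are deterministic in their seed; identical arguments and seed
  reproduce outputs bit-for-bit.
* Degenerate inputs fail loudly (empty designs, zero-variance Welch input,
  single-category $\chi^2$, beads with fewer than two peaks) or propagate
  as flagged missing values (zero-DNA ratio cells, zero-depth SNPs,
  boundary-peak frames, isotropic orientations) — never as silent zeros.
* Test problem sizes (e.g. 20-seed recovery runs, 200-seed null suites,
  depth $10^3$–$10^4$, 24-filament fields, 30–60-frame stacks) were chosen
  as the smallest sizes at which the Monte-Carlo tolerances above are
  meaningful, keeping the whole suite under a minute.

## What the synthetic data does and does not show

The generators reproduce the statistical structure each estimator assumes:
overdispersed counts over the library/well layout, binomial allele
sampling at specified ratios, smooth caps with programmed subpixel motion,
and striation fields with known geometry. They do not emulate barcode
sequencing errors, alignment artifacts, reference-mapping bias toward one
strain's allele, optical aberrations, uneven illumination beyond a smooth
background, touching or curved filaments, or out-of-plane pillar motion.
Passing recovery tests therefore demonstrates correctness of the
estimators under their stated models, not robustness to every failure mode
of real instruments; the QC rules (representation filter, WT replicate
rule, boundary-peak flags, area filters) are the pipeline's defenses for
real data and are exercised on constructed edge cases.

## A worked example

```{r demo}
res <- run_demo(seed = 5)
res$manifest$summary
```

The demo simulates all stages end to end: the MPRA scan localizes the
depressed constructs, the het-group allelic ratio sits near the simulated
0.5 with a cis-consistent Welch test, the tracked 1 μm twitch converts to
~2.7 μN peak force, and the filament field returns its programmed count
and spacing.
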