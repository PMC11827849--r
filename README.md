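# titinreg

Quantitative analysis of the assays used to characterize cardiac enhancer
elements of the titin (*TTN*) gene — the sarcomere protein whose truncating
variants are the most common genetic cause of dilated cardiomyopathy. The
package is aimed at groups dissecting noncoding regulatory elements in
cardiomyocytes who need the downstream quantification, not the wet lab: it
covers reporter-assay activity estimation, allele-specific expression,
engineered-tissue contractility, and sarcomere image metrology, each with a
seeded synthetic-data generator for validation.

## What it computes

* **MPRA quantification** — construct activity as the normalized
  mRNA/DNA barcode ratio, `a_cr = CPM_RNA(c,r) / CPM_DNA(c,r)`, over a
  3-library × 4-well replicate layout; QC exclusions (DNA CPM < 100;
  technical replicates whose wild-type activity deviates ≥ 1 SD from the
  library mean); per-position saturation-mutagenesis effect maps; Welch t
  tests vs wild type with Benjamini–Hochberg adjustment.
  (`mpra_quantify`, `mutagenesis_scan`, `test_vs_wt`)
* **Allele-specific expression** — per-sample mutant-linked/WT-linked
  ratio from strain-distinguishing SNP counts (pooled or mean-of-SNPs),
  Welch cis/trans testing between genotype groups, ΔΔCt qPCR folds
  (`fold = 2^-ΔΔCt`), and Mendelian χ² genotype-ratio tests.
  (`allelic_ratio`, `cis_trans_test`, `ddct`, `mendelian_test`)
* **Micropillar contractility** — two-stage cap tracking (integer-pixel
  normalized cross-correlation, then per-axis parabolic subpixel
  refinement), deflection along the inter-pillar axis, twitch force
  `F = k · d` with k = 2.68 μN/μm, stress `F / area`, and echocardiographic
  fractional shortening `(LVEDD − LVESD)/LVEDD × 100%`.
  (`detect_pillars`, `track_pillars`, `twitch_force`,
  `fractional_shortening`)
* **Sarcomere metrology** — filament segmentation (background correction,
  Otsu threshold, connected components), equivalent-ellipse axes
  `λ = 4√eigenvalue` of the pixel second moments, orientation from
  vertical, center-to-center striation spacing d along strings, per-well
  count comparisons, and rainbow-bead AU→MEFL calibration.
  (`segment_filaments`, `filament_metrics`, `filament_spacing`,
  `mefl_calibrate`)
* **Statistics** — Welch t, χ² goodness of fit, exact binomial enrichment,
  Benjamini–Hochberg adjustment. (`welch_t`, `chi2_gof`,
  `binomial_enrichment`, `bh_adjust`)
* **Synthetic data** — seeded generators with ground-truth records for
  every stage. (`sim_mpra_counts`, `sim_ase_counts`, `sim_pillar_stack`,
  `sim_sarcomere_image`, `sim_bead_table`)

## Worked example

```r
library(titinreg)

# simulate a hybrid-background ASE experiment where the enhancer-deleted
# allele transcribes at half the wild-type allele's rate
sim <- sim_ase_counts(n_per_genotype = 5, true_ratio = 0.5, n_snps = 10,
                      depth_per_snp = 1e4, dispersion = 0.05, seed = 2)
r <- allelic_ratio(sim$counts)
aggregate(ratio ~ genotype, r, mean)
#>   genotype     ratio
#> 1      het 0.5429938
#> 2       wt 0.9933128

cis_trans_test(r$ratio[r$genotype == "wt"],
               r$ratio[r$genotype == "het"])[, c("p_value", "cis_consistent")]
#>        p_value cis_consistent
#> 1 8.300541e-05           TRUE
```

The wild-type-genotype animals sit at a ratio of ~1 (no imbalance), the
heterozygotes at ~0.5: only the allele carrying the deletion lost
expression, the signature of a *cis*-acting element, and the Welch test
confirms the group difference.

```r
# a programmed 1 um twitch tracked back to force
sim <- sim_pillar_stack(amplitude_um = 1, noise_sd = 0, n_frames = 60, seed = 1)
tpl <- detect_pillars(sim$stack[[1]], rbind(c(45, 60), c(115, 60)))
force <- twitch_force(track_pillars(sim$stack, tpl), tissue_geometry())
force$max_force_uN
#> [1] 2.650291
```

A 1.0 μm peak deflection at the device spring constant of 2.68 μN/μm is
recovered as ~2.65 μN peak twitch force (tracking is subpixel-accurate;
the ~1% shortfall is the robust resting-position baseline).

`run_demo(out_dir, seed)` runs all four stages end to end and writes TSV
outputs plus a YAML manifest.

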