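#' Run the end-to-end synthetic demonstration
#'
#' Simulates all four assays with one master seed, runs each analysis stage
#' on its simulated input, and writes the stage outputs plus a YAML run
#' manifest (parameters, seed, package version) to `out_dir`. Outputs are
#' deterministic given the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @return Invisibly, a list with each stage's in-memory results and the
#'   manifest.
#' @export
run_demo <- function(out_dir = tempfile("titinreg_demo_"), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # MPRA: wild type, TF-site deletions and point mutations over an element
  design <- data.frame(
    construct_id = c("WT", sprintf("del_%02d", 1:6), sprintf("pm_%02d", 1:6)),
    category = c("wt", rep("tf_deletion", 6), rep("point_mutation", 6)),
    start = c(NA, seq(101, 151, by = 10), seq(101, 151, by = 10)),
    end = c(NA, seq(110, 160, by = 10), seq(105, 155, by = 10)),
    activity = c(1, 0.4, 1, 1, 0.6, 1, 1, 0.5, 1, 1, 0.7, 1, 1))
  mpra_sim <- sim_mpra_counts(design, mean_depth = 1000, dispersion = 0.05,
                              seed = seed)
  act <- mpra_quantify(mpra_sim$dna, mpra_sim$rna, mpra_sim$replicate_info)
  scan <- mutagenesis_scan(act, design)
  tests <- test_vs_wt(act, design)
  utils::write.table(construct_activity(act),
                     file.path(out_dir, "mpra_activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan, file.path(out_dir, "mpra_effect_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tests, file.path(out_dir, "mpra_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ASE: heterozygous deletion halves the mutant-linked allele
  ase_sim <- sim_ase_counts(n_per_genotype = 5, true_ratio = 0.5,
                            n_snps = 10, depth_per_snp = 1e4,
                            dispersion = 0.05, seed = seed + 1)
  ratios <- allelic_ratio(ase_sim$counts)
  ct_test <- cis_trans_test(ratios$ratio[ratios$genotype == "wt"],
                            ratios$ratio[ratios$genotype == "het"])
  utils::write.table(ratios, file.path(out_dir, "ase_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # contractility: 1 um twitches at 1 Hz
  pil_sim <- sim_pillar_stack(amplitude_um = 1, noise_sd = 0.01,
                              n_frames = 60, seed = seed + 2)
  centers <- pil_sim$truth$parameters$pillar_centers
  tpl <- detect_pillars(pil_sim$stack[[1]], centers)
  trk <- track_pillars(pil_sim$stack, tpl)
  force <- twitch_force(trk, tissue_geometry())
  utils::write.table(force$trace, file.path(out_dir, "pillar_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # sarcomere metrology
  sarc_sim <- sim_sarcomere_image(seed = seed + 3)
  fs <- filament_metrics(segment_filaments(sarc_sim$image,
                                           um_per_px = 0.1625))
  spacing <- filament_spacing(fs)
  utils::write.table(fs$filaments, file.path(out_dir, "filaments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # bead calibration
  bead_sim <- sim_bead_table(slope = 10, intercept = 50, noise_sd = 5,
                             seed = seed + 4)
  cal <- mefl_calibrate(bead_sim$beads$au, bead_sim$beads$mefl)

  manifest <- list(
    package = "titinreg",
    version = as.character(utils::packageVersion("titinreg")),
    seed = seed,
    stages = c("mpra", "ase", "pillar", "sarcomere", "beads"),
    summary = list(
      mpra_constructs = nrow(design),
      ase_het_mean_ratio = mean(ratios$ratio[ratios$genotype == "het"],
                                na.rm = TRUE),
      ase_cis_p = ct_test$p_value,
      max_force_uN = force$max_force_uN,
      n_filaments = length(fs$pixels),
      mean_spacing_um = spacing$mean_d_um,
      mefl_slope = cal$slope))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(mpra = list(activity = act, scan = scan, tests = tests),
                 ase = list(ratios = ratios, cis_trans = ct_test),
                 pillar = force, sarcomere = list(filaments = fs,
                                                  spacing = spacing),
                 beads = cal, manifest = manifest, out_dir = out_dir))
}
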