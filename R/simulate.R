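# Seeded generators emulating each assay's data-generating process, each
# returning its inputs together with a `sim_truth` record of the latent
# quantities so that downstream estimators can be tested for recovery.

sim_truth <- function(stage, parameters, per_item_truth) {
  structure(list(stage = stage, parameters = parameters,
                 per_item_truth = per_item_truth),
            class = "sim_truth")
}

# negative binomial with variance mu + dispersion * mu^2; dispersion 0 -> Poisson
rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate barcoded MPRA count tables
#'
#' Generates paired DNA and RNA construct-by-replicate count matrices for a
#' pooled reporter assay in which each construct is carried by several
#' plasmid libraries, each library transfected into several wells. Library
#' preparation imposes a construct-by-library abundance (lognormal around
#' `mean_depth`); DNA counts are negative-binomial around that abundance and
#' RNA counts are negative-binomial around abundance times the construct's
#' true transcriptional activity, so the expected mRNA/DNA ratio of a
#' construct equals its activity.
#'
#' @param design Data frame with columns `construct_id` and `activity`
#'   (true activity, >= 0); an optional `category` column is carried through.
#' @param n_libraries Number of independent plasmid libraries (default 3).
#' @param n_wells Number of transfected wells per library (default 4).
#' @param mean_depth Expected reads per construct per replicate.
#' @param dispersion Negative-binomial overdispersion alpha
#'   (variance = mu + alpha mu^2); 0 gives Poisson counts.
#' @param library_sd SD of the lognormal construct-by-library abundance
#'   effect (log scale).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   output exactly.
#' @return A list with `dna` and `rna` count matrices (constructs x
#'   replicates, replicate columns named `L<lib>_W<well>`), `replicate_info`
#'   (replicate, library, well) and `truth` (a `sim_truth` whose per-item
#'   table stores each construct's activity).
#' @examples
#' d <- data.frame(construct_id = c("WT", "m1"), activity = c(1, 0.4))
#' sim <- sim_mpra_counts(d, mean_depth = 500, seed = 1)
#' dim(sim$dna)
#' @export
sim_mpra_counts <- function(design, n_libraries = 3, n_wells = 4,
                            mean_depth = 1000, dispersion = 0.1,
                            library_sd = 0.25, seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("construct_id", "activity") %in% names(design)))
  if (nrow(design) == 0) stop("empty design")
  if (anyDuplicated(design$construct_id)) stop("duplicate construct_id")
  if (any(design$activity < 0)) stop("activities must be >= 0")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (n_libraries < 1 || n_wells < 1) stop("need >= 1 library and >= 1 well")
  if (dispersion < 0) stop("dispersion must be >= 0")

  set.seed(seed)
  nc <- nrow(design)
  reps <- expand.grid(well = seq_len(n_wells), library = seq_len(n_libraries))
  rep_ids <- sprintf("L%d_W%d", reps$library, reps$well)

  # construct x library abundance, mean mean_depth
  ab <- matrix(mean_depth *
                 exp(stats::rnorm(nc * n_libraries, 0, library_sd) -
                       library_sd^2 / 2),
               nrow = nc, ncol = n_libraries)

  dna <- matrix(0L, nc, length(rep_ids),
                dimnames = list(design$construct_id, rep_ids))
  rna <- dna
  for (r in seq_along(rep_ids)) {
    mu <- ab[, reps$library[r]]
    dna[, r] <- rnbinom_disp(nc, mu, dispersion)
    rna[, r] <- rnbinom_disp(nc, mu * design$activity, dispersion)
  }

  truth <- sim_truth(
    stage = "mpra",
    parameters = list(n_libraries = n_libraries, n_wells = n_wells,
                      mean_depth = mean_depth, dispersion = dispersion,
                      library_sd = library_sd, seed = seed),
    per_item_truth = data.frame(construct_id = design$construct_id,
                                activity = design$activity,
                                stringsAsFactors = FALSE))
  list(dna = dna, rna = rna,
       replicate_info = data.frame(replicate = rep_ids,
                                   library = reps$library, well = reps$well,
                                   stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate allele-specific expression counts
#'
#' Generates per-SNP counts of the mutant-linked and wild-type-linked alleles
#' for hybrid-background animals. Heterozygous-enhancer samples transcribe
#' the mutant-linked allele at `true_ratio` times the wild-type allele's
#' rate; wild-type-genotype samples transcribe both equally. At each SNP the
#' mutant-allele count is binomial with success probability
#' `ratio / (1 + ratio)`; with `dispersion > 0` the per-SNP probability is
#' drawn from a beta distribution with that mean and concentration
#' `1 / dispersion` (beta-binomial overdispersion across SNPs).
#'
#' @param n_per_genotype Samples per genotype group (wt and het).
#' @param true_ratio Mutant-linked / wild-type-linked transcription ratio in
#'   het samples (>= 0); 1 means no cis effect.
#' @param n_snps Number of strain-distinguishing SNPs per sample.
#' @param depth_per_snp Total read depth at each SNP (scalar or length
#'   `n_snps`; a zero-depth SNP is emitted with zero counts).
#' @param dispersion Beta overdispersion of the per-SNP allelic proportion;
#'   0 gives pure binomial sampling.
#' @param seed Integer seed.
#' @return A list with `counts` (long-format data frame: `sample_id`,
#'   `genotype`, `snp_id`, `allele` in mut_linked/wt_linked, `count`) and
#'   `truth` (per-sample true ratio).
#' @examples
#' sim <- sim_ase_counts(n_per_genotype = 2, true_ratio = 0.5,
#'                       n_snps = 3, depth_per_snp = 1000, seed = 1)
#' head(sim$counts)
#' @export
sim_ase_counts <- function(n_per_genotype = 5, true_ratio = 1, n_snps = 10,
                           depth_per_snp = 1e4, dispersion = 0, seed = 1) {
  if (true_ratio < 0) stop("true_ratio must be >= 0")
  if (n_snps < 1) stop("need at least one SNP")
  if (any(depth_per_snp < 0)) stop("negative depth")
  if (dispersion < 0) stop("dispersion must be >= 0")
  depth <- rep_len(depth_per_snp, n_snps)

  set.seed(seed)
  snp_ids <- sprintf("snp%02d", seq_len(n_snps))
  rows <- list()
  for (geno in c("wt", "het")) {
    ratio <- if (geno == "wt") 1 else true_ratio
    p <- ratio / (1 + ratio)
    for (s in seq_len(n_per_genotype)) {
      sid <- sprintf("%s_%d", geno, s)
      p_snp <- if (dispersion > 0) {
        conc <- 1 / dispersion
        stats::rbeta(n_snps, p * conc, (1 - p) * conc)
      } else rep(p, n_snps)
      mut <- stats::rbinom(n_snps, depth, p_snp)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, genotype = geno,
        snp_id = rep(snp_ids, 2),
        allele = rep(c("mut_linked", "wt_linked"), each = n_snps),
        count = c(mut, depth - mut), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)

  samples <- unique(counts[, c("sample_id", "genotype")])
  truth <- sim_truth(
    stage = "ase",
    parameters = list(n_per_genotype = n_per_genotype,
                      true_ratio = true_ratio, n_snps = n_snps,
                      depth_per_snp = depth_per_snp,
                      dispersion = dispersion, seed = seed),
    per_item_truth = data.frame(
      sample_id = samples$sample_id, genotype = samples$genotype,
      true_ratio = ifelse(samples$genotype == "wt", 1, true_ratio),
      stringsAsFactors = FALSE))
  list(counts = counts, truth = truth)
}

# raised-cosine twitch waveform, 0 at rest, 1 at mid-twitch
twitch_waveform <- function(frame, period_frames) {
  phase <- ((frame - 1) %% period_frames) / period_frames
  0.5 * (1 - cos(2 * pi * phase))
}

render_cap <- function(img, cx, cy, radius, intensity, edge_px) {
  # logistic-edged disk: smooth bright cap with subpixel-defined center
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(radius + 6 * edge_px)
  xr <- max(1, floor(cx - half)):min(w, ceiling(cx + half))
  yr <- max(1, floor(cy - half)):min(h, ceiling(cy + half))
  r <- sqrt(outer((yr - cy)^2, (xr - cx)^2, "+"))
  img[yr, xr] <- img[yr, xr] + intensity / (1 + exp((r - radius) / edge_px))
  img
}

#' Simulate a micropillar time-lapse stack
#'
#' Renders a time-lapse of two bright pillar caps on a dark background; one
#' cap translates along the inter-pillar axis following a raised-cosine
#' twitch (peak displacement `amplitude_um`, one twitch per `period_frames`
#' frames, i.e. 1 Hz pacing at 30 frames/s with the default period of 30).
#' Caps are radially symmetric disks with a smooth logistic edge so the true
#' subpixel center is well defined; the truth table stores the exact center
#' and programmed deflection of every frame.
#'
#' @param frame_size `c(width, height)` in pixels.
#' @param pillar_centers 2x2 matrix of (x, y) centers; row 2 is the moving
#'   pillar, which moves toward pillar 1.
#' @param cap_radius Cap radius in pixels.
#' @param amplitude_um Peak deflection in micrometers (>= 0).
#' @param period_frames Frames per twitch period.
#' @param n_frames Number of frames.
#' @param um_per_px Micrometers per pixel (default 0.1625, a 6.5 um camera
#'   pixel through a 40x objective).
#' @param noise_sd Gaussian intensity noise SD (image intensities are in
#'   \[0, 1\]; the cap amplitude is 0.7 over a 0.08 background).
#' @param edge_px Softness of the cap edge in pixels.
#' @param seed Integer seed (used only for noise).
#' @return A list with `stack` (list of numeric matrices, rows = y), and
#'   `truth` whose per-item table has one row per frame with the moving
#'   cap's exact center and deflection in um.
#' @examples
#' sim <- sim_pillar_stack(n_frames = 5, amplitude_um = 0.5, seed = 1)
#' length(sim$stack)
#' @export
sim_pillar_stack <- function(frame_size = c(160, 120),
                             pillar_centers = rbind(c(45, 60), c(115, 60)),
                             cap_radius = 9, amplitude_um = 1,
                             period_frames = 30, n_frames = 60,
                             um_per_px = 0.1625, noise_sd = 0,
                             edge_px = 2, seed = 1) {
  if (amplitude_um < 0) stop("amplitude_um must be >= 0")
  w <- frame_size[1]; h <- frame_size[2]
  pillar_centers <- as.matrix(pillar_centers)
  stopifnot(nrow(pillar_centers) == 2, ncol(pillar_centers) == 2)

  axis_vec <- pillar_centers[1, ] - pillar_centers[2, ]
  axis_unit <- axis_vec / sqrt(sum(axis_vec^2))
  amp_px <- amplitude_um / um_per_px
  margin <- cap_radius + 6 * edge_px
  extremes <- rbind(pillar_centers[1, ],
                    pillar_centers[2, ],
                    pillar_centers[2, ] + axis_unit * amp_px)
  if (any(extremes[, 1] < 1 + margin) || any(extremes[, 1] > w - margin) ||
      any(extremes[, 2] < 1 + margin) || any(extremes[, 2] > h - margin)) {
    stop("pillar cap leaves the frame at maximum deflection")
  }

  set.seed(seed)
  background <- 0.08
  cap_intensity <- 0.7
  defl_um <- amplitude_um * twitch_waveform(seq_len(n_frames), period_frames)
  stack <- vector("list", n_frames)
  centers <- matrix(NA_real_, n_frames, 2)
  for (f in seq_len(n_frames)) {
    img <- matrix(background, h, w)
    img <- render_cap(img, pillar_centers[1, 1], pillar_centers[1, 2],
                      cap_radius, cap_intensity, edge_px)
    ctr <- pillar_centers[2, ] + axis_unit * defl_um[f] / um_per_px
    centers[f, ] <- ctr
    img <- render_cap(img, ctr[1], ctr[2], cap_radius, cap_intensity, edge_px)
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    }
    stack[[f]] <- pmin(pmax(img, 0), 1)
  }

  truth <- sim_truth(
    stage = "pillar",
    parameters = list(frame_size = frame_size,
                      pillar_centers = pillar_centers,
                      cap_radius = cap_radius, amplitude_um = amplitude_um,
                      period_frames = period_frames, n_frames = n_frames,
                      um_per_px = um_per_px, noise_sd = noise_sd,
                      edge_px = edge_px, seed = seed),
    per_item_truth = data.frame(frame = seq_len(n_frames),
                                x = centers[, 1], y = centers[, 2],
                                deflection_um = defl_um))
  list(stack = stack, truth = truth)
}

#' Simulate a striated sarcomere image
#'
#' Renders fields of titin-GFP-like striations: `n_strings` parallel
#' myofibril strings, each a run of `filaments_per_string` elliptical
#' filaments (Z-line stripes) whose major axis `lambda1_um` lies
#' perpendicular to the string direction and whose minor axis is
#' `lambda2_um`; successive filament centers along a string are
#' `spacing_um` apart (the sarcomere repeat d). `angle_deg` is the
#' orientation of the filament major axes, degrees clockwise from the image
#' vertical axis in \[-90, 90); the strings therefore run perpendicular to
#' it. Filaments have a smooth logistic edge so half-maximum thresholding
#' recovers the programmed ellipse.
#'
#' @param n_strings Number of filament strings (0 gives a blank image and
#'   empty truth).
#' @param filaments_per_string Filaments per string.
#' @param lambda1_um,lambda2_um Full major / minor axis lengths, um.
#' @param spacing_um Center-to-center distance along the string, um; must
#'   exceed `lambda2_um` so neighbors do not merge.
#' @param angle_deg Filament major-axis orientation, degrees from vertical.
#' @param um_per_px Micrometers per pixel.
#' @param image_size `c(width, height)` pixels.
#' @param string_gap_um Center-to-center distance between adjacent strings;
#'   must exceed `lambda1_um`.
#' @param background,noise_sd Background level and Gaussian noise SD
#'   (intensities in \[0, 1\]; filament amplitude 0.6).
#' @param seed Integer seed (used only for noise).
#' @return A list with `image` (numeric matrix) and `truth` (per-filament
#'   centroid, axes, angle and string id).
#' @examples
#' sim <- sim_sarcomere_image(n_strings = 2, filaments_per_string = 3,
#'                            seed = 1)
#' dim(sim$image)
#' @export
sim_sarcomere_image <- function(n_strings = 4, filaments_per_string = 6,
                                lambda1_um = 2.0, lambda2_um = 0.6,
                                spacing_um = 1.8, angle_deg = 0,
                                um_per_px = 0.1625,
                                image_size = c(256, 256),
                                string_gap_um = 4,
                                background = 0.05, noise_sd = 0.02,
                                seed = 1) {
  if (n_strings > 0) {
    if (spacing_um <= lambda2_um) {
      stop("spacing_um must exceed lambda2_um (filaments would merge)")
    }
    if (string_gap_um <= lambda1_um) {
      stop("string_gap_um must exceed lambda1_um (strings would merge)")
    }
    if (lambda1_um < lambda2_um) stop("lambda1_um must be >= lambda2_um")
  }
  w <- image_size[1]; h <- image_size[2]
  set.seed(seed)
  img <- matrix(background, h, w)

  theta <- angle_deg * pi / 180
  major <- c(sin(theta), cos(theta))         # filament long axis (x, y)
  string_dir <- c(cos(theta), -sin(theta))   # perpendicular: string axis

  a <- lambda1_um / 2 / um_per_px
  b <- lambda2_um / 2 / um_per_px
  spacing_px <- spacing_um / um_per_px
  gap_px <- string_gap_um / um_per_px
  center <- c((w + 1) / 2, (h + 1) / 2)
  amp <- 0.6
  edge_px <- 0.75

  truth_rows <- list()
  fid <- 0L
  for (k in seq_len(n_strings)) {
    off_k <- (k - (n_strings + 1) / 2) * gap_px
    for (m in seq_len(filaments_per_string)) {
      off_m <- (m - (filaments_per_string + 1) / 2) * spacing_px
      ctr <- center + major * off_k + string_dir * off_m
      half <- a + 6 * edge_px
      if (ctr[1] < 1 + half || ctr[1] > w - half ||
          ctr[2] < 1 + half || ctr[2] > h - half) {
        stop("filament falls outside the image; enlarge image_size")
      }
      xr <- floor(ctr[1] - half):ceiling(ctr[1] + half)
      yr <- floor(ctr[2] - half):ceiling(ctr[2] + half)
      dx <- outer(rep(1, length(yr)), xr - ctr[1])
      dy <- outer(yr - ctr[2], rep(1, length(xr)))
      u <- dx * major[1] + dy * major[2]
      v <- dx * string_dir[1] + dy * string_dir[2]
      rho <- sqrt((u / a)^2 + (v / b)^2)
      # signed distance to the ellipse boundary (gradient-normalized, so the
      # edge softness is ~edge_px all around); half-max lies on the ellipse
      denom <- sqrt((u / a^2)^2 + (v / b^2)^2)
      denom[denom < 1e-9] <- 1e-9
      dist <- ifelse(rho >= 0.5, (rho - 1) * rho / denom, (rho - 1) * b)
      img[yr, xr] <- img[yr, xr] + amp / (1 + exp(dist / edge_px))
      fid <- fid + 1L
      truth_rows[[fid]] <- data.frame(
        filament_id = fid, string = k, x = ctr[1], y = ctr[2],
        lambda1_um = lambda1_um, lambda2_um = lambda2_um,
        angle_deg = angle_deg)
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  per_item <- if (fid > 0) do.call(rbind, truth_rows) else
    data.frame(filament_id = integer(), string = integer(),
               x = numeric(), y = numeric(), lambda1_um = numeric(),
               lambda2_um = numeric(), angle_deg = numeric())
  truth <- sim_truth(
    stage = "sarcomere",
    parameters = list(n_strings = n_strings,
                      filaments_per_string = filaments_per_string,
                      lambda1_um = lambda1_um, lambda2_um = lambda2_um,
                      spacing_um = spacing_um, angle_deg = angle_deg,
                      um_per_px = um_per_px, image_size = image_size,
                      string_gap_um = string_gap_um,
                      background = background, noise_sd = noise_sd,
                      seed = seed),
    per_item_truth = per_item)
  list(image = img, truth = truth)
}

#' Simulate a rainbow-bead calibration table
#'
#' Generates the peak table of a rainbow calibration particle run: bead peak
#' intensities in arbitrary units (AU, log-spaced) and the manufacturer's
#' reference MEFL values, related by the affine map
#' `MEFL = slope * (AU + noise) + intercept`.
#'
#' @param slope True MEFL per AU (> 0).
#' @param intercept True MEFL offset.
#' @param n_peaks Number of bead peaks (>= 2).
#' @param noise_sd Gaussian AU measurement noise SD.
#' @param au_range Range of true peak AU values (log-spaced within).
#' @param seed Integer seed.
#' @return A list with `beads` (data frame: `peak`, `au`, `mefl`) and
#'   `truth` (per-peak true AU).
#' @examples
#' sim_bead_table(slope = 10, n_peaks = 4, seed = 1)$beads
#' @export
sim_bead_table <- function(slope = 10, intercept = 0, n_peaks = 8,
                           noise_sd = 0, au_range = c(50, 50000), seed = 1) {
  if (n_peaks < 2) stop("need at least 2 bead peaks")
  set.seed(seed)
  au_true <- exp(seq(log(au_range[1]), log(au_range[2]),
                     length.out = n_peaks))
  mefl <- slope * au_true + intercept
  au_obs <- au_true + stats::rnorm(n_peaks, 0, noise_sd)
  beads <- data.frame(peak = seq_len(n_peaks), au = au_obs, mefl = mefl)
  truth <- sim_truth(
    stage = "beads",
    parameters = list(slope = slope, intercept = intercept,
                      n_peaks = n_peaks, noise_sd = noise_sd,
                      au_range = au_range, seed = seed),
    per_item_truth = data.frame(peak = seq_len(n_peaks), au_true = au_true))
  list(beads = beads, truth = truth)
}
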