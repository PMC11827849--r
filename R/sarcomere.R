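# Sarcomere metrology: filament segmentation from fluorescence images,
# second-moment axis/orientation metrics, center-to-center spacing along
# filament strings, per-well count comparisons, and flow-cytometry
# AU -> MEFL bead calibration.

#' Segment filaments from a fluorescence image
#'
#' Illumination-corrects the image by subtracting a large-kernel Gaussian
#' background estimate, thresholds it globally (Otsu by default), labels
#' connected components and discards those below `min_area_px`.
#'
#' @param image Grayscale numeric matrix (rows = y), intensities in \[0, 1\].
#' @param um_per_px Micrometers per pixel.
#' @param threshold_policy `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold on the corrected image when
#'   `threshold_policy = "fixed"`.
#' @param min_area_px Minimum component area in pixels (default 12).
#' @param bg_sigma_px Gaussian sigma of the background estimate; must be
#'   much larger than the filament width (default 15 px).
#' @param smooth_sigma_px Gaussian sigma of the denoising pre-smooth,
#'   well below the filament width (default 1 px; 0 disables).
#' @return A list of class `filament_set`: `pixels` (list of data frames
#'   with `x`, `y` per filament), `um_per_px`, `threshold`, `image_dim`.
#'   Metrics are filled in by [filament_metrics()].
#' @examples
#' sim <- sim_sarcomere_image(n_strings = 2, filaments_per_string = 3,
#'                            seed = 1)
#' fs <- segment_filaments(sim$image, um_per_px = 0.1625)
#' length(fs$pixels)
#' @export
segment_filaments <- function(image, um_per_px,
                              threshold_policy = c("otsu", "fixed"),
                              fixed_value = NULL, min_area_px = 12,
                              bg_sigma_px = 15, smooth_sigma_px = 1) {
  threshold_policy <- match.arg(threshold_policy)
  if (length(image) == 0) stop("empty image")
  h <- nrow(image); w <- ncol(image)

  if (smooth_sigma_px > 0) {
    image <- EBImage::gblur(image, sigma = smooth_sigma_px)
  }
  sigma <- min(bg_sigma_px, floor((min(h, w) - 1) / 8))
  bg <- EBImage::gblur(image, sigma = sigma)
  corrected <- pmax(image - bg, 0)

  if (threshold_policy == "otsu") {
    if (max(corrected) - min(corrected) < 1e-6) {
      warning("uniform image; no filaments segmented")
      return(empty_filament_set(um_per_px, NA_real_, c(h, w)))
    }
    thr <- EBImage::otsu(EBImage::Image(corrected), range = range(corrected))
  } else {
    if (is.null(fixed_value)) stop("fixed threshold requires fixed_value")
    thr <- fixed_value
  }

  labels <- EBImage::bwlabel(corrected > thr)
  n <- max(labels)
  if (n == 0) return(empty_filament_set(um_per_px, thr, c(h, w)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  ys <- ((idx - 1) %% h) + 1
  xs <- ((idx - 1) %/% h) + 1
  pix <- split(data.frame(x = xs, y = ys), lab)
  pix <- pix[vapply(pix, nrow, 0L) >= min_area_px]
  names(pix) <- NULL
  structure(list(pixels = pix, um_per_px = um_per_px,
                 threshold = as.numeric(thr), image_dim = c(h, w),
                 filaments = NULL),
            class = "filament_set")
}

empty_filament_set <- function(um_per_px, thr, dims) {
  structure(list(pixels = list(), um_per_px = um_per_px,
                 threshold = thr, image_dim = dims, filaments = NULL),
            class = "filament_set")
}

#' @export
print.filament_set <- function(x, ...) {
  cat(sprintf("Filament set: %d filaments (threshold %.4g, %.4g um/px)\n",
              length(x$pixels), x$threshold, x$um_per_px))
  invisible(x)
}

#' Compute per-filament axis, area and orientation metrics
#'
#' Fills in the per-filament metrics from the second central moments of each
#' pixel set: the eigen-decomposition of the 2x2 moment matrix gives the
#' equivalent ellipse, whose full axis lengths are
#' `lambda = 4 * sqrt(eigenvalue)` pixels (a solid ellipse of semi-axis a
#' has second moment a^2/4 along that axis). The orientation is the major
#' eigenvector's angle from the image vertical axis, degrees clockwise, in
#' \[-90, 90); it is undefined (NA) for isotropic components. Area is the
#' pixel count scaled by `um_per_px^2`; `lambda2` is floored at one pixel so
#' degenerate single-row components keep a positive width.
#'
#' @param fs A `filament_set` from [segment_filaments()].
#' @return The `filament_set` with a `filaments` data frame: `filament_id`,
#'   `x`, `y` (centroid), `lambda1_um`, `lambda2_um`, `area_um2`,
#'   `angle_deg`, `n_px`.
#' @export
filament_metrics <- function(fs) {
  stopifnot(inherits(fs, "filament_set"))
  upp <- fs$um_per_px
  rows <- lapply(seq_along(fs$pixels), function(i) {
    p <- fs$pixels[[i]]
    n <- nrow(p)
    mx <- mean(p$x); my <- mean(p$y)
    # second central moments with the 1/12 per-pixel integration term
    cxx <- mean((p$x - mx)^2) + 1 / 12
    cyy <- mean((p$y - my)^2) + 1 / 12
    cxy <- mean((p$x - mx) * (p$y - my))
    e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
    l1 <- 4 * sqrt(e$values[1]) * upp
    l2 <- max(4 * sqrt(max(e$values[2], 0)) * upp, upp)
    angle <- if ((e$values[1] - e$values[2]) / e$values[1] < 1e-3) {
      NA_real_  # isotropic: orientation undefined
    } else {
      v <- e$vectors[, 1]
      a <- atan2(v[1], v[2]) * 180 / pi   # from vertical, clockwise
      ((a + 90) %% 180) - 90
    }
    data.frame(filament_id = i, x = mx, y = my,
               lambda1_um = l1, lambda2_um = l2,
               area_um2 = n * upp^2, angle_deg = angle, n_px = n)
  })
  fs$filaments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filament_id = integer(), x = numeric(), y = numeric(),
               lambda1_um = numeric(), lambda2_um = numeric(),
               area_um2 = numeric(), angle_deg = numeric(), n_px = integer())
  fs
}

#' Filament-to-filament spacing along strings
#'
#' For each filament, finds its nearest neighbor along the string direction
#' (perpendicular to the filament's major axis, since striations stack
#' side-by-side along the myofibril) within an angular cone of
#' `max_angle_diff_deg` and a distance cap `max_gap_um`; the
#' center-to-center distance d of each such unordered pair is recorded once.
#'
#' @param fs A `filament_set` with metrics (see [filament_metrics()]).
#' @param max_gap_um Maximum neighbor distance in um (default 3).
#' @param max_angle_diff_deg Half-angle of the search cone around the string
#'   direction (default 30).
#' @return A list with `records` (data frame `i`, `j`, `d_um`) and
#'   `mean_d_um` (NA when no records).
#' @export
filament_spacing <- function(fs, max_gap_um = 3, max_angle_diff_deg = 30) {
  stopifnot(inherits(fs, "filament_set"))
  f <- fs$filaments
  if (is.null(f)) stop("run filament_metrics() first")
  empty <- list(records = data.frame(i = integer(), j = integer(),
                                     d_um = numeric()),
                mean_d_um = NA_real_)
  if (nrow(f) < 2) return(empty)
  upp <- fs$um_per_px
  recs <- list()
  for (i in seq_len(nrow(f))) {
    if (is.na(f$angle_deg[i])) next
    th <- f$angle_deg[i] * pi / 180
    string_dir <- c(cos(th), -sin(th))  # perpendicular to the major axis
    dx <- f$x - f$x[i]; dy <- f$y - f$y[i]
    d_um <- sqrt(dx^2 + dy^2) * upp
    along <- abs(dx * string_dir[1] + dy * string_dir[2]) * upp
    cosang <- ifelse(d_um > 0, along / d_um, 0)
    cand <- which(seq_len(nrow(f)) != i & d_um <= max_gap_um & d_um > 0 &
                    cosang >= cos(max_angle_diff_deg * pi / 180))
    if (length(cand) == 0) next
    j <- cand[which.min(d_um[cand])]
    recs[[length(recs) + 1L]] <- data.frame(i = min(i, j), j = max(i, j),
                                            d_um = d_um[j])
  }
  if (length(recs) == 0) return(empty)
  records <- unique(do.call(rbind, recs))
  rownames(records) <- NULL
  list(records = records, mean_d_um = mean(records$d_um))
}

#' Compare per-well filament counts between groups
#'
#' Per-group mean and SD of per-well filament counts plus pairwise Welch
#' two-tailed t tests, Benjamini-Hochberg adjusted across the pairs tested
#' in the call. Groups with fewer than two wells are skipped.
#'
#' @param groups Named list: group label -> numeric vector of per-well
#'   counts.
#' @return A list with `summary` (group, mean, sd, n_wells) and
#'   `comparisons` (group1, group2, statistic, df, p_value, p_adj).
#' @export
count_and_compare <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  summary <- data.frame(
    group = names(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    n_wells = vapply(groups, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  usable <- names(groups)[vapply(groups, length, 0L) >= 2]
  comps <- list()
  if (length(usable) >= 2) {
    pairs <- utils::combn(usable, 2)
    for (k in seq_len(ncol(pairs))) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      tt <- welch_t(groups[[g1]], groups[[g2]])
      comps[[k]] <- data.frame(group1 = g1, group2 = g2,
                               statistic = tt$statistic, df = tt$df,
                               p_value = tt$p_value,
                               stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame(group1 = character(), group2 = character(),
               statistic = numeric(), df = numeric(), p_value = numeric())
  if (nrow(comparisons)) comparisons$p_adj <- bh_adjust(comparisons$p_value)
  list(summary = summary, comparisons = comparisons)
}

#' Fit and apply a bead AU -> MEFL calibration
#'
#' Least-squares affine fit of reference MEFL values against measured bead
#' peak intensities (arbitrary units), used to place fluorescence
#' measurements from different days on the standardized MEFL scale.
#'
#' @param au Measured bead peak intensities (AU), length >= 2 with positive
#'   variance.
#' @param mefl Manufacturer reference MEFL values, same length.
#' @return A list of class `mefl_calibration`: `slope`, `intercept`,
#'   `residual_sd`, `n_peaks`.
#' @examples
#' cal <- mefl_calibrate(c(100, 200, 400), c(1000, 2000, 4000))
#' mefl_apply(cal, 250)
#' @export
mefl_calibrate <- function(au, mefl) {
  if (length(au) < 2 || length(mefl) != length(au)) {
    stop("need at least 2 (AU, MEFL) bead peaks")
  }
  if (stats::var(au) == 0) stop("bead AU values have zero variance")
  fit <- stats::lm(mefl ~ au)
  n <- length(au)
  res_sd <- if (n > 2) sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else 0
  slope_se <- res_sd / sqrt(sum((au - mean(au))^2))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = res_sd, n_peaks = n,
                 slope_se = slope_se),
            class = "mefl_calibration")
}

#' @rdname mefl_calibrate
#' @param calibration A `mefl_calibration` object.
#' @param au_values AU values to convert.
#' @export
mefl_apply <- function(calibration, au_values) {
  stopifnot(inherits(calibration, "mefl_calibration"))
  calibration$slope * au_values + calibration$intercept
}
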