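# Micropillar contractility: two-stage template tracking of pillar caps
# (integer-pixel normalized cross-correlation, then per-axis parabolic
# subpixel refinement), deflection along the inter-pillar axis, and
# conversion to twitch force and stress.

#' Tissue / device geometry for force conversion
#'
#' @param spring_constant_k Pillar spring constant in uN/um (default 2.68,
#'   the measured stiffness of the devices this pipeline was written for).
#' @param cross_section_area Tissue cross-sectional area in m^2 used for
#'   stress; `NA` skips stress computation.
#' @param um_per_px Micrometers per pixel.
#' @return A list of class `tissue_geometry`.
#' @export
tissue_geometry <- function(spring_constant_k = 2.68,
                            cross_section_area = NA_real_,
                            um_per_px = 0.1625) {
  if (spring_constant_k <= 0) stop("spring constant must be positive")
  if (!is.na(cross_section_area) && cross_section_area <= 0) {
    stop("area must be positive")
  }
  structure(list(spring_constant_k = spring_constant_k,
                 cross_section_area = cross_section_area,
                 um_per_px = um_per_px),
            class = "tissue_geometry")
}

weighted_centroid <- function(img, cx, cy, radius) {
  h <- nrow(img); w <- ncol(img)
  for (i in 1:12) {
    xr <- max(1, round(cx - radius)):min(w, round(cx + radius))
    yr <- max(1, round(cy - radius)):min(h, round(cy + radius))
    patch <- img[yr, xr, drop = FALSE]
    wgt <- patch - min(patch)
    tot <- sum(wgt)
    if (tot <= 0) stop("no intensity contrast near (", cx, ", ", cy, ")")
    nx <- sum(wgt %*% xr) / tot
    ny <- sum(yr %*% wgt) / tot
    moved <- sqrt((nx - cx)^2 + (ny - cy)^2)
    cx <- nx; cy <- ny
    if (moved < 0.01) break
  }
  c(cx, cy)
}

#' Detect pillar caps and extract tracking templates
#'
#' Refines each approximate pillar-cap position to the intensity-weighted
#' centroid of its neighborhood in the reference frame and cuts a square
#' template around it for cross-correlation tracking.
#'
#' @param frame Grayscale reference frame (numeric matrix, rows = y).
#' @param approx_centers 2x2 matrix of approximate (x, y) cap centers.
#' @param template_radius Template half-width in pixels (default 12).
#' @return A list of class `pillar_templates`: per pillar the template
#'   patch, its integer center, and the subpixel reference position.
#' @export
detect_pillars <- function(frame, approx_centers, template_radius = 12) {
  approx_centers <- as.matrix(approx_centers)
  stopifnot(ncol(approx_centers) == 2)
  h <- nrow(frame); w <- ncol(frame)
  if (max(frame) - min(frame) < 1e-6) stop("frame has no contrast")
  pillars <- vector("list", nrow(approx_centers))
  for (i in seq_len(nrow(approx_centers))) {
    ctr0 <- approx_centers[i, ]
    if (ctr0[1] - template_radius < 1 || ctr0[1] + template_radius > w ||
        ctr0[2] - template_radius < 1 || ctr0[2] + template_radius > h) {
      stop("template around pillar ", i, " leaves the frame")
    }
    ctr <- weighted_centroid(frame, ctr0[1], ctr0[2], template_radius)
    if (sqrt(sum((ctr - ctr0)^2)) > template_radius) {
      stop("centroid refinement diverged for pillar ", i)
    }
    ic <- round(ctr)
    xr <- (ic[1] - template_radius):(ic[1] + template_radius)
    yr <- (ic[2] - template_radius):(ic[2] + template_radius)
    if (min(xr) < 1 || max(xr) > w || min(yr) < 1 || max(yr) > h) {
      stop("template around pillar ", i, " leaves the frame")
    }
    pillars[[i]] <- list(template = frame[yr, xr],
                         center = ic, reference = ctr)
  }
  structure(list(pillars = pillars, template_radius = template_radius),
            class = "pillar_templates")
}

# normalized cross-correlation of template over a search window; returns the
# integer offset, the subpixel parabolic correction, and a boundary flag
ncc_track <- function(frame, template, center, search_radius) {
  tr <- (nrow(template) - 1) / 2
  h <- nrow(frame); w <- ncol(frame)
  t0 <- template - mean(template)
  tss <- sqrt(sum(t0^2))
  corr <- matrix(NA_real_, 2 * search_radius + 1, 2 * search_radius + 1)
  for (dy in -search_radius:search_radius) {
    yr <- (center[2] + dy - tr):(center[2] + dy + tr)
    if (min(yr) < 1 || max(yr) > h) next
    for (dx in -search_radius:search_radius) {
      xr <- (center[1] + dx - tr):(center[1] + dx + tr)
      if (min(xr) < 1 || max(xr) > w) next
      patch <- frame[yr, xr]
      p0 <- patch - mean(patch)
      pss <- sqrt(sum(p0^2))
      corr[dy + search_radius + 1, dx + search_radius + 1] <-
        if (pss > 0) sum(t0 * p0) / (tss * pss) else 0
    }
  }
  pk <- which(corr == max(corr, na.rm = TRUE), arr.ind = TRUE)[1, ]
  on_edge <- pk[1] == 1 || pk[1] == nrow(corr) ||
    pk[2] == 1 || pk[2] == ncol(corr) ||
    is.na(corr[pk[1] - 1, pk[2]]) || is.na(corr[pk[1] + 1, pk[2]]) ||
    is.na(corr[pk[1], pk[2] - 1]) || is.na(corr[pk[1], pk[2] + 1])
  offset <- c(pk[2] - search_radius - 1, pk[1] - search_radius - 1)
  if (on_edge) {
    return(list(offset = offset, sub = c(NA_real_, NA_real_), flagged = TRUE))
  }
  parab <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(-0.5, min(0.5, d))
  }
  sub <- c(parab(corr[pk[1], pk[2] - 1], corr[pk[1], pk[2]],
                 corr[pk[1], pk[2] + 1]),
           parab(corr[pk[1] - 1, pk[2]], corr[pk[1], pk[2]],
                 corr[pk[1] + 1, pk[2]]))
  list(offset = offset, sub = sub, flagged = FALSE)
}

#' Track pillar caps through a time-lapse stack
#'
#' Two-stage tracking of each pillar template in every frame: stage 1 finds
#' the integer-pixel offset maximizing the normalized cross-correlation over
#' the search window; stage 2 refines it per axis by 3-point parabolic
#' interpolation of the correlation surface around the peak (correction
#' clamped to half a pixel). Deflection is the signed displacement from the
#' resting position projected onto the inter-pillar axis (positive toward
#' the other pillar, i.e. contraction), in micrometers. The resting position
#' is the per-axis median over the frames in the lowest decile of
#' displacement magnitude (robust diastolic baseline); set
#' `baseline = "first_frame"` to use the reference frame instead. Frames
#' whose correlation peak lies on the search-window boundary are flagged and
#' get missing deflections.
#'
#' @param stack List of grayscale frames (or the `stack` element of
#'   [sim_pillar_stack()] output).
#' @param templates A `pillar_templates` object from [detect_pillars()].
#' @param search_radius Search half-width in pixels (default 12).
#' @param um_per_px Micrometers per pixel.
#' @param baseline `"robust"` (default) or `"first_frame"`.
#' @return A data frame of class `pillar_track` with one row per
#'   (frame, pillar): subpixel `x`, `y`, stage-1 `offset_x/y`, stage-2
#'   `sub_x/y`, `deflection_um`, `flagged`.
#' @examples
#' sim <- sim_pillar_stack(n_frames = 8, amplitude_um = 0.5, seed = 1)
#' tpl <- detect_pillars(sim$stack[[1]], rbind(c(45, 60), c(115, 60)))
#' trk <- track_pillars(sim$stack, tpl)
#' max(trk$deflection_um, na.rm = TRUE)
#' @export
track_pillars <- function(stack, templates, search_radius = 12,
                          um_per_px = 0.1625,
                          baseline = c("robust", "first_frame")) {
  stopifnot(inherits(templates, "pillar_templates"))
  baseline <- match.arg(baseline)
  np <- length(templates$pillars)
  nf <- length(stack)
  refs <- t(vapply(templates$pillars, `[[`, numeric(2), "reference"))

  rows <- vector("list", np)
  for (i in seq_len(np)) {
    ctr <- templates$pillars[[i]]$center
    off0 <- templates$pillars[[i]]$reference - ctr  # subpixel part of ref
    pos <- matrix(NA_real_, nf, 2)
    off <- matrix(NA_integer_, nf, 2)
    sub <- matrix(NA_real_, nf, 2)
    flagged <- logical(nf)
    for (f in seq_len(nf)) {
      m <- ncc_track(stack[[f]], templates$pillars[[i]]$template, ctr,
                     search_radius)
      off[f, ] <- m$offset
      sub[f, ] <- m$sub
      flagged[f] <- m$flagged
      if (!m$flagged) {
        pos[f, ] <- ctr + off0 + m$offset + m$sub
      }
    }
    # inter-pillar axis: unit vector from this pillar toward the others' mean
    other <- colMeans(refs[-i, , drop = FALSE])
    u <- other - refs[i, ]
    u <- u / sqrt(sum(u^2))
    disp <- sweep(pos, 2, refs[i, ])
    if (baseline == "robust") {
      mag <- sqrt(rowSums(disp^2))
      ok <- which(!flagged & !is.na(mag))
      low <- ok[mag[ok] <= stats::quantile(mag[ok], 0.1, na.rm = TRUE)]
      rest <- apply(pos[low, , drop = FALSE], 2, stats::median)
    } else {
      rest <- refs[i, ]
    }
    defl <- ((pos[, 1] - rest[1]) * u[1] + (pos[, 2] - rest[2]) * u[2]) *
      um_per_px
    rows[[i]] <- data.frame(frame = seq_len(nf), pillar = i,
                            x = pos[, 1], y = pos[, 2],
                            offset_x = off[, 1], offset_y = off[, 2],
                            sub_x = sub[, 1], sub_y = sub[, 2],
                            deflection_um = defl, flagged = flagged)
  }
  out <- do.call(rbind, rows)
  attr(out, "um_per_px") <- um_per_px
  attr(out, "reference_positions") <- refs
  class(out) <- c("pillar_track", "data.frame")
  out
}

#' Convert a deflection trace to twitch force and stress
#'
#' Force is the pillar spring constant times deflection
#' (`F[uN] = k[uN/um] * d[um]`); stress is force divided by the tissue
#' cross-sectional area (`1 uN / 1 m^2 = 1e-6 Pa`, so with area in m^2,
#' `stress[Pa] = F[uN] * 1e-6 / area[m^2]`).
#'
#' @param track A `pillar_track` data frame.
#' @param geom A `tissue_geometry` object.
#' @return A list of class `force_trace`: `trace` (frame, pillar,
#'   deflection_um, force_uN, stress_Pa) and summary fields
#'   `max_deflection_um`, `max_force_uN`, `max_stress_Pa`.
#' @export
twitch_force <- function(track, geom = tissue_geometry()) {
  stopifnot(inherits(track, "pillar_track"), inherits(geom, "tissue_geometry"))
  if (all(is.na(track$deflection_um))) stop("no unflagged frames to summarize")
  force <- geom$spring_constant_k * track$deflection_um
  stress <- if (!is.na(geom$cross_section_area)) {
    force * 1e-6 / geom$cross_section_area
  } else rep(NA_real_, length(force))
  trace <- data.frame(frame = track$frame, pillar = track$pillar,
                      deflection_um = track$deflection_um,
                      force_uN = force, stress_Pa = stress)
  structure(list(trace = trace,
                 max_deflection_um = max(abs(track$deflection_um), na.rm = TRUE),
                 max_force_uN = max(abs(force), na.rm = TRUE),
                 max_stress_Pa = if (all(is.na(stress))) NA_real_ else
                   max(abs(stress), na.rm = TRUE),
                 geometry = geom),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Twitch force trace: %d frames, max force %.3f uN (k = %.2f uN/um)\n",
              max(x$trace$frame), x$max_force_uN,
              x$geometry$spring_constant_k))
  invisible(x)
}

#' Left-ventricular fractional shortening
#'
#' Echocardiographic contractility index
#' `FS = (LVEDD - LVESD) / LVEDD * 100` (percent), from the end-diastolic
#' and end-systolic left-ventricular dimensions.
#'
#' @param lvedd End-diastolic dimension (> 0), any length unit.
#' @param lvesd End-systolic dimension, `0 <= lvesd <= lvedd` (same unit).
#' @return Fractional shortening in percent.
#' @examples
#' fractional_shortening(4.0, 2.4)
#' @export
fractional_shortening <- function(lvedd, lvesd) {
  if (any(lvedd <= 0)) stop("LVEDD must be positive")
  if (any(lvesd < 0) || any(lvesd > lvedd)) {
    stop("LVESD must lie in [0, LVEDD]")
  }
  (lvedd - lvesd) / lvedd * 100
}
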