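# build a filament_set directly from a binary mask (bypasses segmentation)
mask_to_set <- function(mask, um_per_px) {
  idx <- which(mask > 0)
  h <- nrow(mask)
  pix <- data.frame(x = ((idx - 1) %/% h) + 1, y = ((idx - 1) %% h) + 1)
  structure(list(pixels = list(pix), um_per_px = um_per_px,
                 threshold = 0.5, image_dim = dim(mask), filaments = NULL),
            class = "filament_set")
}

test_that("segmentation finds disjoint bright objects and handles blank images", {
  blank <- matrix(0.1, 128, 128)
  expect_warning(fs <- segment_filaments(blank, 0.1625), "uniform")
  expect_length(fs$pixels, 0)

  img <- matrix(0.05, 128, 128)
  img[30:40, 30:34] <- 0.8
  img[80:90, 90:94] <- 0.8
  fs <- segment_filaments(img, 0.1625, smooth_sigma_px = 0)
  expect_length(fs$pixels, 2)
})

test_that("segmentation recovers the programmed filament count from synthetic images", {
  sim <- sim_sarcomere_image(n_strings = 4, filaments_per_string = 6,
                             noise_sd = 0.1, seed = 3)
  fs <- segment_filaments(sim$image, 0.1625)
  expect_equal(length(fs$pixels), 24)
})

test_that("moment metrics match brute-force pixel moments for a rectangle", {
  # vertical solid rectangle: 20 px tall, 4 px wide, 0.1 um/px
  mask <- matrix(0, 64, 64)
  mask[21:40, 31:34] <- 1
  fs <- filament_metrics(mask_to_set(mask, 0.1))
  f <- fs$filaments

  # oracle: brute-force second central moments over the pixel set,
  # with the 1/12 per-pixel integration term; lambda = 4 sqrt(moment)
  ys <- rep(21:40, times = 4); xs <- rep(31:34, each = 20)
  vy <- mean((ys - mean(ys))^2) + 1 / 12
  vx <- mean((xs - mean(xs))^2) + 1 / 12
  expect_equal(f$lambda1_um, 4 * sqrt(vy) * 0.1, tolerance = 1e-9)
  expect_equal(f$lambda2_um, 4 * sqrt(vx) * 0.1, tolerance = 1e-9)
  expect_equal(f$angle_deg, 0, tolerance = 1e-9)        # vertical major axis
  expect_equal(f$area_um2, 80 * 0.01, tolerance = 1e-12)
  expect_equal(f$x, 32.5)
  expect_equal(f$y, 30.5)
})

test_that("a circle has equal axes and undefined orientation", {
  mask <- matrix(0, 64, 64)
  cx <- cy <- 32
  for (x in 1:64) for (y in 1:64) {
    if ((x - cx)^2 + (y - cy)^2 <= 100) mask[y, x] <- 1
  }
  f <- filament_metrics(mask_to_set(mask, 0.1))$filaments
  expect_equal(f$lambda1_um, f$lambda2_um, tolerance = 0.02)
  expect_true(is.na(f$angle_deg))
})

test_that("orientation recovery is equivariant across programmed rotations", {
  # noiseless: every single filament's orientation within 2 degrees
  for (ang in c(-60, -30, 0, 30, 60)) {
    sim <- sim_sarcomere_image(n_strings = 2, filaments_per_string = 4,
                               angle_deg = ang, noise_sd = 0, seed = 5)
    fs <- filament_metrics(segment_filaments(sim$image, 0.1625))
    expect_equal(nrow(fs$filaments), 8)
    got <- fs$filaments$angle_deg
    dev <- abs(((got - ang + 90) %% 180) - 90)  # compare mod 180
    expect_lt(max(dev), 2)
  }
})

test_that("spacing records respect the cone and gap and match a brute-force filter", {
  # two parallel vertical strings 10 um apart, within-string spacing 2 um
  sim <- sim_sarcomere_image(n_strings = 2, filaments_per_string = 5,
                             spacing_um = 2, string_gap_um = 10,
                             angle_deg = 0, noise_sd = 0, seed = 1)
  fs <- filament_metrics(segment_filaments(sim$image, 0.1625))
  sp <- filament_spacing(fs, max_gap_um = 5, max_angle_diff_deg = 30)

  # brute force: all pairs within 5 um whose direction lies in the cone
  f <- fs$filaments
  ok_pairs <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(f))) {
    if (i >= j) next
    dx <- f$x[j] - f$x[i]; dy <- f$y[j] - f$y[i]
    d_um <- sqrt(dx^2 + dy^2) * 0.1625
    if (d_um > 5 || d_um == 0) next
    th <- f$angle_deg[i] * pi / 180
    cone <- abs(dx * cos(th) - dy * sin(th)) / sqrt(dx^2 + dy^2)
    if (cone >= cos(30 * pi / 180)) ok_pairs[[length(ok_pairs) + 1]] <- c(i, j)
  }
  # every recorded pair must be admissible under the brute-force filter,
  # and cross-string pairs (10 um) must never appear
  expect_true(nrow(sp$records) >= 1)
  for (k in seq_len(nrow(sp$records))) {
    expect_true(any(vapply(ok_pairs, function(p)
      all(p == c(sp$records$i[k], sp$records$j[k])), logical(1))))
  }
  expect_equal(sp$mean_d_um, 2, tolerance = 0.1)

  # a single filament yields no records
  one <- sim_sarcomere_image(n_strings = 1, filaments_per_string = 1,
                             noise_sd = 0, seed = 1)
  fs1 <- filament_metrics(segment_filaments(one$image, 0.1625))
  expect_equal(nrow(filament_spacing(fs1)$records), 0)
})

test_that("spacing recovery hits the generator parameter", {
  sim <- sim_sarcomere_image(spacing_um = 1.8, noise_sd = 0.1, seed = 2)
  fs <- filament_metrics(segment_filaments(sim$image, 0.1625))
  sp <- filament_spacing(fs)
  expect_equal(sp$mean_d_um, 1.8, tolerance = 0.1)
})

test_that("count_and_compare summarizes groups and Welch-tests the pairs", {
  same <- list(a = c(10, 12, 11), b = c(10, 12, 11))
  res <- count_and_compare(same)
  expect_equal(res$comparisons$p_value, 1)

  set.seed(17)
  groups <- list(wt = rnorm(6, 100, 10), mut = rnorm(6, 50, 10))
  res <- count_and_compare(groups)
  expect_lt(res$comparisons$p_value, 1e-3)
  expect_equal(res$summary$n_wells, c(6L, 6L))

  solo <- count_and_compare(list(only = c(5, 6, 7)))
  expect_equal(nrow(solo$comparisons), 0)
})

test_that("MEFL calibration: exact fits, round trip, and noisy recovery", {
  cal <- mefl_calibrate(c(100, 200, 400), c(1000, 2000, 4000))
  expect_equal(cal$slope, 10, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(mefl_apply(cal, 250), 2500, tolerance = 1e-9)

  ident <- mefl_calibrate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$slope, 1, tolerance = 1e-12)

  # round trip on noiseless beads reproduces reference MEFL exactly
  b <- sim_bead_table(slope = 7, intercept = 120, noise_sd = 0, seed = 2)
  cal <- mefl_calibrate(b$beads$au, b$beads$mefl)
  expect_equal(mefl_apply(cal, b$beads$au), b$beads$mefl, tolerance = 1e-6)

  # noisy beads: fitted slope within 3 SE of truth
  b <- sim_bead_table(slope = 10, intercept = 0, noise_sd = 200, seed = 3)
  cal <- mefl_calibrate(b$beads$au, b$beads$mefl)
  expect_lt(abs(cal$slope - 10), 3 * cal$slope_se)

  expect_error(mefl_calibrate(100, 1000), "at least 2")
  expect_error(mefl_calibrate(c(5, 5), c(1, 2)), "zero variance")
})

test_that("metrics are invariant under integer image translation", {
  base <- sim_sarcomere_image(n_strings = 2, filaments_per_string = 3,
                              angle_deg = 20, noise_sd = 0, seed = 9)
  img <- base$image
  shift <- c(6, 4)  # (x, y)
  moved <- matrix(min(img), nrow(img), ncol(img))
  moved[(1 + shift[2]):nrow(img), (1 + shift[1]):ncol(img)] <-
    img[1:(nrow(img) - shift[2]), 1:(ncol(img) - shift[1])]

  f1 <- filament_metrics(segment_filaments(img, 0.1625))$filaments
  f2 <- filament_metrics(segment_filaments(moved, 0.1625))$filaments
  o1 <- order(f1$y, f1$x); o2 <- order(f2$y, f2$x)
  expect_equal(f2$x[o2], f1$x[o1] + shift[1], tolerance = 0.05)
  expect_equal(f2$y[o2], f1$y[o1] + shift[2], tolerance = 0.05)
  expect_equal(f2$lambda1_um[o2], f1$lambda1_um[o1], tolerance = 0.02)
  expect_equal(f2$angle_deg[o2], f1$angle_deg[o1], tolerance = 0.5)
})
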