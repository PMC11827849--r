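test_that("assign_barcodes sums barcode reads per construct and tallies unmatched", {
  design <- data.frame(construct_id = c("A", "B"),
                       barcodes = c("b1,b2", "b3"))
  reads <- data.frame(barcode = c("b1", "b2", "bX"), count = c(10, 5, 7))
  m <- assign_barcodes(reads, design)
  expect_equal(m["A", "rep1"], 15)
  expect_equal(m["B", "rep1"], 0)
  expect_equal(unname(attr(m, "unmatched")["rep1"]), 7)

  empty <- assign_barcodes(reads[0, ], design)
  expect_true(all(empty == 0))

  expect_error(assign_barcodes(reads, data.frame(
    construct_id = c("A", "B"), barcodes = c("b1,b2", "b2"))),
    "duplicate barcode")
})

test_that("assign_barcodes equals a per-barcode linear-scan oracle on random input", {
  set.seed(21)
  n_con <- 100
  design <- data.frame(
    construct_id = sprintf("c%03d", 1:n_con),
    barcodes = vapply(1:n_con, function(i)
      paste(sprintf("bc%03d_%d", i, 1:3), collapse = ","), ""))
  all_bc <- unlist(strsplit(design$barcodes, ","))
  reads <- data.frame(
    barcode = c(sample(all_bc, 500, replace = TRUE),
                sprintf("junk%d", 1:40)),
    count = sample(1:50, 540, replace = TRUE))
  m <- assign_barcodes(reads, design)

  # oracle: scan every read against every construct's barcode list
  for (i in sample(n_con, 15)) {
    bcs <- strsplit(design$barcodes[i], ",")[[1]]
    total <- 0
    for (r in seq_len(nrow(reads))) {
      if (reads$barcode[r] %in% bcs) total <- total + reads$count[r]
    }
    expect_equal(unname(m[design$construct_id[i], 1]), total)
  }
})

test_that("cpm normalization conserves one million per replicate", {
  m <- cbind(r1 = c(10, 30, 60))
  expect_equal(unname(cpm_normalize(m)[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(unname(cpm_normalize(cbind(r1 = 42))[1, 1]), 1e6)

  set.seed(5)
  big <- matrix(rpois(600, 80), 100, 6,
                dimnames = list(sprintf("c%d", 1:100), sprintf("r%d", 1:6)))
  cpm <- cpm_normalize(big)
  expect_equal(unname(colSums(cpm)), rep(1e6, 6), tolerance = 1e-9)

  withzero <- cbind(r1 = c(5, 5), r2 = c(0, 0))
  z <- cpm_normalize(withzero)
  expect_true(all(is.na(z[, "r2"])))
  expect_equal(attr(z, "zero_total"), "r2")
})

test_that("activity ratio is RNA/DNA with zero-DNA cells undefined", {
  rna <- cbind(r1 = c(200, 100))
  dna <- cbind(r1 = c(100, 0))
  ratio <- activity_ratio(rna, dna)
  expect_equal(unname(ratio[1, 1]), 2)
  expect_true(is.na(ratio[2, 1]))
})

test_that("qc_filter applies the low-count boundary and the WT replicate rule", {
  mk_act <- function(ratio, dna_cpm, libs) {
    reps <- colnames(ratio)
    mpra_activity_table(ratio, dna_cpm, ratio * dna_cpm,
                        data.frame(replicate = reps, library = libs,
                                   well = seq_along(reps)))
  }
  # boundary: DNA CPM 99.9 excluded, 100.0 retained
  ratio <- matrix(1, 2, 2, dimnames = list(c("WT", "c1"), c("L1_W1", "L1_W2")))
  dna <- matrix(c(500, 99.9, 500, 100), 2, 2, byrow = FALSE,
                dimnames = dimnames(ratio))
  act <- qc_filter(mk_act(ratio, dna, c(1, 1)))
  expect_false(act$included["c1", "L1_W1"])
  expect_equal(act$reason["c1", "L1_W1"], "low_norm_count")
  expect_true(act$included["c1", "L1_W2"])

  # WT activities [1,1,1,2]: mean 1.25, SD 0.5, |2-1.25| >= 0.5 -> dropped
  ratio <- matrix(1, 2, 4,
                  dimnames = list(c("WT", "c1"), sprintf("L1_W%d", 1:4)))
  ratio["WT", ] <- c(1, 1, 1, 2)
  dna <- matrix(500, 2, 4, dimnames = dimnames(ratio))
  act <- qc_filter(mk_act(ratio, dna, rep(1, 4)))
  expect_equal(attr(act, "qc_report")$replicates_excluded, "L1_W4")
  expect_false(any(act$included[, "L1_W4"]))
  expect_true(all(act$included[, 1:3]))

  # all WT activities equal: nothing dropped
  ratio["WT", ] <- 1
  act <- qc_filter(mk_act(ratio, dna, rep(1, 4)))
  expect_length(attr(act, "qc_report")$replicates_excluded, 0)

  # no WT surviving rule (a) aborts
  dna["WT", ] <- 1
  expect_error(qc_filter(mk_act(ratio, dna, rep(1, 4))), "wild-type")
})

test_that("lowering the low-count threshold never excludes a previously included cell", {
  d <- data.frame(construct_id = c("WT", sprintf("c%d", 1:9)),
                  activity = runif(10, 0.3, 2))
  sim <- sim_mpra_counts(d, mean_depth = 150, dispersion = 0.3, seed = 9)
  strict <- mpra_quantify(sim$dna, sim$rna, sim$replicate_info,
                          min_norm_count = 200)
  loose <- mpra_quantify(sim$dna, sim$rna, sim$replicate_info,
                         min_norm_count = 50)
  expect_true(all(loose$included[strict$included]))
})

test_that("mutagenesis scan projects activities onto covered positions only", {
  reps <- c("L1_W1", "L1_W2")
  ids <- c("WT", "d1", "d2")
  ratio <- matrix(c(1, 1, 0.4, 0.4, 0.8, 0.8), 3, 2, byrow = TRUE,
                  dimnames = list(ids, reps))
  act <- mpra_activity_table(ratio, ratio * 0 + 500, ratio * 500,
                             data.frame(replicate = reps, library = 1,
                                        well = 1:2))
  design <- data.frame(construct_id = ids,
                       category = c("wt", "tf_deletion", "tf_deletion"),
                       start = c(NA, 10, 13), end = c(NA, 15, 20))
  prof <- mutagenesis_scan(act, design)

  expect_equal(sort(unique(prof$position)), 10:20)  # gaps outside coverage
  expect_equal(prof$mean_activity[prof$position == 10], 0.4)
  expect_equal(prof$mean_activity[prof$position == 14], 0.6)  # overlap mean
  expect_equal(prof$mean_activity[prof$position == 18], 0.8)

  # brute-force per-position oracle over every covered position
  for (p in 10:20) {
    covering <- c(if (p >= 10 && p <= 15) "d1", if (p >= 13 && p <= 20) "d2")
    oracle <- mean(ratio[covering, ])
    expect_equal(prof$mean_activity[prof$position == p], oracle)
  }

  # WT-only design gives an empty profile
  empty <- mutagenesis_scan(act, design[design$category == "wt", ,
                                        drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("deletion and point-mutation categories are separate tracks", {
  reps <- c("L1_W1", "L1_W2")
  ids <- c("WT", "del1", "pm1")
  ratio <- matrix(c(1, 1, 0.4, 0.4, 0.9, 0.9), 3, 2, byrow = TRUE,
                  dimnames = list(ids, reps))
  act <- mpra_activity_table(ratio, ratio * 0 + 500, ratio * 500,
                             data.frame(replicate = reps, library = 1,
                                        well = 1:2))
  design <- data.frame(construct_id = ids,
                       category = c("wt", "tf_deletion", "point_mutation"),
                       start = c(NA, 10, 10), end = c(NA, 12, 12))
  prof <- mutagenesis_scan(act, design)
  expect_setequal(unique(prof$category), c("tf_deletion", "point_mutation"))
  expect_equal(prof$mean_activity[prof$category == "tf_deletion" &
                                    prof$position == 11], 0.4)
  expect_equal(prof$mean_activity[prof$category == "point_mutation" &
                                    prof$position == 11], 0.9)
})

test_that("test_vs_wt: null group, strong effect, and the single-group BH identity", {
  reps <- sprintf("L1_W%d", 1:4)
  ids <- c("WT", "same")
  ratio <- matrix(rep(c(1, 1.1, 0.9, 1), 2), 2, 4, byrow = TRUE,
                  dimnames = list(ids, reps))
  act <- mpra_activity_table(ratio, ratio * 0 + 500, ratio * 500,
                             data.frame(replicate = reps, library = 1,
                                        well = 1:4))
  design <- data.frame(construct_id = ids, category = c("wt", "tf_deletion"),
                       start = c(NA, 1), end = c(NA, 2))
  res <- test_vs_wt(act, design)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$p_adj, res$p_value)  # single group: BH is the identity

  # simulated strong effect: 0.4 vs 1.0, n = 12 per group, SD 0.05
  set.seed(31)
  reps <- sprintf("L1_W%d", 1:12)
  ratio <- rbind(WT = rnorm(12, 1, 0.05), lo = rnorm(12, 0.4, 0.05))
  colnames(ratio) <- reps
  act <- mpra_activity_table(ratio, ratio * 0 + 500, ratio * 500,
                             data.frame(replicate = reps, library = 1,
                                        well = 1:12))
  res <- test_vs_wt(act, design = data.frame(construct_id = c("WT", "lo"),
                                             category = c("wt", "tf_deletion"),
                                             start = c(NA, 1), end = c(NA, 2)))
  expect_lt(res$p_adj, 1e-6)
})

test_that("the full quantification path recovers simulated activities relative to WT", {
  d <- data.frame(construct_id = c("WT", sprintf("c%d", 1:3)),
                  activity = c(1, 0.4, 1, 2))
  sim <- sim_mpra_counts(d, mean_depth = 2e4, dispersion = 0, seed = 12)
  act <- mpra_quantify(sim$dna, sim$rna, sim$replicate_info)
  est <- construct_activity(act, relative_to = "WT")
  expect_equal(est$activity[match(d$construct_id, est$construct_id)],
               d$activity, tolerance = 0.05)
})
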