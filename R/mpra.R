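# MPRA quantification: barcode-to-construct counting, counts-per-million
# normalization, mRNA/DNA activity ratios, QC exclusions, per-position
# mutagenesis effect maps, and construct-vs-WT testing.

#' Sum barcode-level reads into construct-level counts
#'
#' Maps each barcode to its construct and sums read counts, the first step
#' after sequencing reads have been matched to barcodes. Barcodes not present
#' in the design are tallied separately, never silently dropped.
#'
#' @param reads Data frame with columns `barcode` and `count`, optionally
#'   `replicate` (a single replicate is assumed when absent).
#' @param design List of construct descriptors or a data frame with columns
#'   `construct_id` and `barcodes` (comma-joined barcode strings). Barcode
#'   sets must be pairwise disjoint across constructs.
#' @return An integer matrix constructs x replicates with attribute
#'   `unmatched` (named vector of unmatched read totals per replicate).
#' @examples
#' design <- data.frame(construct_id = "A", barcodes = "b1,b2")
#' reads <- data.frame(barcode = c("b1", "b2", "bX"), count = c(10, 5, 7))
#' assign_barcodes(reads, design)
#' @export
assign_barcodes <- function(reads, design) {
  stopifnot(all(c("barcode", "count") %in% names(reads)))
  if (!"replicate" %in% names(reads)) {
    reads[["replicate"]] <- rep("rep1", nrow(reads))
  }
  bc_map <- barcode_map(design)

  constructs <- unique(design$construct_id)
  reps <- unique(reads$replicate)
  if (length(reps) == 0) reps <- "rep1"
  m <- matrix(0L, length(constructs), length(reps),
              dimnames = list(constructs, reps))
  unmatched <- stats::setNames(numeric(length(reps)), reps)
  if (nrow(reads) > 0) {
    hit <- bc_map[reads$barcode]
    miss <- is.na(hit)
    if (any(miss)) {
      um <- tapply(reads$count[miss], reads$replicate[miss], sum)
      unmatched[names(um)] <- um
    }
    keep <- reads[!miss, , drop = FALSE]
    if (nrow(keep) > 0) {
      agg <- stats::aggregate(count ~ construct + replicate,
                              data = data.frame(construct = hit[!miss],
                                                replicate = keep$replicate,
                                                count = keep$count),
                              FUN = sum)
      m[cbind(match(agg$construct, constructs),
              match(agg$replicate, reps))] <- agg$count
    }
  }
  attr(m, "unmatched") <- unmatched
  m
}

barcode_map <- function(design) {
  stopifnot(all(c("construct_id", "barcodes") %in% names(design)))
  bcs <- strsplit(as.character(design$barcodes), ",", fixed = TRUE)
  bcs <- lapply(bcs, trimws)
  flat <- unlist(bcs)
  if (anyDuplicated(flat)) {
    stop("duplicate barcode across constructs: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  }
  stats::setNames(rep(design$construct_id, lengths(bcs)), flat)
}

#' Counts-per-million normalization
#'
#' Normalizes each replicate (column) to its total barcode-read count and
#' rescales to one million, so per-replicate normalized sums equal 1e6.
#' A zero-total replicate is returned as all-`NA` and recorded in the
#' `zero_total` attribute so downstream steps can exclude it.
#'
#' @param counts Non-negative construct x replicate count matrix.
#' @return Matrix of the same shape in counts per million, with attribute
#'   `zero_total` (character vector of flagged replicate names).
#' @examples
#' cpm_normalize(cbind(r1 = c(10, 30, 60)))
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  zero <- totals == 0
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  cpm[, zero] <- NA_real_
  attr(cpm, "zero_total") <- colnames(counts)[zero]
  cpm
}

#' Per-cell mRNA/DNA activity ratios
#'
#' Divides normalized RNA abundance by normalized DNA abundance per
#' (construct, replicate) cell: the MPRA activity statistic. No pseudocount
#' is used; cells with zero DNA are returned `NA` and must be excluded
#' rather than imputed.
#'
#' @param rna_cpm,dna_cpm Matrices from [cpm_normalize()] sharing dimnames.
#' @return Matrix of activity ratios (`NA` where DNA is 0 or either CPM is
#'   missing).
#' @export
activity_ratio <- function(rna_cpm, dna_cpm) {
  stopifnot(identical(dim(rna_cpm), dim(dna_cpm)),
            identical(dimnames(rna_cpm), dimnames(dna_cpm)))
  ratio <- rna_cpm / dna_cpm
  ratio[!is.finite(ratio)] <- NA_real_
  ratio
}

#' Build an MPRA activity table
#'
#' Container for per-cell activities plus inclusion state. Usually produced
#' by [mpra_quantify()]; exposed so tables can also be built directly.
#'
#' @param ratio Activity matrix (constructs x replicates).
#' @param dna_cpm,rna_cpm Normalized count matrices with the same dimnames.
#' @param replicate_info Data frame with columns `replicate`, `library`,
#'   `well` describing each column.
#' @param included Logical matrix; defaults to wherever `ratio` is defined.
#' @param reason Character matrix of exclusion reason codes ("" = included).
#' @return An object of class `mpra_activity`.
#' @export
mpra_activity_table <- function(ratio, dna_cpm, rna_cpm, replicate_info,
                                included = NULL, reason = NULL) {
  stopifnot(identical(dim(ratio), dim(dna_cpm)),
            identical(dim(ratio), dim(rna_cpm)))
  if (is.null(included)) included <- !is.na(ratio)
  if (is.null(reason)) {
    reason <- matrix("", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
    reason[is.na(ratio)] <- "undefined_ratio"
  }
  stopifnot(all(replicate_info$replicate == colnames(ratio)))
  structure(list(ratio = ratio, dna_cpm = dna_cpm, rna_cpm = rna_cpm,
                 included = included, reason = reason,
                 replicate_info = replicate_info),
            class = "mpra_activity")
}

#' @export
print.mpra_activity <- function(x, ...) {
  cat(sprintf("MPRA activity table: %d constructs x %d replicates (%d cells included)\n",
              nrow(x$ratio), ncol(x$ratio), sum(x$included)))
  invisible(x)
}

#' Apply MPRA quality-control exclusions
#'
#' Applies the two exclusion rules used before any activity analysis:
#' (a) a (construct, replicate) cell is excluded when its normalized DNA
#' count falls below `min_norm_count` counts per million (insufficient
#' plasmid representation; cells at exactly the threshold are retained);
#' (b) an entire technical replicate is excluded when the wild-type
#' construct's activity in that replicate deviates from the mean wild-type
#' activity across its library's replicates by at least `wt_sd_k` standard
#' deviations.
#'
#' @param act An `mpra_activity` object.
#' @param wt_id Construct id of the wild-type reference (default `"WT"`).
#' @param min_norm_count Minimum DNA counts-per-million per cell
#'   (default 100).
#' @param wt_sd_k SD multiplier for the replicate-level wild-type rule
#'   (default 1).
#' @param filter_assay Apply rule (a) to the `"dna"` matrix only (default)
#'   or to `"both"` assays.
#' @return The `mpra_activity` object with `included`/`reason` updated and a
#'   `qc_report` attribute listing per-rule exclusion counts.
#' @export
qc_filter <- function(act, wt_id = "WT", min_norm_count = 100, wt_sd_k = 1,
                      filter_assay = c("dna", "both")) {
  stopifnot(inherits(act, "mpra_activity"))
  filter_assay <- match.arg(filter_assay)
  if (!wt_id %in% rownames(act$ratio)) {
    stop("wild-type construct '", wt_id, "' not found")
  }
  inc <- act$included
  reason <- act$reason

  low <- act$dna_cpm < min_norm_count & inc
  if (filter_assay == "both") {
    low <- low | (act$rna_cpm < min_norm_count & inc)
  }
  low[is.na(low)] <- FALSE
  inc[low] <- FALSE
  reason[low] <- "low_norm_count"
  n_low <- sum(low)

  if (!any(inc[wt_id, ])) {
    stop("no wild-type replicate survives the low-count filter")
  }

  # replicate-level rule: WT activity vs its library's replicate mean
  wt_act <- act$ratio[wt_id, ]
  wt_act[!inc[wt_id, ]] <- NA
  dropped_reps <- character()
  for (lib in unique(act$replicate_info$library)) {
    cols <- which(act$replicate_info$library == lib)
    vals <- wt_act[cols]
    if (sum(!is.na(vals)) < 2) next
    mu <- mean(vals, na.rm = TRUE)
    sdv <- stats::sd(vals, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) next
    out <- !is.na(vals) & abs(vals - mu) >= wt_sd_k * sdv
    dropped_reps <- c(dropped_reps, colnames(act$ratio)[cols][out])
  }
  for (r in dropped_reps) {
    newly <- inc[, r]
    inc[newly, r] <- FALSE
    reason[newly, r] <- "wt_outlier_replicate"
  }

  act$included <- inc
  act$reason <- reason
  attr(act, "qc_report") <- list(
    min_norm_count = min_norm_count, wt_sd_k = wt_sd_k,
    filter_assay = filter_assay,
    n_cells_low_count = n_low,
    replicates_excluded = dropped_reps,
    n_cells_included = sum(inc))
  act
}

#' Quantify MPRA activity from count matrices
#'
#' Full quantification path: counts-per-million normalization of the DNA and
#' RNA matrices, per-cell mRNA/DNA ratios, and QC exclusions
#' (see [qc_filter()]).
#'
#' @param dna_counts,rna_counts Construct x replicate count matrices with
#'   identical dimnames.
#' @param replicate_info Data frame (`replicate`, `library`, `well`); when
#'   `NULL`, parsed from column names of the form `L<lib>_W<well>`.
#' @param ... Passed to [qc_filter()] (`wt_id`, `min_norm_count`, `wt_sd_k`,
#'   `filter_assay`).
#' @return An `mpra_activity` object with QC applied (see [qc_filter()]).
#' @examples
#' d <- data.frame(construct_id = c("WT", "m1"), activity = c(1, 0.5))
#' sim <- sim_mpra_counts(d, mean_depth = 2000, seed = 1)
#' act <- mpra_quantify(sim$dna, sim$rna, sim$replicate_info)
#' construct_activity(act)
#' @export
mpra_quantify <- function(dna_counts, rna_counts, replicate_info = NULL, ...) {
  stopifnot(identical(dimnames(dna_counts), dimnames(rna_counts)))
  if (is.null(replicate_info)) {
    replicate_info <- parse_replicate_info(colnames(dna_counts))
  }
  dna_cpm <- cpm_normalize(dna_counts)
  rna_cpm <- cpm_normalize(rna_counts)
  ratio <- activity_ratio(rna_cpm, dna_cpm)
  act <- mpra_activity_table(ratio, dna_cpm, rna_cpm, replicate_info)
  dead <- union(attr(dna_cpm, "zero_total"), attr(rna_cpm, "zero_total"))
  if (length(dead)) {
    act$included[, dead] <- FALSE
    act$reason[, dead] <- "zero_total_replicate"
  }
  qc_filter(act, ...)
}

parse_replicate_info <- function(rep_ids) {
  m <- regmatches(rep_ids, regexec("^L([0-9]+)_W([0-9]+)$", rep_ids))
  ok <- lengths(m) == 3
  if (!all(ok)) {
    # fall back to a single-library layout
    return(data.frame(replicate = rep_ids, library = 1L,
                      well = seq_along(rep_ids), stringsAsFactors = FALSE))
  }
  data.frame(replicate = rep_ids,
             library = as.integer(vapply(m, `[`, "", 2)),
             well = as.integer(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Per-construct activity estimates
#'
#' Mean activity of each construct over its included replicate cells,
#' optionally expressed relative to the wild-type construct (each replicate's
#' ratio divided by the wild-type ratio in that replicate before averaging,
#' which removes the global normalization scale).
#'
#' @param act An `mpra_activity` object.
#' @param relative_to Construct id to normalize against, or `NULL` (raw
#'   mRNA/DNA ratios).
#' @return Data frame with `construct_id`, `activity` (mean), `sd`, `n`.
#' @export
construct_activity <- function(act, relative_to = NULL) {
  stopifnot(inherits(act, "mpra_activity"))
  vals <- act$ratio
  vals[!act$included] <- NA
  if (!is.null(relative_to)) {
    if (!relative_to %in% rownames(vals)) stop("unknown construct: ", relative_to)
    vals <- sweep(vals, 2, vals[relative_to, ], "/")
  }
  data.frame(construct_id = rownames(vals),
             activity = rowMeans(vals, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n = rowSums(!is.na(vals)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-position mutagenesis effect map
#'
#' Projects construct activities onto genomic positions: every position of
#' the assayed element gets the mean activity over all included
#' (construct, replicate) cells of constructs whose mutated interval covers
#' it, separately per mutation category (TF-site deletions and point
#' mutations are plotted as separate tracks). Positions covered by no
#' construct are gaps, not zeros.
#'
#' @param act An `mpra_activity` object.
#' @param design Data frame with `construct_id`, `category`, `start`, `end`
#'   (1-based inclusive genomic coordinates; `NA` for the wild-type /
#'   control constructs, which never contribute).
#' @param element_interval Length-2 vector restricting reported positions;
#'   defaults to the range of the design's mutated intervals.
#' @return Data frame (`position`, `category`, `mean_activity`, `sd`,
#'   `n_constructs`, `n_cells`) with one row per covered position x category.
#' @export
mutagenesis_scan <- function(act, design, element_interval = NULL) {
  stopifnot(inherits(act, "mpra_activity"),
            all(c("construct_id", "category", "start", "end") %in% names(design)))
  mut <- design[!is.na(design$start) & !is.na(design$end), , drop = FALSE]
  mut <- mut[mut$construct_id %in% rownames(act$ratio), , drop = FALSE]
  if (nrow(mut) == 0) {
    return(data.frame(position = integer(), category = character(),
                      mean_activity = numeric(), sd = numeric(),
                      n_constructs = integer(), n_cells = integer()))
  }
  if (any(mut$end < mut$start)) stop("interval end before start")
  if (is.null(element_interval)) {
    element_interval <- c(min(mut$start), max(mut$end))
  }

  vals <- act$ratio
  vals[!act$included] <- NA
  out <- list()
  for (cat in unique(mut$category)) {
    sub <- mut[mut$category == cat, , drop = FALSE]
    pos_list <- mapply(seq, sub$start, sub$end, SIMPLIFY = FALSE)
    cover <- data.frame(
      position = unlist(pos_list),
      construct_id = rep(sub$construct_id, lengths(pos_list)))
    cover <- cover[cover$position >= element_interval[1] &
                     cover$position <= element_interval[2], , drop = FALSE]
    if (nrow(cover) == 0) next
    for (p in sort(unique(cover$position))) {
      ids <- cover$construct_id[cover$position == p]
      cells <- as.vector(vals[ids, , drop = FALSE])
      cells <- cells[!is.na(cells)]
      if (length(cells) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        position = p, category = cat,
        mean_activity = mean(cells), sd = stats::sd(cells),
        n_constructs = length(ids), n_cells = length(cells))
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(), category = character(),
                      mean_activity = numeric(), sd = numeric(),
                      n_constructs = integer(), n_cells = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$category, res$position), , drop = FALSE]
}

#' Test construct (or motif) activities against wild type
#'
#' Welch's unpaired two-tailed t test of each group's included activity
#' cells against the wild-type construct's cells, Benjamini-Hochberg
#' adjusted across all groups tested in the call.
#'
#' @param act An `mpra_activity` object.
#' @param design Design data frame; needs `construct_id`, plus `motif_label`
#'   when grouping by motif.
#' @param group_by `"construct"` (default) or `"motif_label"`.
#' @param wt_id Wild-type construct id.
#' @return Data frame (`group`, `estimate` = mean group activity,
#'   `wt_mean`, `statistic`, `df`, `p_value`, `p_adj`, `n`). Groups with
#'   fewer than two included cells are skipped with a warning.
#' @export
test_vs_wt <- function(act, design, group_by = c("construct", "motif_label"),
                       wt_id = "WT") {
  stopifnot(inherits(act, "mpra_activity"))
  group_by <- match.arg(group_by)
  vals <- act$ratio
  vals[!act$included] <- NA
  wt_vals <- vals[wt_id, ]
  wt_vals <- wt_vals[!is.na(wt_vals)]
  if (length(wt_vals) < 2) stop("need >= 2 included wild-type replicates")

  if (group_by == "construct") {
    groups <- split(setdiff(rownames(vals), wt_id),
                    setdiff(rownames(vals), wt_id))
  } else {
    stopifnot("motif_label" %in% names(design))
    lab <- design[!is.na(design$motif_label) & design$motif_label != "" &
                    design$construct_id != wt_id, , drop = FALSE]
    groups <- split(lab$construct_id, lab$motif_label)
  }

  rows <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], rownames(vals))
    cells <- as.vector(vals[ids, , drop = FALSE])
    cells <- cells[!is.na(cells)]
    if (length(cells) < 2) {
      warning("group '", g, "' has < 2 included observations; skipped")
      next
    }
    tt <- welch_t(cells, wt_vals)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, estimate = mean(cells), wt_mean = mean(wt_vals),
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      n = length(cells), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(group = character(), estimate = numeric(),
                      wt_mean = numeric(), statistic = numeric(),
                      df = numeric(), p_value = numeric(),
                      p_adj = numeric(), n = integer()))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_value)
  res[, c("group", "estimate", "wt_mean", "statistic", "df",
          "p_value", "p_adj", "n")]
}
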