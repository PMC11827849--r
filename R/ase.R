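# Allele-specific expression: per-sample mutant/WT allelic ratios from
# strain-distinguishing SNP counts, cis/trans testing between genotype
# groups, qPCR delta-delta-Ct quantification, and Mendelian-ratio tests.

#' Per-sample allelic expression ratio
#'
#' Estimates each sample's mutant-linked / wild-type-linked expression ratio
#' from per-SNP allele counts. `"pooled"` (default) sums counts over SNPs
#' before taking the ratio (depth-weighted); `"mean_of_snps"` averages
#' per-SNP ratios over SNPs where both alleles were observed. The two
#' coincide exactly when every SNP has the same depth and ratio. A ratio of
#' 1 is the null of no cis-regulatory effect; a sample whose wild-type-linked
#' counts are all zero gets an `NA` ratio and is flagged.
#'
#' @param counts Long-format allele count table: columns `sample_id`,
#'   `snp_id`, `allele` (`"mut_linked"` / `"wt_linked"`), `count`; an
#'   optional `genotype` column is carried through.
#' @param aggregation `"pooled"` or `"mean_of_snps"`.
#' @return Data frame with one row per sample: `sample_id` (+ `genotype`),
#'   `ratio`, `total_depth`, `n_snps_used`, `flag` (`""` or
#'   `"undefined_ratio"`). Per-SNP ratios are attached as the
#'   `per_snp` attribute (sample_id, snp_id, mut, wt, ratio).
#' @examples
#' sim <- sim_ase_counts(n_per_genotype = 2, true_ratio = 0.5, seed = 1)
#' allelic_ratio(sim$counts)
#' @export
allelic_ratio <- function(counts, aggregation = c("pooled", "mean_of_snps")) {
  aggregation <- match.arg(aggregation)
  stopifnot(all(c("sample_id", "snp_id", "allele", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (!all(counts$allele %in% c("mut_linked", "wt_linked"))) {
    stop("allele must be 'mut_linked' or 'wt_linked'")
  }

  wide <- merge(
    stats::aggregate(count ~ sample_id + snp_id,
                     counts[counts$allele == "mut_linked", ], sum),
    stats::aggregate(count ~ sample_id + snp_id,
                     counts[counts$allele == "wt_linked", ], sum),
    by = c("sample_id", "snp_id"), all = TRUE,
    suffixes = c("_mut", "_wt"))
  wide$count_mut[is.na(wide$count_mut)] <- 0
  wide$count_wt[is.na(wide$count_wt)] <- 0
  wide$ratio <- ifelse(wide$count_mut > 0 & wide$count_wt > 0,
                       wide$count_mut / wide$count_wt, NA_real_)

  rows <- lapply(split(wide, wide$sample_id), function(d) {
    mut <- sum(d$count_mut); wt <- sum(d$count_wt)
    if (aggregation == "pooled") {
      ratio <- if (wt > 0) mut / wt else NA_real_
      n_used <- sum(d$count_mut + d$count_wt > 0)
    } else {
      ok <- !is.na(d$ratio)
      ratio <- if (any(ok)) mean(d$ratio[ok]) else NA_real_
      n_used <- sum(ok)
    }
    data.frame(sample_id = d$sample_id[1], ratio = ratio,
               total_depth = mut + wt, n_snps_used = n_used,
               flag = if (is.na(ratio)) "undefined_ratio" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if ("genotype" %in% names(counts)) {
    geno <- unique(counts[, c("sample_id", "genotype")])
    res <- merge(res, geno, by = "sample_id", sort = FALSE)
    res <- res[, c("sample_id", "genotype", "ratio", "total_depth",
                   "n_snps_used", "flag")]
  }
  attr(res, "per_snp") <- data.frame(
    sample_id = wide$sample_id, snp_id = wide$snp_id,
    mut = wide$count_mut, wt = wide$count_wt, ratio = wide$ratio,
    stringsAsFactors = FALSE)
  attr(res, "aggregation") <- aggregation
  res
}

#' Cis/trans test of allelic ratios between genotype groups
#'
#' Welch's unpaired two-tailed t test of per-sample allelic ratios between
#' wild-type-genotype and heterozygous-deletion samples. A significant
#' depression of the het-group ratio while the wild-type group sits near 1
#' is the cis-regulation signature (the deleted element suppresses only the
#' allele on its own chromosome); a shared shift in both groups would point
#' to a trans effect.
#'
#' @param wt_ratios,het_ratios Numeric vectors of per-sample ratios
#'   (>= 2 each, `NA` dropped).
#' @param alpha Significance level for the cis call (default 0.05).
#' @return A one-row data frame with group means and SDs, the Welch test
#'   (`statistic`, `df`, `p_value`) and `cis_consistent` (TRUE when the het
#'   mean is significantly below the wild-type mean).
#' @export
cis_trans_test <- function(wt_ratios, het_ratios, alpha = 0.05) {
  wt_ratios <- wt_ratios[!is.na(wt_ratios)]
  het_ratios <- het_ratios[!is.na(het_ratios)]
  if (length(wt_ratios) < 2 || length(het_ratios) < 2) {
    stop("need at least two samples with defined ratios per group")
  }
  tt <- welch_t(wt_ratios, het_ratios)
  data.frame(wt_mean = mean(wt_ratios), wt_sd = stats::sd(wt_ratios),
             het_mean = mean(het_ratios), het_sd = stats::sd(het_ratios),
             statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
             cis_consistent = tt$p_value < alpha &&
               mean(het_ratios) < mean(wt_ratios))
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification: for each sample and target gene,
#' `dCt = Ct(target) - Ct(housekeeping)`, `ddCt = dCt - mean dCt` of the
#' reference group for that gene, and fold change `2^(-ddCt)`.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene`, `ct`.
#' @param reference_group Group whose mean dCt defines fold = 1.
#' @param housekeeping Housekeeping gene name (default `"HPRT"`); its Ct
#'   must be present for every sample.
#' @return Data frame (`sample_id`, `group`, `gene`, `dct`, `ddct`, `fold`)
#'   for every non-housekeeping gene.
#' @examples
#' ct <- data.frame(
#'   sample_id = rep(c("a", "b"), each = 2),
#'   group = rep(c("ref", "mut"), each = 2),
#'   gene = rep(c("TTN", "HPRT"), 2),
#'   ct = c(21, 16, 20, 16))
#' ddct(ct, reference_group = "ref")
#' @export
ddct <- function(ct, reference_group, housekeeping = "HPRT") {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  if (!reference_group %in% ct$group) stop("reference group not found")
  if (any(!is.finite(ct$ct))) stop("all Ct values must be finite")
  hk <- ct[ct$gene == housekeeping, ]
  if (anyDuplicated(hk$sample_id)) stop("duplicate housekeeping Ct per sample")
  targets <- ct[ct$gene != housekeeping, ]
  hk_ct <- stats::setNames(hk$ct, hk$sample_id)
  if (!all(targets$sample_id %in% names(hk_ct))) {
    stop("missing housekeeping Ct for sample(s): ",
         paste(setdiff(targets$sample_id, names(hk_ct)), collapse = ", "))
  }
  targets$dct <- targets$ct - hk_ct[targets$sample_id]
  res <- lapply(split(targets, targets$gene), function(d) {
    ref_mean <- mean(d$dct[d$group == reference_group])
    if (is.nan(ref_mean)) stop("reference group has no samples for gene ",
                               d$gene[1])
    d$ddct <- d$dct - ref_mean
    d$fold <- 2^(-d$ddct)
    d
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[, c("sample_id", "group", "gene", "dct", "ddct", "fold")]
}

#' Mendelian genotype-ratio test
#'
#' Chi-square goodness-of-fit of observed offspring genotype counts against
#' an expected Mendelian ratio (e.g. 1:2:1 for a heterozygous intercross),
#' used to detect missing genotype classes such as embryonic-lethal
#' homozygotes.
#'
#' @param observed Named (or positional) genotype counts.
#' @param expected_ratio Expected weights in the same order / with the same
#'   names (default `c(1, 2, 1)`).
#' @return A one-row data frame from [chi2_gof()].
#' @examples
#' mendelian_test(c(wt = 0, het = 94, hom = 47), c(1, 2, 1))
#' @export
mendelian_test <- function(observed, expected_ratio = c(1, 2, 1)) {
  if (!is.null(names(observed)) && !is.null(names(expected_ratio))) {
    if (!setequal(names(observed), names(expected_ratio))) {
      stop("observed and expected_ratio names disagree")
    }
    expected_ratio <- expected_ratio[names(observed)]
  }
  chi2_gof(observed, expected_ratio)
}
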