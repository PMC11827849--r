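# Readers and writers for the pipeline's delimited-text and TIFF formats.

#' Read a construct x replicate count table
#'
#' Tab-separated text with a `construct_id` column followed by one column
#' per replicate.
#'
#' @param path File path.
#' @return Integer matrix with construct rownames and replicate colnames.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot("construct_id" %in% names(d))
  m <- as.matrix(d[, setdiff(names(d), "construct_id"), drop = FALSE])
  rownames(m) <- d$construct_id
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_count_matrix
#' @param m Count matrix to write.
#' @export
write_count_matrix <- function(m, path) {
  d <- data.frame(construct_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an MPRA design table
#'
#' Tab-separated text with columns `construct_id`, `category`, `chrom`,
#' `start`, `end`, `motif_label`, `barcodes` (comma-joined). Empty
#' coordinates are allowed for wild-type / control constructs.
#'
#' @param path File path.
#' @return Data frame with typed columns.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("construct_id", "category")
  stopifnot(all(need %in% names(d)))
  for (col in c("start", "end")) {
    if (col %in% names(d)) d[[col]] <- suppressWarnings(as.integer(d[[col]]))
  }
  d
}

#' Read a long-format allele count table
#'
#' Tab-separated text with columns `sample_id`, `genotype`, `snp_id`,
#' `allele`, `count`.
#'
#' @param path File path.
#' @return Data frame suitable for [allelic_ratio()].
#' @export
read_allele_counts <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("sample_id", "snp_id", "allele", "count") %in% names(d)))
  d$count <- as.integer(d$count)
  d
}

#' Read or write a grayscale image stack as multi-page TIFF
#'
#' Images are stored 16-bit; intensities are in \[0, 1\] in memory.
#'
#' @param path File path.
#' @return `read_image_stack()`: list of numeric matrices.
#'   `read_image()`: a single matrix.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}

#' @rdname read_image_stack
#' @param stack List of numeric matrices in \[0, 1\].
#' @export
write_image_stack <- function(stack, path) {
  if (!is.list(stack)) stack <- list(stack)
  tiff::writeTIFF(stack, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_image_stack
#' @export
read_image <- function(path) {
  read_image_stack(path)[[1]]
}
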