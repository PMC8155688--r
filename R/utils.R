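# Internal helpers shared across modules.

#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor hclust as.dist p.adjust pbinom rnorm runif rpois setNames
#' @importFrom utils head
NULL

# Canonical chromosome ordering: autosomes 1-22, then X, Y.
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix and upper-cases X/Y so that both the UCSC
#' ("chr8") and ensembl/plain ("8") dialects map onto one internal vocabulary.
#'
#' @param x character vector of chromosome names.
#' @return character vector of bare chromosome names.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  toupper(x)
}

# Order index for (chrom, start) sorting with the canonical chromosome order.
chrom_rank <- function(chrom) match(chrom, chrom_levels())

# Column name for a (feature, channel) pair; the "__" separator is reserved.
axis_col <- function(feature_id, channel) paste0(feature_id, "__", channel)

#' Parse a feature-matrix axis
#'
#' Feature matrices are wide tibbles whose data columns are named
#' `<feature_id>__amp` / `<feature_id>__del`. This returns the axis as a tidy
#' tibble in column order.
#'
#' @param fm a feature matrix tibble (first column `sample_id`).
#' @return tibble with columns `column`, `feature_id`, `channel`.
#' @export
matrix_axis <- function(fm) {
  cols <- setdiff(names(fm), "sample_id")
  ok <- grepl("__(amp|del)$", cols)
  if (!all(ok)) {
    abort(paste0("not a feature matrix: bad column name(s) ",
                 paste(head(cols[!ok], 3), collapse = ", ")))
  }
  tibble::tibble(
    column = cols,
    feature_id = sub("__(amp|del)$", "", cols),
    channel = sub("^.*__", "", cols)
  )
}

# Dense numeric matrix view of a feature-matrix tibble (rownames = sample_id).
fm_values <- function(fm) {
  m <- as.matrix(fm[, setdiff(names(fm), "sample_id"), drop = FALSE])
  rownames(m) <- fm$sample_id
  storage.mode(m) <- "double"
  m
}

# Rebuild the tibble form from a values matrix and sample ids.
fm_from_values <- function(values, sample_ids) {
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE,
                                         check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

# GRanges view of a feature table or segment table (0-based half-open input;
# IRanges is 1-based closed, so shift start by +1).
to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
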