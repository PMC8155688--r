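# Mapping segments onto a feature space (cytobands or genes) as a
# samples x channel-feature matrix, and denormalizing a selected cytoband
# panel to its constituent genes.
#
# A feature matrix is a wide tibble: first column `sample_id`, then one
# numeric column per (feature, channel) named `<feature_id>__amp` /
# `<feature_id>__del`. Amplifications and deletions are separate channels
# because their amplitudes are normalized independently.

#' Map one sample's segments onto a feature space
#'
#' For feature f and channel c, the raw value is the coverage-weighted
#' aberration load: the sum over sign-matching segments of
#' `overlap_length(segment, f) / length(f) * |log2 ratio|`. Segments with
#' value 0 (copy-number neutral) contribute to neither channel; a feature
#' with no overlapping segment scores 0 on both channels.
#'
#' @param segments segment tibble for a single sample.
#' @param features feature tibble ([read_cytobands()] / [read_genes()]).
#' @return one-row feature-matrix tibble.
#' @export
map_profile_to_features <- function(segments, features) {
  if (length(unique(segments$sample_id)) > 1) {
    stopf("map_profile_to_features expects a single sample, got %d",
          length(unique(segments$sample_id)))
  }
  build_matrix(segments, features)
}

#' Build a raw feature matrix for a cohort
#'
#' Applies the per-sample feature mapping (see [map_profile_to_features()])
#' to every sample in the segment table. Rows follow the order in which
#' samples first appear in `segments`; columns follow `features` order with
#' an `amp` and a `del` channel per feature.
#'
#' @param segments segment tibble for one or more samples.
#' @param features feature tibble.
#' @return raw (unnormalized) feature-matrix tibble; values are >= 0.
#' @export
build_matrix <- function(segments, features) {
  validate_features(features)
  sample_ids <- unique(segments$sample_id)
  cols <- as.vector(rbind(axis_col(features$feature_id, "amp"),
                          axis_col(features$feature_id, "del")))
  values <- matrix(0, nrow = length(sample_ids), ncol = length(cols),
                   dimnames = list(sample_ids, cols))
  segs <- segments[segments$value != 0, , drop = FALSE]
  if (nrow(segs) > 0) {
    hits <- GenomicRanges::findOverlaps(to_granges(segs), to_granges(features))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      ovl <- pmin(segs$end[qi], features$end[si]) -
        pmax(segs$start[qi], features$start[si])
      contrib <- ovl / (features$end[si] - features$start[si]) *
        abs(segs$value[qi])
      channel <- ifelse(segs$value[qi] > 0, "amp", "del")
      col <- axis_col(features$feature_id[si], channel)
      row <- segs$sample_id[qi]
      agg <- rowsum(contrib, group = paste(row, col, sep = "\r"))
      key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
      values[cbind(match(key[, 1], sample_ids), match(key[, 2], cols))] <-
        agg[, 1]
    }
  }
  fm_from_values(values, sample_ids)
}

#' Normalize a feature matrix to \[0, 1\]
#'
#' The amplification and deletion channels are normalized independently:
#' each channel's values are divided by that channel's q-th percentile taken
#' across all entries of the channel, then clipped to \[0, 1\]. The default
#' `q = 99` is robust to single outlier segments; `q = 100` gives exact
#' max-division. An all-zero channel is left untouched.
#'
#' @param fm raw feature-matrix tibble (all values >= 0).
#' @param q percentile used as the channel's scale (default 99).
#' @return normalized feature-matrix tibble, every value in \[0, 1\].
#' @export
normalize_matrix <- function(fm, q = 99) {
  values <- fm_values(fm)
  if (any(values < 0)) stopf("normalize_matrix: negative raw value")
  axis <- matrix_axis(fm)
  for (ch in c("amp", "del")) {
    idx <- which(axis$channel == ch)
    if (!length(idx)) next
    v <- values[, idx, drop = FALSE]
    scale <- stats::quantile(v, probs = q / 100, names = FALSE, type = 7)
    if (scale > 0) values[, idx] <- pmin(v / scale, 1)
  }
  fm_from_values(values, fm$sample_id)
}

#' Denormalize a selected cytoband panel to genes
#'
#' Expands the cytoband features selected in phase 1 into the protein-coding
#' genes they contain. A gene belongs to a cytoband when its midpoint lies
#' within the band interval, so a gene straddling a band boundary is assigned
#' to exactly one band. Genes contained in any selected band (on either
#' channel) are returned once, in genomic order.
#'
#' @param panel a relevance panel over cytobands ([select_features()]), or a
#'   character vector of cytoband feature ids.
#' @param cytobands cytoband feature tibble.
#' @param genes gene feature tibble.
#' @return gene feature tibble (subset of `genes`), genomically sorted.
#' @export
denormalize_panel_to_genes <- function(panel, cytobands, genes) {
  if (nrow(genes) == 0) stopf("denormalize_panel_to_genes: empty gene set")
  ids <- if (is.character(panel)) panel else
    unique(panel$feature_id[panel$selected])
  bands <- cytobands[cytobands$feature_id %in% ids, , drop = FALSE]
  mid <- (genes$start + genes$end) / 2
  keep <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(bands))) {
    keep <- keep | (genes$chrom == bands$chrom[i] & mid >= bands$start[i] &
                      mid < bands$end[i])
  }
  out <- genes[keep, , drop = FALSE]
  dplyr::arrange(out, chrom_rank(.data$chrom), .data$start)
}

#' Write / read a feature matrix as TSV
#'
#' The matrix is persisted as a TSV (`sample_id` plus channel-feature
#' columns) with a JSON sidecar (`<path>.axis.json`) recording the feature
#' axis in column order.
#'
#' @param fm feature-matrix tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fm, path) {
  readr::write_tsv(fm, path, progress = FALSE)
  axis <- matrix_axis(fm)
  jsonlite::write_json(axis, paste0(path, ".axis.json"), digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"), progress = FALSE)
}
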