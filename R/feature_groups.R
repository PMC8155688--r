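# Partitioning the selected feature genes into focal features and regional
# feature groups by adjacency merging, and per-subtype group amplitudes.

#' Merge adjacent panel genes into focal/regional feature groups
#'
#' Single left-to-right sweep per chromosome over the (sorted) panel genes of
#' one channel: a gene joins the open group when the gap from the previous
#' member's end to its start is at most `merge_distance` (inclusive;
#' default 5 Mb), otherwise a new group opens. Groups never span
#' chromosomes. A singleton group — a gene more than `merge_distance` away
#' from its neighbors on both sides — is a focal feature; a group of two or
#' more genes is a regional feature group.
#'
#' @param genes gene feature tibble restricted to one channel's panel genes,
#'   sorted by (chrom, start); unsorted input is an error.
#' @param channel channel label recorded on the output ("amp" or "del").
#' @param merge_distance maximum end-to-start gap in bp (default 5e6).
#' @param gap optional gap rule: `"end_to_start"` (default) or
#'   `"center_to_center"`.
#' @return tibble of groups: `group_id`, `kind` ("focal"/"regional"),
#'   `channel`, `chrom`, `start`, `end`, `members` (list column of gene
#'   ids), `n_members`, `span_bp`.
#' @export
merge_features <- function(genes, channel, merge_distance = 5e6,
                           gap = c("end_to_start", "center_to_center")) {
  gap <- match.arg(gap)
  if (nrow(genes) == 0) {
    return(tibble::tibble(group_id = character(), kind = character(),
                          channel = character(), chrom = character(),
                          start = double(), end = double(),
                          members = list(), n_members = integer(),
                          span_bp = double()))
  }
  ord <- order(chrom_rank(genes$chrom), genes$start)
  if (!identical(ord, seq_len(nrow(genes)))) {
    stopf("merge_features: genes must be sorted by (chrom, start)")
  }
  mid <- (genes$start + genes$end) / 2
  group <- integer(nrow(genes))
  group[1] <- 1L
  open_end <- genes$end[1]
  for (i in seq_len(nrow(genes))[-1]) {
    new_chrom <- genes$chrom[i] != genes$chrom[i - 1]
    g <- if (gap == "end_to_start") genes$start[i] - open_end else
      mid[i] - mid[i - 1]
    if (new_chrom || g > merge_distance) {
      group[i] <- group[i - 1] + 1L
      open_end <- genes$end[i]
    } else {
      group[i] <- group[i - 1]
      open_end <- max(open_end, genes$end[i])
    }
  }
  out <- tibble::tibble(gid = group, feature_id = genes$feature_id,
                        chrom = genes$chrom, gstart = genes$start,
                        gend = genes$end) |>
    dplyr::group_by(.data$gid) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$gstart), end = max(.data$gend),
                     members = list(.data$feature_id),
                     n_members = dplyr::n(), .groups = "drop")
  tibble::tibble(
    group_id = sprintf("%s_%s_%03d", channel, out$chrom, out$gid),
    kind = ifelse(out$n_members >= 2, "regional", "focal"),
    channel = channel,
    chrom = out$chrom, start = out$start, end = out$end,
    members = out$members, n_members = out$n_members,
    span_bp = out$end - out$start
  )
}

#' Per-subtype amplitude of a feature group
#'
#' For each subtype, the mean of the normalized channel values over the grid
#' of (member genes x subtype samples) — the average normalized CNV log
#' ratio of the group in that subtype.
#'
#' @param groups feature-group tibble from [merge_features()] (any number of
#'   rows).
#' @param gene_matrix normalized gene feature matrix.
#' @param subtypes subtype tibble ([group_subtypes()] output or the
#'   post-merge groups): needs `label` and `sample_ids`.
#' @return tibble: `group_id`, `label` (subtype), `amplitude`.
#' @export
group_amplitude <- function(groups, gene_matrix, subtypes) {
  V <- fm_values(gene_matrix)
  out <- list()
  for (i in seq_len(nrow(groups))) {
    cols <- axis_col(groups$members[[i]], groups$channel[i])
    missing_cols <- setdiff(cols, colnames(V))
    if (length(missing_cols)) {
      stopf("group_amplitude: member feature '%s' absent from the matrix",
            missing_cols[1])
    }
    for (j in seq_len(nrow(subtypes))) {
      idx <- match(subtypes$sample_ids[[j]], gene_matrix$sample_id)
      if (anyNA(idx)) stopf("group_amplitude: unknown subtype sample in '%s'",
                            subtypes$label[j])
      out[[length(out) + 1]] <- tibble::tibble(
        group_id = groups$group_id[i], label = subtypes$label[j],
        amplitude = mean(V[idx, cols, drop = FALSE]))
    }
  }
  dplyr::bind_rows(out)
}

#' Summarise feature groups by kind and size class
#'
#' @param groups feature-group tibble (both channels may be concatenated).
#' @param size_cut span separating small from large groups (default 5 Mb).
#' @return tibble of counts per (channel, kind, size_class); zero rows for
#'   empty input are filled with zero counts.
#' @export
size_summary <- function(groups, size_cut = 5e6) {
  base <- tidyr::expand_grid(channel = c("amp", "del"),
                             kind = c("focal", "regional"),
                             size_class = c("small", "large"))
  if (nrow(groups) == 0) return(dplyr::mutate(base, n = 0L))
  counted <- groups |>
    dplyr::mutate(size_class = ifelse(.data$span_bp < size_cut,
                                      "small", "large")) |>
    dplyr::count(.data$channel, .data$kind, .data$size_class)
  dplyr::left_join(base, counted,
                   by = c("channel", "kind", "size_class")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Write feature groups as TSV (members comma-joined)
#' @param groups feature-group tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  out <- dplyr::mutate(groups,
                       members = purrr::map_chr(.data$members, paste,
                                                collapse = ","))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
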