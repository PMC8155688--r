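# Segment, metadata, and annotation IO with validation and sample-level QC.
#
# All genomic coordinates are 0-based half-open throughout the package;
# readers document deviations of their source formats where they exist.

#' Read a copy-number segment file
#'
#' Reads a tab-separated segment file (Progenetix-style `.seg` dialect) with
#' header columns `sample_id`, `chromosome`, `start`, `end`, `value` into a
#' validated tidy segment table. One row is one contiguous genomic segment
#' with a normalized log2 ratio (`> 0` amplification, `< 0` deletion).
#' Coordinates are 0-based half-open. Chromosome names are accepted in both
#' the "chr8" and "8" dialects and normalized to bare names (1-22, X, Y);
#' the mitochondrial chromosome is not part of the supported set.
#'
#' @param path path to the TSV file.
#' @param genome optional tibble with columns `chrom`, `length` declaring the
#'   genome's chromosome set; segments on unlisted chromosomes or extending
#'   past a chromosome end are rejected.
#' @return tibble with columns `sample_id`, `chrom`, `start`, `end`, `value`,
#'   sorted by (sample, chromosome, start). Errors name the offending input
#'   line for malformed rows, empty or inverted segments, unknown
#'   chromosomes, and overlapping segments within one sample/chromosome.
#' @export
read_segments <- function(path, genome = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample_id", "chromosome", "start", "end", "value")
  if (!all(need %in% names(raw))) {
    stopf("segment file %s: missing column(s) %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  segs <- tibble::tibble(
    sample_id = raw$sample_id,
    chrom = normalize_chrom(raw$chromosome),
    start = suppressWarnings(as.numeric(raw$start)),
    end = suppressWarnings(as.numeric(raw$end)),
    value = suppressWarnings(as.numeric(raw$value)),
    line = seq_len(nrow(raw)) + 1L  # header is line 1
  )
  validate_segments(segs, genome = genome, context = path)
  dplyr::arrange(segs[setdiff(names(segs), "line")],
                 .data$sample_id, chrom_rank(.data$chrom), .data$start)
}

# Shared validation for segment tables (also used by the simulator's output
# self-check). `segs` may carry a `line` column for error reporting.
validate_segments <- function(segs, genome = NULL, context = "segments") {
  line <- if ("line" %in% names(segs)) segs$line else seq_len(nrow(segs))
  bad <- which(is.na(segs$sample_id) | is.na(segs$start) | is.na(segs$end) |
                 is.na(segs$value))
  if (length(bad)) {
    stopf("%s line %d: malformed row (non-numeric or missing field)",
          context, line[bad[1]])
  }
  chroms <- if (is.null(genome)) chrom_levels() else genome$chrom
  bad <- which(!segs$chrom %in% chroms)
  if (length(bad)) {
    stopf("%s line %d: unknown chromosome '%s'", context, line[bad[1]],
          segs$chrom[bad[1]])
  }
  bad <- which(segs$start >= segs$end)
  if (length(bad)) {
    i <- bad[1]
    what <- if (segs$start[i] == segs$end[i]) "empty segment" else
      "inverted segment (start >= end)"
    stopf("%s line %d: %s", context, line[i], what)
  }
  if (!is.null(genome) && "length" %in% names(genome)) {
    len <- genome$length[match(segs$chrom, genome$chrom)]
    bad <- which(segs$end > len)
    if (length(bad)) {
      stopf("%s line %d: segment end %g beyond chromosome %s length %g",
            context, line[bad[1]], segs$end[bad[1]], segs$chrom[bad[1]],
            len[bad[1]])
    }
  }
  # overlap check within (sample, chrom)
  ord <- order(segs$sample_id, chrom_rank(segs$chrom), segs$start)
  s <- segs[ord, ]
  l <- line[ord]
  same <- s$sample_id[-1] == s$sample_id[-nrow(s)] &
    s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1) {
    ovl <- which(same & s$start[-1] < s$end[-nrow(s)])
    if (length(ovl)) {
      stopf("%s line %d: overlapping segments for sample '%s' on chromosome %s",
            context, l[ovl[1] + 1L], s$sample_id[ovl[1] + 1L],
            s$chrom[ovl[1] + 1L])
    }
  }
  invisible(segs)
}

#' Write a segment table
#'
#' Inverse of [read_segments()]: writes the package's TSV segment dialect
#' (header `sample_id\tchromosome\tstart\tend\tvalue`).
#'
#' @param segments segment tibble as returned by [read_segments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- tibble::tibble(
    sample_id = segments$sample_id,
    chromosome = segments$chrom,
    start = format_bp(segments$start),
    end = format_bp(segments$end),
    value = segments$value
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Base positions are integral; print them without scientific notation.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a sample metadata table
#'
#' TSV with header `sample_id`, `icdo_morphology`, `icdo_topography`,
#' `organ`: ICD-O-3 morphology (histology, e.g. "8500/3") and topography
#' (site, e.g. "C50.9") codes plus a free-text organ label. Empty codes are
#' preserved as empty strings; QC decides their fate later.
#'
#' @param path path to the TSV file.
#' @return tibble with the four columns; duplicate sample ids or missing
#'   columns are errors.
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  need <- c("sample_id", "icdo_morphology", "icdo_topography", "organ")
  if (!all(need %in% names(raw))) {
    stopf("metadata file %s: missing column(s) %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup)) {
    stopf("metadata file %s: duplicate sample_id '%s'", path, dup[1])
  }
  tibble::as_tibble(raw[need])
}

#' Write a sample metadata table
#' @param metadata metadata tibble as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read a UCSC cytoband annotation
#'
#' Parses the 5-column `cytoBand.txt` format (chrom, start, end, band,
#' stain; gzip allowed; no header). Feature ids are chromosome + band, e.g.
#' "8q24.1". Source coordinates are already 0-based half-open and are kept.
#'
#' @param path path to the cytoband file.
#' @return feature tibble with columns `feature_id`, `chrom`, `start`,
#'   `end`, `kind` (= "cytoband"), in genomic order.
#' @export
read_cytobands <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "band", "stain"),
                         col_types = "ciicc", progress = FALSE)
  if (nrow(raw) == 0) stopf("cytoband file %s: no cytobands", path)
  if (anyNA(raw$start) || anyNA(raw$end) || anyNA(raw$band)) {
    stopf("cytoband file %s: unparsable line %d", path,
          which(is.na(raw$start) | is.na(raw$end) | is.na(raw$band))[1])
  }
  feats <- tibble::tibble(
    feature_id = paste0(normalize_chrom(raw$chrom), raw$band),
    chrom = normalize_chrom(raw$chrom),
    start = as.numeric(raw$start),
    end = as.numeric(raw$end),
    kind = "cytoband"
  )
  validate_features(feats, path)
  dplyr::arrange(feats, chrom_rank(.data$chrom), .data$start)
}

#' Read a gene annotation (BED4)
#'
#' BED4: chrom, start, end, gene symbol; 0-based half-open as BED defines.
#' Duplicate symbols (e.g. one gene split across assembly patches) are
#' collapsed to the widest span covering all their rows.
#'
#' @param path path to the BED file.
#' @return feature tibble (`feature_id` = gene symbol, `kind` = "gene") in
#'   genomic order.
#' @export
read_genes <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = "c"), progress = FALSE)
  if (ncol(raw) < 4) stopf("gene BED %s: gene name required (BED4)", path)
  feats <- tibble::tibble(
    feature_id = raw[[4]],
    chrom = normalize_chrom(raw[[1]]),
    start = suppressWarnings(as.numeric(raw[[2]])),
    end = suppressWarnings(as.numeric(raw[[3]])),
    kind = "gene"
  )
  if (anyNA(feats$start) || anyNA(feats$end) || anyNA(feats$feature_id)) {
    stopf("gene BED %s: malformed line %d", path,
          which(is.na(feats$start) | is.na(feats$end))[1])
  }
  # duplicate symbols: keep the widest span (union of rows, same chromosome)
  feats <- feats |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), end = max(.data$end),
                     kind = "gene", .groups = "drop")
  validate_features(feats, path)
  dplyr::arrange(feats, chrom_rank(.data$chrom), .data$start)
}

validate_features <- function(feats, context = "features") {
  if (any(feats$start >= feats$end)) {
    stopf("%s: degenerate feature interval (start >= end) for '%s'", context,
          feats$feature_id[which(feats$start >= feats$end)[1]])
  }
  dup <- feats$feature_id[duplicated(feats$feature_id)]
  if (length(dup)) {
    stopf("%s: duplicate feature_id '%s'", context, dup[1])
  }
  invisible(feats)
}

#' Sample-level quality control
#'
#' Removes samples that carry too few aberrations to interpret and (optionally)
#' samples with incomplete diagnostic information. A sample present in the
#' segment table but absent from the metadata is rejected with reason
#' `no_metadata` rather than raising an error. The segment-count threshold is
#' inclusive: a sample with exactly `min_segments` segments is kept.
#'
#' @param segments segment tibble ([read_segments()]).
#' @param metadata metadata tibble ([read_metadata()]).
#' @param min_segments minimum number of segments a sample must carry
#'   (default 3).
#' @param require_codes if `TRUE` (default), samples with an empty ICD-O
#'   morphology or topography code are rejected with reason
#'   `incomplete_diagnosis`.
#' @return list with elements `segments` (kept rows), `metadata` (kept rows),
#'   and `rejections`, a tibble of `sample_id`, `reason`. Every input sample
#'   appears either in the kept metadata/segments or in the rejection log.
#' @export
qc_filter <- function(segments, metadata, min_segments = 3,
                      require_codes = TRUE) {
  seg_ids <- unique(segments$sample_id)
  all_ids <- union(seg_ids, metadata$sample_id)
  n_seg <- table(segments$sample_id)
  counts <- as.integer(n_seg[all_ids])
  counts[is.na(counts)] <- 0L

  meta_idx <- match(all_ids, metadata$sample_id)
  reason <- rep(NA_character_, length(all_ids))
  reason[is.na(meta_idx)] <- "no_metadata"
  few <- is.na(reason) & counts < min_segments
  reason[few] <- "too_few_segments"
  if (require_codes) {
    morph <- metadata$icdo_morphology[meta_idx]
    topo <- metadata$icdo_topography[meta_idx]
    incomplete <- is.na(reason) &
      (is.na(morph) | morph == "" | is.na(topo) | topo == "")
    reason[incomplete] <- "incomplete_diagnosis"
  }
  kept <- all_ids[is.na(reason)]
  list(
    segments = segments[segments$sample_id %in% kept, , drop = FALSE],
    metadata = metadata[metadata$sample_id %in% kept, , drop = FALSE],
    rejections = tibble::tibble(sample_id = all_ids[!is.na(reason)],
                                reason = reason[!is.na(reason)])
  )
}
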