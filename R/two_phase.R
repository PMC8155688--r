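# Two-phase feature extraction: cytobands first, then the genes of the
# selected cytobands. Each phase builds and normalizes the feature matrix,
# trains the (denoising) autoencoder, propagates relevance with LRP,
# aggregates and thresholds.

#' Run the two-phase cytoband-to-gene feature extraction
#'
#' Phase 1 maps the cohort's segments onto cytobands, trains the autoencoder
#' on the normalized matrix, scores every channel-feature by aggregated LRP
#' relevance and thresholds the panel. Phase 2 denormalizes the selected
#' cytobands to their protein-coding genes and repeats the extraction on the
#' gene matrix. Per-phase training seeds are derived from `config$seed`
#' (seed + 1, seed + 2), so a run is fully reproducible from config alone.
#'
#' @param segments QC-passed segment tibble.
#' @param cytobands cytoband feature tibble.
#' @param genes gene feature tibble.
#' @param config an [ae_config()].
#' @return object of class `cna_two_phase`: `cytoband_panel` and
#'   `gene_panel` (relevance panels with selection), `cytoband_matrix` and
#'   `gene_matrix` (normalized), `phase2_genes` (gene features entering
#'   phase 2), `models` (both autoencoders) and the config.
#' @export
run_two_phase <- function(segments, cytobands, genes, config) {
  run_phase <- function(fm_norm, seed, phase) {
    cfg <- config
    cfg$seed <- seed
    model <- train_autoencoder(fm_norm, cfg)
    R <- lrp_relevance(model, fm_norm, epsilon = config$epsilon,
                       reference = "mean")
    panel <- aggregate_relevance(R)
    panel <- select_features(panel, threshold = config$threshold,
                             mode = config$threshold_mode, phase = phase)
    list(model = model, panel = panel)
  }

  cyto_norm <- normalize_matrix(build_matrix(segments, cytobands),
                                q = config$q)
  p1 <- run_phase(cyto_norm, config$seed + 1L, "cytoband")
  if (!any(p1$panel$selected)) {
    stopf("run_two_phase: phase-1 selection empty (threshold too strict)")
  }

  phase2_genes <- denormalize_panel_to_genes(p1$panel, cytobands, genes)
  if (nrow(phase2_genes) == 0) {
    stopf("run_two_phase: no genes fall in the selected cytobands")
  }
  gene_norm <- normalize_matrix(build_matrix(segments, phase2_genes),
                                q = config$q)
  p2 <- run_phase(gene_norm, config$seed + 2L, "gene")

  structure(list(
    cytoband_panel = p1$panel, gene_panel = p2$panel,
    cytoband_matrix = cyto_norm, gene_matrix = gene_norm,
    phase2_genes = phase2_genes,
    models = list(cytoband = p1$model, gene = p2$model),
    config = config
  ), class = "cna_two_phase")
}

#' Feature counts before and after each extraction phase
#'
#' @param x a `cna_two_phase` result.
#' @return tibble with one row per (phase, step): the number of
#'   channel-features entering and leaving each phase.
#' @export
extraction_summary <- function(x) {
  tibble::tibble(
    phase = c("phase1", "phase1", "phase2", "phase2"),
    step = c("input", "output", "input", "output"),
    representation = c("cytobands", "cytobands", "genes", "genes"),
    n_channel_features = c(nrow(x$cytoband_panel),
                           sum(x$cytoband_panel$selected),
                           nrow(x$gene_panel),
                           sum(x$gene_panel$selected))
  )
}

#' Write a relevance panel as TSV
#' @param panel relevance panel with `selected` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}
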