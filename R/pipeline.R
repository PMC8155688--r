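# Stage runner chaining the pipeline: simulate -> extract -> signatures ->
# groups -> classify. Every stage reads its inputs from, and writes its
# artifacts to, the run's output directory, so stages can be run singly or
# as "all"; a manifest records config hash, seed and completed stages.
# One run seed drives every stochastic stage through derived per-stage
# seeds.

config_error <- function(msg) {
  abort(msg, class = "cnasig_config_error")
}

#' Assemble or load a pipeline run configuration
#'
#' @param config a named list, or a path to a YAML file with the same
#'   structure. Recognized blocks: `seed` (required), `out_dir` (required),
#'   `paths` (segments/metadata/cytobands/genes input files; optional when
#'   the simulate stage provides them), `qc` (`min_segments`,
#'   `require_codes`), `model` ([ae_config()] fields except seed),
#'   `signature` (`min_samples`, `alpha`, `r_threshold`), `grouping`
#'   (`merge_distance`), `classifier` (`k`, `trees`, `target`).
#' @return validated config list of class `cna_runconfig`, with defaults
#'   filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) config_error("config field 'seed' is required")
  if (is.null(config$out_dir)) config_error("config field 'out_dir' is required")
  defaults <- list(
    qc = list(min_segments = 3, require_codes = TRUE),
    model = list(noise_fraction = 0.2, epochs = 200, batch_size = 64,
                 learning_rate = 1e-3, threshold = 0.1,
                 threshold_mode = "weight", q = 99, epsilon = 0.01,
                 variant = "denoising"),
    signature = list(min_samples = 50, alpha = 0.05, r_threshold = 0.9),
    grouping = list(merge_distance = 5e6),
    classifier = list(k = 5, trees = 500, target = "median")
  )
  for (block in names(defaults)) {
    config[[block]] <- utils::modifyList(defaults[[block]],
                                         config[[block]] %||% list())
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "cna_runconfig")
}

artifact <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, producer) {
  p <- artifact(config, name)
  if (!file.exists(p)) {
    stopf("missing artifact '%s': run the '%s' stage first", name, producer)
  }
  p
}

read_subtype_members <- function(path) {
  m <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  m |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(organ = dplyr::first(.data$organ),
                     morphology = dplyr::first(.data$morphology),
                     n = dplyr::n(),
                     sample_ids = list(.data$sample_id), .groups = "drop")
}

stage_simulate <- function(config) {
  sim_seed <- config$seed
  scen <- default_scenario(seed = sim_seed)
  if (!is.null(config$simulate$n_samples)) {
    for (a in names(scen$archetypes)) {
      scen$archetypes[[a]]$n_samples <- config$simulate$n_samples
    }
  }
  if (!is.null(config$simulate$passenger_rate)) {
    scen$passenger_rate <- config$simulate$passenger_rate
  }
  cohort <- simulate_cohort(scen)
  write_segments(cohort$segments, artifact(config, "segments.tsv"))
  write_metadata(cohort$metadata[, c("sample_id", "icdo_morphology",
                                     "icdo_topography", "organ")],
                 artifact(config, "metadata.tsv"))
  readr::write_tsv(cohort$truth$events, artifact(config, "truth_events.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$loci, artifact(config, "truth_loci.tsv"),
                   progress = FALSE)
  tg <- scen$genome
  readr::write_tsv(tg$genome, artifact(config, "genome.tsv"), progress = FALSE)
  readr::write_tsv(tg$cytobands, artifact(config, "cytobands.tsv"),
                   progress = FALSE)
  readr::write_tsv(tg$genes, artifact(config, "genes.tsv"), progress = FALSE)
  invisible(NULL)
}

read_feature_tsv <- function(path) {
  readr::read_tsv(path, col_types = "ccddc", progress = FALSE)[,
    c("feature_id", "chrom", "start", "end", "kind")]
}

load_stage_inputs <- function(config) {
  paths <- config$paths %||% list()
  seg_path <- paths$segments %||%
    require_artifact(config, "segments.tsv", "simulate")
  meta_path <- paths$metadata %||%
    require_artifact(config, "metadata.tsv", "simulate")
  if (!is.null(paths$cytobands)) {
    cytobands <- read_cytobands(paths$cytobands)
  } else {
    cytobands <- read_feature_tsv(
      require_artifact(config, "cytobands.tsv", "simulate"))
  }
  if (!is.null(paths$genes)) {
    genes <- read_genes(paths$genes)
  } else {
    genes <- read_feature_tsv(require_artifact(config, "genes.tsv",
                                               "simulate"))
  }
  genome <- NULL
  gpath <- artifact(config, "genome.tsv")
  if (file.exists(gpath)) {
    genome <- readr::read_tsv(gpath, col_types = "cd", progress = FALSE)
  }
  segments <- read_segments(seg_path, genome = genome)
  metadata <- read_metadata(meta_path)
  list(segments = segments, metadata = metadata, cytobands = cytobands,
       genes = genes)
}

stage_extract <- function(config) {
  if (is.null(config$paths$segments) &&
      !file.exists(artifact(config, "segments.tsv"))) {
    config_error("config field 'paths.segments' required (or run 'simulate' first)")
  }
  inp <- load_stage_inputs(config)
  qc <- qc_filter(inp$segments, inp$metadata,
                  min_segments = config$qc$min_segments,
                  require_codes = config$qc$require_codes)
  readr::write_tsv(qc$rejections, artifact(config, "qc_rejections.tsv"),
                   progress = FALSE)
  write_metadata(qc$metadata, artifact(config, "metadata_qc.tsv"))
  cfg <- do.call(ae_config, c(list(seed = config$seed + 100L),
                              config$model))
  tp <- run_two_phase(qc$segments, inp$cytobands, inp$genes, cfg)
  write_panel(tp$cytoband_panel, artifact(config, "panel_cytobands.tsv"))
  write_panel(tp$gene_panel, artifact(config, "panel_genes.tsv"))
  write_matrix(tp$gene_matrix, artifact(config, "matrix_genes.tsv"))
  readr::write_tsv(tp$phase2_genes, artifact(config, "phase2_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(extraction_summary(tp),
                   artifact(config, "extraction_summary.tsv"),
                   progress = FALSE)
  invisible(NULL)
}

stage_signatures <- function(config) {
  meta <- read_metadata(require_artifact(config, "metadata_qc.tsv", "extract"))
  gene_matrix <- read_matrix(require_artifact(config, "matrix_genes.tsv",
                                              "extract"))
  panel <- readr::read_tsv(require_artifact(config, "panel_genes.tsv",
                                            "extract"),
                           col_types = "ccdl", progress = FALSE)
  groups <- group_subtypes(meta, min_samples = config$signature$min_samples)
  merged <- merge_subtypes(groups, gene_matrix, panel,
                           r_threshold = config$signature$r_threshold,
                           alpha = config$signature$alpha)
  readr::write_tsv(merged$signatures, artifact(config, "signatures.tsv"),
                   progress = FALSE)
  readr::write_tsv(merged$merge_log, artifact(config, "merge_log.tsv"),
                   progress = FALSE)
  readr::write_tsv(merged$label_map, artifact(config, "label_map.tsv"),
                   progress = FALSE)
  members <- tibble::tibble(
    label = rep(merged$groups$label, lengths(merged$groups$sample_ids)),
    organ = rep(merged$groups$organ, lengths(merged$groups$sample_ids)),
    morphology = rep(merged$groups$morphology,
                     lengths(merged$groups$sample_ids)),
    sample_id = unlist(merged$groups$sample_ids))
  readr::write_tsv(members, artifact(config, "subtype_members.tsv"),
                   progress = FALSE)
  if (length(unique(merged$signatures$label)) >= 2) {
    cl <- cluster_signatures(merged$signatures)
    readr::write_tsv(tibble::tibble(position = seq_along(cl$order),
                                    label = cl$order),
                     artifact(config, "signature_order.tsv"),
                     progress = FALSE)
  }
  invisible(NULL)
}

stage_groups <- function(config) {
  panel <- readr::read_tsv(require_artifact(config, "panel_genes.tsv",
                                            "extract"),
                           col_types = "ccdl", progress = FALSE)
  phase2 <- read_feature_tsv(require_artifact(config, "phase2_genes.tsv",
                                              "extract"))
  gene_matrix <- read_matrix(require_artifact(config, "matrix_genes.tsv",
                                              "extract"))
  subtypes <- read_subtype_members(
    require_artifact(config, "subtype_members.tsv", "signatures"))
  groups <- dplyr::bind_rows(lapply(c("amp", "del"), function(ch) {
    ids <- panel$feature_id[panel$selected & panel$channel == ch]
    genes <- phase2[phase2$feature_id %in% ids, , drop = FALSE]
    genes <- dplyr::arrange(genes, chrom_rank(.data$chrom), .data$start)
    merge_features(genes, channel = ch,
                   merge_distance = config$grouping$merge_distance)
  }))
  write_groups(groups, artifact(config, "feature_groups.tsv"))
  amp <- group_amplitude(groups, gene_matrix, subtypes)
  readr::write_tsv(amp, artifact(config, "group_amplitudes.tsv"),
                   progress = FALSE)
  readr::write_tsv(size_summary(groups),
                   artifact(config, "group_size_summary.tsv"),
                   progress = FALSE)
  invisible(NULL)
}

stage_classify <- function(config) {
  gene_matrix <- read_matrix(require_artifact(config, "matrix_genes.tsv",
                                              "extract"))
  signatures <- readr::read_tsv(
    require_artifact(config, "signatures.tsv", "signatures"),
    col_types = "cccddd", progress = FALSE)
  subtypes <- read_subtype_members(
    require_artifact(config, "subtype_members.tsv", "signatures"))
  ds <- make_dataset(gene_matrix, subtypes, signatures)
  cv <- cross_validate(ds, k = config$classifier$k,
                       seed = config$seed + 200L,
                       trees = config$classifier$trees,
                       target = config$classifier$target)
  report <- list(
    subtype = list(macro_f1 = cv$subtype$macro_f1,
                   accuracy = cv$subtype$accuracy,
                   per_class = cv$subtype$per_class),
    organ = list(macro_f1 = cv$organ$macro_f1,
                 accuracy = cv$organ$accuracy,
                 per_class = cv$organ$per_class),
    f1_size_correlation = cv$f1_size_correlation)
  jsonlite::write_json(report, artifact(config, "classification_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_confusion <- function(m, path) {
    readr::write_tsv(tibble::as_tibble(as.data.frame.matrix(m),
                                       rownames = "true"),
                     path, progress = FALSE)
  }
  write_confusion(cv$subtype$confusion,
                  artifact(config, "confusion_subtype.tsv"))
  write_confusion(cv$organ$confusion, artifact(config, "confusion_organ.tsv"))
  invisible(NULL)
}

#' Run pipeline stages
#'
#' Runs one stage or the whole chain (`"all"` =
#' simulate, extract, signatures, groups, classify) against the config's
#' output directory, then writes/updates `manifest.json` (completed stages,
#' config hash, seed, package version). Artifacts of one stage are only
#' read, never mutated, by later stages.
#'
#' @param config a [run_config()], raw list, or YAML path.
#' @param stages character vector of stage names, or `"all"`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  config <- run_config(config)
  all_stages <- c("simulate", "extract", "signatures", "groups", "classify")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) config_error(sprintf("unknown stage '%s'", bad[1]))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_yaml <- artifact(config, "run_config.yaml")
  yaml::write_yaml(unclass(config), cfg_yaml)
  cfg_hash <- unname(tools::md5sum(cfg_yaml))

  runners <- list(simulate = stage_simulate, extract = stage_extract,
                  signatures = stage_signatures, groups = stage_groups,
                  classify = stage_classify)
  done <- character()
  for (st in all_stages[all_stages %in% stages]) {
    message(sprintf("[cnasig] stage %s", st))
    runners[[st]](config)
    done <- c(done, st)
  }
  manifest_path <- artifact(config, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  manifest <- list(
    stages = union(prev$stages, done),
    config_hash = cfg_hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cnasig"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
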