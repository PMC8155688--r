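# Lazily computed canonical-scenario artifacts, shared across test files so
# the expensive extraction runs once per suite.

.cna_test_cache <- new.env(parent = emptyenv())

canonical_cohort <- function() {
  if (is.null(.cna_test_cache$co)) {
    .cna_test_cache$co <- simulate_cohort(default_scenario())
  }
  .cna_test_cache$co
}

canonical_two_phase <- function() {
  if (is.null(.cna_test_cache$tp)) {
    co <- canonical_cohort()
    tg <- co$config$genome
    .cna_test_cache$tp <- run_two_phase(co$segments, tg$cytobands, tg$genes,
                                        ae_config(seed = 101))
  }
  .cna_test_cache$tp
}

canonical_merged <- function() {
  if (is.null(.cna_test_cache$merged)) {
    co <- canonical_cohort()
    tp <- canonical_two_phase()
    groups <- group_subtypes(co$metadata[, 1:4], min_samples = 50)
    .cna_test_cache$merged <- merge_subtypes(groups, tp$gene_matrix,
                                             tp$gene_panel,
                                             r_threshold = 0.9)
  }
  .cna_test_cache$merged
}

canonical_dataset <- function() {
  if (is.null(.cna_test_cache$ds)) {
    tp <- canonical_two_phase()
    merged <- canonical_merged()
    .cna_test_cache$ds <- make_dataset(tp$gene_matrix, merged$groups,
                                       merged$signatures)
  }
  .cna_test_cache$ds
}

canonical_cv <- function() {
  if (is.null(.cna_test_cache$cv)) {
    .cna_test_cache$cv <- cross_validate(canonical_dataset(), k = 5,
                                         seed = 11)
  }
  .cna_test_cache$cv
}

# Archetype-level truth channel-feature keys ("<feature_id>__<channel>").
truth_keys <- function(role) {
  loci <- canonical_cohort()$truth$loci
  unique(paste0(loci$feature_id[loci$role == role], "__",
                loci$channel[loci$role == role]))
}

# A small, fast scenario for pipeline and two-phase unit tests.
small_scenario <- function(seed = 7, n_samples = 30, passenger_rate = 3) {
  tg <- toy_genome(n_chrom = 2, bins_per_chrom = 20, bin_size = 1e6)
  arch <- list(
    alpha = list(
      organ = "lung", topography = "C34.9", morphology = "8140/3",
      n_samples = n_samples,
      aberrations = dplyr::bind_rows(
        aberration("1", 2e6, 4e6, "amp"),
        aberration("1", 10e6, 12e6, "del"))),
    beta = list(
      organ = "breast", topography = "C50.9", morphology = "8500/3",
      n_samples = n_samples,
      aberrations = dplyr::bind_rows(
        aberration("2", 5e6, 7e6, "del"),
        aberration("2", 14e6, 16e6, "amp")))
  )
  sim_config(tg, arch, passenger_rate = passenger_rate,
             passenger_size = c(2e5, 5e6), seed = seed)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
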