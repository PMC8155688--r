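test_that("planted aberrations appear exactly when deterministic", {
  tg <- toy_genome(n_chrom = 1, bins_per_chrom = 10)
  ab <- aberration("1", 2e6, 4e6, "amp", carrier_frequency = 1,
                   boundary_jitter_sd = 0, amplitude_sd = 0)
  cfg <- sim_config(tg, archetypes = list(
    x = list(organ = "lung", topography = "C34.9", morphology = "8140/3",
             n_samples = 20, aberrations = ab)),
    passenger_rate = 0, seed = 5)
  co <- simulate_cohort(cfg)
  # carrier_frequency 1, no jitter, no passengers: exactly one segment each
  expect_equal(nrow(co$segments), 20)
  expect_true(all(co$segments$start == 2e6 & co$segments$end == 4e6 &
                    co$segments$value == 0.8))
  expect_equal(nrow(co$metadata), 20)
})

test_that("simulation is byte-identical under one seed", {
  cfg <- small_scenario(seed = 11)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(simulate_cohort(cfg)$segments, f1)
  write_segments(simulate_cohort(cfg)$segments, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  cfg2 <- small_scenario(seed = 12)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(simulate_cohort(cfg2)$segments, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("empirical carrier and passenger rates match their parameters", {
  cfg <- small_scenario(seed = 21, n_samples = 200, passenger_rate = 5)
  co <- simulate_cohort(cfg)
  ev <- co$truth$events
  # each aberration: carried count within 3 sd of n * p
  counts <- dplyr::count(ev, .data$archetype, .data$channel, .data$role)
  for (i in seq_len(nrow(counts))) {
    n <- 200; p <- 0.7
    expect_lt(abs(counts$n[i] - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
  # passengers-only cohort: surviving distinct events ~ Poisson(lambda * N)
  # thinned by the small-|value| filter (P(|N(0, 0.4)| < 0.05) ~ 0.0995)
  tg <- toy_genome(n_chrom = 2, bins_per_chrom = 20)
  cfg_p <- sim_config(tg, archetypes = list(
    x = list(organ = "o", topography = "t", morphology = "m",
             n_samples = 400, aberrations = NULL)),
    passenger_rate = 5, passenger_size = c(2e5, 5e6),
    passenger_amplitude_sd = 0.4, seed = 33)
  co_p <- simulate_cohort(cfg_p)
  n_events <- nrow(unique(co_p$segments[c("sample_id", "value")]))
  keep_frac <- 1 - (pnorm(0.05, 0, 0.4) - pnorm(-0.05, 0, 0.4))
  lambda <- 5 * 400 * keep_frac
  expect_lt(abs(n_events - lambda), 3 * sqrt(5 * 400) + 10)
})

test_that("truth events are consistent with emitted segments", {
  co <- simulate_cohort(small_scenario(seed = 31, n_samples = 40))
  ev <- co$truth$events
  segs <- co$segments
  covered <- vapply(seq_len(nrow(ev)), function(i) {
    s <- segs[segs$sample_id == ev$sample_id[i] &
                segs$chrom == ev$chrom[i] &
                sign(segs$value) == sign(ev$value[i]), , drop = FALSE]
    if (nrow(s) == 0) return(0)
    sum(pmax(0, pmin(s$end, ev$end[i]) - pmax(s$start, ev$start[i])))
  }, 0)
  frac <- covered / (ev$end - ev$start)
  # every truth event has matching emitted coverage of >= 50% of its span
  expect_true(all(frac >= 0.5))
  expect_gt(mean(frac), 0.95)
})

test_that("aberrations outside their chromosome are rejected", {
  tg <- toy_genome(n_chrom = 1, bins_per_chrom = 10)  # 10 Mb
  ab <- aberration("1", 8e6, 12e6, "amp")
  cfg <- sim_config(tg, archetypes = list(
    x = list(organ = "o", topography = "t", morphology = "m",
             n_samples = 2, aberrations = ab)), seed = 1)
  expect_error(simulate_cohort(cfg), "outside its chromosome")
  ab2 <- aberration("7", 0, 1e6, "amp")
  cfg2 <- sim_config(tg, archetypes = list(
    x = list(organ = "o", topography = "t", morphology = "m",
             n_samples = 2, aberrations = ab2)), seed = 1)
  expect_error(simulate_cohort(cfg2), "outside its chromosome")
})

test_that("the default scenario has the declared structure", {
  cfg <- default_scenario()
  expect_equal(length(cfg$archetypes), 6)
  expect_equal(sum(vapply(cfg$archetypes, function(a) a$n_samples, 0)), 900)
  expect_equal(nrow(cfg$genome$cytobands), 300)
  # discriminative loci disjoint across archetypes
  ab <- dplyr::bind_rows(lapply(names(cfg$archetypes), function(a) {
    dplyr::mutate(cfg$archetypes[[a]]$aberrations, archetype = a)
  }))
  expect_equal(nrow(ab), 24)
  expect_true(all(ab$carrier_frequency == 0.7))
  key <- paste(ab$chrom, ab$start)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(length(unique(ab$chrom)), 6)  # one chromosome per archetype
  expect_equal(nrow(cfg$shared_ubiquitous), 3)
  expect_true(all(cfg$shared_ubiquitous$carrier_frequency == 0.9))
  # ubiquitous loci never overlap discriminative loci
  for (i in seq_len(nrow(cfg$shared_ubiquitous))) {
    u <- cfg$shared_ubiquitous[i, ]
    same <- ab[ab$chrom == u$chrom, ]
    expect_true(all(same$start >= u$end | same$end <= u$start))
  }
})

test_that("the toy fixture is tiny, valid, and hand-checkable", {
  fx <- toy_fixture()
  expect_equal(nrow(fx$segments), 7)
  expect_equal(length(unique(fx$segments$sample_id)), 3)
  expect_equal(length(unique(fx$segments$chrom)), 2)
  # hand-computed cytoband matrix (coverage fraction x |log2|):
  fm <- build_matrix(fx$segments, fx$cytobands)
  expect_equal(fm$`1p__amp`, c(0.5, 0.5, 0))
  expect_equal(fm$`1p__del`, c(0, 0, 0.25))
  expect_equal(fm$`1q__amp`, c(0, 0.5, 0.05))
  expect_equal(fm$`2p__amp`, c(0, 0, 0.2))
  expect_equal(fm$`2p__del`, c(0, 0, 0.15))
  expect_equal(fm$`2q__del`, c(1, 0, 0))
})
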