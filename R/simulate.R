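# Synthetic multi-subtype CNA cohort simulator with known ground truth:
# subtype-discriminative aberrations, cohort-wide ubiquitous aberrations,
# and random passenger segments, emitted in the package's segment/metadata
# dialects together with truth tables.

#' Build a toy genome with cytoband bins and genes
#'
#' A compact genome for simulation and testing: `n_chrom` chromosomes of
#' `bins_per_chrom` equal cytoband-like bins (`bin_size` bp each; the first
#' half of each chromosome is the p arm, the second the q arm) and two genes
#' per bin.
#'
#' @param n_chrom number of chromosomes (default 6).
#' @param bins_per_chrom cytoband bins per chromosome (default 50).
#' @param bin_size bin width in bp (default 1e6).
#' @return list: `genome` (tibble `chrom`, `length`), `cytobands` and
#'   `genes` (feature tibbles).
#' @export
toy_genome <- function(n_chrom = 6, bins_per_chrom = 50, bin_size = 1e6) {
  chroms <- as.character(seq_len(n_chrom))
  genome <- tibble::tibble(chrom = chroms,
                           length = bins_per_chrom * bin_size)
  half <- ceiling(bins_per_chrom / 2)
  bins <- tidyr::expand_grid(chrom = chroms,
                             bin = seq_len(bins_per_chrom)) |>
    dplyr::mutate(
      arm = ifelse(.data$bin <= half, "p", "q"),
      band = ifelse(.data$arm == "p", .data$bin, .data$bin - half),
      feature_id = sprintf("%s%s%02d", .data$chrom, .data$arm, .data$band),
      start = (.data$bin - 1) * bin_size,
      end = .data$bin * bin_size,
      kind = "cytoband")
  cytobands <- bins[c("feature_id", "chrom", "start", "end", "kind")]
  genes <- dplyr::bind_rows(
    dplyr::mutate(bins, feature_id = sprintf("G%s.%02dA", .data$chrom, .data$bin),
                  start = .data$start + 0.10 * bin_size,
                  end = .data$start + 0.30 * bin_size),
    dplyr::mutate(bins, feature_id = sprintf("G%s.%02dB", .data$chrom, .data$bin),
                  start = .data$start + 0.55 * bin_size,
                  end = .data$start + 0.75 * bin_size)
  ) |>
    dplyr::mutate(kind = "gene") |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$start)
  genes <- genes[c("feature_id", "chrom", "start", "end", "kind")]
  list(genome = genome, cytobands = cytobands, genes = genes)
}

#' Define an aberration
#'
#' @param chrom,start,end locus (0-based half-open bp).
#' @param channel "amp" or "del".
#' @param carrier_frequency probability a sample of the archetype carries it.
#' @param amplitude_mean,amplitude_sd log2-ratio magnitude (mean must be
#'   positive; the sign comes from the channel).
#' @param boundary_jitter_sd per-endpoint positional jitter in bp.
#' @param role "discriminative" or "ubiquitous".
#' @return one-row aberration tibble.
#' @export
aberration <- function(chrom, start, end, channel,
                       carrier_frequency = 0.7, amplitude_mean = 0.8,
                       amplitude_sd = 0.15, boundary_jitter_sd = 1e5,
                       role = "discriminative") {
  stopifnot(carrier_frequency >= 0, carrier_frequency <= 1,
            amplitude_mean > 0, start < end,
            channel %in% c("amp", "del"))
  tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                 channel = channel, carrier_frequency = carrier_frequency,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 boundary_jitter_sd = boundary_jitter_sd, role = role)
}

#' Simulation configuration
#'
#' @param genome a [toy_genome()]-style list (`genome`, `cytobands`,
#'   `genes`) or a bare genome tibble.
#' @param archetypes named list; each element a list with `organ`,
#'   `topography`, `morphology`, `n_samples`, and `aberrations` (tibble of
#'   [aberration()] rows; their discriminative loci).
#' @param shared_ubiquitous aberration tibble applied to every archetype.
#' @param passenger_rate mean passenger segments per sample (Poisson).
#' @param passenger_size two-element bp range; sizes are log-uniform in it.
#' @param passenger_amplitude_sd sd of the (signed, zero-mean) passenger
#'   log2 ratio; passengers with |value| < 0.05 are dropped as unobservable.
#' @param seed integer seed; the whole cohort is deterministic under it.
#' @return list of class `cna_simconfig`.
#' @export
sim_config <- function(genome, archetypes, shared_ubiquitous = NULL,
                       passenger_rate = 10, passenger_size = c(2e5, 2e7),
                       passenger_amplitude_sd = 0.4, seed) {
  if (is.data.frame(genome)) genome <- list(genome = genome)
  if (anyDuplicated(names(archetypes))) {
    stopf("sim_config: archetype names must be unique")
  }
  for (a in archetypes) {
    if (a$n_samples < 1) stopf("sim_config: n_samples must be >= 1")
  }
  structure(list(
    genome = genome, archetypes = archetypes,
    shared_ubiquitous = shared_ubiquitous,
    passenger_rate = passenger_rate, passenger_size = passenger_size,
    passenger_amplitude_sd = passenger_amplitude_sd,
    seed = as.integer(seed)
  ), class = "cna_simconfig")
}

# Subtract occupied intervals (matrix with columns start, end; disjoint,
# sorted) from [s, e); returns remaining pieces as a 2-column matrix.
subtract_occupied <- function(s, e, occ) {
  pieces <- matrix(c(s, e), ncol = 2)
  if (is.null(occ) || nrow(occ) == 0) return(pieces)
  out <- NULL
  cur <- s
  for (i in seq_len(nrow(occ))) {
    os <- occ[i, 1]; oe <- occ[i, 2]
    if (oe <= cur || os >= e) next
    if (os > cur) out <- rbind(out, c(cur, os))
    cur <- max(cur, oe)
    if (cur >= e) break
  }
  if (cur < e) out <- rbind(out, c(cur, e))
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Simulate a CNA cohort with ground truth
#'
#' Per sample of each archetype: every applicable aberration (the
#' archetype's own plus the shared ubiquitous ones) is included by an
#' independent Bernoulli draw at its carrier frequency, endpoints jittered
#' by a truncated normal, and its amplitude drawn from a normal with the
#' channel's sign. Poisson-many passenger segments are added at
#' length-weighted random positions. Where same-sample segments overlap, the
#' event with the larger |value| wins the overlapped bases, so emitted
#' profiles satisfy the non-overlap invariant.
#'
#' @param config a [sim_config()].
#' @return list: `segments`, `metadata` (package dialects), `truth` — a list
#'   of `events` (every planted event per sample with realized coordinates)
#'   and `loci` (per-archetype discriminative and shared ubiquitous
#'   channel-features over the config's cytobands, if the genome carries
#'   cytobands) — and `config`.
#' @export
simulate_cohort <- function(config) {
  genome <- config$genome$genome
  glen <- setNames(genome$length, genome$chrom)
  all_ab <- dplyr::bind_rows(lapply(config$archetypes,
                                    function(a) a$aberrations))
  if (!is.null(config$shared_ubiquitous)) {
    all_ab <- dplyr::bind_rows(all_ab, config$shared_ubiquitous)
  }
  if (nrow(all_ab) > 0) {
    bad <- which(!all_ab$chrom %in% genome$chrom |
                   all_ab$end > glen[all_ab$chrom])
    if (length(bad)) {
      stopf("simulate_cohort: aberration outside its chromosome (%s:%g-%g)",
            all_ab$chrom[bad[1]], all_ab$start[bad[1]], all_ab$end[bad[1]])
    }
  }

  arch_names <- names(config$archetypes)
  n_per <- vapply(config$archetypes, function(a) a$n_samples, 0)
  total <- sum(n_per)
  sid <- sprintf("S%04d", seq_len(total))
  arch_of <- rep(arch_names, n_per)

  with_private_seed(config$seed, {
    metadata <- tibble::tibble(
      sample_id = sid,
      icdo_morphology = rep(vapply(config$archetypes,
                                   function(a) a$morphology, ""), n_per),
      icdo_topography = rep(vapply(config$archetypes,
                                   function(a) a$topography, ""), n_per),
      organ = rep(vapply(config$archetypes, function(a) a$organ, ""), n_per),
      archetype = arch_of)

    # planted events: vectorized Bernoulli carriage + jitter per archetype
    ev_list <- list()
    offset <- 0L
    for (an in arch_names) {
      arch <- config$archetypes[[an]]
      planted <- dplyr::bind_rows(arch$aberrations, config$shared_ubiquitous)
      n <- arch$n_samples
      k <- nrow(planted)
      if (k > 0) {
        carried <- matrix(runif(n * k), n, k) <=
          matrix(planted$carrier_frequency, n, k, byrow = TRUE)
        idx <- which(carried, arr.ind = TRUE)
        if (nrow(idx)) {
          j <- idx[, 2]
          len <- unname(glen[planted$chrom[j]])
          st <- round(planted$start[j] +
                        rnorm(nrow(idx), 0, planted$boundary_jitter_sd[j]))
          en <- round(planted$end[j] +
                        rnorm(nrow(idx), 0, planted$boundary_jitter_sd[j]))
          st <- pmin(pmax(st, 0), len - 1)
          en <- pmin(pmax(en, st + 1), len)
          mag <- pmax(abs(rnorm(nrow(idx), planted$amplitude_mean[j],
                                planted$amplitude_sd[j])), 0.05)
          ev_list[[an]] <- data.frame(
            si = offset + idx[, 1], chrom = planted$chrom[j],
            start = st, end = en,
            value = ifelse(planted$channel[j] == "amp", mag, -mag),
            role = planted$role[j], channel = planted$channel[j])
        }
      }
      offset <- offset + n
    }

    # passenger segments: Poisson count per sample, length-weighted position
    n_pass <- rpois(total, config$passenger_rate)
    P <- sum(n_pass)
    if (P > 0) {
      psi <- rep(seq_len(total), n_pass)
      pchrom <- sample(genome$chrom, P, replace = TRUE,
                       prob = genome$length)
      plen <- unname(glen[pchrom])
      psize <- round(exp(runif(P, log(config$passenger_size[1]),
                               log(pmin(config$passenger_size[2], plen)))))
      pst <- round(runif(P, 0, plen - psize))
      pval <- rnorm(P, 0, config$passenger_amplitude_sd)
      keep <- abs(pval) >= 0.05
      ev_list[["passengers"]] <- data.frame(
        si = psi[keep], chrom = pchrom[keep], start = pst[keep],
        end = (pst + psize)[keep], value = pval[keep], role = "passenger",
        channel = ifelse(pval[keep] > 0, "amp", "del"))
    }

    ev <- do.call(rbind, ev_list)
    truth_events <- ev[ev$role != "passenger", , drop = FALSE]
    truth_events <- tibble::tibble(
      sample_id = sid[truth_events$si], archetype = arch_of[truth_events$si],
      chrom = truth_events$chrom, start = truth_events$start,
      end = truth_events$end, value = truth_events$value,
      role = truth_events$role, channel = truth_events$channel)
    truth_events <- dplyr::arrange(truth_events, .data$sample_id,
                                   chrom_rank(.data$chrom), .data$start)

    # per-sample overlap resolution: stronger |value| wins the bases
    ev <- ev[order(ev$si, -abs(ev$value)), , drop = FALSE]
    out_si <- integer(0); out_chrom <- character(0)
    out_start <- numeric(0); out_end <- numeric(0); out_val <- numeric(0)
    starts <- which(!duplicated(ev$si))
    bounds <- c(starts, nrow(ev) + 1L)
    for (g in seq_along(starts)) {
      rows <- seq.int(bounds[g], bounds[g + 1L] - 1L)
      occ <- list()
      for (i in rows) {
        ch <- ev$chrom[i]
        pieces <- subtract_occupied(ev$start[i], ev$end[i], occ[[ch]])
        if (nrow(pieces) == 0) next
        out_si <- c(out_si, rep(ev$si[i], nrow(pieces)))
        out_chrom <- c(out_chrom, rep(ch, nrow(pieces)))
        out_start <- c(out_start, pieces[, 1])
        out_end <- c(out_end, pieces[, 2])
        out_val <- c(out_val, rep(ev$value[i], nrow(pieces)))
        m <- rbind(occ[[ch]], pieces)
        occ[[ch]] <- m[order(m[, 1]), , drop = FALSE]
      }
    }
    segments <- tibble::tibble(sample_id = sid[out_si], chrom = out_chrom,
                               start = out_start, end = out_end,
                               value = out_val) |>
      dplyr::arrange(.data$sample_id, chrom_rank(.data$chrom), .data$start)
    validate_segments(segments, genome = genome, context = "simulated cohort")
    loci <- NULL
    if (!is.null(config$genome$cytobands)) {
      loci <- truth_loci(config, config$genome$cytobands)
    }
    list(segments = segments, metadata = metadata,
         truth = list(events = truth_events, loci = loci),
         config = config)
  })
}

# Channel-features (cytoband bins) a planted aberration is expected to light
# up: bins with >= 50% of their width covered by the nominal span.
truth_loci <- function(config, cytobands) {
  rows <- list()
  add <- function(ab, archetype) {
    if (is.null(ab)) return(invisible())
    for (i in seq_len(nrow(ab))) {
      cov <- pmin(ab$end[i], cytobands$end) - pmax(ab$start[i], cytobands$start)
      hit <- cytobands$chrom == ab$chrom[i] &
        cov >= 0.5 * (cytobands$end - cytobands$start)
      if (any(hit)) {
        rows[[length(rows) + 1]] <<- tibble::tibble(
          archetype = archetype, role = ab$role[i],
          feature_id = cytobands$feature_id[hit], channel = ab$channel[i])
      }
    }
  }
  for (arch_name in names(config$archetypes)) {
    add(config$archetypes[[arch_name]]$aberrations, arch_name)
  }
  if (!is.null(config$shared_ubiquitous)) {
    add(config$shared_ubiquitous, "shared")
  }
  dplyr::bind_rows(rows)
}

#' The canonical synthetic scenario
#'
#' Six archetypes across three organs (two sibling subtypes per organ), 150
#' samples each, on a 300-bin toy genome (6 chromosomes x 50 1-Mb bins).
#' Each archetype carries 4 focal discriminative aberrations (2 bins wide,
#' high amplitude, on the q arm of its own chromosome, disjoint across
#' archetypes, carrier frequency 0.7). Three ubiquitous aberrations shared
#' by all archetypes emulate the arm-level events that are near-universal in
#' real tumor cohorts (e.g. whole-8p deletions): each spans a full 25-bin p
#' arm at one-copy amplitude (0.5), carrier frequency 0.9. Passenger
#' segments arrive at rate 10 per sample.
#'
#' @param seed scenario seed (default 4242, the canonical value).
#' @return a [sim_config()].
#' @export
default_scenario <- function(seed = 4242) {
  tg <- toy_genome(n_chrom = 6, bins_per_chrom = 50, bin_size = 1e6)
  Mb <- 1e6
  organs <- list(
    list(organ = "lung", topography = "C34.9",
         morph = c("8140/3", "8070/3")),
    list(organ = "breast", topography = "C50.9",
         morph = c("8500/3", "8520/3")),
    list(organ = "kidney", topography = "C64.9",
         morph = c("8310/3", "8312/3"))
  )
  archetypes <- list()
  arch_i <- 0L
  for (org in organs) {
    for (m in org$morph) {
      arch_i <- arch_i + 1L
      chrom <- as.character(arch_i)  # one private chromosome per archetype
      ab <- dplyr::bind_rows(lapply(seq_len(4), function(k) {
        start <- (26 + (k - 1) * 6) * Mb  # q-arm bins 27-28, 33-34, 39-40, 45-46
        aberration(chrom, start, start + 2 * Mb,
                   channel = if (k %% 2 == 1) "amp" else "del",
                   carrier_frequency = 0.7, amplitude_mean = 0.8,
                   amplitude_sd = 0.15, boundary_jitter_sd = 1e5,
                   role = "discriminative")
      }))
      archetypes[[paste0(org$organ, "_", sub("/", "", m))]] <- list(
        organ = org$organ, topography = org$topography, morphology = m,
        n_samples = 150, aberrations = ab)
    }
  }
  # arm-level shared events: full p arm, one-copy amplitude
  ubiq <- dplyr::bind_rows(
    aberration("2", 0, 25 * Mb, "amp", carrier_frequency = 0.9,
               amplitude_mean = 0.5, amplitude_sd = 0.1,
               boundary_jitter_sd = 5e5, role = "ubiquitous"),
    aberration("4", 0, 25 * Mb, "del", carrier_frequency = 0.9,
               amplitude_mean = 0.5, amplitude_sd = 0.1,
               boundary_jitter_sd = 5e5, role = "ubiquitous"),
    aberration("6", 0, 25 * Mb, "del", carrier_frequency = 0.9,
               amplitude_mean = 0.5, amplitude_sd = 0.1,
               boundary_jitter_sd = 5e5, role = "ubiquitous")
  )
  sim_config(genome = tg, archetypes = archetypes,
             shared_ubiquitous = ubiq, passenger_rate = 10,
             passenger_size = c(2e5, 2e7), passenger_amplitude_sd = 0.4,
             seed = seed)
}

#' Tiny hand-enumerable fixture cohort
#'
#' Three samples on a 2-chromosome genome (10 Mb each, two 5-Mb cytobands
#' per chromosome, one gene per band), seven segments in total. Every
#' downstream quantity (feature-matrix entries, merges, signatures) can be
#' computed by hand from this table.
#'
#' @return list: `segments`, `metadata`, `genome`, `cytobands`, `genes`.
#' @export
toy_fixture <- function() {
  genome <- tibble::tibble(chrom = c("1", "2"), length = c(1e7, 1e7))
  cytobands <- tibble::tibble(
    feature_id = c("1p", "1q", "2p", "2q"),
    chrom = c("1", "1", "2", "2"),
    start = c(0, 5e6, 0, 5e6), end = c(5e6, 1e7, 5e6, 1e7),
    kind = "cytoband")
  genes <- tibble::tibble(
    feature_id = c("GA", "GB", "GC", "GD"),
    chrom = c("1", "1", "2", "2"),
    start = c(1e6, 6e6, 1e6, 6e6), end = c(2e6, 7e6, 2e6, 7e6),
    kind = "gene")
  segments <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S3", "S3", "S3", "S3"),
    chrom = c("1", "2", "1", "1", "1", "2", "2"),
    start = c(0, 5e6, 2.5e6, 0, 5e6, 0, 2e6),
    end = c(5e6, 1e7, 7.5e6, 2.5e6, 6e6, 1e6, 3e6),
    value = c(0.5, -1.0, 1.0, -0.5, 0.25, 1.0, -0.75))
  metadata <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    icdo_morphology = c("8140/3", "8140/3", "8500/3"),
    icdo_topography = c("C34.9", "C34.9", "C50.9"),
    organ = c("lung", "lung", "breast"))
  validate_segments(segments, genome = genome, context = "toy fixture")
  list(segments = segments, metadata = metadata, genome = genome,
       cytobands = cytobands, genes = genes)
}
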