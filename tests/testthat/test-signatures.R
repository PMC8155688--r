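# Subtype grouping, signature derivation, correlation merging, clustering,
# and gene-family enrichment.

make_meta <- function(n, topo, morph, organ = "lung") {
  tibble::tibble(sample_id = sprintf("%s_%s_%03d", topo, gsub("/", "", morph),
                                     seq_len(n)),
                 icdo_morphology = morph, icdo_topography = topo,
                 organ = organ)
}

test_that("subtype grouping applies the strict <50 rule", {
  meta <- dplyr::bind_rows(make_meta(50, "C34.9", "8140/3"),
                           make_meta(49, "C34.9", "8070/3"),
                           make_meta(60, "C50.9", "8500/3", "breast"))
  groups <- group_subtypes(meta, min_samples = 50)
  expect_setequal(groups$label, c("C34.9|8140/3", "C50.9|8500/3"))
  expect_equal(attr(groups, "dropped"), "C34.9|8070/3")  # 49 -> dropped
  expect_equal(groups$n[groups$label == "C34.9|8140/3"], 50)  # 50 -> kept

  incomplete <- dplyr::bind_rows(meta, tibble::tibble(
    sample_id = "X1", icdo_morphology = "", icdo_topography = "C34.9",
    organ = "lung"))
  expect_warning(group_subtypes(incomplete, min_samples = 50), "excluded")

  expect_error(group_subtypes(make_meta(5, "C34.9", "8140/3"),
                              min_samples = 50), "no group")
})

# A gene matrix with a controllable enrichment: the first `n_hot` samples
# carry three co-occurring hot genes (distinct amplitudes, so signatures
# have a non-degenerate intensity profile) vs a background alteration rate.
enrich_matrix <- function(n_group = 100, n_bg = 400, n_hot = 80,
                          bg_rate = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_group + n_bg
  carrier <- c(rep(1, n_hot), rep(0, n_group - n_hot),
               rbinom(n_bg, 1, bg_rate))
  cold <- rbinom(n, 1, bg_rate) * 0.6
  tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                 H1__amp = carrier * 0.8, H2__amp = carrier * 0.5,
                 H3__amp = carrier * 0.3, C__amp = cold)
}

panel_hc <- tibble::tibble(feature_id = c("H1", "H2", "H3", "C"),
                           channel = "amp",
                           weight = c(1, 0.9, 0.85, 0.8), selected = TRUE)

test_that("signatures keep genes enriched above the cohort background", {
  gm <- enrich_matrix()
  group <- list(label = "G", sample_ids = list(gm$sample_id[1:100]))
  sig <- subtype_signature(group, gm, panel_hc, alpha = 0.05)
  expect_setequal(sig$gene, c("H1", "H2", "H3"))  # 80/100 vs bg ~0.1
  expect_true(all(sig$q_value < 1e-10))
  expect_equal(sig$frequency, rep(0.8, 3))
  expect_equal(sig$intensity[sig$gene == "H1"], mean(gm$H1__amp[1:100]))

  # a group that IS the whole cohort can never be enriched over itself
  all_g <- list(label = "all", sample_ids = list(gm$sample_id))
  expect_equal(nrow(subtype_signature(all_g, gm, panel_hc)), 0)

  # genes at exactly the background frequency are excluded
  gm2 <- gm
  gm2$H1__amp <- gm2$C__amp
  gm2$H2__amp <- gm2$C__amp
  gm2$H3__amp <- gm2$C__amp
  expect_equal(nrow(subtype_signature(group, gm2, panel_hc)), 0)

  expect_error(subtype_signature(list(label = "e", sample_ids = list(character())),
                                 gm, panel_hc), "empty group")
})

test_that("signature correlation works on the union of entries", {
  a <- tibble::tibble(label = "a", gene = c("g1", "g2"), channel = "amp",
                      frequency = 1, intensity = c(0.8, 0.4), q_value = 0.01)
  expect_equal(signature_correlation(a, a), 1)
  # scale invariance of Pearson
  half <- dplyr::mutate(a, intensity = intensity / 2)
  expect_equal(signature_correlation(a, half), 1)
  # disjoint gene sets with equal intensities anti-correlate
  b <- dplyr::mutate(a, gene = c("g3", "g4"))
  expect_lt(signature_correlation(a, b), 0)
  empty <- a[0, ]
  expect_warning(r <- signature_correlation(empty, empty), "undefined")
  expect_true(is.na(r))
})

test_that("merging is strict at the threshold and regenerates signatures", {
  gm <- enrich_matrix(n_group = 200, n_bg = 300, n_hot = 150, seed = 2)
  ids <- gm$sample_id
  groups <- tibble::tibble(
    label = c("C1|m1", "C1|m2"), topography = "C1",
    morphology = c("m1", "m2"), organ = "lung", n = 100,
    sample_ids = list(ids[1:100], ids[101:200]))
  sigs <- lapply(1:2, function(i)
    subtype_signature(groups[i, ], gm, panel_hc))
  r <- signature_correlation(sigs[[1]], sigs[[2]])
  expect_gt(r, 0.99)  # same generating process

  merged <- merge_subtypes(groups, gm, panel_hc, r_threshold = 0.9)
  expect_equal(nrow(merged$groups), 1)
  expect_equal(merged$groups$n, 200)
  expect_equal(nrow(merged$merge_log), 1)
  expect_equal(unique(merged$label_map$final_label), merged$groups$label)
  # the merged signature is regenerated from the union of members
  expect_equal(merged$signatures,
               subtype_signature(merged$groups[1, ], gm, panel_hc))

  # strictly-greater rule: threshold at exactly r -> no merge
  not_merged <- merge_subtypes(groups, gm, panel_hc, r_threshold = r)
  expect_equal(nrow(not_merged$groups), 2)
  merged2 <- merge_subtypes(groups, gm, panel_hc, r_threshold = r - 1e-9)
  expect_equal(nrow(merged2$groups), 1)
})

test_that("the morphology hierarchy decides merge direction", {
  gm <- enrich_matrix(n_group = 200, n_bg = 300, n_hot = 200, seed = 3)
  ids <- gm$sample_id
  groups <- tibble::tibble(
    label = c("C1|specific", "C1|general"), topography = "C1",
    morphology = c("specific", "general"), organ = "lung",
    n = c(120, 80),  # specific is LARGER; hierarchy must still win
    sample_ids = list(ids[1:120], ids[121:200]))
  hier <- tibble::tibble(child = "specific", parent = "general")
  merged <- merge_subtypes(groups, gm, panel_hc, r_threshold = 0.5,
                           hierarchy = hier)
  expect_equal(merged$groups$label, "C1|general")
  expect_equal(merged$merge_log$absorbed, "C1|specific")

  # without a hierarchy the larger group absorbs the smaller
  merged2 <- merge_subtypes(groups, gm, panel_hc, r_threshold = 0.5)
  expect_equal(merged2$groups$label, "C1|specific")

  cyc <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"))
  groups_cyc <- dplyr::mutate(groups, morphology = c("a", "b"))
  expect_error(merge_subtypes(groups_cyc, gm, panel_hc, r_threshold = 0.5,
                              hierarchy = cyc), "cyclic")
})

test_that("merging is order-invariant and leaves no within-organ pair above r", {
  tp <- list(gene_matrix = enrich_matrix(n_group = 300, n_bg = 200,
                                         n_hot = 240, seed = 4))
  ids <- tp$gene_matrix$sample_id
  groups <- tibble::tibble(
    label = c("C1|a", "C1|b", "C1|c"), topography = "C1",
    morphology = c("a", "b", "c"), organ = "lung", n = 100,
    sample_ids = list(ids[1:100], ids[101:200], ids[201:300]))
  m1 <- merge_subtypes(groups, tp$gene_matrix, panel_hc, r_threshold = 0.9)
  m2 <- merge_subtypes(groups[c(3, 1, 2), ], tp$gene_matrix, panel_hc,
                       r_threshold = 0.9)
  expect_setequal(m1$groups$label, m2$groups$label)
  expect_lte(nrow(m1$merge_log), nrow(groups) - 1)
  # every sample belongs to exactly one post-merge subtype
  expect_setequal(unlist(m1$groups$sample_ids), ids[1:300])
  expect_equal(anyDuplicated(unlist(m1$groups$sample_ids)), 0)
  # surviving within-organ pairs are all at or below the threshold
  if (nrow(m1$groups) > 1) {
    sigs <- lapply(seq_len(nrow(m1$groups)), function(i)
      subtype_signature(m1$groups[i, ], tp$gene_matrix, panel_hc))
    for (i in 1:(length(sigs) - 1)) for (j in (i + 1):length(sigs)) {
      r <- suppressWarnings(signature_correlation(sigs[[i]], sigs[[j]]))
      if (!is.na(r)) expect_lte(r, 0.9)
    }
  }
})

test_that("signature clustering joins identical signatures first", {
  base <- tibble::tibble(gene = c("g1", "g2", "g3"), channel = "amp",
                         frequency = 1, q_value = 0.01)
  sigs <- dplyr::bind_rows(
    dplyr::mutate(base, label = "s1", intensity = c(1, 0.2, 0)),
    dplyr::mutate(base, label = "s2", intensity = c(1, 0.2, 0)),
    dplyr::mutate(base, label = "s3", intensity = c(0, 0.1, 1)))
  cl <- cluster_signatures(sigs)
  # the identical pair merges at height 0, before s3 joins
  expect_equal(cl$hclust$height[1], 0)
  first_pair <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first_pair, c("s1", "s2"))
  expect_equal(cl$dist, t(cl$dist))
  expect_true(all(diag(cl$dist) == 0))
  # deterministic leaf order
  expect_equal(cl$order, cluster_signatures(sigs)$order)
  expect_error(cluster_signatures(sigs[sigs$label == "s1", ]), ">= 2")
})

test_that("family enrichment applies the binomial test and >= 5-gene rule", {
  background <- sprintf("g%04d", 1:1000)
  # family of 10 genes, all 10 in a 50-gene panel: strong enrichment
  fam10 <- tibble::tibble(gene = background[1:10], family = "F10")
  panel <- tibble::tibble(feature_id = background[1:50], channel = "amp",
                          weight = 1, selected = TRUE)
  res <- family_enrichment(panel, fam10, background)
  expect_true(res$enriched[res$family == "F10"])
  expect_equal(res$n_panel[res$family == "F10"], 10)
  # exact binomial tail: P(X >= 10), X ~ Bin(50, 0.01)
  expect_equal(res$p_value[res$family == "F10"],
               pbinom(9, 50, 0.01, lower.tail = FALSE))

  # significant but with only 4 panel genes: fails the >= 5 rule
  fam4 <- tibble::tibble(gene = background[1:4], family = "F4")
  res4 <- family_enrichment(panel, fam4, background)
  expect_lt(res4$p_value, 0.05)
  expect_false(res4$enriched)

  # family at exactly its background proportion is not significant
  famflat <- tibble::tibble(gene = background[seq(1, 1000, by = 10)],
                            family = "FLAT")  # 10% of background
  panel_flat <- tibble::tibble(feature_id = background[1:100],
                               channel = "amp", weight = 1, selected = TRUE)
  resf <- family_enrichment(panel_flat, famflat, background)
  expect_false(resf$enriched[resf$family == "FLAT"])

  expect_error(family_enrichment(panel, fam10, character()), "empty background")
})
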