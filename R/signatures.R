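# Subtype grouping, per-subtype CNA signatures, correlation-based subtype
# merging, signature clustering, and gene-family enrichment.

#' Group samples into (topography, morphology) subtypes
#'
#' One group per distinct ICD-O (topography, morphology) pair; samples with
#' an empty code are excluded with a warning. Groups below `min_samples`
#' members are dropped (strict `<`: a group of exactly `min_samples` is
#' retained) and logged in the `dropped` attribute.
#'
#' @param metadata QC-passed metadata tibble.
#' @param min_samples minimum group size (default 50).
#' @return tibble with columns `label` ("topography|morphology"),
#'   `topography`, `morphology`, `organ`, `n`, `sample_ids` (list column).
#' @export
group_subtypes <- function(metadata, min_samples = 50) {
  miss <- is.na(metadata$icdo_morphology) | metadata$icdo_morphology == "" |
    is.na(metadata$icdo_topography) | metadata$icdo_topography == ""
  if (any(miss)) {
    warn(sprintf("%d sample(s) without complete ICD-O codes excluded from grouping",
                 sum(miss)))
  }
  meta <- metadata[!miss, , drop = FALSE]
  groups <- meta |>
    dplyr::group_by(topography = .data$icdo_topography,
                    morphology = .data$icdo_morphology) |>
    dplyr::summarise(organ = dplyr::first(.data$organ),
                     n = dplyr::n(),
                     sample_ids = list(.data$sample_id), .groups = "drop") |>
    dplyr::mutate(label = paste(.data$topography, .data$morphology,
                                sep = "|"), .before = 1) |>
    dplyr::arrange(.data$label)
  kept <- groups[groups$n >= min_samples, , drop = FALSE]
  if (nrow(kept) == 0) stopf("group_subtypes: no group has >= %d samples",
                             min_samples)
  attr(kept, "dropped") <- groups$label[groups$n < min_samples]
  kept
}

#' Derive a subtype's CNA signature
#'
#' For every selected (gene, channel) of the panel, the number of group
#' samples with a nonzero normalized value is tested against the cohort-wide
#' background alteration frequency with a one-sided (greater) exact binomial
#' test; p-values are Benjamini-Hochberg adjusted across all tests within
#' the group. The signature keeps entries with `q < alpha` whose group
#' frequency exceeds the background frequency; its intensity is the group
#' mean of the normalized values.
#'
#' @param group one row of [group_subtypes()] output (or any list with
#'   `label` and `sample_ids`).
#' @param gene_matrix normalized gene feature matrix covering the cohort
#'   (the background) including the group members.
#' @param panel gene relevance panel with a `selected` column.
#' @param alpha FDR level (default 0.05).
#' @return signature tibble: `label`, `gene`, `channel`, `frequency`,
#'   `intensity`, `q_value`; zero rows when nothing is significantly
#'   enriched.
#' @export
subtype_signature <- function(group, gene_matrix, panel, alpha = 0.05) {
  sample_ids <- if (is.list(group$sample_ids)) group$sample_ids[[1]] else
    group$sample_ids
  label <- group$label[[1]]
  if (length(sample_ids) == 0) stopf("subtype_signature: empty group '%s'", label)
  idx <- match(sample_ids, gene_matrix$sample_id)
  if (anyNA(idx)) {
    stopf("subtype_signature: %d group sample(s) missing from the matrix",
          sum(is.na(idx)))
  }
  sel <- panel[panel$selected, , drop = FALSE]
  cols <- axis_col(sel$feature_id, sel$channel)
  V <- fm_values(gene_matrix)[, cols, drop = FALSE]
  altered <- V > 0
  bg <- colMeans(altered)
  n <- length(idx)
  k <- colSums(altered[idx, , drop = FALSE])
  p <- pbinom(k - 1, n, bg, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  freq <- k / n
  keep <- q < alpha & freq > bg
  tibble::tibble(
    label = label,
    gene = sel$feature_id[keep],
    channel = sel$channel[keep],
    frequency = unname(freq[keep]),
    intensity = unname(colMeans(V[idx, keep, drop = FALSE])),
    q_value = unname(q[keep])
  )
}

# Intensity vectors of two signatures on the union of their entries.
signature_union_vectors <- function(a, b) {
  keys <- unique(rbind(data.frame(gene = a$gene, channel = a$channel),
                       data.frame(gene = b$gene, channel = b$channel)))
  lookup <- function(sig) {
    i <- match(paste(keys$gene, keys$channel),
               paste(sig$gene, sig$channel))
    v <- sig$intensity[i]
    v[is.na(v)] <- 0
    v
  }
  list(x = lookup(a), y = lookup(b))
}

#' Pearson correlation of two subtype signatures
#'
#' Computed over the union of the two signatures' (gene, channel) entries,
#' taking intensity 0 where a signature lacks an entry.
#'
#' @param a,b signature tibbles from [subtype_signature()].
#' @return Pearson r, or `NA` with a warning when the correlation is
#'   undefined (both signatures empty, or a constant union vector).
#' @export
signature_correlation <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) {
    warn("signature_correlation: both signatures empty; correlation undefined")
    return(NA_real_)
  }
  v <- signature_union_vectors(a, b)
  if (length(v$x) < 2 || stats::sd(v$x) == 0 || stats::sd(v$y) == 0) {
    warn("signature_correlation: correlation undefined (constant vector)")
    return(NA_real_)
  }
  cor(v$x, v$y)
}

# Depth of a morphology code in the parent map (root depth 0); NA if the
# code is absent from the hierarchy. Errors on cycles.
morphology_depth <- function(code, hierarchy) {
  if (is.null(hierarchy) || !code %in% hierarchy$child) {
    return(if (!is.null(hierarchy) && code %in% hierarchy$parent) 0L else
             NA_integer_)
  }
  depth <- 0L
  seen <- character()
  cur <- code
  while (cur %in% hierarchy$child) {
    if (cur %in% seen) stopf("cyclic morphology hierarchy at '%s'", cur)
    seen <- c(seen, cur)
    cur <- hierarchy$parent[match(cur, hierarchy$child)]
    depth <- depth + 1L
  }
  depth
}

# TRUE if `anc` is an ancestor (more general term) of `code`.
is_ancestor <- function(anc, code, hierarchy) {
  if (is.null(hierarchy)) return(FALSE)
  cur <- code
  seen <- character()
  while (cur %in% hierarchy$child) {
    if (cur %in% seen) stopf("cyclic morphology hierarchy at '%s'", cur)
    seen <- c(seen, cur)
    cur <- hierarchy$parent[match(cur, hierarchy$child)]
    if (identical(cur, anc)) return(TRUE)
  }
  FALSE
}

#' Merge highly correlated subtypes within each organ
#'
#' Within each organ, signature correlations are computed for all subtype
#' pairs and the pair with the highest r strictly above `r_threshold` is
#' merged; the subtype with the more specific morphology is absorbed into
#' the more general one (by the supplied hierarchy; same or unknown level:
#' into the larger group, ties broken by lexicographic label). The merged
#' group's signature is regenerated and the process repeats until no pair
#' exceeds the threshold. Greedy and deterministic.
#'
#' @param groups subtype tibble from [group_subtypes()].
#' @param gene_matrix,panel,alpha as in [subtype_signature()].
#' @param r_threshold merge when r is strictly greater (default 0.9).
#' @param hierarchy optional tibble with columns `child`, `parent` mapping a
#'   morphology code to its more general term; cycles are an error.
#' @return list: `groups` (post-merge subtype tibble), `signatures`
#'   (combined signature tibble of the surviving subtypes), `label_map`
#'   (tibble `original_label` -> `final_label` for every input subtype) and
#'   `merge_log` (one row per merge: organ, absorbed, into, r, iteration).
#' @export
merge_subtypes <- function(groups, gene_matrix, panel, r_threshold = 0.9,
                           hierarchy = NULL, alpha = 0.05) {
  if (!is.null(hierarchy)) {
    for (code in unique(hierarchy$child)) morphology_depth(code, hierarchy)
  }
  groups <- dplyr::arrange(groups, .data$label)
  sigs <- lapply(seq_len(nrow(groups)), function(i)
    subtype_signature(groups[i, ], gene_matrix, panel, alpha = alpha))
  names(sigs) <- groups$label
  map <- setNames(groups$label, groups$label)
  log <- list()
  iter <- 0L

  repeat {
    merged_any <- FALSE
    for (org in sort(unique(groups$organ))) {
      idx <- which(groups$organ == org)
      if (length(idx) < 2) next
      best <- NULL
      pairs <- utils::combn(sort(idx), 2)
      for (pc in seq_len(ncol(pairs))) {
        i <- pairs[1, pc]; j <- pairs[2, pc]
        r <- suppressWarnings(
          signature_correlation(sigs[[groups$label[i]]],
                                sigs[[groups$label[j]]]))
        if (!is.na(r) && r > r_threshold &&
            (is.null(best) || r > best$r)) {
          best <- list(i = i, j = j, r = r)
        }
      }
      if (is.null(best)) next
      iter <- iter + 1L
      merged_any <- TRUE
      gi <- groups[best$i, ]; gj <- groups[best$j, ]
      # decide the surviving (more general) subtype
      win <- if (is_ancestor(gi$morphology, gj$morphology, hierarchy)) {
        best$i
      } else if (is_ancestor(gj$morphology, gi$morphology, hierarchy)) {
        best$j
      } else {
        di <- morphology_depth(gi$morphology, hierarchy)
        dj <- morphology_depth(gj$morphology, hierarchy)
        if (!is.na(di) && !is.na(dj) && di != dj) {
          if (di < dj) best$i else best$j
        } else if (gi$n != gj$n) {
          if (gi$n > gj$n) best$i else best$j
        } else if (gi$label <= gj$label) best$i else best$j
      }
      lose <- if (win == best$i) best$j else best$i
      log[[length(log) + 1]] <- tibble::tibble(
        organ = org, absorbed = groups$label[lose],
        into = groups$label[win], r = best$r, iteration = iter)
      map[map == groups$label[lose]] <- groups$label[win]
      groups$sample_ids[[win]] <- c(groups$sample_ids[[win]],
                                    groups$sample_ids[[lose]])
      groups$n[win] <- length(groups$sample_ids[[win]])
      sigs[[groups$label[win]]] <-
        subtype_signature(groups[win, ], gene_matrix, panel, alpha = alpha)
      sigs[[groups$label[lose]]] <- NULL
      groups <- groups[-lose, , drop = FALSE]
    }
    if (!merged_any) break
  }

  list(
    groups = groups,
    signatures = dplyr::bind_rows(sigs[groups$label]),
    label_map = tibble::tibble(original_label = names(map),
                               final_label = unname(map)),
    merge_log = if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(organ = character(), absorbed = character(),
                     into = character(), r = double(), iteration = integer())
  )
}

#' Hierarchically cluster subtype signatures for reporting
#'
#' Average-linkage hierarchical clustering on correlation distance (1 - r)
#' between signature intensity vectors over the union of all entries.
#'
#' @param signatures combined signature tibble (>= 2 distinct labels).
#' @return list: `hclust` (the stats::hclust tree), `order` (leaf labels in
#'   plotting order), `dist` (the symmetric distance matrix).
#' @export
cluster_signatures <- function(signatures) {
  labels <- sort(unique(signatures$label))
  if (length(labels) < 2) stopf("cluster_signatures: need >= 2 signatures")
  keys <- unique(paste(signatures$gene, signatures$channel, sep = "__"))
  M <- matrix(0, nrow = length(labels), ncol = length(keys),
              dimnames = list(labels, keys))
  M[cbind(match(signatures$label, labels),
          match(paste(signatures$gene, signatures$channel, sep = "__"),
                keys))] <- signatures$intensity
  r <- suppressWarnings(cor(t(M)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  d <- 1 - r
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, order = labels[hc$order], dist = d)
}

#' Gene-family enrichment of the selected panel
#'
#' Per gene family and channel, tests whether the panel's selected genes
#' over-represent the family relative to the background gene set with a
#' one-sided (greater) binomial test. A family is reported as enriched when
#' `p < alpha` and at least `min_genes` panel genes belong to it.
#'
#' @param panel gene relevance panel with a `selected` column.
#' @param family_map tibble with columns `gene`, `family`.
#' @param background character vector of background gene ids (all genes
#'   entering phase 2).
#' @param min_genes minimum panel members per reported family (default 5).
#' @param alpha significance level (default 0.05).
#' @return tibble: `family`, `channel`, `n_panel`, `n_background`,
#'   `prop_background`, `p_value`, `enriched`.
#' @export
family_enrichment <- function(panel, family_map, background, min_genes = 5,
                              alpha = 0.05) {
  if (length(background) == 0) stopf("family_enrichment: empty background")
  fam_bg <- family_map[family_map$gene %in% background, , drop = FALSE]
  if (nrow(fam_bg) == 0) stopf("family_enrichment: family map covers no background gene")
  N <- length(unique(background))
  out <- list()
  for (ch in c("amp", "del")) {
    pg <- unique(panel$feature_id[panel$selected & panel$channel == ch])
    pg <- pg[pg %in% background]
    n <- length(pg)
    if (n == 0) next
    for (fam in sort(unique(fam_bg$family))) {
      members <- unique(fam_bg$gene[fam_bg$family == fam])
      x <- sum(pg %in% members)
      p0 <- length(members) / N
      pval <- pbinom(x - 1, n, p0, lower.tail = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        family = fam, channel = ch, n_panel = x,
        n_background = length(members), prop_background = p0,
        p_value = pval, enriched = pval < alpha && x >= min_genes)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(family = character(), channel = character(),
                          n_panel = integer(), n_background = integer(),
                          prop_background = double(), p_value = double(),
                          enriched = logical()))
  }
  dplyr::bind_rows(out)
}
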