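# Independent oracles used by property and acceptance tests. These stay
# deliberately naive (explicit loops, union-find) so they share no code with
# the implementation they check.

# Build a standalone random encoder as a cna_autoencoder-shaped object.
make_encoder <- function(sizes, bias_free = TRUE, seed = 1) {
  set.seed(seed)
  L <- length(sizes) - 1L
  weights <- lapply(seq_len(L), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1]), nrow = sizes[l])
  })
  biases <- lapply(seq_len(L), function(l) {
    if (bias_free) numeric(sizes[l + 1]) else rnorm(sizes[l + 1])
  })
  structure(list(
    weights = weights, biases = biases, layer_sizes = sizes,
    encoder_layers = L, activation = "relu", output_activation = "relu",
    noise_fraction = 0, seed = seed, loss_history = numeric(0),
    input_axis = paste0("f", seq_len(sizes[1]), "__amp"),
    config = list(epsilon = 0)
  ), class = "cna_autoencoder")
}

# Brute-force LRP: materializes every a_j * w_jk share explicitly, neuron by
# neuron, following the propagation rule with the bias as the index-0 term.
brute_lrp <- function(model, x, epsilon = 0) {
  L <- model$encoder_layers
  a <- list(as.numeric(x))
  for (l in seq_len(L)) {
    z <- as.numeric(a[[l]] %*% model$weights[[l]]) + model$biases[[l]]
    a[[l + 1]] <- pmax(z, 0)
  }
  R <- a[[L + 1]]
  for (l in rev(seq_len(L))) {
    W <- model$weights[[l]]
    Rj <- numeric(length(a[[l]]))
    for (k in seq_along(R)) {
      z <- model$biases[[l]][k]
      for (j in seq_along(a[[l]])) z <- z + a[[l]][j] * W[j, k]
      if (abs(z) < epsilon) z <- z + epsilon * (if (z >= 0) 1 else -1)
      if (R[k] == 0) next
      for (j in seq_along(a[[l]])) {
        Rj[j] <- Rj[j] + a[[l]][j] * W[j, k] / z * R[k]
      }
    }
    R <- Rj
  }
  R
}

# Transitive-closure interval merging via union-find over all pairs with
# inter-interval gap <= d (same chromosome only).
brute_group_members <- function(genes, d) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j || genes$chrom[i] != genes$chrom[j]) next
      gap <- max(genes$start[i], genes$start[j]) -
        min(genes$end[i], genes$end[j])
      if (gap <= d) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(genes$feature_id, roots))
}

# Canonical set-of-sets form for comparing partitions.
partition_key <- function(member_sets) {
  sort(vapply(member_sets, function(m) paste(sort(m), collapse = ","), ""))
}

# Random sorted gene table on up to 3 chromosomes.
random_gene_table <- function(n, seed) {
  set.seed(seed)
  chrom <- sort(sample(c("1", "2", "3"), n, replace = TRUE))
  start <- round(runif(n, 0, 8e7))
  len <- round(runif(n, 1e4, 2e6))
  g <- tibble::tibble(feature_id = sprintf("g%03d", seq_len(n)),
                      chrom = chrom, start = start, end = start + len,
                      kind = "gene")
  g[order(match(g$chrom, c("1", "2", "3")), g$start), ]
}
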