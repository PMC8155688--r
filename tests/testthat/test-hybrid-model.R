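# Autoencoder training, LRP propagation, relevance aggregation and
# thresholding: the feature-extraction core.

rank_k_matrix <- function(n, d, k, seed) {
  set.seed(seed)
  X <- matrix(runif(n * k), n) %*% matrix(runif(k * d), k)
  X <- X / max(X)
  colnames(X) <- paste0("f", seq_len(d), "__amp")
  X
}

test_that("training reduces reconstruction error and is seed-deterministic", {
  X <- rank_k_matrix(200, 40, 3, seed = 3)
  m <- train_autoencoder(X, ae_config(seed = 5, hidden = c(16, 8),
                                      epochs = 40))
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
  m2 <- train_autoencoder(X, ae_config(seed = 5, hidden = c(16, 8),
                                       epochs = 40))
  expect_identical(m$weights, m2$weights)
  expect_identical(m$biases, m2$biases)
  m3 <- train_autoencoder(X, ae_config(seed = 6, hidden = c(16, 8),
                                       epochs = 40))
  expect_false(identical(m$weights, m3$weights))
})

test_that("a noiseless linear autoencoder reaches the PCA reconstruction limit", {
  # encoding dimension >= data rank: reconstruction should be near-exact
  X <- rank_k_matrix(60, 10, 2, seed = 8)
  m <- train_autoencoder(
    X, ae_config(seed = 5, hidden = c(8, 4), noise_fraction = 0,
                 epochs = 400, learning_rate = 5e-3, weight_decay = 0),
    activation = "linear", output_activation = "linear")
  expect_lt(mean((reconstruct(m, X) - X)^2), 1e-3)
})

test_that("degenerate training configurations are caught", {
  X <- rank_k_matrix(20, 6, 2, seed = 1)
  expect_warning(train_autoencoder(X, ae_config(seed = 1, hidden = c(8, 6),
                                                epochs = 1)),
                 "identity")
  expect_error(train_autoencoder(X[1, , drop = FALSE],
                                 ae_config(seed = 1, epochs = 1)),
               ">= 2 samples")
  expect_error(train_autoencoder(X * 3, ae_config(seed = 1, epochs = 1)),
               "normalized")
  expect_error(ae_config(seed = 1, noise_fraction = 1), "noise_fraction")
  expect_error(ae_config(), "seed is required")
})

test_that("the propagation rule distributes relevance by activation-weight shares", {
  # one linear unit, inputs a = (1, 1), weights w = (1, 1), bias 0:
  # each input gets share a_j w_j / sum = 1/2 of the output relevance.
  m <- make_encoder(c(2, 1), bias_free = TRUE, seed = 1)
  m$weights[[1]] <- matrix(c(1, 1), nrow = 2)
  x <- c(1, 1)
  # raw reference: output relevance = encoding activation = 2 -> (1, 1)
  expect_equal(unname(lrp_relevance(m, x, epsilon = 0)), c(1, 1))
  # explicit reference shifting output relevance to 1 -> (0.5, 0.5)
  expect_equal(unname(lrp_relevance(m, x, epsilon = 0, reference = 1)),
               c(0.5, 0.5))
  # a zero-activation input receives zero relevance
  expect_equal(unname(lrp_relevance(m, c(2, 0), epsilon = 0))[2], 0)
  expect_error(lrp_relevance(m, c(1, 2, 3)), "features")
})

test_that("relevance is conserved across layers of bias-free networks", {
  for (i in 1:25) {
    sizes <- c(sample(3:20, 1), sample(2:12, 1), sample(2:8, 1))
    m <- make_encoder(sizes, bias_free = TRUE, seed = i)
    set.seed(i + 100)
    x <- runif(sizes[1])
    r_in <- lrp_relevance(m, x, epsilon = 0)
    enc <- encode(m, matrix(x, 1))
    # conservation, relative to the total relevance mass (the signed total
    # cancels catastrophically when shares explode through weak denominators)
    expect_lte(abs(sum(r_in) - sum(enc)),
               1e-6 * max(1e-12, sum(abs(r_in))))
  }
})

test_that("vectorized LRP matches the brute-force share materialization", {
  for (i in 1:25) {
    n_layers <- sample(2:4, 1)
    sizes <- c(sample(4:20, 1), sample(2:15, n_layers - 1, replace = TRUE))
    bias_free <- i %% 2 == 0
    m <- make_encoder(sizes, bias_free = bias_free, seed = i)
    set.seed(i + 500)
    x <- runif(sizes[1])
    got <- unname(lrp_relevance(m, x, epsilon = 0))
    expect_equal(got, brute_lrp(m, x, epsilon = 0), tolerance = 1e-8)
    # with a meaningful stabilizer too
    got_eps <- unname(lrp_relevance(m, x, epsilon = 0.01))
    expect_equal(got_eps, brute_lrp(m, x, epsilon = 0.01), tolerance = 1e-8)
  }
})

test_that("mean-reference relevance propagates encoding deviations", {
  m <- make_encoder(c(4, 2), bias_free = TRUE, seed = 2)
  set.seed(9)
  X <- matrix(runif(20), 5, 4,
              dimnames = list(NULL, paste0("f", 1:4, "__amp")))
  E <- encode(m, X)
  R <- lrp_relevance(m, X, epsilon = 0, reference = "mean")
  # per-sample total relevance equals the total encoding deviation
  expect_equal(unname(rowSums(R)),
               unname(rowSums(sweep(E, 2, colMeans(E)))),
               tolerance = 1e-8)
  expect_error(lrp_relevance(m, X[1, ], reference = "mean"), "multiple rows")
  expect_error(lrp_relevance(m, X, reference = c(1, 2, 3)), "encoding dimension")
})

test_that("relevance aggregation sums |R| and max-normalizes", {
  R <- rbind(c(1, 0), c(1, 2))
  colnames(R) <- c("A__amp", "B__del")
  panel <- aggregate_relevance(R)
  expect_equal(panel$weight, c(1, 1))  # sums (2, 2) -> (1, 1)
  expect_equal(panel$feature_id, c("A", "B"))
  expect_equal(panel$channel, c("amp", "del"))
  # single sample: weights proportional to |relevance|
  single <- aggregate_relevance(R[2, , drop = FALSE])
  expect_equal(single$weight, c(0.5, 1))
  # permutation invariance
  expect_equal(aggregate_relevance(R[c(2, 1), ]), panel)
  expect_error(aggregate_relevance(R * 0), "degenerate")
})

test_that("feature selection thresholds weights with inclusive ties", {
  panel <- tibble::tibble(feature_id = c("a", "b", "c"), channel = "amp",
                          weight = c(0.9, 0.5, 0.1))
  sel <- select_features(panel, threshold = 0.6)
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE))
  # boundary tie kept
  sel2 <- select_features(panel, threshold = 0.5)
  expect_equal(sel2$selected, c(TRUE, TRUE, FALSE))
  # all-equal weights: everything selected at any threshold
  flat <- dplyr::mutate(panel, weight = 1)
  expect_true(all(select_features(flat, threshold = 0.99)$selected))
  # top-fraction mode
  topf <- select_features(panel, threshold = 0.34, mode = "top_fraction")
  expect_equal(sum(topf$selected), 2)  # ceil(0.34 * 3)
  expect_error(select_features(panel, threshold = 0), "threshold")
  expect_error(select_features(panel, threshold = 1), "threshold")
})

test_that("raising the selection threshold never adds a feature", {
  set.seed(12)
  panel <- tibble::tibble(feature_id = sprintf("f%02d", 1:40),
                          channel = "amp", weight = runif(40))
  panel$weight <- panel$weight / max(panel$weight)
  prev <- select_features(panel, threshold = 0.05)$selected
  for (t in seq(0.1, 0.95, by = 0.05)) {
    cur <- select_features(panel, threshold = t)$selected
    expect_true(all(prev | !cur))  # cur is a subset of prev
    prev <- cur
  }
})

test_that("two-phase extraction is reproducible and structured", {
  co <- simulate_cohort(small_scenario())
  tg <- small_scenario()$genome
  cfg <- ae_config(seed = 42, epochs = 25)
  tp <- run_two_phase(co$segments, tg$cytobands, tg$genes, cfg)
  expect_s3_class(tp, "cna_two_phase")
  expect_true(any(tp$cytoband_panel$selected))
  expect_true(any(tp$gene_panel$selected))
  # gene panel features come from genes inside selected cytobands
  expect_true(all(tp$gene_panel$feature_id %in% tp$phase2_genes$feature_id))
  s <- extraction_summary(tp)
  expect_equal(s$n_channel_features[1], 2 * nrow(tg$cytobands))
  expect_equal(s$n_channel_features[3], 2 * nrow(tp$phase2_genes))
  # same config, fresh run: identical panels
  tp2 <- run_two_phase(co$segments, tg$cytobands, tg$genes, cfg)
  expect_equal(tp2$cytoband_panel, tp$cytoband_panel)
  expect_equal(tp2$gene_panel, tp$gene_panel)
})
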