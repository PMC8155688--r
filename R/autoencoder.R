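# Denoising autoencoder: a small fully connected encoder/decoder trained by
# backpropagation with Adam, written on base R matrix operations. The model
# is deliberately compact and exactly reproducible under a seed: weights are
# Glorot-uniform initialized from R's RNG and every training draw (shuffles,
# masking noise) comes from the same stream.

#' Autoencoder / extraction configuration
#'
#' Bundles the tunable parameters of the hybrid feature extractor. Defaults:
#' a mirrored encoder `input -> input/2 -> input/8` with rectifier (ReLU)
#' activations and a sigmoid output layer, masking noise 0.2, Adam with
#' learning rate 1e-3, 200 epochs, batch 64. The seed is mandatory: every
#' stochastic choice in training derives from it.
#'
#' @param seed integer seed (required).
#' @param hidden integer vector of encoder hidden sizes ending in the
#'   encoding dimension; `NULL` (default) uses `c(input/2, input/8)`.
#' @param noise_fraction fraction of input entries masked to 0 during
#'   training (denoising); 0 gives a basic autoencoder.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param weight_decay decoupled L2 weight decay per step (AdamW style;
#'   default 1e-3). Decay is what lets the denoising objective prune input
#'   weights that carry no reconstruction information — without it, weights
#'   from uninformative (e.g. ubiquitous) inputs persist at their random
#'   initialization scale and pollute the relevance ranking.
#' @param epsilon LRP stabilizer added to denominators whose magnitude falls
#'   below it (default 0.01). A meaningful epsilon absorbs the relevance
#'   flowing through weak activations, whose shares are otherwise amplified
#'   without bound; set 0 for exact conservation checks on bias-free
#'   networks.
#' @param threshold relevance selection cutoff on \[0,1\]-normalized weights.
#' @param threshold_mode `"weight"` (absolute cutoff on normalized weight) or
#'   `"top_fraction"` (keep the top `threshold` fraction of features).
#' @param q percentile used by [normalize_matrix()].
#' @param variant `"denoising"` (default) or `"basic"` (forces
#'   `noise_fraction = 0`).
#' @return a list of class `cna_config`.
#' @export
ae_config <- function(seed, hidden = NULL, noise_fraction = 0.2,
                      epochs = 200, batch_size = 64, learning_rate = 1e-3,
                      weight_decay = 1e-3,
                      epsilon = 0.01, threshold = 0.1,
                      threshold_mode = c("weight", "top_fraction"),
                      q = 99, variant = c("denoising", "basic")) {
  if (missing(seed) || is.null(seed)) stopf("ae_config: seed is required")
  variant <- match.arg(variant)
  if (variant == "basic") noise_fraction <- 0
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stopf("noise_fraction must be in [0, 1)")
  }
  structure(list(
    seed = as.integer(seed), hidden = hidden,
    noise_fraction = noise_fraction, epochs = epochs,
    batch_size = batch_size, learning_rate = learning_rate,
    weight_decay = weight_decay,
    epsilon = epsilon, threshold = threshold,
    threshold_mode = match.arg(threshold_mode), q = q, variant = variant
  ), class = "cna_config")
}

default_hidden <- function(d) {
  c(max(ceiling(d / 2), 2L), max(ceiling(d / 8), 2L))
}

# Run a block with a private RNG state so training does not disturb the
# caller's stream (and is unaffected by it).
with_private_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a (denoising) autoencoder on a feature matrix
#'
#' Minimizes mean squared reconstruction error of the clean inputs from
#' noise-corrupted copies (a random `noise_fraction` of entries masked to 0
#' per presentation). Hidden layers (including the encoding) use ReLU; the
#' output layer is sigmoid, matching inputs normalized to \[0,1\]. The
#' optimizer is Adam. Fully deterministic given `config$seed`.
#'
#' @param fm normalized feature-matrix tibble (values in \[0,1\], >= 2
#'   samples), or a plain numeric matrix.
#' @param config an [ae_config()].
#' @param activation hidden activation; only `"relu"` and `"linear"` are
#'   supported (`"linear"` exists for the PCA-limit sanity checks).
#' @param output_activation `"sigmoid"` (default) or `"linear"`.
#' @return object of class `cna_autoencoder`: `weights`, `biases` (one per
#'   layer, encoder then mirrored decoder), `layer_sizes`, activations,
#'   `loss_history` (mean batch MSE per epoch), `input_axis`, and the config.
#' @export
train_autoencoder <- function(fm, config, activation = "relu",
                              output_activation = "sigmoid") {
  X <- if (is.matrix(fm)) fm else fm_values(fm)
  if (nrow(X) < 2) stopf("train_autoencoder: need >= 2 samples")
  if (min(X) < 0 || max(X) > 1 + 1e-12) {
    stopf("train_autoencoder: matrix must be normalized to [0,1]")
  }
  d <- ncol(X)
  hidden <- config$hidden %||% default_hidden(d)
  enc_dim <- hidden[length(hidden)]
  if (enc_dim >= d) {
    warn("encoding dimension >= input dimension: autoencoder may learn the identity")
  }
  sizes <- c(d, hidden, rev(hidden)[-1], d)
  n_layers <- length(sizes) - 1L

  with_private_seed(config$seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -s, s),
                       nrow = sizes[l])
      b[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L
    n <- nrow(X)
    batch <- min(config$batch_size, n)
    loss_history <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + batch - 1L, n)]
        Xc <- X[idx, , drop = FALSE]
        Xin <- Xc
        if (config$noise_fraction > 0) {
          mask <- matrix(runif(length(Xin)) < config$noise_fraction,
                         nrow = nrow(Xin))
          Xin[mask] <- 0
        }
        # forward
        A <- vector("list", n_layers + 1L)
        Z <- vector("list", n_layers)
        A[[1]] <- Xin
        for (l in seq_len(n_layers)) {
          Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
          A[[l + 1]] <- if (l < n_layers) {
            if (activation == "relu") relu(Z[[l]]) else Z[[l]]
          } else {
            if (output_activation == "sigmoid") sigmoid(Z[[l]]) else Z[[l]]
          }
        }
        out <- A[[n_layers + 1L]]
        loss <- mean((out - Xc)^2)
        if (!is.finite(loss)) stopf("train_autoencoder: NaN loss at epoch %d", epoch)
        ep_loss <- ep_loss + loss * length(idx)
        # backward
        delta <- 2 * (out - Xc) / length(out)
        if (output_activation == "sigmoid") delta <- delta * out * (1 - out)
        for (l in rev(seq_len(n_layers))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(W[[l]])
            if (activation == "relu") delta <- delta * (Z[[l - 1]] > 0)
          }
          step_l <- step + 1L  # shared step counter per minibatch
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^step_l)
          vhW <- vW[[l]] / (1 - beta2^step_l)
          mhb <- mb[[l]] / (1 - beta1^step_l)
          vhb <- vb[[l]] / (1 - beta2^step_l)
          W[[l]] <- W[[l]] - lr * (mhW / (sqrt(vhW) + adam_eps) +
                                     (config$weight_decay %||% 0) * W[[l]])
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + adam_eps)
        }
        step <- step + 1L
      }
      loss_history[epoch] <- ep_loss / n
    }

    structure(list(
      weights = W, biases = b, layer_sizes = sizes,
      encoder_layers = length(hidden),
      activation = activation, output_activation = output_activation,
      noise_fraction = config$noise_fraction, seed = config$seed,
      loss_history = loss_history,
      input_axis = colnames(X), config = config
    ), class = "cna_autoencoder")
  })
}

# Forward pass through the first `n_layers` layers (default: whole network).
ae_forward <- function(model, X, n_layers = length(model$weights)) {
  A <- vector("list", n_layers + 1L)
  A[[1]] <- X
  total <- length(model$weights)
  for (l in seq_len(n_layers)) {
    Zl <- sweep(A[[l]] %*% model$weights[[l]], 2, model$biases[[l]], "+")
    A[[l + 1]] <- if (l < total) {
      if (model$activation == "relu") relu(Zl) else Zl
    } else {
      switch(model$output_activation,
             sigmoid = sigmoid(Zl), relu = relu(Zl), Zl)
    }
  }
  A
}

#' Reconstruct inputs through the autoencoder
#' @param model a `cna_autoencoder`.
#' @param fm feature-matrix tibble or numeric matrix.
#' @return numeric matrix of reconstructions (samples x input features).
#' @export
reconstruct <- function(model, fm) {
  X <- if (is.matrix(fm)) fm else fm_values(fm)
  A <- ae_forward(model, X)
  out <- A[[length(A)]]
  dimnames(out) <- dimnames(X)
  out
}

#' Encode inputs to the bottleneck representation
#' @inheritParams reconstruct
#' @return numeric matrix (samples x encoding dimension).
#' @export
encode <- function(model, fm) {
  X <- if (is.matrix(fm)) fm else fm_values(fm)
  A <- ae_forward(model, X, n_layers = model$encoder_layers)
  A[[length(A)]]
}

#' Layer-wise relevance propagation through the encoder
#'
#' Distributes each sample's encoding activation back to its input features
#' with the basic LRP rule: the relevance of neuron j in the layer below is
#' `R_j = sum_k a_j * w_jk / (b_k + sum_j a_j * w_jk) * R_k`, where the
#' denominator includes the bias as the index-0 term. The initial relevance
#' is the encoding activation vector itself. When a denominator's magnitude
#' falls below `epsilon`, a stabilizer of matching sign is added; with
#' `epsilon = 0` and a bias-free network, total relevance is conserved
#' exactly across layers.
#'
#' @param model a `cna_autoencoder`; only its encoder layers are used.
#' @param x one input row (numeric vector), a matrix of rows, or a feature
#'   matrix tibble.
#' @param epsilon denominator stabilizer (default: the model config's
#'   `epsilon`, 1e-9).
#' @param reference what the encoding is measured against before
#'   propagation. `"none"` (default) propagates the raw encoding
#'   activations. `"mean"` propagates each sample's deviation from the mean
#'   encoding of the supplied rows — the between-sample information — so
#'   that inputs whose encoding contribution is constant across the cohort
#'   (ubiquitous aberrations) receive no relevance for what they share. A
#'   numeric vector of encoding length supplies an explicit reference.
#' @return relevance per input channel-feature: a vector for a single row,
#'   otherwise a matrix with one row per sample.
#' @export
lrp_relevance <- function(model, x, epsilon = NULL, reference = "none") {
  epsilon <- epsilon %||% model$config$epsilon %||% 1e-9
  single <- is.numeric(x) && is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else if (is.matrix(x)) x else
    fm_values(x)
  if (ncol(X) != model$layer_sizes[1]) {
    stopf("lrp_relevance: input has %d features, model expects %d",
          ncol(X), model$layer_sizes[1])
  }
  L <- model$encoder_layers
  A <- ae_forward(model, X, n_layers = L)
  E <- A[[L + 1L]]
  R <- if (identical(reference, "none")) {
    E  # initial relevance = encoding activations
  } else if (identical(reference, "mean")) {
    if (nrow(E) < 2) {
      stopf("lrp_relevance: reference = \"mean\" needs multiple rows")
    }
    sweep(E, 2, colMeans(E))
  } else if (is.numeric(reference)) {
    if (length(reference) != ncol(E)) {
      stopf("lrp_relevance: reference length %d, encoding dimension %d",
            length(reference), ncol(E))
    }
    sweep(E, 2, reference)
  } else stopf("lrp_relevance: unknown reference")
  for (l in rev(seq_len(L))) {
    W <- model$weights[[l]]
    Z <- sweep(A[[l]] %*% W, 2, model$biases[[l]], "+")
    if (epsilon > 0) {
      small <- abs(Z) < epsilon
      Z[small] <- Z[small] + epsilon * ifelse(Z[small] >= 0, 1, -1)
    }
    S <- R / Z
    S[R == 0] <- 0  # 0/0 guard: a dead unit carries no relevance
    R <- A[[l]] * (S %*% t(W))
  }
  colnames(R) <- model$input_axis
  if (single) R[1, ] else R
}

#' Aggregate per-sample relevance into feature weights
#'
#' Per channel-feature, absolute relevances are summed over all samples
#' (so amplification and deletion contributions of opposite sign cannot
#' cancel) and the sums divided by their maximum, giving weights in \[0,1\]
#' with max 1.
#'
#' @param relevances matrix of per-sample relevance rows (named columns), as
#'   returned by [lrp_relevance()] on a multi-row input.
#' @return relevance-panel tibble: `feature_id`, `channel`, `weight`.
#' @export
aggregate_relevance <- function(relevances) {
  if (is.null(dim(relevances))) relevances <- matrix(relevances, nrow = 1,
    dimnames = list(NULL, names(relevances)))
  w <- colSums(abs(relevances))
  if (max(w) == 0) stopf("aggregate_relevance: degenerate relevance (all zero)")
  w <- w / max(w)
  cols <- colnames(relevances)
  if (is.null(cols)) stopf("aggregate_relevance: relevance columns must be named")
  tibble::tibble(
    feature_id = sub("__(amp|del)$", "", cols),
    channel = sub("^.*__", "", cols),
    weight = unname(w)
  )
}

#' Threshold a relevance panel into a selected feature set
#'
#' With `mode = "weight"` (default), features whose normalized weight is
#' `>= threshold` are selected; boundary ties are all kept. With
#' `mode = "top_fraction"`, the top `threshold` fraction of channel-features
#' by weight is kept (again including boundary ties).
#'
#' @param panel relevance-panel tibble from [aggregate_relevance()].
#' @param threshold cutoff in (0, 1).
#' @param mode `"weight"` or `"top_fraction"`.
#' @param phase optional label ("cytoband" or "gene") recorded on the result.
#' @return the panel with a logical `selected` column; attributes
#'   `threshold`, `threshold_mode` and `phase` record the applied rule.
#' @export
select_features <- function(panel, threshold = 0.1,
                            mode = c("weight", "top_fraction"),
                            phase = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stopf("select_features: threshold must be in (0, 1)")
  }
  sel <- if (mode == "weight") {
    panel$weight >= threshold
  } else {
    k <- ceiling(threshold * nrow(panel))
    cut <- sort(panel$weight, decreasing = TRUE)[k]
    panel$weight >= cut
  }
  out <- dplyr::mutate(panel, selected = sel)
  attr(out, "threshold") <- threshold
  attr(out, "threshold_mode") <- mode
  attr(out, "phase") <- phase
  out
}
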