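# broom-style tidiers and print methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.cna_autoencoder <- function(x, ...) {
  cat(sprintf("<cna_autoencoder> %s; layers %s; noise %.2f; final MSE %.3g\n",
              x$activation, paste(x$layer_sizes, collapse = "-"),
              x$noise_fraction, tail(x$loss_history, 1)))
  invisible(x)
}

#' @rdname train_autoencoder
#' @param x a `cna_autoencoder`.
#' @param ... unused.
#' @method tidy cna_autoencoder
#' @export
tidy.cna_autoencoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname train_autoencoder
#' @method glance cna_autoencoder
#' @export
glance.cna_autoencoder <- function(x, ...) {
  tibble::tibble(
    input_dim = x$layer_sizes[1],
    encoding_dim = x$layer_sizes[x$encoder_layers + 1],
    n_params = sum(vapply(x$weights, length, 0L)) +
      sum(vapply(x$biases, length, 0L)),
    epochs = length(x$loss_history),
    final_loss = tail(x$loss_history, 1),
    noise_fraction = x$noise_fraction,
    seed = x$seed)
}

#' @method autoplot cna_autoencoder
#' @export
autoplot.cna_autoencoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "reconstruction MSE",
                  title = "Autoencoder training loss")
}

#' @export
print.cna_two_phase <- function(x, ...) {
  s <- extraction_summary(x)
  cat("<cna_two_phase>\n")
  print(s)
  invisible(x)
}

#' @rdname train_classifier
#' @param x a `cna_rf`.
#' @param ... unused.
#' @method tidy cna_rf
#' @export
tidy.cna_rf <- function(x, ...) {
  imp <- x$fit$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname train_classifier
#' @method glance cna_rf
#' @export
glance.cna_rf <- function(x, ...) {
  tibble::tibble(n_trees = x$fit$num.trees, mtry = x$fit$mtry,
                 n_features = length(x$features),
                 n_classes = length(x$levels),
                 oob_error = x$fit$prediction.error, seed = x$seed)
}

#' @rdname classification_report
#' @param x a `cna_report`.
#' @param ... unused.
#' @method tidy cna_report
#' @export
tidy.cna_report <- function(x, ...) x$per_class

#' @rdname classification_report
#' @method glance cna_report
#' @export
glance.cna_report <- function(x, ...) {
  tibble::tibble(macro_f1 = x$macro_f1, accuracy = x$accuracy, n = x$n,
                 n_classes = nrow(x$per_class))
}

#' @export
print.cna_report <- function(x, ...) {
  cat(sprintf("<cna_report> n = %d, accuracy = %.3f, macro-F1 = %.3f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$per_class)
  invisible(x)
}

#' @method autoplot cna_report
#' @export
autoplot.cna_report <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$confusion)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(title = "Confusion matrix (true vs predicted)")
}

#' @rdname cross_validate
#' @param x a `cna_cv`.
#' @param ... unused.
#' @method tidy cna_cv
#' @export
tidy.cna_cv <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$subtype$per_class, level = "subtype", .before = 1),
    dplyr::mutate(x$organ$per_class, level = "organ", .before = 1))
}

#' @rdname cross_validate
#' @method glance cna_cv
#' @export
glance.cna_cv <- function(x, ...) {
  tibble::tibble(subtype_macro_f1 = x$subtype$macro_f1,
                 subtype_accuracy = x$subtype$accuracy,
                 organ_macro_f1 = x$organ$macro_f1,
                 organ_accuracy = x$organ$accuracy,
                 f1_size_correlation = x$f1_size_correlation,
                 n = x$subtype$n)
}

#' Plot a relevance panel along the feature axis
#'
#' Channel-feature weights in panel order, colored by channel, with the
#' applied selection threshold when the panel carries one.
#'
#' @param panel relevance panel tibble (optionally with `selected`).
#' @return a ggplot object.
#' @export
plot_relevance <- function(panel) {
  df <- dplyr::mutate(panel, index = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$weight,
                                        color = .data$channel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "channel-feature (genomic order)",
                  y = "normalized relevance weight")
  thr <- attr(panel, "threshold")
  if (!is.null(thr) && identical(attr(panel, "threshold_mode"), "weight")) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' Plot focal/regional feature groups along the genome
#'
#' @param groups feature-group tibble from [merge_features()].
#' @return a ggplot object: one horizontal segment per group at its genomic
#'   span, faceted by chromosome, shaped by kind.
#' @export
plot_feature_groups <- function(groups) {
  ggplot2::ggplot(groups,
                  ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                               y = .data$channel, yend = .data$channel,
                               color = .data$kind)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Focal and regional feature groups")
}

#' Heatmap of subtype signatures
#'
#' Signature intensities (0 where a subtype lacks an entry) as a tile plot,
#' subtypes ordered by [cluster_signatures()] when more than one signature
#' is present.
#'
#' @param signatures combined signature tibble.
#' @return a ggplot object.
#' @export
plot_signature_heatmap <- function(signatures) {
  df <- tidyr::complete(
    dplyr::mutate(signatures,
                  entry = paste(.data$gene, .data$channel, sep = "__")),
    .data$label, .data$entry, fill = list(intensity = 0))
  if (length(unique(signatures$label)) >= 2) {
    ord <- cluster_signatures(signatures)$order
    df$label <- factor(df$label, levels = ord)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entry, y = .data$label,
                                   fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "signature entry (gene x channel)", y = NULL)
}

#' @importFrom utils tail
NULL
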