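# Class-balanced random-forest classification of cancer subtype from
# signature-gene features, with organ prediction via the subtype-to-organ
# label map. The forest itself is ranger; balancing, the evaluation
# protocol, and the report metrics live here.

#' Assemble a labeled dataset from signature genes
#'
#' Restricts the gene matrix to the (gene, channel) entries appearing in any
#' subtype signature and attaches the subtype label of each sample.
#'
#' @param gene_matrix normalized gene feature matrix.
#' @param subtypes subtype tibble with `label`, `organ`, `sample_ids`
#'   (e.g. the post-merge groups).
#' @param signatures combined signature tibble; its entries define the
#'   feature columns.
#' @return list of class `cna_dataset`: `data` (tibble `sample_id`,
#'   `subtype`, then feature columns) and `subtype_to_organ` (named
#'   character vector).
#' @export
make_dataset <- function(gene_matrix, subtypes, signatures) {
  cols <- unique(axis_col(signatures$gene, signatures$channel))
  if (!length(cols)) stopf("make_dataset: signatures contain no entries")
  label <- rep(subtypes$label, lengths(subtypes$sample_ids))
  ids <- unlist(subtypes$sample_ids)
  idx <- match(ids, gene_matrix$sample_id)
  if (anyNA(idx)) stopf("make_dataset: subtype sample missing from matrix")
  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids, subtype = label),
    gene_matrix[idx, cols, drop = FALSE])
  structure(list(
    data = data,
    subtype_to_organ = setNames(subtypes$organ, subtypes$label)
  ), class = "cna_dataset")
}

#' Rebalance classes by under- and oversampling
#'
#' Every class is resampled to the target count: larger classes are sampled
#' without replacement (undersampling), smaller classes with replacement
#' (oversampling). Feature values of retained samples are untouched — no
#' synthetic interpolation. Deterministic under `seed`; the drawn original
#' row indices are recorded in the `resample_log` attribute.
#'
#' @param data labeled tibble with a `subtype` column (as in
#'   [make_dataset()]'s `$data`).
#' @param target `"median"` (default: median class size) or an integer count.
#' @param seed integer seed.
#' @return resampled tibble with attribute `resample_log` (tibble `subtype`,
#'   `row`: index into the input).
#' @export
balance_classes <- function(data, target = "median", seed) {
  sizes <- table(data$subtype)
  if (length(sizes) < 2) stopf("balance_classes: need >= 2 classes")
  if (any(sizes == 0)) stopf("balance_classes: empty class")
  n_target <- if (identical(target, "median")) {
    as.integer(round(stats::median(sizes)))
  } else as.integer(target)
  with_private_seed(seed, {
    picks <- lapply(sort(names(sizes)), function(cl) {
      rows <- which(data$subtype == cl)
      if (length(rows) == n_target) rows
      else if (length(rows) > n_target) sample(rows, n_target)
      else sample(rows, n_target, replace = TRUE)
    })
    rows <- unlist(picks)
    out <- data[rows, , drop = FALSE]
    attr(out, "resample_log") <- tibble::tibble(subtype = out$subtype,
                                                row = rows)
    out
  })
}

#' Train the subtype random forest
#'
#' Fits a ranger random forest on the (balanced) training data: subtype as
#' label, every non-identifier column as a feature. Defaults: 500 trees,
#' unlimited depth, sqrt(p) candidate features per split.
#'
#' @param data labeled tibble (`subtype` + feature columns; `sample_id`
#'   ignored if present).
#' @param trees number of trees (default 500).
#' @param seed integer seed (mandatory: forests are stochastic).
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @return object of class `cna_rf`: the ranger fit, feature names and class
#'   levels; feature importances available via [tidy()].
#' @export
train_classifier <- function(data, trees = 500, seed, mtry = NULL) {
  feats <- setdiff(names(data), c("sample_id", "subtype"))
  y <- factor(data$subtype)
  if (nlevels(y) < 2) stopf("train_classifier: single-class input")
  X <- as.data.frame(data[, feats, drop = FALSE])
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = trees,
    mtry = mtry %||% max(1L, floor(sqrt(length(feats)))),
    importance = "impurity",
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, features = feats, levels = levels(y),
                 seed = seed), class = "cna_rf")
}

#' Predict subtypes for new samples
#' @param model a `cna_rf`.
#' @param data tibble containing the model's feature columns.
#' @return character vector of predicted subtype labels.
#' @export
predict_subtype <- function(model, data) {
  if (nrow(data) == 0) return(character())
  X <- as.data.frame(data[, model$features, drop = FALSE])
  as.character(stats::predict(model$fit, data = X,
                              num.threads = 1)$predictions)
}

#' Predict organ of origin via the subtype-to-organ map
#'
#' Predicts subtypes and maps each predicted label to its organ; the model
#' is never retrained on organ labels.
#'
#' @param model a `cna_rf`.
#' @param data tibble containing the model's feature columns.
#' @param subtype_to_organ named character vector mapping every subtype
#'   label the model can emit to an organ.
#' @return character vector of organ labels.
#' @export
predict_organ <- function(model, data, subtype_to_organ) {
  pred <- predict_subtype(model, data)
  if (!length(pred)) return(character())
  missing_lab <- setdiff(unique(pred), names(subtype_to_organ))
  if (length(missing_lab)) {
    stopf("predict_organ: predicted subtype '%s' missing from the organ map",
          missing_lab[1])
  }
  unname(subtype_to_organ[pred])
}

#' Classification report from truth/prediction pairs
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @return object of class `cna_report`: `confusion` (true rows x predicted
#'   columns over the union of labels), `per_class` tibble
#'   (precision/recall/F1/support, undefined ratios scored 0), `macro_f1`,
#'   `accuracy`, `n` .
#' @export
classification_report <- function(truth, pred) {
  labels <- sort(union(unique(truth), unique(pred)))
  confusion <- table(factor(truth, levels = labels),
                     factor(pred, levels = labels))
  names(dimnames(confusion)) <- c("true", "predicted")
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted_n <- colSums(confusion)
  precision <- ifelse(predicted_n > 0, tp / predicted_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    label = labels, support = as.integer(support),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1))
  structure(list(
    confusion = unclass(confusion),
    per_class = per_class,
    macro_f1 = mean(f1[support > 0]),
    accuracy = sum(tp) / length(truth),
    n = length(truth)
  ), class = "cna_report")
}

# Aggregate a confusion matrix through a label map (e.g. subtype -> organ).
aggregate_confusion <- function(confusion, map) {
  to <- unname(map[rownames(confusion)])
  lv <- sort(unique(to))
  agg <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(to)) for (j in seq_along(to)) {
    agg[to[i], to[j]] <- agg[to[i], to[j]] + confusion[i, j]
  }
  agg
}

#' Stratified cross-validated evaluation
#'
#' Stratified k-fold cross-validation on the original samples. Class
#' balancing ([balance_classes()]) is applied inside each training fold
#' only, so oversampled duplicates can never leak into a test fold.
#' Predictions are pooled over folds into one subtype report and one organ
#' report (organ labels obtained by mapping the subtype predictions).
#'
#' @param dataset a `cna_dataset` from [make_dataset()], or a list with
#'   `data` and `subtype_to_organ`.
#' @param k number of folds (default 5); every class must have >= k members.
#' @param seed integer seed driving fold assignment, balancing and forests.
#' @param trees,target forwarded to [train_classifier()] /
#'   [balance_classes()].
#' @return object of class `cna_cv`: `subtype` and `organ` reports
#'   (`cna_report`), `predictions` (tibble sample_id/fold/truth/pred), and
#'   `f1_size_correlation` (Pearson r of per-subtype F1 with class size).
#' @export
cross_validate <- function(dataset, k = 5, seed, trees = 500,
                           target = "median") {
  data <- dataset$data
  map <- dataset$subtype_to_organ
  sizes <- table(data$subtype)
  too_small <- names(sizes)[sizes < k]
  if (length(too_small)) {
    stopf("cross_validate: class '%s' has fewer than k = %d members",
          too_small[1], k)
  }
  fold <- integer(nrow(data))
  with_private_seed(seed, {
    for (cl in sort(names(sizes))) {
      rows <- which(data$subtype == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    balanced <- balance_classes(train, target = target,
                                seed = seed + 1000L + f)
    model <- train_classifier(balanced, trees = trees, seed = seed + 2000L + f)
    preds[[f]] <- tibble::tibble(
      sample_id = test$sample_id, fold = f, truth = test$subtype,
      pred = predict_subtype(model, test))
  }
  predictions <- dplyr::bind_rows(preds)
  subtype_report <- classification_report(predictions$truth,
                                          predictions$pred)
  organ_report <- classification_report(unname(map[predictions$truth]),
                                        unname(map[predictions$pred]))
  pc <- subtype_report$per_class
  structure(list(
    subtype = subtype_report, organ = organ_report,
    predictions = predictions,
    f1_size_correlation = if (nrow(pc) > 2 && stats::sd(pc$support) > 0 &&
                              stats::sd(pc$f1) > 0)
      cor(pc$f1, pc$support) else NA_real_
  ), class = "cna_cv")
}
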