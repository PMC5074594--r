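#' Stratified k-fold cross-validation of a hairpin classifier
#'
#' Assigns stratified folds (each label shuffled with the given seed and
#' dealt round-robin), trains on k-1 folds, predicts the held-out fold, and
#' evaluates the pooled out-of-fold predictions. TP rate, precision and
#' recall are class-size-weighted averages over both classes (the
#' convention of the common evaluation toolkits; a class never predicted
#' contributes precision 0); the ROC area is the rank-statistic AUC of the
#' pooled probabilities, which for two classes equals its class-weighted
#' average over both orientations.
#'
#' @param features Labelled feature table.
#' @param feature_names Predictor features (ignored for `model = "zero_r"`).
#' @param model `"logistic"` (IRLS, with automatic tiny-ridge fallback on
#'   separated folds) or `"zero_r"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param positive_label Passed to [train_logistic()].
#' @param threshold Classification cut-off on P(positive).
#' @return A `hairpin_cv` object: list with `$metrics` (one-row tibble:
#'   `tp_rate`, `precision`, `recall`, `roc_area`), `$per_class`,
#'   `$per_fold`, `$confusion`, `$predictions`, `$seed`.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 60), plant_profile(n = 60), seed = 3)
#' ft <- extract_features(hp)
#' cv <- cross_validate(ft, c("n_helix", "n_stack", "length", "mfe"),
#'                      k = 5, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(features, feature_names,
                           model = c("logistic", "zero_r"),
                           k = 10L, seed = 1L,
                           positive_label = NULL, threshold = 0.5) {
  model <- match.arg(model)
  if (k < 2) abort("k must be >= 2")
  features <- features[!is.na(features$label), , drop = FALSE]
  labs <- sort(unique(features$label))
  if (length(labs) != 2)
    abort("cross-validation needs exactly two labels")
  counts <- table(features$label)
  if (any(counts < k))
    abort(sprintf("every class needs at least k = %d members (smallest has %d)",
                  k, min(counts)))
  if (is.null(positive_label))
    positive_label <- if ("animal" %in% labs) "animal" else labs[1]
  negative_label <- setdiff(labs, positive_label)

  n <- nrow(features)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (lab in labs) {
      idx <- sample(which(features$label == lab))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })

  prob <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    fit <- if (model == "zero_r") {
      zero_r(train)
    } else {
      tryCatch(
        train_logistic(train, feature_names, positive_label = positive_label),
        error = function(e)
          suppressWarnings(
            train_logistic(train, feature_names,
                           positive_label = positive_label, ridge = TRUE)))
    }
    prob[fold == f] <- if (model == "zero_r") {
      # score on the positive-label scale for a common ROC convention
      p <- predict(fit, test)
      if (fit$majority == positive_label) p else 1 - p
    } else {
      predict(fit, test)
    }
  }

  truth <- features$label
  call <- ifelse(prob >= threshold, positive_label, negative_label)
  per_class <- purrr::map(labs, function(lab) {
    tp <- sum(truth == lab & call == lab)
    fn <- sum(truth == lab & call != lab)
    fp <- sum(truth != lab & call == lab)
    tibble::tibble(
      label = lab, n = sum(truth == lab),
      tp_rate = tp / (tp + fn),
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = tp / (tp + fn))
  }) |> dplyr::bind_rows()
  wts <- per_class$n / sum(per_class$n)
  auc <- roc_auc(prob, truth, positive_label)
  metrics <- tibble::tibble(
    tp_rate = sum(wts * per_class$tp_rate),
    precision = sum(wts * per_class$precision),
    recall = sum(wts * per_class$recall),
    roc_area = sum(wts * c(auc, auc)))

  per_fold <- purrr::map(seq_len(k), function(f) {
    i <- fold == f
    tibble::tibble(
      fold = f, n = sum(i),
      accuracy = mean(call[i] == truth[i]),
      roc_area = if (length(unique(truth[i])) == 2)
        roc_auc(prob[i], truth[i], positive_label) else NA_real_)
  }) |> dplyr::bind_rows()

  structure(list(
    metrics = metrics,
    per_class = per_class,
    per_fold = per_fold,
    confusion = table(truth = truth, predicted = call),
    predictions = tibble::tibble(id = features$id, label = truth,
                                 fold = fold, prob = prob, call = call),
    model = model, feature_names = feature_names, k = k, seed = seed,
    positive_label = positive_label
  ), class = "hairpin_cv")
}

#' @export
print.hairpin_cv <- function(x, ...) {
  m <- x$metrics
  cat("<hairpin_cv> ", x$k, "-fold CV of ", x$model, " model (seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  tp_rate %.3f | precision %.3f | recall %.3f | roc_area %.3f\n",
              m$tp_rate, m$precision, m$recall, m$roc_area))
  invisible(x)
}

#' @method tidy hairpin_cv
#' @export
tidy.hairpin_cv <- function(x, ...) {
  x$per_fold
}

#' @method glance hairpin_cv
#' @export
glance.hairpin_cv <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(k = x$k, model = x$model, seed = x$seed))
}
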