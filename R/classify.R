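#' Construct a logistic hairpin classifier
#'
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector; names must be catalog features.
#' @param positive_label Class whose probability is modelled.
#' @param negative_label The other class.
#' @return A `hairpin_logit` object.
#' @export
hairpin_logit <- function(intercept, coefficients,
                          positive_label = "animal",
                          negative_label = "plant") {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    abort("coefficients must be named")
  unknown <- setdiff(names(coefficients), .catalog_names)
  if (length(unknown) > 0)
    abort(paste0("coefficient name(s) not in the feature catalog: ",
                 paste(unknown, collapse = ", ")))
  if (!all(is.finite(c(intercept, coefficients))))
    abort("model parameters must be finite")
  structure(list(
    intercept = as.double(intercept),
    coefficients = coefficients,
    positive_label = positive_label,
    negative_label = negative_label
  ), class = "hairpin_logit")
}

#' The published four-feature animal/plant logistic model
#'
#' A fixed-coefficient logistic classifier over helix number, stack number,
#' precursor length and minimum free energy:
#' `logit(P) = 6.1436 + 0.0893 * n_helix - 0.0691 * n_stack
#'  - 0.0241 * length + 0.0263 * mfe`,
#' where `P` is the probability that the hairpin is an animal pre-miRNA.
#'
#' @return A `hairpin_logit` object with the fixed published coefficients.
#' @examples
#' m <- published_model()
#' predict(m, tibble::tibble(n_helix = 3, n_stack = 20, length = 85, mfe = -35))
#' @export
published_model <- function() {
  hairpin_logit(
    intercept = 6.1436,
    coefficients = c(n_helix = 0.0893, n_stack = -0.0691,
                     length = -0.0241, mfe = 0.0263),
    positive_label = "animal",
    negative_label = "plant"
  )
}

#' Predict from a hairpin logistic model
#'
#' @param object A `hairpin_logit` model.
#' @param newdata Data frame (e.g. a feature table) containing every model
#'   feature; a named numeric vector also works for a single record.
#' @param type `"response"` for P(positive class), `"link"` for the linear
#'   predictor, `"class"` for the label call at `threshold`.
#' @param threshold Probability cut-off for `type = "class"` (default 0.5;
#'   a probability at or above it calls the positive class).
#' @param ... Unused.
#' @return Numeric vector of probabilities or logits, or a character vector
#'   of class calls.
#' @export
predict.hairpin_logit <- function(object, newdata,
                                  type = c("response", "link", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- tibble::as_tibble_row(as.list(newdata))
  nms <- names(object$coefficients)
  miss <- setdiff(nms, names(newdata))
  if (length(miss) > 0)
    abort(paste0("newdata lacks model feature(s): ", paste(miss, collapse = ", ")))
  X <- as.matrix(as.data.frame(newdata)[, nms, drop = FALSE])
  if (anyNA(X)) {
    bad <- nms[apply(is.na(X), 2, any)]
    abort(paste0("missing values in model feature(s): ",
                 paste(bad, collapse = ", ")))
  }
  eta <- as.vector(object$intercept + X %*% object$coefficients)
  switch(type,
    link = eta,
    response = plogis(eta),
    class = ifelse(plogis(eta) >= threshold,
                   object$positive_label, object$negative_label))
}

#' @export
print.hairpin_logit <- function(x, ...) {
  cat("<hairpin_logit> P(", x$positive_label, ") via logit = ",
      format(x$intercept, digits = 6), " + ",
      paste(sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @method tidy hairpin_logit
#' @export
tidy.hairpin_logit <- function(x, ...) {
  est <- c(x$intercept, x$coefficients)
  out <- tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                        estimate = unname(est))
  if (!is.null(x$se)) {
    out$std.error <- unname(x$se)
    out$statistic <- out$estimate / out$std.error
    out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  }
  out
}

#' @method glance hairpin_logit
#' @export
glance.hairpin_logit <- function(x, ...) {
  tibble::tibble(nobs = x$n %||% NA_integer_,
                 logLik = x$loglik %||% NA_real_,
                 iter = x$iterations %||% NA_integer_,
                 converged = x$converged %||% NA)
}

#' Train a logistic classifier by IRLS
#'
#' Maximum-likelihood logistic regression fitted with iteratively
#' reweighted least squares; convergence when the largest coefficient
#' change falls below `tol`. On (quasi-)separated data the MLE diverges:
#' the fit then errors unless `ridge = TRUE`, which adds a tiny L2 penalty
#' (`ridge_lambda`, default `1e-6`) to the slopes to keep the solution
#' finite — useful when cleanly separable synthetic cohorts are expected.
#'
#' @param features Feature table with exactly two labels and no missing
#'   values in the chosen columns.
#' @param feature_names Character vector of predictor feature names.
#' @param positive_label Class to model; defaults to `"animal"` when
#'   present, otherwise the alphabetically first label.
#' @param tol Convergence tolerance on the coefficient step (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param ridge Add a tiny L2 penalty instead of failing on separation.
#' @param ridge_lambda Penalty strength when `ridge = TRUE`.
#' @return A fitted `hairpin_logit` with standard errors (`$se`),
#'   `$loglik`, `$n`, `$iterations`, `$converged`.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 80), plant_profile(n = 80), seed = 2)
#' ft <- extract_features(hp)
#' fit <- train_logistic(ft, c("n_helix", "n_stack", "length", "mfe"),
#'                       ridge = TRUE)
#' tidy(fit)
#' @export
train_logistic <- function(features, feature_names,
                           positive_label = NULL,
                           tol = 1e-8, max_iter = 100L,
                           ridge = FALSE, ridge_lambda = 1e-6) {
  labs <- sort(unique(features$label[!is.na(features$label)]))
  if (length(labs) != 2)
    abort("training needs a feature table with exactly two labels")
  if (is.null(positive_label))
    positive_label <- if ("animal" %in% labs) "animal" else labs[1]
  if (!positive_label %in% labs)
    abort(paste0("positive_label '", positive_label, "' not among labels"))
  negative_label <- setdiff(labs, positive_label)
  miss <- setdiff(feature_names, names(features))
  if (length(miss) > 0)
    abort(paste0("unknown feature(s): ", paste(miss, collapse = ", ")))
  keep <- !is.na(features$label)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(features)[keep, feature_names, drop = FALSE]))
  if (anyNA(X))
    abort("missing values in predictor columns; drop or impute first")
  y <- as.numeric(features$label[keep] == positive_label)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p)
    abort("need more observations than parameters")

  pen <- diag(c(0, rep(if (ridge) ridge_lambda else 0, p - 1)), p, p)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) abort(paste0("IRLS normal equations singular: ",
                                       conditionMessage(e))))
    step <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (!all(is.finite(beta))) break
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  mu_fit <- plogis(as.vector(X %*% beta))
  if (!converged && !ridge && max(pmin(mu_fit, 1 - mu_fit)) < 1e-6)
    abort(paste0("IRLS did not converge and every fitted probability is ",
                 "pinned at 0/1 - the classes appear (quasi-)separated; ",
                 "retry with ridge = TRUE"))
  if (!converged)
    warn(sprintf("IRLS did not converge in %d iterations (last step %.3g)",
                 max_iter, step))

  eta <- as.vector(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X + pen
  se <- sqrt(diag(solve(info)))
  loglik <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))

  model <- hairpin_logit(beta[1], setNames(beta[-1], feature_names),
                         positive_label, negative_label)
  model$se <- setNames(se, c("(Intercept)", feature_names))
  model$loglik <- loglik
  model$n <- n
  model$iterations <- iter
  model$converged <- converged
  model$ridge <- ridge
  model
}

#' Majority-class (ZeroR) baseline
#'
#' Always predicts the majority class, with constant probability equal to
#' the majority fraction; ties are broken toward the alphabetically first
#' label. Its rank-based ROC area is 0.5 by construction.
#'
#' @param features Labelled feature table.
#' @return A `zero_r_model` with `$majority`, `$fraction`, `$labels`.
#' @export
zero_r <- function(features) {
  labs <- features$label[!is.na(features$label)]
  if (length(labs) == 0) abort("no labels present")
  tab <- sort(table(labs), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  majority <- sort(top)[1]
  structure(list(majority = majority,
                 fraction = as.numeric(max(tab)) / length(labs),
                 labels = sort(unique(labs))),
            class = "zero_r_model")
}

#' @export
predict.zero_r_model <- function(object, newdata,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  n <- if (is.data.frame(newdata)) nrow(newdata) else length(newdata)
  switch(type,
    response = rep(object$fraction, n),
    class = rep(object$majority, n))
}

#' @export
print.zero_r_model <- function(x, ...) {
  cat("<zero_r_model> always predicts '", x$majority, "' (p = ",
      format(x$fraction, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' ROC area from the rank statistic
#'
#' Mann-Whitney form of the AUC: the probability that a random positive
#' scores above a random negative, with ties counted half. For a binary
#' problem the class-size-weighted average over the two orientations equals
#' this same number, which is the convention reported by
#' [cross_validate()].
#'
#' @param scores Numeric scores (higher means more positive).
#' @param labels Class labels.
#' @param positive The positive label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write / read a logistic model as flat text
#'
#' One `feature<TAB>coefficient` line per term, plus `__intercept__` and
#' `__positive_label__` (and `__negative_label__`) lines.
#'
#' @param model A `hairpin_logit`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed `hairpin_logit`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hairpin_logit"))
  lines <- c(
    paste0("__intercept__\t", format(model$intercept, digits = 17)),
    paste0("__positive_label__\t", model$positive_label),
    paste0("__negative_label__\t", model$negative_label),
    paste0(names(model$coefficients), "\t",
           vapply(model$coefficients, format, character(1), digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fields <- strsplit(readLines(path), "\t")
  keys <- vapply(fields, `[[`, character(1), 1)
  vals <- vapply(fields, `[[`, character(1), 2)
  need <- c("__intercept__", "__positive_label__")
  if (!all(need %in% keys))
    abort("model file lacks __intercept__ / __positive_label__ lines")
  coef_i <- !startsWith(keys, "__")
  hairpin_logit(
    intercept = as.double(vals[keys == "__intercept__"]),
    coefficients = setNames(as.double(vals[coef_i]), keys[coef_i]),
    positive_label = vals[keys == "__positive_label__"],
    negative_label = if ("__negative_label__" %in% keys)
      vals[keys == "__negative_label__"] else "other"
  )
}
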