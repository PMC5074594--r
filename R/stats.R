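#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum distance between the two empirical
#' distribution functions, `D = sup_x |F1(x) - F2(x)|`, evaluated over the
#' pooled sample points (ties handled exactly). The default p-value is the
#' asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n1 * n2 / (n1 + n2)) * D` — appropriate for the cohort sizes this
#' screen is designed for; `exact = TRUE` delegates to the exact
#' distribution for small, tie-free samples.
#'
#' @param x,y Numeric samples; `NA`s are dropped.
#' @param exact Use the exact null distribution for the p-value.
#' @return A one-row tibble with `d`, `p`, `n1`, `n2`.
#' @examples
#' ks_two_sample(c(1, 3), c(2, 4))
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  f1 <- findInterval(pts, sort(x)) / n1
  f2 <- findInterval(pts, sort(y)) / n2
  d <- max(abs(f1 - f2))
  p <- if (exact) {
    suppressWarnings(stats::ks.test(x, y, exact = TRUE)$p.value)
  } else if (d == 0) {
    1
  } else {
    .kolmogorov_sf(sqrt(n1 * n2 / (n1 + n2)) * d)
  }
  tibble::tibble(d = d, p = min(max(p, 0), 1), n1 = n1, n2 = n2)
}

# survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
.kolmogorov_sf <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, 0), 1)
}

#' Welch two-sample t-test with degenerate-data conventions
#'
#' Thin wrapper over [stats::t.test()] (two-sided, unequal variances) that
#' assigns `t = 0, p = 1` when both groups are constant with equal means and
#' `t = +/-Inf, p = 0` when they are constant with different means, so a
#' whole-catalog screen never fails on a degenerate feature.
#'
#' @param x,y Numeric samples; `NA`s are dropped.
#' @return A one-row tibble with `statistic` and `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    abort("both samples must have at least 2 observations")
  res <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  if (is.null(res)) {
    dm <- mean(x) - mean(y)
    if (dm == 0) return(tibble::tibble(statistic = 0, p = 1))
    return(tibble::tibble(statistic = sign(dm) * Inf, p = 0))
  }
  tibble::tibble(statistic = unname(res$statistic), p = res$p.value)
}

#' Screen every feature between two labelled cohorts
#'
#' For each of the 132 catalog features, compares the two label groups with
#' the two-sample KS test and a Welch t-test, reports the direction of the
#' mean difference, and flags features passing the KS-statistic threshold
#' (`d >= d_threshold`) and the KS p-value threshold (`p < p_threshold`).
#' Rows with a missing value are dropped per feature, with the count
#' reported.
#'
#' @param features Feature table from [extract_features()] with exactly two
#'   distinct labels.
#' @param d_threshold KS statistic threshold (default 0.15).
#' @param p_threshold p-value threshold (default 0.001).
#' @return A `screening_table` tibble with one row per feature: `feature`,
#'   `class`, `index`, `ks_d`, `ks_p`, `t_stat`, `t_p`, `direction`
#'   (`"higher_in_<label>"`), `pass_d`, `pass_p`, `n_missing_dropped`.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 40), plant_profile(n = 40), seed = 1)
#' scr <- screen_features(extract_features(hp))
#' dplyr::arrange(scr, dplyr::desc(ks_d))
#' @export
screen_features <- function(features, d_threshold = 0.15, p_threshold = 0.001) {
  stopifnot(d_threshold >= 0, d_threshold <= 1,
            p_threshold >= 0, p_threshold <= 1)
  labs <- sort(unique(features$label[!is.na(features$label)]))
  if (length(labs) != 2)
    abort(paste0("screening needs exactly two labels; found: ",
                 paste(labs, collapse = ", ")))
  g1 <- features[features$label == labs[1], , drop = FALSE]
  g2 <- features[features$label == labs[2], , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(.catalog)), function(i) {
    nm <- .catalog$name[i]
    x <- g1[[nm]]
    y <- g2[[nm]]
    n_drop <- sum(is.na(x)) + sum(is.na(y))
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(feature = nm, class = .catalog$class[i],
                            index = i, ks_d = NA_real_, ks_p = NA_real_,
                            t_stat = NA_real_, t_p = NA_real_,
                            direction = NA_character_, pass_d = FALSE,
                            pass_p = FALSE, n_missing_dropped = n_drop))
    }
    ks <- ks_two_sample(x, y)
    tt <- welch_t(x, y)
    dir <- if (mean(y) >= mean(x)) labs[2] else labs[1]
    tibble::tibble(
      feature = nm, class = .catalog$class[i], index = i,
      ks_d = ks$d, ks_p = ks$p, t_stat = tt$statistic, t_p = tt$p,
      direction = paste0("higher_in_", dir),
      pass_d = ks$d >= d_threshold, pass_p = ks$p < p_threshold,
      n_missing_dropped = n_drop)
  })
  out <- dplyr::bind_rows(rows)
  total_drop <- sum(out$n_missing_dropped)
  if (total_drop > 0)
    inform(sprintf("screening dropped %d missing value(s) pairwise across features",
                   total_drop))
  structure(out, class = c("screening_table", class(out)),
            labels = labs, d_threshold = d_threshold,
            p_threshold = p_threshold)
}

#' Pearson correlation matrix of the 132 features
#'
#' Pairwise-complete Pearson correlations between all catalog features;
#' zero-variance features give `NA` rows/columns.
#'
#' @param features Feature table from [extract_features()].
#' @return A symmetric 132 x 132 named matrix.
#' @export
feature_correlations <- function(features) {
  m <- as.matrix(features[, .catalog_names, drop = FALSE])
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                              method = "pearson"))
}
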