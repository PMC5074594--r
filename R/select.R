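# correlation pre-computation shared by cfs_merit and the searches:
# r_cf = |Pearson r| of each candidate with the 0/1 class indicator,
# r_ff = |Pearson r| between candidates; zero-variance features get 0.
.cfs_correlations <- function(features, candidates) {
  labs <- sort(unique(features$label[!is.na(features$label)]))
  if (length(labs) != 2)
    abort("CFS needs a feature table with exactly two labels")
  cls <- as.numeric(features$label == labs[2])
  m <- as.matrix(features[, candidates, drop = FALSE])
  r_cf <- suppressWarnings(as.vector(stats::cor(m, cls,
                                                use = "pairwise.complete.obs")))
  r_cf <- abs(ifelse(is.na(r_cf), 0, r_cf))
  names(r_cf) <- candidates
  r_ff <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r_ff <- abs(r_ff)
  r_ff[is.na(r_ff)] <- 0
  diag(r_ff) <- 1
  list(r_cf = r_cf, r_ff = r_ff, labels = labs)
}

.cfs_merit_idx <- function(idx, r_cf, r_ff) {
  k <- length(idx)
  if (k == 0) return(0)
  rcf_bar <- mean(r_cf[idx])
  if (k == 1) return(rcf_bar)
  rff_bar <- (sum(r_ff[idx, idx]) - k) / (k * (k - 1))
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection scores a subset S of k features as
#' `merit(S) = k * rcf / sqrt(k + k * (k - 1) * rff)`, where `rcf` is the
#' mean absolute Pearson correlation of the subset features with the 0/1
#' class indicator and `rff` the mean absolute pairwise correlation within
#' the subset: good subsets are individually predictive and mutually
#' non-redundant. The empty subset has merit 0; for a single feature the
#' merit is its absolute class correlation.
#'
#' @param features Feature table with exactly two labels.
#' @param subset Character vector of feature names.
#' @return The merit (a single number).
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 60), plant_profile(n = 60), seed = 1)
#' ft <- extract_features(hp)
#' cfs_merit(ft, c("n_stack", "length"))
#' @export
cfs_merit <- function(features, subset) {
  if (length(subset) == 0) return(0)
  miss <- setdiff(subset, names(features))
  if (length(miss) > 0)
    abort(paste0("unknown feature(s): ", paste(miss, collapse = ", ")))
  cc <- .cfs_correlations(features, subset)
  .cfs_merit_idx(seq_along(subset), cc$r_cf, cc$r_ff)
}

#' Search for the best CFS subset
#'
#' Three search strategies over the candidate features:
#' `"best_first"` (forward best-first search that stops after 5 consecutive
#' expansions without improving the best merit), `"greedy_forward"`
#' (add the single best feature while the merit improves), and
#' `"exhaustive"` (all non-empty subsets; capped at 25 candidates).
#' Ties are broken toward the lexicographically smallest name set so every
#' search is reproducible.
#'
#' @param features Feature table with exactly two labels.
#' @param candidates Character vector of candidate feature names; defaults
#'   to all 132 catalog features (use a screened shortlist for exhaustive
#'   search).
#' @param method Search strategy.
#' @param max_k Optional cap on subset size.
#' @param stale_limit Best-first stopping patience (default 5 expansions).
#' @return A `cfs_selection` object: list with `features` (selected names,
#'   sorted), `merit`, `method`, and `n_evaluated`.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 60), plant_profile(n = 60), seed = 1)
#' ft <- extract_features(hp)
#' select_features(ft, candidates = c("n_helix", "n_stack", "length", "mfe"),
#'                 method = "exhaustive")
#' @export
select_features <- function(features,
                            candidates = feature_names(),
                            method = c("best_first", "greedy_forward",
                                       "exhaustive"),
                            max_k = Inf, stale_limit = 5L) {
  method <- match.arg(method)
  candidates <- sort(unique(candidates))
  miss <- setdiff(candidates, names(features))
  if (length(miss) > 0)
    abort(paste0("unknown candidate feature(s): ", paste(miss, collapse = ", ")))
  # drop features with no complete values (all-NA columns break correlations)
  usable <- candidates[vapply(candidates, function(nm)
    sum(!is.na(features[[nm]])) >= 2, logical(1))]
  cc <- .cfs_correlations(features, usable)
  K <- length(usable)
  merit_of <- function(idx) .cfs_merit_idx(idx, cc$r_cf, cc$r_ff)

  result <- switch(method,
    exhaustive = .search_exhaustive(K, merit_of, max_k),
    greedy_forward = .search_greedy(K, merit_of, max_k),
    best_first = .search_best_first(K, merit_of, max_k, stale_limit))

  structure(list(
    features = usable[sort(result$idx)],
    merit = result$merit,
    method = method,
    n_evaluated = result$n_eval,
    candidates = usable
  ), class = "cfs_selection")
}

# lexicographic comparison on sorted index sets (candidates are sorted by
# name, so index order is name order)
.lex_smaller <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

.search_exhaustive <- function(K, merit_of, max_k) {
  if (K > 25) abort("exhaustive search capped at 25 candidates; use method = 'best_first'")
  if (K == 0) return(list(idx = integer(0), merit = 0, n_eval = 0L))
  best_idx <- integer(0)
  best_merit <- 0
  n_eval <- 0L
  bits <- 2^(0:(K - 1))
  for (mask in seq_len(2^K - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    if (length(idx) > max_k) next
    m <- merit_of(idx)
    n_eval <- n_eval + 1L
    if (m > best_merit ||
        (m == best_merit && .lex_smaller(idx, best_idx))) {
      best_merit <- m
      best_idx <- idx
    }
  }
  list(idx = best_idx, merit = best_merit, n_eval = n_eval)
}

.search_greedy <- function(K, merit_of, max_k) {
  current <- integer(0)
  current_merit <- 0
  n_eval <- 0L
  repeat {
    if (length(current) >= min(K, max_k)) break
    remaining <- setdiff(seq_len(K), current)
    merits <- vapply(remaining, function(j) merit_of(c(current, j)), numeric(1))
    n_eval <- n_eval + length(remaining)
    best <- max(merits)
    if (best <= current_merit) break
    j <- remaining[which(merits == best)]
    current <- c(current, min(j))  # lexicographic tie-break
    current_merit <- best
  }
  list(idx = current, merit = current_merit, n_eval = n_eval)
}

.search_best_first <- function(K, merit_of, max_k, stale_limit) {
  key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  open <- list(list(idx = integer(0), merit = 0))
  visited <- new.env(parent = emptyenv())
  assign(key(integer(0)), TRUE, envir = visited)
  best_idx <- integer(0)
  best_merit <- 0
  stale <- 0L
  n_eval <- 0L
  while (length(open) > 0 && stale < stale_limit) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    at <- which.max(merits)
    node <- open[[at]]
    open[[at]] <- NULL
    improved <- FALSE
    if (length(node$idx) < min(K, max_k)) {
      for (j in setdiff(seq_len(K), node$idx)) {
        child <- sort(c(node$idx, j))
        k <- key(child)
        if (exists(k, envir = visited)) next
        assign(k, TRUE, envir = visited)
        m <- merit_of(child)
        n_eval <- n_eval + 1L
        open[[length(open) + 1L]] <- list(idx = child, merit = m)
        if (m > best_merit ||
            (m == best_merit && length(best_idx) > 0 &&
             .lex_smaller(child, best_idx))) {
          if (m > best_merit) improved <- TRUE
          best_merit <- m
          best_idx <- child
        }
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(idx = best_idx, merit = best_merit, n_eval = n_eval)
}

#' @export
print.cfs_selection <- function(x, ...) {
  cat("<cfs_selection> method = ", x$method, ", merit = ",
      format(x$merit, digits = 6), "\n  features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy cfs_selection
#' @export
tidy.cfs_selection <- function(x, ...) {
  tibble::tibble(feature = x$features)
}

#' @method glance cfs_selection
#' @export
glance.cfs_selection <- function(x, ...) {
  tibble::tibble(method = x$method, k = length(x$features),
                 merit = x$merit, n_evaluated = x$n_evaluated)
}
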