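# Independent brute-force oracles used to cross-check the implementation.

# KS statistic by direct ECDF evaluation at every pooled sample point
brute_ks_d <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (t in pts) {
    f1 <- mean(x <= t)
    f2 <- mean(y <= t)
    d <- max(d, abs(f1 - f2))
  }
  d
}

# entropy by an explicit loop, no vectorised shortcuts
brute_entropy <- function(p) {
  e <- 0
  for (pi in p) {
    if (pi > 0) e <- e - pi * log(pi) / log(2)
  }
  e
}

# stack steps counted directly from the pair table: a step exists between
# pairs (i, j) and (i+1, j-1)
brute_stack_count <- function(pairs) {
  n <- length(pairs)
  steps <- 0L
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j > i && i + 1 <= n && pairs[i + 1] == j - 1 && j - 1 > i + 1)
      steps <- steps + 1L
  }
  steps
}

# AUC by trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(scores, labels, positive) {
  curve <- roc_points(scores, labels, positive)
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

# random nested dot-bracket string: random walk over (, ), . with
# feasibility constraints
random_structure <- function(L, p_open = 0.35, p_close = 0.35) {
  chars <- character(L)
  depth <- 0
  for (i in seq_len(L)) {
    left <- L - i
    u <- stats::runif(1)
    if (depth > 0 && depth >= left) {
      chars[i] <- ")"
      depth <- depth - 1
    } else if (u < p_open && left > depth) {
      chars[i] <- "("
      depth <- depth + 1
    } else if (u < p_open + p_close && depth > 0) {
      chars[i] <- ")"
      depth <- depth - 1
    } else {
      chars[i] <- "."
    }
  }
  paste(chars, collapse = "")
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# small ready-made feature table with planted group structure
make_toy_features <- function(n = 200, seed = 42, shift = c(length = 3)) {
  withr::with_seed(seed, {
    lab <- rep(c("animal", "plant"), each = n / 2)
    hp <- generate_cohorts(animal_profile(n = n / 2),
                           plant_profile(n = n / 2), seed = seed)
    extract_features(hp)
  })
}
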