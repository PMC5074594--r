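# small labelled table with controllable feature columns, using catalog
# names so the constructors accept them
make_cfs_table <- function(n, cols, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("animal", "plant"), each = n / 2)
    tab <- tibble::tibble(id = as.character(seq_len(n)), label = lab)
    cls <- as.numeric(lab == "plant")
    for (nm in names(cols)) {
      tab[[nm]] <- rnorm(n) + cols[[nm]] * cls
    }
    tab
  })
}

test_that("single-feature merit is the absolute class correlation", {
  tab <- make_cfs_table(200, list(AAA = 1.5))
  cls <- as.numeric(tab$label == "plant")
  expect_equal(cfs_merit(tab, "AAA"), abs(stats::cor(tab$AAA, cls)),
               tolerance = 1e-12)
  expect_equal(cfs_merit(tab, character(0)), 0)
})

test_that("a perfectly redundant feature never raises the merit", {
  tab <- make_cfs_table(300, list(AAA = 1.5))
  tab$AAC <- tab$AAA  # perfectly correlated duplicate
  m1 <- cfs_merit(tab, "AAA")
  m2 <- cfs_merit(tab, c("AAA", "AAC"))
  # closed form: with r_ff = 1 and equal class correlations the pair
  # scores exactly the single-feature merit, never above it
  expect_equal(m2, 2 * m1 / sqrt(2 + 2), tolerance = 1e-12)
  expect_lte(m2, m1 + 1e-12)
  # a degraded copy (same signal + extra noise) strictly lowers the merit
  withr::with_seed(4, tab$AAG <- tab$AAA + rnorm(300, sd = 2))
  expect_lt(cfs_merit(tab, c("AAA", "AAG")), m1)
})

test_that("two independent signal carriers beat either alone", {
  tab <- make_cfs_table(4000, list(AAA = 1, AAC = 1), seed = 10)
  expect_gt(cfs_merit(tab, c("AAA", "AAC")), cfs_merit(tab, "AAA"))
  expect_gt(cfs_merit(tab, c("AAA", "AAC")), cfs_merit(tab, "AAC"))
})

test_that("best-first equals the exhaustive optimum on small instances", {
  tab <- make_cfs_table(150, list(AAA = 1.2, AAC = 0.8, AAG = 0), seed = 3)
  ex <- select_features(tab, candidates = c("AAA", "AAC", "AAG"),
                        method = "exhaustive")
  bf <- select_features(tab, candidates = c("AAA", "AAC", "AAG"),
                        method = "best_first")
  expect_equal(bf$merit, ex$merit, tolerance = 1e-12)
  expect_identical(bf$features, ex$features)
})

test_that("greedy <= best-first <= exhaustive on random instances", {
  withr::with_seed(55, {
    nms <- feature_names("B")[1:8]
    for (i in 1:10) {
      effects <- setNames(as.list(round(runif(8, 0, 1), 2)), nms)
      tab <- make_cfs_table(120, effects, seed = i)
      ms <- vapply(c("greedy_forward", "best_first", "exhaustive"),
                   function(m) select_features(tab, candidates = nms,
                                               method = m)$merit,
                   numeric(1))
      expect_lte(ms[["greedy_forward"]], ms[["best_first"]] + 1e-12)
      expect_lte(ms[["best_first"]], ms[["exhaustive"]] + 1e-12)
    }
  })
})

test_that("selection is invariant to affine rescaling of a feature", {
  tab <- make_cfs_table(200, list(AAA = 1.2, AAC = 0.6, AAG = 0), seed = 6)
  s1 <- select_features(tab, candidates = c("AAA", "AAC", "AAG"),
                        method = "exhaustive")
  tab$AAA <- 100 * tab$AAA - 7
  tab$AAG <- -0.01 * tab$AAG + 2
  s2 <- select_features(tab, candidates = c("AAA", "AAC", "AAG"),
                        method = "exhaustive")
  expect_identical(s1$features, s2$features)
  expect_equal(s1$merit, s2$merit, tolerance = 1e-12)
})

test_that("all-noise candidates yield only a chance-level merit", {
  tab <- make_cfs_table(400, setNames(as.list(rep(0, 6)),
                                      feature_names("B")[1:6]), seed = 12)
  sel <- select_features(tab, candidates = feature_names("B")[1:6],
                         method = "exhaustive")
  # no subset of independent noise comes near a real signal's merit
  # (|r_cf| is O(1/sqrt(n)) under the null)
  expect_lt(sel$merit, 0.25)
  signal <- make_cfs_table(400, list(AAA = 1), seed = 12)
  expect_gt(cfs_merit(signal, "AAA"), 2 * sel$merit)
})

test_that("exhaustive search above the candidate cap is refused", {
  hp <- generate_cohorts(animal_profile(n = 5), plant_profile(n = 5), seed = 1)
  ft <- extract_features(hp)
  expect_error(select_features(ft, candidates = feature_names("C")[1:26],
                               method = "exhaustive"), "best_first")
})
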