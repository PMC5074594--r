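test_that("KS statistic matches hand-checked cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$d, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$d, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS statistic and asymptotic p agree with stats::ks.test", {
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- rnorm(sample(5:40, 1))
      y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
      ours <- ks_two_sample(x, y)
      ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      expect_equal(ours$d, unname(ref$statistic), tolerance = 1e-12)
      # ks.test truncates its asymptotic series at ~1e-6 absolute
      expect_equal(ours$p, ref$p.value, tolerance = 1e-4)
    }
  })
})

test_that("KS d is invariant under strictly monotone transforms and grows with shift", {
  withr::with_seed(31, {
    x <- rnorm(80)
    y <- rnorm(60, 0.5)
    d0 <- ks_two_sample(x, y)$d
    expect_equal(ks_two_sample(exp(x), exp(y))$d, d0)
    expect_equal(ks_two_sample(x^3, y^3)$d, d0)
    shifts <- c(0, 0.5, 1, 2, 4)
    ds <- vapply(shifts, function(s) ks_two_sample(x, x + s)$d, numeric(1))
    expect_true(all(diff(ds) >= 0))
  })
})

test_that("Welch t wrapper handles extreme and degenerate inputs", {
  withr::with_seed(5, {
    x <- rnorm(50, 0, 0.01)
    y <- rnorm(50, 5, 0.01)
    res <- welch_t(x, y)
    expect_lt(res$p, 1e-10)
    expect_lt(res$statistic, 0)
  })
  same <- c(1, 1, 1)
  expect_equal(welch_t(same, same), tibble::tibble(statistic = 0, p = 1))
  expect_equal(welch_t(c(0, 0), c(5, 5))$p, 0)
})

test_that("screening flags shifted features and not null ones", {
  withr::with_seed(77, {
    n <- 500
    hp <- generate_cohorts(animal_profile(n = 5), plant_profile(n = 5), seed = 1)
    ft <- extract_features(hp)
    # overwrite two feature columns with controlled draws at larger n
    lab <- rep(c("animal", "plant"), each = n)
    tab <- ft[rep(1, 2 * n), ]
    tab$id <- as.character(seq_len(2 * n))
    tab$label <- lab
    tab$AAA <- rnorm(2 * n)                      # null feature
    tab$length <- rnorm(2 * n) + 3 * (lab == "plant")  # 3 SD shift
    scr <- suppressMessages(screen_features(tab))
    expect_false(scr$pass_d[scr$feature == "AAA"])
    expect_true(scr$pass_d[scr$feature == "length"])
    expect_equal(scr$direction[scr$feature == "length"], "higher_in_plant")
    # constant feature (every row is the same record): d = 0, excluded
    expect_equal(scr$ks_d[scr$feature == "GGG"], 0)
    expect_false(scr$pass_d[scr$feature == "GGG"])
  })
})

test_that("screening requires two labels and reports pairwise drops", {
  hp <- generate_cohorts(animal_profile(n = 4), plant_profile(n = 4), seed = 4)
  ft <- extract_features(hp)
  expect_error(screen_features(dplyr::filter(ft, label == "animal")),
               "two labels")
  ft$mfei[1:2] <- NA
  scr <- suppressMessages(screen_features(ft))
  expect_equal(scr$n_missing_dropped[scr$feature == "mfei"], 2)
  expect_true(all(scr$pass_d == (scr$ks_d >= 0.15), na.rm = TRUE))
})

test_that("feature correlations are Pearson, symmetric, unit-diagonal", {
  hp <- generate_cohorts(animal_profile(n = 30), plant_profile(n = 30), seed = 8)
  ft <- extract_features(hp)
  cm <- feature_correlations(ft)
  expect_equal(dim(cm), c(132, 132))
  expect_equal(unname(diag(cm)[!is.na(diag(cm))]),
               rep(1, sum(!is.na(diag(cm)))))
  expect_equal(cm, t(cm))
  expect_equal(cm["length", "amfe"],
               stats::cor(ft$length, ft$amfe), tolerance = 1e-12)
  # negation correlates at exactly -1
  ft2 <- ft
  ft2$AAA <- -ft2$length
  expect_equal(feature_correlations(ft2)["AAA", "length"], -1)
})
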