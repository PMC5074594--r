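test_that("the published model has the fixed coefficients and orientation", {
  m <- published_model()
  expect_equal(m$intercept, 6.1436)
  expect_length(m$coefficients, 4)
  expect_equal(m$coefficients,
               c(n_helix = 0.0893, n_stack = -0.0691,
                 length = -0.0241, mfe = 0.0263))
  expect_equal(m$positive_label, "animal")
})

test_that("prediction applies the logit link and calls classes at 0.5", {
  m <- published_model()
  origin <- c(n_helix = 0, n_stack = 0, length = 0, mfe = 0)
  expect_equal(predict(m, origin, type = "link"), 6.1436)
  expect_equal(predict(m, origin), stats::plogis(6.1436), tolerance = 1e-10)

  plantish <- c(n_helix = 8, n_stack = 45, length = 200, mfe = -90)
  expect_equal(predict(m, plantish, type = "link"), -3.4385, tolerance = 1e-10)
  expect_equal(predict(m, plantish), stats::plogis(-3.4385), tolerance = 1e-10)
  expect_equal(predict(m, plantish, type = "class"), "plant")

  animalish <- c(n_helix = 3, n_stack = 20, length = 85, mfe = -35)
  expect_equal(predict(m, animalish, type = "link"), 2.0605, tolerance = 1e-10)
  expect_equal(predict(m, animalish), stats::plogis(2.0605), tolerance = 1e-10)
  expect_equal(predict(m, animalish, type = "class"), "animal")

  expect_error(predict(m, c(n_helix = 1)), "n_stack")
  expect_error(predict(m, c(n_helix = NA, n_stack = 0, length = 0, mfe = 0)),
               "missing")
})

test_that("prediction is monotone in each feature with the coefficient sign", {
  m <- published_model()
  base <- tibble::tibble(n_helix = 4, n_stack = 30, length = 100, mfe = -40)
  for (nm in names(m$coefficients)) {
    up <- base
    up[[nm]] <- up[[nm]] + 10
    delta <- predict(m, up) - predict(m, base)
    expect_equal(sign(delta), sign(m$coefficients[[nm]]))
  }
})

test_that("IRLS training matches stats::glm on well-behaved data", {
  withr::with_seed(42, {
    n <- 600
    tab <- tibble::tibble(
      id = as.character(1:n),
      length = rnorm(n, 100, 25),
      mfe = rnorm(n, -40, 12))
    eta <- 1 - 0.02 * tab$length - 0.05 * tab$mfe
    tab$label <- ifelse(runif(n) < plogis(eta), "animal", "plant")
    fit <- train_logistic(tab, c("length", "mfe"))
    ref <- stats::glm(I(label == "animal") ~ length + mfe,
                      data = tab, family = stats::binomial())
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-4)
    expect_true(fit$converged)
  })
})

test_that("intercept-only structure recovers the log odds of the base rate", {
  withr::with_seed(8, {
    n <- 1000
    tab <- tibble::tibble(id = as.character(1:n),
                          AAA = rnorm(n),
                          label = rep(c("animal", "plant"), times = c(700, 300)))
    fit <- train_logistic(tab, "AAA")
    expect_equal(fit$intercept, log(0.7 / 0.3), tolerance = 0.15)
    expect_lt(abs(fit$coefficients[["AAA"]]), 3 * fit$se[["AAA"]])
  })
})

test_that("separated data error without ridge and fit with it", {
  tab <- tibble::tibble(
    id = as.character(1:40),
    length = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)),
    label = rep(c("animal", "plant"), each = 20))
  expect_error(train_logistic(tab, "length"), "separat")
  fit <- suppressWarnings(train_logistic(tab, "length", ridge = TRUE))
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  p <- predict(fit, tab)
  expect_true(all(p[1:20] > 0.5) && all(p[21:40] < 0.5))
})

test_that("ZeroR predicts the majority with its fraction and AUC 0.5", {
  tab <- tibble::tibble(id = as.character(1:10),
                        label = rep(c("animal", "plant"), times = c(7, 3)))
  zr <- zero_r(tab)
  expect_equal(zr$majority, "animal")
  expect_equal(zr$fraction, 0.7)
  expect_equal(predict(zr, tab), rep(0.7, 10))
  expect_equal(roc_auc(predict(zr, tab), tab$label, "animal"), 0.5)
  # tie: deterministic lexicographic pick
  tie <- tibble::tibble(id = as.character(1:4),
                        label = c("plant", "plant", "animal", "animal"))
  expect_equal(zero_r(tie)$majority, "animal")
})

test_that("rank AUC equals trapezoidal ROC integration and pROC", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      lab <- sample(c("animal", "plant"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
      if (length(unique(lab)) < 2) next
      scores <- rnorm(n) + (lab == "animal") * runif(1, 0, 2)
      scores <- round(scores, 1)  # induce ties
      a <- roc_auc(scores, lab, "animal")
      expect_equal(a, trapezoid_auc(scores, lab, "animal"), tolerance = 1e-10)
      ref <- pROC::auc(pROC::roc(lab, scores, levels = c("plant", "animal"),
                                 direction = "<", quiet = TRUE))
      expect_equal(a, as.numeric(ref), tolerance = 1e-10)
    }
  })
})

test_that("model files round-trip through the flat text format", {
  m <- published_model()
  path <- withr::local_tempfile()
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$positive_label, "animal")
  expect_equal(back$negative_label, "plant")
})

test_that("cross-validation is perfect on separable data and null on shuffled labels", {
  hp <- generate_cohorts(animal_profile(n = 50), plant_profile(n = 50), seed = 14)
  ft <- extract_features(hp)
  # make the cohorts cleanly separable on one column
  ft$length <- ifelse(ft$label == "animal", ft$length, ft$length + 1000)
  cv <- cross_validate(ft, "length", k = 5, seed = 2)
  expect_equal(cv$metrics$precision, 1)
  expect_equal(cv$metrics$roc_area, 1)

  withr::with_seed(99, ft$label <- sample(ft$label))
  cv0 <- cross_validate(ft, c("AAA", "ACG"), k = 5, seed = 2)
  expect_lt(abs(cv0$metrics$roc_area - 0.5), 0.15)
})

test_that("cross-validation demands enough members per class", {
  hp <- generate_cohorts(animal_profile(n = 5), plant_profile(n = 5), seed = 1)
  ft <- extract_features(hp)
  expect_error(cross_validate(ft, "length", k = 10, seed = 1), "at least k")
})

test_that("zero_r cross-validation reports the majority TP rate and AUC 0.5", {
  hp <- generate_cohorts(animal_profile(n = 30), plant_profile(n = 20), seed = 6)
  ft <- extract_features(hp)
  cv <- cross_validate(ft, "length", model = "zero_r", k = 5, seed = 3)
  expect_equal(cv$metrics$roc_area, 0.5)
  expect_equal(cv$metrics$tp_rate, 0.6)  # majority fraction 30/50
})
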