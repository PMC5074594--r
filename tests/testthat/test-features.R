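test_that("composition frequencies use overlapping windows", {
  f <- seq_composition("AACG")
  expect_equal(unname(f[c("A", "C", "G", "U")]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(f[c("AA", "AC", "CG")]), rep(1 / 3, 3))
  f <- seq_composition("UUUU")
  expect_equal(unname(f[c("U", "UU", "UUU")]), c(1, 1, 1))
  f <- seq_composition("ACGUACGU")
  expect_equal(unname(f[c("A", "C", "G", "U")]), rep(0.25, 4))
})

test_that("triplet states follow the left/self/right mark convention", {
  d <- triplet_state_features("ACGU", "....")
  expect_equal(unname(d[c("A...", "C...", "G...", "U...")]), rep(0.25, 4))
  expect_equal(sum(d), 1)
  d <- triplet_state_features("GC", "()")
  expect_equal(unname(d["G.++"]), 0.5)  # virtual unpaired left neighbour
  expect_equal(unname(d["C++."]), 0.5)
  # interior position with paired left, paired self, unpaired right
  d <- triplet_state_features("GGGAAACCC", "(((...)))")
  expect_equal(unname(d["G++."]), 1 / 9)
})

test_that("energy and ratio features follow their definitions", {
  expect_equal(unname(energy_features(-50, 100, 0.5)), c(-50, -50, -1))
  expect_equal(unname(energy_features(0, 80, 0.4)), c(0, 0, 0))
  expect_true(is.na(energy_features(-10, 50, 0)[["mfei"]]))
  r <- ratio_features("GGCC")
  expect_equal(unname(r["gc_content"]), 1)
  expect_true(is.na(r[["gc_over_au"]]))
  expect_equal(unname(r["a_over_c"]), 0)
  expect_true(is.na(r[["g_over_u"]]))
  r <- ratio_features("ACGU")
  expect_equal(unname(r), c(0.5, 1, 1, 1))
  expect_true(is.na(ratio_features("AAAA")[["a_over_c"]]))
})

test_that("entropy matches the closed forms and rejects bad input", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("the catalog partitions 132 unique names into the eight classes", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 132)
  expect_equal(anyDuplicated(cat$name), 0)
  expect_equal(as.integer(table(cat$class)[LETTERS[1:8]]),
               c(4, 16, 64, 32, 5, 3, 4, 4))
})

test_that("extract_all produces the full named vector with hand-checked values", {
  fv <- extract_all("GGGAAACCC", "(((...)))", mfe = -1.2)
  expect_length(fv, 132)
  expect_identical(names(fv), feature_catalog()$name)
  expect_equal(unname(fv[c("n_bulge", "n_helix", "n_interior", "n_stack", "length")]),
               c(0, 1, 0, 2, 9))
  expect_equal(unname(fv["iesn"]), -3 * (1 / 3) * log2(1 / 3))
  expect_equal(unname(fv["amfe"]), 100 * -1.2 / 9)
  # determinism: identical input, identical vector
  expect_identical(fv, extract_all("GGGAAACCC", "(((...)))", mfe = -1.2))
})

test_that("frequency classes are normalised and entropies match brute force on random hairpins", {
  hp <- generate_cohorts(animal_profile(n = 10), plant_profile(n = 10), seed = 9)
  ft <- extract_features(hp)
  for (i in seq_len(nrow(ft))) {
    for (cl in c("A", "B", "C", "D")) {
      expect_equal(sum(as.numeric(ft[i, feature_names(cl)])), 1,
                   tolerance = 1e-12)
    }
    expect_equal(ft$iesn[i],
                 brute_entropy(as.numeric(ft[i, feature_names("A")])),
                 tolerance = 1e-12)
    expect_equal(ft$iess[i],
                 brute_entropy(as.numeric(ft[i, feature_names("D")])),
                 tolerance = 1e-12)
  }
})

test_that("class A and its entropy are invariant under sequence shuffling", {
  withr::with_seed(3, {
    seq <- random_rna(60)
    shuf <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
    a1 <- seq_composition(seq)[feature_names("A")]
    a2 <- seq_composition(shuf)[feature_names("A")]
    expect_equal(a1, a2)
    expect_equal(shannon_entropy(a1), shannon_entropy(a2))
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(seq_composition(rev_seq)[feature_names("A")], a1)
  })
})

test_that("records without energies yield NA class F with one warning", {
  hp <- generate_cohorts(animal_profile(n = 2), plant_profile(n = 2), seed = 2)
  hp$mfe[1] <- NA
  expect_warning(ft <- extract_features(hp), "class F")
  expect_true(all(is.na(ft[1, c("mfe", "amfe", "mfei")])))
  expect_false(anyNA(ft[2, c("mfe", "amfe", "mfei")]))
})
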