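#' Describe a synthetic hairpin cohort
#'
#' A profile fixes the generative law of one labelled cohort: the length
#' distribution, the target GC fraction, the per-stem-event rates of bulge
#' and interior-loop insertion, and a linear-in-stacks energy surrogate
#' (`mfe = energy_per_stack * n_stack + N(0, energy_sd)`), so no
#' thermodynamic folding engine is needed to obtain consistent
#' sequence/structure/energy triples.
#'
#' @param label Cohort label (e.g. `"animal"`).
#' @param n Cohort size.
#' @param length_law List describing the length distribution: either
#'   `list(family = "normal", mean =, sd =)` or
#'   `list(family = "lognormal", meanlog =, sdlog =)`; draws are rounded
#'   and truncated to `min_length`.
#' @param gc_mean Target G+C fraction in `[0, 1]`.
#' @param bulge_rate,interior_rate Per-stem-event insertion probabilities.
#' @param energy_per_stack Mean energy per stack step (kcal/mol, negative).
#' @param energy_sd Gaussian noise sd on the surrogate energy.
#' @param min_length Lower truncation of the length law (>= 40).
#' @return A `cohort_profile` object.
#' @export
cohort_profile <- function(label, n,
                           length_law = list(family = "normal",
                                             mean = 85, sd = 12),
                           gc_mean = 0.45,
                           bulge_rate = 0.05, interior_rate = 0.04,
                           energy_per_stack = -1.4, energy_sd = 3,
                           min_length = 55) {
  stopifnot(n >= 1, gc_mean >= 0, gc_mean <= 1,
            bulge_rate >= 0, bulge_rate <= 1,
            interior_rate >= 0, interior_rate <= 1,
            bulge_rate + interior_rate < 1,
            energy_sd >= 0, min_length >= 40)
  if (!length_law$family %in% c("normal", "lognormal"))
    abort("length_law$family must be 'normal' or 'lognormal'")
  structure(list(label = label, n = as.integer(n), length_law = length_law,
                 gc_mean = gc_mean, bulge_rate = bulge_rate,
                 interior_rate = interior_rate,
                 energy_per_stack = energy_per_stack, energy_sd = energy_sd,
                 min_length = as.integer(min_length)),
            class = "cohort_profile")
}

#' Default cohort profiles
#'
#' The animal-like cohort has tightly concentrated lengths
#' (normal, mean 85, sd 12 nt — most sequences fall in 70–100 nt), while
#' the plant-like cohort is longer with a heavy right tail (lognormal,
#' median 130 nt, sdlog 0.55 — a few percent of draws exceed 318 nt) and
#' slightly more frequent bulge/interior interruptions, giving it more
#' helices and interior loops per precursor. Longer plant-like stems carry
#' more stacks and hence lower surrogate energies, reproducing the
#' qualitative animal/plant contrasts in length, stack count and MFE.
#'
#' @param n Cohort size.
#' @return A `cohort_profile`.
#' @examples
#' generate_cohorts(animal_profile(n = 10), plant_profile(n = 10), seed = 1)
#' @export
animal_profile <- function(n = 500) {
  cohort_profile("animal", n,
                 length_law = list(family = "normal", mean = 85, sd = 12),
                 gc_mean = 0.46, bulge_rate = 0.05, interior_rate = 0.04)
}

#' @rdname animal_profile
#' @export
plant_profile <- function(n = 500) {
  cohort_profile("plant", n,
                 length_law = list(family = "lognormal",
                                   meanlog = log(130), sdlog = 0.55),
                 gc_mean = 0.44, bulge_rate = 0.07, interior_rate = 0.06)
}

.draw_length <- function(law, min_length) {
  for (i in 1:1000) {
    L <- switch(law$family,
                normal = round(rnorm(1, law$mean, law$sd)),
                lognormal = round(stats::rlnorm(1, law$meanlog, law$sdlog)))
    if (L >= min_length) return(as.integer(L))
  }
  abort("length law almost never exceeds min_length; check the profile")
}

.draw_base <- function(n, gc) {
  sample(c("G", "C", "A", "U"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

.draw_pair <- function(gc, wobble = 0.05) {
  u <- runif(1)
  if (u < wobble) {
    if (runif(1) < 0.5) c("G", "U") else c("U", "G")
  } else if (u < wobble + (1 - wobble) * gc) {
    if (runif(1) < 0.5) c("G", "C") else c("C", "G")
  } else {
    if (runif(1) < 0.5) c("A", "U") else c("U", "A")
  }
}

#' Generate one synthetic hairpin
#'
#' Draws a length from the profile's law, then assembles a stem-loop from
#' the outside in: each stem event is a Watson-Crick/wobble pair, a 1-2 nt
#' bulge on one strand, or a 1 nt-per-strand interior loop, at the profile
#' rates; a 3-8 nt terminal loop closes the stem. The emitted dot-bracket
#' is consistent with the sequence by construction, and the surrogate
#' energy is linear in the resulting stack count. Uses the current RNG
#' state; seed control lives in [generate_cohorts()].
#'
#' @param profile A [cohort_profile()].
#' @return A one-row hairpin tibble (`id`, `sequence`, `structure`, `mfe`,
#'   `label`).
#' @export
generate_hairpin <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  L <- .draw_length(profile$length_law, profile$min_length)
  loop <- sample(3:8, 1)
  if (L < 2 + loop) abort(sprintf("length %d infeasible for a stem-loop", L))
  rem <- L - loop
  s5 <- s3 <- character(0)   # outer -> inner
  d5 <- d3 <- character(0)
  n_pairs <- 0L
  while (rem >= 2) {
    u <- runif(1)
    if (n_pairs > 0 && u < profile$bulge_rate && rem >= 3) {
      b <- min(sample(1:2, 1), rem - 2L)
      side <- sample(c("5", "3"), 1)
      bases <- .draw_base(b, profile$gc_mean)
      if (side == "5") {
        s5 <- c(s5, bases); d5 <- c(d5, rep(".", b))
      } else {
        s3 <- c(s3, bases); d3 <- c(d3, rep(".", b))
      }
      rem <- rem - b
    } else if (n_pairs > 0 &&
               u < profile$bulge_rate + profile$interior_rate && rem >= 4) {
      s5 <- c(s5, .draw_base(1, profile$gc_mean))
      s3 <- c(s3, .draw_base(1, profile$gc_mean))
      d5 <- c(d5, "."); d3 <- c(d3, ".")
      rem <- rem - 2L
    } else {
      pr <- .draw_pair(profile$gc_mean)
      s5 <- c(s5, pr[1]); s3 <- c(s3, pr[2])
      d5 <- c(d5, "("); d3 <- c(d3, ")")
      n_pairs <- n_pairs + 1L
      rem <- rem - 2L
    }
  }
  loop <- loop + rem  # absorb a possible leftover nucleotide
  loop_bases <- .draw_base(loop, profile$gc_mean)
  sequence <- paste(c(s5, loop_bases, rev(s3)), collapse = "")
  db <- paste(c(d5, rep(".", loop), rev(d3)), collapse = "")
  el <- decompose_structure(db)
  mfe <- min(0, profile$energy_per_stack * el$n_stack +
                  rnorm(1, 0, profile$energy_sd))
  new_hairpin_tbl(id = paste0(profile$label, "_hp"), sequence = sequence,
                  structure = db, mfe = mfe, label = profile$label)
}

#' Generate two labelled synthetic cohorts
#'
#' @param profile1,profile2 [cohort_profile()]s, by default the animal-like
#'   and plant-like defaults.
#' @param seed Integer seed; the draw is fully reproducible given it.
#' @return A hairpin tibble with `profile1$n + profile2$n` rows and unique
#'   ids `<label>_<i>`.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 10), plant_profile(n = 10), seed = 1)
#' dplyr::count(hp, label)
#' @export
generate_cohorts <- function(profile1 = animal_profile(),
                             profile2 = plant_profile(),
                             seed = 1L) {
  gen <- function() {
    purrr::map(list(profile1, profile2), function(pr) {
      recs <- purrr::map(seq_len(pr$n), function(i) {
        r <- generate_hairpin(pr)
        r$id <- paste0(pr$label, "_", i)
        r
      })
      dplyr::bind_rows(recs)
    }) |> dplyr::bind_rows()
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
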