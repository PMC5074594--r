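#' Run the full screening / selection / evaluation pipeline
#'
#' Chains the package stages on a labelled hairpin table: feature
#' extraction, two-sample screening, CFS subset search over the screened
#' shortlist, and stratified cross-validation of a logistic classifier on
#' the selected subset. Writes five artifacts to `outdir` (features,
#' screening table, selected subset, CV report, plain-text summary), each
#' stamped with the seed and package version; re-running with the same
#' inputs and seed reproduces them byte for byte.
#'
#' @param hairpins Labelled hairpin tibble (two labels), with structures
#'   present or an `engine` configured.
#' @param outdir Output directory (created if needed).
#' @param d_threshold,p_threshold Screening thresholds (defaults 0.15 and
#'   0.001).
#' @param top_n Size cap of the screened shortlist handed to subset search
#'   (the `pass_d` features ranked by KS statistic; default 17).
#' @param select_method Search strategy for [select_features()].
#' @param folds,seed Cross-validation folds (default 10) and seed.
#' @param engine Optional folding engine for records without structures.
#' @return Invisibly, a list with the stage results (`features`,
#'   `screening`, `selection`, `cv`) and `paths` to the written artifacts.
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 60), plant_profile(n = 60), seed = 1)
#' res <- run_pipeline(hp, outdir = tempfile(), folds = 5, seed = 1)
#' res$selection
#' @export
run_pipeline <- function(hairpins, outdir,
                         d_threshold = 0.15, p_threshold = 0.001,
                         top_n = 17L,
                         select_method = c("best_first", "greedy_forward",
                                           "exhaustive"),
                         folds = 10L, seed = 1L, engine = NULL) {
  select_method <- match.arg(select_method)
  .check_hairpins(hairpins)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) inform(paste0("[pipeline] ", sprintf(...)))

  log_line("extract: %d records in", nrow(hairpins))
  features <- extract_features(hairpins, engine = engine)
  p_features <- file.path(outdir, "features.tsv")
  write_feature_table(features, p_features)

  screening <- screen_features(features, d_threshold = d_threshold,
                               p_threshold = p_threshold)
  n_pass <- sum(screening$pass_d, na.rm = TRUE)
  log_line("screen: %d/%d features pass d >= %.3g", n_pass,
           nrow(screening), d_threshold)
  p_screen <- file.path(outdir, "screening.tsv")
  readr::write_tsv(screening, p_screen, na = "NA")

  shortlist <- screening |>
    dplyr::filter(.data$pass_d) |>
    dplyr::arrange(dplyr::desc(.data$ks_d), .data$feature) |>
    dplyr::pull(.data$feature)
  if (length(shortlist) < 2)
    shortlist <- screening |>
      dplyr::arrange(dplyr::desc(.data$ks_d), .data$feature) |>
      dplyr::pull(.data$feature)
  shortlist <- head(shortlist, top_n)
  selection <- select_features(features, candidates = shortlist,
                               method = select_method)
  log_line("select (%s): %d features, merit %.4f", select_method,
           length(selection$features), selection$merit)
  p_select <- file.path(outdir, "selected_subset.tsv")
  readr::write_tsv(
    tibble::tibble(feature = selection$features,
                   merit = selection$merit, method = select_method),
    p_select)

  cv <- cross_validate(features, selection$features, model = "logistic",
                       k = folds, seed = seed)
  log_line("evaluate: %d-fold CV roc_area %.3f", folds,
           cv$metrics$roc_area)
  p_cv <- file.path(outdir, "cv_report.tsv")
  readr::write_tsv(dplyr::bind_cols(glance(cv)), p_cv)

  p_summary <- file.path(outdir, "summary.txt")
  writeLines(c(
    paste0("mirkingdom pipeline v",
           as.character(utils::packageVersion("mirkingdom"))),
    paste0("seed: ", seed),
    paste0("records: ", nrow(hairpins)),
    paste0("screen: d_threshold ", d_threshold, ", p_threshold ", p_threshold,
           ", pass_d ", n_pass),
    paste0("selected (", select_method, ", merit ",
           format(selection$merit, digits = 6), "): ",
           paste(selection$features, collapse = ", ")),
    sprintf("cv (%d-fold): tp_rate %.4f precision %.4f recall %.4f roc_area %.4f",
            folds, cv$metrics$tp_rate, cv$metrics$precision,
            cv$metrics$recall, cv$metrics$roc_area)
  ), p_summary)

  invisible(list(
    features = features, screening = screening, selection = selection,
    cv = cv,
    paths = c(features = p_features, screening = p_screen,
              selected = p_select, cv = p_cv, summary = p_summary)))
}
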