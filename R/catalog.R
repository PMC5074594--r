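#' The canonical 132-feature catalog
#'
#' Every hairpin descriptor computed by this package is one of 132 named
#' features, organised in eight classes:
#'
#' * **A** (4): mononucleotide frequencies over A, C, G, U.
#' * **B** (16): overlapping dinucleotide frequencies.
#' * **C** (64): overlapping trinucleotide frequencies.
#' * **D** (32): triplet matching-state frequencies — each position is coded
#'   by its base together with the paired (`+`) / unpaired (`.`) status of
#'   its left neighbour, itself, and its right neighbour (e.g. `"G++."`).
#' * **E** (5): structural counts — bulge loops, helices, interior loops,
#'   stacks, and precursor length.
#' * **F** (3): minimum free energy (MFE, kcal/mol), adjusted MFE
#'   (`amfe = 100 * mfe / length`), and the MFE index
#'   (`mfei = amfe / (100 * gc_content)`).
#' * **G** (4): G+C content, (G+C)/(A+U), A/C and G/U ratios.
#' * **H** (4): Shannon entropies (bits) of the class A, B, C and D
#'   frequency vectors (`iesn`, `iedn`, `ietn`, `iess`).
#'
#' Feature order is fixed; name-based access is the stable contract.
#'
#' @return A tibble with one row per feature and columns `name`, `class`
#'   (letters A–H), `index` (1–132), and `description`.
#' @examples
#' feature_catalog()
#' dplyr::count(feature_catalog(), class)
#' @export
feature_catalog <- function() {
  .catalog
}

.bases <- c("A", "C", "G", "U")

.kmer_names <- function(k) {
  sort(do.call(paste0, rev(expand.grid(rep(list(.bases), k),
                                       stringsAsFactors = FALSE))))
}

# mark patterns in binary order, "." (unpaired) before "+" (paired),
# positions: left neighbour, self, right neighbour
.mark_patterns <- c("...", "..+", ".+.", ".++", "+..", "+.+", "++.", "+++")

.triplet_names <- as.vector(t(outer(.bases, .mark_patterns, paste0)))

.catalog_names <- local({
  e <- c("n_bulge", "n_helix", "n_interior", "n_stack", "length")
  f <- c("mfe", "amfe", "mfei")
  g <- c("gc_content", "gc_over_au", "a_over_c", "g_over_u")
  h <- c("iesn", "iedn", "ietn", "iess")
  c(.bases, .kmer_names(2), .kmer_names(3), .triplet_names, e, f, g, h)
})

.catalog_classes <- rep(LETTERS[1:8], times = c(4, 16, 64, 32, 5, 3, 4, 4))

.catalog <- local({
  desc <- c(
    paste0("frequency of ", .bases),
    paste0("frequency of dinucleotide ", .kmer_names(2)),
    paste0("frequency of trinucleotide ", .kmer_names(3)),
    paste0("frequency of triplet matching state ", .triplet_names),
    "number of bulge loops", "number of helices", "number of interior loops",
    "number of stacks (adjacent stacked pair-steps)", "precursor length (nt)",
    "minimum free energy (kcal/mol)", "adjusted MFE (100 * mfe / length)",
    "MFE index (amfe / GC%)",
    "G+C fraction", "(G+C)/(A+U) ratio", "A/C ratio", "G/U ratio",
    "entropy of mononucleotide frequencies (bits)",
    "entropy of dinucleotide frequencies (bits)",
    "entropy of trinucleotide frequencies (bits)",
    "entropy of triplet matching-state frequencies (bits)"
  )
  tibble::tibble(
    name = .catalog_names,
    class = .catalog_classes,
    index = seq_along(.catalog_names),
    description = desc
  )
})

#' Names of the features in a feature class
#'
#' @param classes Character vector of class letters among `LETTERS[1:8]`.
#' @return Character vector of feature names, in canonical order.
#' @examples
#' feature_names("E")
#' @export
feature_names <- function(classes = LETTERS[1:8]) {
  stopifnot(all(classes %in% LETTERS[1:8]))
  .catalog_names[.catalog_classes %in% classes]
}
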