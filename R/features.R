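#' Sequence composition features (classes A, B, C)
#'
#' Mono-, di- and trinucleotide frequencies with overlapping windows, so the
#' denominators are L, L-1 and L-2. Each class sums to 1 where defined;
#' dinucleotide (trinucleotide) frequencies are `NA` when the sequence is
#' shorter than 2 (3) nt.
#'
#' @param sequence RNA string over `A/C/G/U`.
#' @return Named numeric vector of the 84 class A-C frequencies in
#'   canonical order.
#' @examples
#' seq_composition("AACG")
#' @export
seq_composition <- function(sequence) {
  sequence <- .norm_sequence(sequence)
  .check_sequence(sequence, "<input>", "strict")
  L <- nchar(sequence)
  out <- numeric(0)
  for (k in 1:3) {
    nm <- .kmer_names(k)
    if (L < k) {
      out <- c(out, setNames(rep(NA_real_, length(nm)), nm))
      next
    }
    kmers <- substring(sequence, 1:(L - k + 1), k:L)
    cnt <- table(factor(kmers, levels = nm))
    out <- c(out, setNames(as.numeric(cnt) / (L - k + 1), nm))
  }
  out
}

#' Triplet matching-state frequencies (class D)
#'
#' Each position contributes one of 32 states: its base combined with the
#' paired (`+`) / unpaired (`.`) status of the left neighbour, the position
#' itself, and the right neighbour — e.g. `"G++."` is a paired G whose left
#' neighbour is paired and whose right neighbour is not. Terminal positions
#' use a virtual unpaired neighbour, so the 32 frequencies always sum to 1.
#'
#' @param sequence RNA string.
#' @param structure Dot-bracket string of the same length, or a pair table.
#' @return Named numeric vector of the 32 state frequencies.
#' @examples
#' triplet_state_features("GC", "()")
#' @export
triplet_state_features <- function(sequence, structure) {
  sequence <- .norm_sequence(sequence)
  .check_sequence(sequence, "<input>", "strict")
  pairs <- if (is.character(structure)) parse_dotbracket(structure)
           else as.integer(structure)
  L <- nchar(sequence)
  if (length(pairs) != L)
    abort("structure length does not match sequence length")
  paired <- pairs > 0
  mark <- function(p) ifelse(p, "+", ".")
  left <- c(FALSE, paired[-L])
  right <- c(paired[-1], FALSE)
  states <- paste0(strsplit(sequence, "")[[1]],
                   mark(left), mark(paired), mark(right))
  cnt <- table(factor(states, levels = .triplet_names))
  setNames(as.numeric(cnt) / L, .triplet_names)
}

#' Structural count features (class E)
#'
#' @param sequence RNA string (supplies the length).
#' @param structure Dot-bracket string or pair table, or a precomputed
#'   [decompose_structure()] result.
#' @return Named numeric vector `n_bulge`, `n_helix`, `n_interior`,
#'   `n_stack`, `length`.
#' @export
structural_counts <- function(sequence, structure) {
  el <- if (inherits(structure, "structural_elements")) structure
        else decompose_structure(structure)
  c(n_bulge = as.numeric(el$n_bulge), n_helix = as.numeric(el$n_helix),
    n_interior = as.numeric(el$n_interior), n_stack = as.numeric(el$n_stack),
    length = as.numeric(nchar(sequence)))
}

#' Energy features (class F)
#'
#' `amfe` normalises the minimum free energy per 100 nt
#' (`100 * mfe / length`); `mfei` divides it by the GC percentage
#' (`amfe / (100 * gc_fraction)`), and is `NA` for GC-free sequences.
#'
#' @param mfe Minimum free energy in kcal/mol (`NA` gives all-`NA` class F).
#' @param length Sequence length in nt.
#' @param gc_fraction G+C fraction in `[0, 1]`.
#' @return Named numeric vector `mfe`, `amfe`, `mfei`.
#' @examples
#' energy_features(-50, 100, 0.5)
#' @export
energy_features <- function(mfe, length, gc_fraction) {
  if (length < 1) abort("length must be >= 1")
  if (is.na(mfe))
    return(c(mfe = NA_real_, amfe = NA_real_, mfei = NA_real_))
  amfe <- 100 * mfe / length
  mfei <- if (!is.na(gc_fraction) && gc_fraction > 0)
    amfe / (100 * gc_fraction) else NA_real_
  c(mfe = mfe, amfe = amfe, mfei = mfei)
}

#' Base-ratio features (class G)
#'
#' @param sequence RNA string.
#' @return Named numeric vector `gc_content`, `gc_over_au`, `a_over_c`,
#'   `g_over_u`; a zero denominator yields `NA`.
#' @examples
#' ratio_features("ACGU")
#' @export
ratio_features <- function(sequence) {
  sequence <- .norm_sequence(sequence)
  .check_sequence(sequence, "<input>", "strict")
  n <- .base_counts(sequence)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  c(gc_content = (n[["G"]] + n[["C"]]) / sum(n),
    gc_over_au = rat(n[["G"]] + n[["C"]], n[["A"]] + n[["U"]]),
    a_over_c = rat(n[["A"]], n[["C"]]),
    g_over_u = rat(n[["G"]], n[["U"]]))
}

#' Shannon information entropy of a frequency vector
#'
#' Computes `-sum(p * log2(p))` in bits, with the convention
#' `0 * log2(0) = 0`. Applied to the class A, B, C and D frequency vectors
#' this yields the four entropy features `iesn`, `iedn`, `ietn`, `iess`.
#'
#' @param p Non-negative frequencies summing to 1 (tolerance `1e-9`).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))
#' @export
shannon_entropy <- function(p) {
  if (anyNA(p)) return(NA_real_)
  if (any(p < 0)) abort("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) abort("frequencies must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# the full 132-vector for one record; warn_energy controls the class F note
.extract_one <- function(id, sequence, structure, mfe) {
  abc <- seq_composition(sequence)
  d <- triplet_state_features(sequence, structure)
  el <- decompose_structure(structure)
  e <- structural_counts(sequence, el)
  g <- ratio_features(sequence)
  f <- energy_features(mfe, nchar(sequence), g[["gc_content"]])
  ent <- function(nms) {
    v <- abc[intersect(nms, names(abc))]
    if (anyNA(v)) NA_real_ else shannon_entropy(v)
  }
  h <- c(iesn = ent(.kmer_names(1)), iedn = ent(.kmer_names(2)),
         ietn = ent(.kmer_names(3)), iess = shannon_entropy(d))
  out <- c(abc, d, e, f, g, h)
  stopifnot(identical(names(out), .catalog_names))
  out
}

#' Extract the 132-feature vector of one hairpin
#'
#' @param sequence RNA string.
#' @param structure Dot-bracket string of the same length.
#' @param mfe Minimum free energy in kcal/mol; `NA` leaves class F missing.
#' @return Named numeric vector of the 132 catalog features.
#' @examples
#' fv <- extract_all("GGGAAACCC", "(((...)))", mfe = -1.2)
#' length(fv)
#' fv[c("n_helix", "n_stack", "length", "mfe")]
#' @export
extract_all <- function(sequence, structure, mfe = NA_real_) {
  sequence <- .norm_sequence(sequence)
  .check_sequence(sequence, "<input>", "strict")
  if (is.na(structure)) abort("structure is required (or configure a folding engine)")
  if (nchar(structure) != nchar(sequence))
    abort("structure length does not match sequence length")
  .extract_one("<record>", sequence, structure, mfe)
}

#' Extract features for a table of hairpins
#'
#' The workhorse of the pipeline: takes a hairpin tibble (as returned by
#' [read_vienna()], [generate_cohorts()] or [read_hairpin_fasta()] +
#' [fold_hairpins()]) and returns the feature table, one row per record with
#' `id`, `label` and the 132 canonical feature columns. Records without a
#' structure are folded when an engine is supplied and rejected otherwise;
#' records without an energy get `NA` in class F, with one summary warning.
#'
#' @param hairpins Hairpin tibble with columns `id`, `sequence` and
#'   optionally `structure`, `mfe`, `label`.
#' @param engine Optional folding engine (see [rnafold_engine()]).
#' @return A feature table tibble (`id`, `label`, 132 feature columns).
#' @examples
#' hp <- generate_cohorts(animal_profile(n = 5), plant_profile(n = 5), seed = 1)
#' extract_features(hp)
#' @export
extract_features <- function(hairpins, engine = NULL) {
  .check_hairpins(hairpins)
  if (!"label" %in% names(hairpins)) hairpins$label <- NA_character_
  hairpins <- fold_hairpins(hairpins, engine = engine)
  n_noenergy <- sum(is.na(hairpins$mfe))
  if (n_noenergy > 0)
    warn(sprintf("%d record(s) lack an energy; class F features set to NA",
                 n_noenergy))
  rows <- purrr::pmap(
    list(hairpins$id, hairpins$sequence, hairpins$structure, hairpins$mfe),
    function(id, seq, db, mfe) {
      if (nchar(db) != nchar(seq))
        abort(paste0("record '", id, "': structure/sequence length mismatch"))
      tibble::as_tibble_row(.extract_one(id, seq, db, mfe))
    })
  dplyr::bind_cols(
    tibble::tibble(id = hairpins$id, label = hairpins$label),
    dplyr::bind_rows(rows)
  )
}
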