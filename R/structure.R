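#' Parse a dot-bracket structure into a pair table
#'
#' @param db A dot-bracket string over `.`, `(`, `)` describing a nested
#'   (pseudoknot-free) secondary structure.
#' @return An integer vector of length `nchar(db)`; element `i` is the
#'   1-based partner of position `i`, or `0` when unpaired.
#' @examples
#' parse_dotbracket("(((...)))")
#' @export
parse_dotbracket <- function(db) {
  if (length(db) != 1 || is.na(db)) abort("db must be a single string")
  chars <- strsplit(db, "")[[1]]
  if (length(chars) > 0 && !all(chars %in% c(".", "(", ")")))
    abort("dot-bracket may contain only '.', '(' and ')'")
  pairs <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket: unmatched '('")
  pairs
}

#' Decompose a secondary structure into its elements
#'
#' Walks a nested pair table and counts the classical stem-loop elements.
#' A *helix* is a maximal run of consecutively stacked pairs
#' (i,j), (i+1,j-1), ...; a *stack* is one adjacent pair-step inside a
#' helix, so `n_stack = n_pairs - n_helix`. For a pair directly enclosing
#' exactly one pair, the two unpaired gaps decide between a *bulge* (one
#' gap positive) and an *interior loop* (both positive); a pair enclosing
#' no pair closes a *hairpin loop*, and one enclosing two or more branches
#' closes a *multiloop*.
#'
#' @param x A dot-bracket string or a pair table from [parse_dotbracket()].
#' @return An object of class `structural_elements`: a list with counts
#'   `n_pairs`, `n_helix`, `n_stack`, `n_bulge`, `n_interior`, `n_hairpin`,
#'   `n_multiloop` and a `helices` tibble (outermost pair `i`, `j` and
#'   `n_pairs` per helix).
#' @examples
#' decompose_structure("((..((...))..))")
#' @export
decompose_structure <- function(x) {
  pairs <- if (is.character(x)) parse_dotbracket(x) else as.integer(x)
  n <- length(pairs)
  opens <- which(pairs > seq_len(n))
  n_pairs <- length(opens)

  # helix starts: opening pair not stacked on the previous opening pair
  helix_start <- opens[vapply(opens, function(i) {
    i == 1L || pairs[i - 1L] != pairs[i] + 1L
  }, logical(1))]
  n_helix <- length(helix_start)
  helices <- tibble::tibble(
    i = helix_start,
    j = pairs[helix_start],
    n_pairs = vapply(helix_start, function(i) {
      len <- 1L
      while (i + len <= n && pairs[i + len] == pairs[i] - len &&
             pairs[i + len] > i + len) len <- len + 1L
      len
    }, integer(1))
  )

  n_bulge <- n_interior <- n_hairpin <- n_multi <- 0L
  for (i in opens) {
    j <- pairs[i]
    branches <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (pairs[k] > k) {
        branches <- c(branches, k)
        k <- pairs[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    if (length(branches) == 0L) {
      n_hairpin <- n_hairpin + 1L
    } else if (length(branches) == 1L) {
      i2 <- branches[1L]
      j2 <- pairs[i2]
      g1 <- i2 - i - 1L
      g2 <- j - j2 - 1L
      if (g1 > 0L && g2 > 0L) n_interior <- n_interior + 1L
      else if (g1 > 0L || g2 > 0L) n_bulge <- n_bulge + 1L
      # both gaps zero: stacked pair, part of the same helix
    } else {
      n_multi <- n_multi + 1L
    }
  }

  structure(list(
    n_pairs = n_pairs, n_helix = n_helix,
    n_stack = n_pairs - n_helix,
    n_bulge = n_bulge, n_interior = n_interior,
    n_hairpin = n_hairpin, n_multiloop = n_multi,
    helices = helices
  ), class = "structural_elements")
}

#' @export
print.structural_elements <- function(x, ...) {
  cat("<structural_elements> ", x$n_pairs, " pairs in ", x$n_helix,
      " helices (", x$n_stack, " stacks); loops: ", x$n_hairpin,
      " hairpin, ", x$n_bulge, " bulge, ", x$n_interior, " interior, ",
      x$n_multiloop, " multibranch\n", sep = "")
  invisible(x)
}

#' @method tidy structural_elements
#' @export
tidy.structural_elements <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, n_helix = x$n_helix, n_stack = x$n_stack,
    n_bulge = x$n_bulge, n_interior = x$n_interior,
    n_hairpin = x$n_hairpin, n_multiloop = x$n_multiloop
  )
}

#' Folding adapters
#'
#' Structure prediction is pluggable: any function taking an RNA string and
#' returning `list(structure = <dot-bracket>, mfe = <kcal/mol>)` can serve
#' as an engine. `rnafold_engine()` builds such an adapter around an
#' RNAfold-compatible executable; every pipeline path also accepts
#' precomputed structures, so no engine is ever required.
#'
#' @param cmd Name or path of the RNAfold-compatible executable.
#' @return A folding engine function.
#' @export
rnafold_engine <- function(cmd = "RNAfold") {
  if (!nzchar(Sys.which(cmd)))
    abort(paste0("executable not found: ", cmd))
  force(cmd)
  function(sequence) {
    out <- system2(cmd, args = c("--noPS"), input = sequence, stdout = TRUE)
    sl <- trimws(out[2])
    m <- regmatches(sl, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)\\s*$", sl))[[1]]
    if (length(m) == 0) abort(paste0(cmd, " returned unparseable output"))
    list(structure = m[2], mfe = as.double(m[3]))
  }
}

#' Fold a single sequence with a configured engine
#'
#' @param sequence RNA string over `A/C/G/U`.
#' @param engine A folding engine such as [rnafold_engine()]; `NULL` errors.
#' @return `list(structure = <dot-bracket>, mfe = <kcal/mol>)`.
#' @export
fold_sequence <- function(sequence, engine = NULL) {
  if (is.null(engine))
    abort(paste0("no folding engine configured; supply precomputed ",
                 "structures or an engine such as rnafold_engine()"))
  sequence <- .norm_sequence(sequence)
  .check_sequence(sequence, "<fold input>", "strict")
  res <- engine(sequence)
  if (nchar(res$structure) != nchar(sequence))
    abort("engine returned a structure of the wrong length")
  parse_dotbracket(res$structure)
  res
}

#' Fill missing structures in a hairpin table by folding
#'
#' @param hairpins A hairpin tibble (`id`, `sequence`, `structure`, `mfe`).
#' @param engine A folding engine; required if any structure is missing.
#' @return The hairpin tibble with `structure`/`mfe` completed.
#' @export
fold_hairpins <- function(hairpins, engine = NULL) {
  .check_hairpins(hairpins)
  if (!"structure" %in% names(hairpins)) hairpins$structure <- NA_character_
  if (!"mfe" %in% names(hairpins)) hairpins$mfe <- NA_real_
  todo <- which(is.na(hairpins$structure))
  if (length(todo) == 0) return(hairpins)
  for (i in todo) {
    res <- fold_sequence(hairpins$sequence[i], engine)
    hairpins$structure[i] <- res$structure
    hairpins$mfe[i] <- res$mfe
  }
  hairpins
}
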