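#' Read pre-miRNA hairpin sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA-style `T` is mapped to `U` on ingest,
#' so miRBase-style hairpin FASTA files can be used directly. Records with
#' characters outside `A/C/G/U` (after normalisation) either fail the whole
#' read (`mode = "strict"`) or are skipped with a warning
#' (`mode = "pipeline"`), which is the robust choice for large libraries.
#'
#' @param path Path to a FASTA file.
#' @param mode `"strict"` (default) errors on any invalid record;
#'   `"pipeline"` drops invalid records with a warning.
#' @return A hairpin tibble with columns `id`, `sequence`, `structure`
#'   (`NA`), `mfe` (`NA`), `label` (`NA`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hp1", "ACGT"), fa)
#' read_hairpin_fasta(fa)
#' @export
read_hairpin_fasta <- function(path, mode = c("strict", "pipeline")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- .norm_sequence(as.character(set))
  keep <- vapply(seq_along(seqs),
                 function(i) .check_sequence(seqs[i], ids[i], mode),
                 logical(1))
  new_hairpin_tbl(id = ids[keep], sequence = seqs[keep])
}

#' Read hairpins with dot-bracket structures (Vienna format)
#'
#' Parses repeated blocks of `>id` / sequence / structure, where the
#' structure line may carry a trailing energy in parentheses, as printed by
#' RNAfold (e.g. `"(((...))) (-1.20)"`). Structures must match the sequence
#' length and have balanced brackets.
#'
#' @inheritParams read_hairpin_fasta
#' @return A hairpin tibble with `structure` and (when present) `mfe` filled.
#' @examples
#' f <- tempfile()
#' writeLines(c(">x", "GGGAAACCC", "(((...))) (-1.20)"), f)
#' read_vienna(f)
#' @export
read_vienna <- function(path, mode = c("strict", "pipeline")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(paste0("no Vienna records in ", path))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    if (i + 2 > length(lines) ||
        (k < length(starts) && starts[k + 1] < i + 3))
      abort(paste0("truncated Vienna record at line ", i))
    id <- sub("\\s.*$", "", sub("^>", "", lines[i]))
    seq <- .norm_sequence(trimws(lines[i + 1]))
    sl <- trimws(lines[i + 2])
    m <- regmatches(sl, regexec("^([.()]+)(\\s*\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\))?\\s*$", sl))[[1]]
    if (length(m) == 0)
      abort(paste0("malformed structure line for record '", id, "'"))
    db <- m[2]
    mfe <- if (nzchar(m[4])) as.double(m[4]) else NA_real_
    rec_ok <- tryCatch({
      if (!.check_sequence(seq, id, mode)) FALSE else {
        if (nchar(db) != nchar(seq))
          abort(sprintf("record '%s': structure length %d != sequence length %d",
                        id, nchar(db), nchar(seq)))
        parse_dotbracket(db)  # validates balance
        TRUE
      }
    }, error = function(e) {
      if (mode == "strict") abort(conditionMessage(e))
      warn(paste0("skipping record '", id, "': ", conditionMessage(e)))
      FALSE
    })
    out[[k]] <- if (rec_ok) new_hairpin_tbl(id, seq, db, mfe) else NULL
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) abort(paste0("no valid Vienna records in ", path))
  res
}

#' Read one hairpin from an Mfold CT file
#'
#' Standard connectivity-table layout: a header line carrying the sequence
#' length (and usually an energy, e.g. `dG = -23.4`), then one line per base
#' with fields index, base, previous index, next index, pairing partner
#' (0 = unpaired), and the index again. The pair table is converted to
#' dot-bracket; inconsistent pairing (`p[i] = j` but `p[j] != i`) is an error.
#'
#' @param path Path to a CT file.
#' @param id Record identifier; defaults to the name found on the header
#'   line, or the file basename.
#' @return A one-row hairpin tibble.
#' @export
read_ct <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort(paste0("not a CT file: ", path))
  hdr <- trimws(lines[1])
  n <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", hdr)))
  if (is.na(n) || n < 1) abort("CT header does not start with the length")
  em <- regmatches(hdr, regexec("[dD][gG]\\s*=?\\s*(-?[0-9]+\\.?[0-9]*)", hdr))[[1]]
  if (length(em) == 0)
    em <- regmatches(hdr, regexec("ENERGY\\s*=?\\s*(-?[0-9]+\\.?[0-9]*)", hdr))[[1]]
  mfe <- if (length(em) >= 2) as.double(em[2]) else NA_real_
  if (length(lines) < n + 1) abort("CT file shorter than declared length")
  body <- lines[2:(n + 1)]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 6)
  if (length(bad) > 0)
    abort(paste0("malformed CT base line at position ", bad[1]))
  base <- vapply(fields, `[[`, character(1), 2)
  pair <- as.integer(vapply(fields, `[[`, character(1), 5))
  if (anyNA(pair) || any(pair < 0 | pair > n))
    abort("CT pair index out of range")
  for (i in seq_len(n)) {
    j <- pair[i]
    if (j > 0 && (pair[j] != i || j == i))
      abort(sprintf("inconsistent CT pairing: position %d pairs with %d but %d pairs with %d",
                    i, j, j, pair[j]))
  }
  db <- rep(".", n)
  db[pair > seq_len(n)] <- "("
  db[pair != 0 & pair < seq_len(n)] <- ")"
  db <- paste(db, collapse = "")
  parse_dotbracket(db)  # rejects pseudoknotted tables
  seq <- .norm_sequence(paste(base, collapse = ""))
  if (is.null(id)) {
    nm <- trimws(sub("^[0-9]+\\s*", "", sub(".*[dD][gG]\\s*=?\\s*-?[0-9.]+", "", hdr)))
    id <- if (nzchar(nm)) sub("\\s.*$", "", nm) else
      sub("\\.[^.]*$", "", basename(path))
  }
  .check_sequence(seq, id, "strict")
  new_hairpin_tbl(id, seq, db, mfe)
}

#' Write / read a feature table as TSV
#'
#' The on-disk layout is one row per hairpin with columns `id`, `label`,
#' then the 132 catalog features in canonical order, tab-delimited with a
#' header row; missing values are written as `NA`. The round trip is
#' lossless to full double precision.
#'
#' @param table A feature table as produced by [extract_features()].
#' @param path Output (or input) TSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature table tibble.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("id", "label", .catalog_names)
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0)
    abort(paste0("feature table lacks column(s): ", paste(miss, collapse = ", ")))
  readr::write_tsv(table[cols], path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                         col_types = readr::cols(
                           id = readr::col_character(),
                           label = readr::col_character(),
                           .default = readr::col_double()))
  expected <- c("id", "label", .catalog_names)
  absent <- setdiff(expected, names(tbl))
  if (length(absent) > 0)
    abort(paste0("feature table is missing column(s): ",
                 paste(absent, collapse = ", ")))
  unknown <- setdiff(names(tbl), expected)
  if (length(unknown) > 0)
    abort(paste0("unknown column(s) in feature table: ",
                 paste(unknown, collapse = ", ")))
  tbl[expected]
}
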