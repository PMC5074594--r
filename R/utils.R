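# shared internal helpers

.norm_sequence <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

.check_sequence <- function(seq, id, mode = c("strict", "pipeline")) {
  mode <- match.arg(mode)
  ok <- grepl("^[ACGU]+$", seq)
  if (ok) return(TRUE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "U"))
  msg <- sprintf("record '%s' contains non-ACGU character(s): %s",
                 id, paste(bad, collapse = ", "))
  if (mode == "strict") abort(msg) else warn(paste0("skipping ", msg))
  FALSE
}

.base_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(.bases, function(b) sum(chars == b), integer(1))
}

.gc_fraction <- function(seq) {
  n <- .base_counts(seq)
  (n[["G"]] + n[["C"]]) / sum(n)
}

new_hairpin_tbl <- function(id = character(), sequence = character(),
                            structure = NA_character_, mfe = NA_real_,
                            label = NA_character_) {
  tibble::tibble(id = as.character(id), sequence = as.character(sequence),
                 structure = structure, mfe = as.double(mfe),
                 label = as.character(label))
}

.check_hairpins <- function(hairpins) {
  req <- c("id", "sequence")
  miss <- setdiff(req, names(hairpins))
  if (length(miss) > 0)
    abort(paste0("hairpin table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(hairpins$id))
    abort("hairpin ids must be unique")
  invisible(hairpins)
}
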