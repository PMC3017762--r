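# Shared internal helpers: alphabets, alignment coercion, seeded RNG.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_ALPHABET <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Coerce an alignment (tibble with id/seq, named character vector, or
# character matrix) to a character matrix with one row per sequence.
#' @noRd
aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) {
      rownames(alignment) <- paste0("seq", seq_len(nrow(alignment)))
    }
    return(alignment)
  }
  if (is_tibble(alignment) || is.data.frame(alignment)) {
    seqs <- setNames(alignment$seq, alignment$id)
  } else if (is.character(alignment)) {
    seqs <- alignment
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    abort("alignment must be a tibble with id/seq columns, a named character vector, or a character matrix")
  }
  lens <- unique(nchar(seqs))
  if (length(seqs) < 2) abort("an alignment needs at least 2 sequences")
  if (length(lens) != 1) abort("alignment rows differ in length")
  if (any(grepl(".", seqs, fixed = TRUE))) {
    abort("'.' is not accepted as a gap character; use '-'")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' @noRd
aln_tibble <- function(m) {
  tibble(id = rownames(m), seq = apply(m, 1, paste, collapse = ""))
}

#' @noRd
validate_residues <- function(seq, moltype, id = "<sequence>") {
  chars <- unique(strsplit(toupper(seq), "")[[1]])
  allowed <- switch(moltype,
    protein = c(AA_ALPHABET, GAP_CHAR, "X", "*"),
    cds = c(NT_ALPHABET, GAP_CHAR, "N"),
    abort("moltype must be 'protein' or 'cds'")
  )
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort(sprintf("illegal %s residue(s) %s in record '%s'",
                  moltype, paste(bad, collapse = ","), id))
  }
  invisible(TRUE)
}

#' @noRd
roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))
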