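# Conserved-motif extraction, degenerate-pattern matching, and
# relative-entropy logo heights.

#' Parse a degenerate motif pattern
#'
#' Patterns are strings of fixed residues, `x` wildcards, and two-residue
#' alternatives written `K(R)` (either K or R).
#'
#' @param pattern Pattern string, e.g. `"NLVxYL"` or
#'   `"LYLxxxGxGGxK(R)xxxxxFGADQFD"`.
#' @param name Optional pattern name.
#' @return A list of class `fam_motif`: `elements` (list; each a residue,
#'   a residue set, or `"x"`), `name`, `pattern`.
#' @export
parse_motif_pattern <- function(pattern, name = pattern) {
  chars <- strsplit(pattern, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      elements[[length(elements) + 1L]] <- "x"
      i <- i + 1L
    } else if (ch %in% AA_ALPHABET) {
      if (i + 3 <= length(chars) && chars[i + 1] == "(" && chars[i + 3] == ")") {
        elements[[length(elements) + 1L]] <- c(ch, chars[i + 2])
        i <- i + 4L
      } else {
        elements[[length(elements) + 1L]] <- ch
        i <- i + 1L
      }
    } else {
      abort(sprintf("cannot parse motif pattern at position %d of '%s'", i, pattern))
    }
  }
  if (length(elements) < 3) abort("a motif pattern needs length >= 3")
  if (all(vapply(elements, function(e) identical(e, "x"), logical(1)))) {
    abort("a motif pattern needs at least one non-wildcard element")
  }
  structure(list(elements = elements, name = name, pattern = pattern),
            class = "fam_motif")
}

#' Match a degenerate pattern in a protein
#'
#' Reports every ungapped occurrence with 1-based start positions.
#'
#' @param protein Protein string (gaps are removed before matching).
#' @param pattern A pattern string or parsed `fam_motif`.
#' @return A tibble `start`, `match`.
#' @export
match_pattern <- function(protein, pattern) {
  if (!inherits(pattern, "fam_motif")) pattern <- parse_motif_pattern(pattern)
  seq <- gsub("-", "", protein, fixed = TRUE)
  re <- paste(vapply(pattern$elements, function(e) {
    if (identical(e, "x")) "." else if (length(e) == 1) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, ""), collapse = "")
  hits <- gregexpr(re, seq)[[1]]
  if (hits[1] == -1) return(tibble(start = integer(), match = character()))
  len <- length(pattern$elements)
  tibble(start = as.integer(hits),
         match = substring(seq, hits, hits + len - 1L))
}

#' Find conserved motif windows in an alignment
#'
#' Per-column conservation is the frequency of the most common residue (gaps
#' counted in the denominator). Scanning left to right, a window opens at a
#' column whose conservation reaches `cons_threshold` and is greedily
#' extended while the window's mean conservation stays at or above it;
#' windows shorter than `min_len` are dropped. Each window's consensus
#' pattern uses a fixed residue when the top frequency is >= 0.9, a
#' two-residue alternative when the top two jointly reach 0.9, and `x`
#' otherwise.
#'
#' @param alignment Alignment of family proteins.
#' @param min_len Minimum window length in columns (default 5).
#' @param cons_threshold Mean-conservation threshold (default 0.8).
#' @return A tibble `start`, `end`, `mean_conservation`, `consensus`,
#'   `pattern` (list of parsed `fam_motif`).
#' @export
find_conserved_motifs <- function(alignment, min_len = 5, cons_threshold = 0.8) {
  m <- aln_matrix(alignment)
  nseq <- nrow(m)
  freq <- function(j) {
    cnt <- table(factor(m[, j][m[, j] %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(cnt) / nseq
  }
  freqs <- vapply(seq_len(ncol(m)), freq, numeric(20))
  rownames(freqs) <- AA_ALPHABET
  cons <- apply(freqs, 2, max)
  windows <- list()
  j <- 1L
  while (j <= ncol(m)) {
    if (cons[j] < cons_threshold) { j <- j + 1L; next }
    end <- j
    while (end + 1L <= ncol(m) &&
           mean(cons[j:(end + 1L)]) >= cons_threshold) end <- end + 1L
    if (end - j + 1L >= min_len) {
      consensus <- vapply(j:end, function(col) {
        f <- sort(freqs[, col], decreasing = TRUE)
        if (f[1] >= 0.9) names(f)[1]
        else if (f[1] + f[2] >= 0.9) sprintf("%s(%s)", names(f)[1], names(f)[2])
        else "x"
      }, "")
      windows[[length(windows) + 1L]] <- tibble(
        start = j, end = end,
        mean_conservation = mean(cons[j:end]),
        consensus = paste(consensus, collapse = "")
      )
    }
    j <- end + 1L
  }
  res <- bind_rows(windows)
  if (nrow(res) == 0) {
    return(tibble(start = integer(), end = integer(),
                  mean_conservation = numeric(), consensus = character(),
                  pattern = list()))
  }
  res$pattern <- lapply(res$consensus, function(cs) {
    tryCatch(parse_motif_pattern(cs), error = function(e) NULL)
  })
  res
}

#' Relative-entropy logo heights
#'
#' Per-column residue frequencies, relative entropy (bits) against a
#' background distribution (uniform 1/20 by default), and per-letter heights
#' (entropy x frequency) — the quantity an HMM-logo display stacks.
#'
#' @param alignment_window Alignment (or window of one).
#' @param background Named numeric background distribution over the 20
#'   residues (default uniform).
#' @return A list of class `fam_logo`: `freq` (20 x L), `entropy` (per
#'   column, bits), `heights` (20 x L).
#' @export
logo_heights <- function(alignment_window,
                         background = setNames(rep(1 / 20, 20), AA_ALPHABET)) {
  m <- aln_matrix(alignment_window)
  if (ncol(m) == 0) abort("empty alignment window")
  q <- background[AA_ALPHABET]
  if (any(is.na(q)) || abs(sum(q) - 1) > 1e-8) {
    abort("background must be a distribution over the 20 amino acids")
  }
  freq <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j][m[, j] %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    if (length(col) == 0) rep(0, 20) else as.numeric(cnt) / length(col)
  }, numeric(20))
  rownames(freq) <- AA_ALPHABET
  entropy <- vapply(seq_len(ncol(freq)), function(j) {
    p <- freq[, j]
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[nz]))
  }, numeric(1))
  heights <- sweep(freq, 2, entropy, `*`)
  structure(list(freq = freq, entropy = entropy, heights = heights),
            class = "fam_logo")
}

#' @exportS3Method generics::tidy
tidy.fam_logo <- function(x, ...) {
  as_tibble(as.data.frame.table(x$heights, stringsAsFactors = FALSE)) |>
    rename(residue = "Var1", column = "Var2", height = "Freq") |>
    mutate(column = as.integer(factor(.data$column, levels = unique(.data$column))))
}

#' @exportS3Method ggplot2::autoplot
autoplot.fam_logo <- function(object, ...) {
  df <- tidy(object)
  df <- filter(df, .data$height > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$height,
                                   fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "alignment column", y = "relative entropy (bits)",
                  fill = "residue") +
    ggplot2::theme_minimal()
}
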