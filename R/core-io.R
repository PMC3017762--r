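# Readers and writers for the external formats the pipeline touches.
# Coordinates are 1-based inclusive everywhere; conversion (if a caller needs
# another convention) happens outside these functions.

#' Read a gene-position table
#'
#' Reads a TSV with columns `gene_id`, `chromosome`, `start`, `end`, `strand`,
#' `annotation`, `is_family` (1-based inclusive coordinates) and returns a
#' validated gene set sorted by chromosome then start.
#'
#' @param path Path to a tab-separated gene table.
#' @return A tibble sorted by `(chromosome, start)` with strand normalized to
#'   `"+"`/`"-"` and `is_family` logical.
#' @export
read_gene_table <- function(path) {
  cols <- readr::cols(
    gene_id = readr::col_character(),
    chromosome = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    annotation = readr::col_character(),
    is_family = readr::col_logical()
  )
  tbl <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed gene table row at line %d of %s: %s",
                  probs$row[1] + 1L, path, probs$expected[1]))
  }
  missing <- setdiff(c("gene_id", "chromosome", "start", "end", "strand",
                       "annotation", "is_family"), names(tbl))
  if (length(missing) > 0) {
    abort(paste("gene table is missing column(s):", paste(missing, collapse = ", ")))
  }
  validate_gene_set(tbl)
}

#' Validate and sort a gene table
#'
#' @param genes A data frame of gene models.
#' @return The input as a tibble, sorted by `(chromosome, start)`.
#' @export
validate_gene_set <- function(genes) {
  genes <- as_tibble(genes)
  genes$annotation <- genes$annotation %||% ""
  genes$annotation[is.na(genes$annotation)] <- ""
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste("duplicate gene_id:", paste(unique(dup), collapse = ", ")))
  }
  genes$strand <- ifelse(genes$strand %in% c("+", "plus", "1"), "+",
                  ifelse(genes$strand %in% c("-", "minus", "-1"), "-", NA))
  if (anyNA(genes$strand)) abort("strand values must normalize to '+' or '-'")
  if (any(genes$start < 1)) abort("start coordinates must be >= 1 (1-based inclusive)")
  bad <- genes$gene_id[genes$end < genes$start]
  if (length(bad) > 0) {
    abort(paste("end < start for gene(s):", paste(bad, collapse = ", ")))
  }
  arrange(genes, .data$chromosome, .data$start)
}

#' Write a gene table
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(validate_gene_set(genes), path, progress = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @param moltype `"protein"` or `"cds"`.
#' @return A tibble with columns `id`, `seq`, `moltype`.
#' @export
read_fasta <- function(path, moltype = c("protein", "cds")) {
  moltype <- match.arg(moltype)
  set <- if (moltype == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  purrr::walk2(seqs, ids, validate_residues, moltype = moltype)
  tibble(id = ids, seq = unname(seqs), moltype = moltype)
}

#' Write sequences to FASTA
#'
#' @param records Tibble with `id` and `seq` columns (gaps allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a phylogenetic tree as newick
#'
#' Branch lengths are kept; bootstrap supports (stored as `node.label`) are
#' written as MEGA-style internal node labels.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Newick file path.
#' @return An [ape::phylo] object (node labels carry bootstrap supports).
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read an expression matrix
#'
#' Expects a TSV whose first column is `gene_id` and remaining columns are
#' named `<sample>.<replicate>` (e.g. `R.1`, `R.2`). Returns the long, tidy
#' form used by all expression operations.
#'
#' @param path TSV path.
#' @return A tibble with columns `gene_id`, `sample`, `replicate`, `signal`.
#' @export
read_expression_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = c("sample", "replicate"),
                              names_pattern = "^(.*)\\.([0-9]+)$",
                              values_to = "signal")
  long$replicate <- as.integer(long$replicate)
  if (any(long$signal <= 0, na.rm = TRUE)) abort("expression signals must be positive")
  long
}

#' Write an expression matrix
#' @param expr Long expression tibble (`gene_id`, `sample`, `replicate`, `signal`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  wide <- tidyr::pivot_wider(expr,
    id_cols = "gene_id",
    names_from = c("sample", "replicate"), names_sep = ".",
    values_from = "signal")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a collinearity block table
#'
#' Anchor-pair definition of segmental duplication blocks: one row per anchor
#' pair with columns `block_id`, `gene_a`, `gene_b`.
#'
#' @param path TSV path.
#' @return A tibble with columns `block_id`, `gene_a`, `gene_b`.
#' @export
read_block_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    block_id = readr::col_character(),
    gene_a = readr::col_character(),
    gene_b = readr::col_character()
  ), progress = FALSE)
}

#' Write a collinearity block table
#' @param blocks Tibble with `block_id`, `gene_a`, `gene_b`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  readr::write_tsv(blocks, path, progress = FALSE)
  invisible(path)
}
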