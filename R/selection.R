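# Selection analysis: protein-guided codon alignment and Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction.

#' Back-translate a protein alignment pair to a codon alignment
#'
#' Each amino-acid column becomes a codon column; protein gaps become `---`.
#' Every CDS must translate (standard code) to its ungapped protein row.
#'
#' @param protein_a,protein_b Gapped protein rows of equal length.
#' @param cds_a,cds_b Ungapped in-frame coding sequences.
#' @return A list of class `fam_codon_aln`: `codon_a`, `codon_b` (gapped,
#'   equal length, divisible by 3).
#' @export
back_translate_alignment <- function(protein_a, protein_b, cds_a, cds_b) {
  if (nchar(protein_a) != nchar(protein_b)) {
    abort("aligned protein rows differ in length")
  }
  row <- function(protein, cds, which) {
    aas <- strsplit(protein, "")[[1]]
    codons <- split_codons(cds)
    trans <- CODON_AA[codons]
    res_idx <- which(aas != GAP_CHAR)
    if (length(res_idx) != length(codons)) {
      abort(sprintf("CDS %s has %d codons but protein row has %d residues",
                    which, length(codons), length(res_idx)))
    }
    mismatch <- which(trans != aas[res_idx])
    if (length(mismatch) > 0) {
      abort(sprintf("CDS %s does not translate to its protein row at residue %d (%s vs %s)",
                    which, mismatch[1], trans[mismatch[1]], aas[res_idx][mismatch[1]]))
    }
    out <- rep("---", length(aas))
    out[res_idx] <- codons
    paste(out, collapse = "")
  }
  structure(list(codon_a = row(protein_a, cds_a, "a"),
                 codon_b = row(protein_b, cds_b, "b")),
            class = "fam_codon_aln")
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Counts synonymous and nonsynonymous sites per codon (each position's
#' synonymous fraction of its three possible changes; mutations to stop
#' codons count as nonsynonymous so S + N = 3 per codon), averages site
#' counts over the two sequences, counts differences by averaging over all
#' minimal mutational pathways (pathways through stop codons excluded), and
#' corrects the proportions with Jukes-Cantor `d = -3/4 ln(1 - 4p/3)`.
#' Codons containing gaps or ambiguous bases are skipped.
#'
#' @param pair A `fam_codon_aln`, a `fam_codon_pair`, or a length-2 character
#'   vector of equal-length in-frame (optionally gapped) CDS rows.
#' @return A list of class `fam_kaks`: `ka`, `ks`, `ratio` (NA when Ks is 0
#'   or saturated), `n_sites`, `s_sites`, `n_diffs`, `s_diffs`,
#'   `codons_compared`, `purifying`, `saturated`.
#' @export
kaks_ng86 <- function(pair) {
  rows <- if (inherits(pair, "fam_codon_aln")) {
    c(pair$codon_a, pair$codon_b)
  } else if (inherits(pair, "fam_codon_pair")) {
    c(pair$cds_a, pair$cds_b)
  } else if (is.character(pair) && length(pair) == 2) {
    pair
  } else {
    abort("pair must be a codon alignment, a simulated codon pair, or 2 CDS strings")
  }
  if (nchar(rows[1]) != nchar(rows[2])) abort("codon rows differ in length")
  ca <- split_codons(rows[1])
  cb <- split_codons(rows[2])
  usable <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0) abort("no comparable codons")

  s_sites <- (sum(CODON_SYN_SITES[ca]) + sum(CODON_SYN_SITES[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  diff_idx <- which(ca != cb)
  s_diffs <- 0; n_diffs <- 0
  for (i in diff_idx) {
    cnt <- codon_pair_diffs(ca[i], cb[i])
    s_diffs <- s_diffs + cnt[["syn"]]
    n_diffs <- n_diffs + cnt[["nonsyn"]]
  }
  # zero observed differences mean zero distance even when the site count
  # happens to be zero (e.g. an all-Met comparison has no synonymous sites)
  ps <- if (s_diffs == 0) 0 else s_diffs / s_sites
  pn <- if (n_diffs == 0) 0 else n_diffs / n_sites
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps)
  ka <- jc(pn)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (saturated || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 n_sites = n_sites, s_sites = s_sites,
                 n_diffs = n_diffs, s_diffs = s_diffs,
                 codons_compared = length(ca),
                 purifying = if (is.na(ratio)) NA else ratio < 1,
                 saturated = saturated),
            class = "fam_kaks")
}

#' @export
print.fam_kaks <- function(x, ...) {
  cat(sprintf("<fam_kaks> Ka=%.4f Ks=%.4f Ka/Ks=%s (%d codons)\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$codons_compared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fam_kaks <- function(x, ...) {
  tibble(ka = x$ka, ks = x$ks, ratio = x$ratio,
         n_sites = x$n_sites, s_sites = x$s_sites,
         n_diffs = x$n_diffs, s_diffs = x$s_diffs,
         codons_compared = x$codons_compared,
         purifying = x$purifying, saturated = x$saturated)
}

#' Ka/Ks ratio and purifying-selection flag
#'
#' Recomputes the ratio from (possibly printed, rounded) Ka and Ks values:
#' ratio = Ka/Ks, purifying when ratio < 1. Ks = 0 gives an undefined ratio.
#'
#' @param ka,ks Substitution rates per site (vectorized).
#' @return A tibble `ka`, `ks`, `ratio`, `purifying`.
#' @export
ratio_and_flag <- function(ka, ks) {
  ratio <- ifelse(ks > 0, ka / ks, NA_real_)
  tibble(ka = ka, ks = ks, ratio = ratio,
         purifying = ifelse(is.na(ratio), NA, ratio < 1))
}

#' Pairwise protein identity
#'
#' Identical columns divided by aligned columns, as a percentage. By default
#' the denominator is every column where at least one row has a residue
#' (gap-vs-residue columns count against identity); `denominator =
#' "ungapped"` restricts to columns where both rows have residues.
#'
#' @param protein_a,protein_b Gapped protein rows of equal length.
#' @param denominator `"aligned"` (default) or `"ungapped"`.
#' @return Identity percentage.
#' @export
pairwise_protein_identity <- function(protein_a, protein_b,
                                      denominator = c("aligned", "ungapped")) {
  denominator <- match.arg(denominator)
  a <- strsplit(protein_a, "")[[1]]
  b <- strsplit(protein_b, "")[[1]]
  if (length(a) != length(b)) abort("aligned rows differ in length")
  keep <- if (denominator == "aligned") {
    a != GAP_CHAR | b != GAP_CHAR
  } else {
    a != GAP_CHAR & b != GAP_CHAR
  }
  if (!any(keep)) abort("no aligned columns")
  100 * sum(a[keep] == b[keep] & a[keep] != GAP_CHAR) / sum(keep)
}

#' Ka/Ks table for a set of paralog pairs
#'
#' Runs [kaks_ng86()] for each pair of gene ids over a CDS table (sequences
#' assumed aligned in frame, as produced by the family simulator or by
#' [back_translate_alignment()]).
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (extra columns carried along).
#' @param cds Tibble with `id`, `seq`.
#' @return `pairs` with `ka`, `ks`, `ratio`, `purifying`, `identity`
#'   columns appended.
#' @export
kaks_table <- function(pairs, cds) {
  seqs <- setNames(cds$seq, cds$id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seqs))
  if (length(missing) > 0) {
    abort(paste("no CDS for gene(s):", paste(head(missing, 5), collapse = ", ")))
  }
  res <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(a, b) {
    kk <- kaks_ng86(c(seqs[[a]], seqs[[b]]))
    pa <- translate_cds(seqs[[a]])
    pb <- translate_cds(seqs[[b]])
    ident <- if (nchar(pa) == nchar(pb)) {
      pairwise_protein_identity(pa, pb)
    } else NA_real_
    tibble(ka = kk$ka, ks = kk$ks, ratio = kk$ratio,
           purifying = kk$purifying, saturated = kk$saturated,
           identity = ident)
  })
  dplyr::bind_cols(pairs, res)
}
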