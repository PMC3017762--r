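# Family screening: position-specific scoring profile + keyword search,
# transcript dedup, partial-domain and annotation-based exclusion.

#' Build a domain scoring profile from a seed alignment
#'
#' Per-column amino-acid log-odds (bits) against a uniform 1/20 background,
#' with an additive pseudocount. Gap characters do not contribute counts.
#'
#' @param seed_alignment Alignment (tibble with `id`/`seq`, named character
#'   vector, or character matrix) of the domain region.
#' @param pseudocount Additive pseudocount per residue (default 1).
#' @param min_coverage Minimum matched-profile fraction for a full-domain
#'   call; stored on the profile (default 0.8).
#' @return A list of class `fam_profile` with `log_odds` (20 x L matrix),
#'   `length`, `score_threshold` (NA until [calibrate_threshold()] is run),
#'   `min_coverage` and `consensus`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1, min_coverage = 0.8) {
  m <- aln_matrix(seed_alignment)
  if (ncol(m) == 0) abort("empty seed alignment")
  if (min_coverage <= 0 || min_coverage > 1) abort("min_coverage must be in (0, 1]")
  log_odds <- matrix(NA_real_, nrow = 20, ncol = ncol(m),
                     dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% AA_ALPHABET]
    if (length(col) == 0) abort(sprintf("profile column %d is entirely gaps", j))
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + pseudocount) / (length(col) + 20 * pseudocount)
    log_odds[, j] <- log2(p * 20)
  }
  consensus <- AA_ALPHABET[apply(log_odds, 2, which.max)]
  structure(list(log_odds = log_odds, length = ncol(m),
                 score_threshold = NA_real_, min_coverage = min_coverage,
                 consensus = paste(consensus, collapse = "")),
            class = "fam_profile")
}

#' Scan a protein with a domain profile
#'
#' Slides the profile along the protein over every ungapped offset, allowing
#' truncation at the sequence ends. The score of a placement is the sum of
#' per-column log-odds of the aligned residues; coverage is the fraction of
#' profile columns that are aligned inside the sequence with positive
#' log-odds (i.e. matched better than background).
#'
#' @param protein A protein string.
#' @param profile A `fam_profile`.
#' @return A one-row tibble: `best_score`, `best_start` (1-based protein
#'   position aligned to profile column 1; may be < 1 for truncated
#'   placements), `coverage`.
#' @export
scan_protein <- function(protein, profile) {
  stopifnot(inherits(profile, "fam_profile"), nchar(protein) >= 1)
  chars <- strsplit(toupper(protein), "")[[1]]
  aa_idx <- match(chars, AA_ALPHABET)
  plen <- length(chars)
  L <- profile$length
  lo <- profile$log_odds
  col_min <- apply(lo, 2, min)
  best <- list(score = -Inf, start = NA_integer_, coverage = 0)
  for (start in seq(1L - L + 1L, plen)) {
    j <- seq_len(L)
    pos <- start + j - 1L
    keep <- pos >= 1L & pos <= plen
    if (!any(keep)) next
    jj <- j[keep]
    idx <- aa_idx[pos[keep]]
    val <- ifelse(is.na(idx), col_min[jj], lo[cbind(idx, jj)])
    score <- sum(val)
    if (score > best$score) {
      best <- list(score = score, start = start,
                   coverage = sum(val > 0) / L)
    }
  }
  tibble(best_score = best$score, best_start = best$start,
         coverage = best$coverage)
}

#' Calibrate the profile acceptance threshold
#'
#' Sets the score threshold to the given quantile (default 99.9%) of best
#' scan scores over residue-shuffled versions of the supplied sequences —
#' a null distribution with the same composition as the family.
#'
#' @param profile A `fam_profile`.
#' @param sequences Character vector of protein sequences to shuffle.
#' @param n_shuffle Shuffles per sequence (default 5).
#' @param quantile_level Null quantile used as threshold (default 0.999).
#' @param seed Integer seed.
#' @return The profile with `score_threshold` set.
#' @export
calibrate_threshold <- function(profile, sequences, n_shuffle = 5,
                                quantile_level = 0.999, seed = 1L) {
  stopifnot(inherits(profile, "fam_profile"))
  scores <- with_seed(seed, {
    unlist(lapply(sequences, function(s) {
      chars <- strsplit(gsub("-", "", s, fixed = TRUE), "")[[1]]
      vapply(seq_len(n_shuffle), function(i) {
        scan_protein(paste(sample(chars), collapse = ""), profile)$best_score
      }, numeric(1))
    }))
  })
  profile$score_threshold <- as.numeric(quantile(scores, quantile_level))
  profile
}

#' Screen candidate proteins for family membership
#'
#' Accepts the union of profile hits (best score at or above the calibrated
#' threshold) and keyword hits (annotation matching any keyword,
#' case-insensitive), after keeping one transcript per locus (the longest;
#' locus = id with a trailing `.N` stripped). Candidates whose annotation
#' matches an exclusion term are excluded; remaining candidates with profile
#' coverage below `min_coverage` are excluded as partial-domain.
#'
#' @param proteins Tibble with `id`, `seq`.
#' @param gene_set Gene tibble supplying annotations (matched on `gene_id`).
#' @param profile A calibrated `fam_profile`.
#' @param keywords Annotation keywords counting as hits.
#' @param exclusion_terms Annotation terms forcing exclusion.
#' @return A list of class `fam_screen` with tibbles `accepted`,
#'   `excluded_partial`, `excluded_annotation` (disjoint) and `scores`
#'   (per-candidate evidence).
#' @export
screen <- function(proteins, gene_set, profile,
                   keywords = c("PTR", "peptide transporter",
                                "proton-dependent oligopeptide transport"),
                   exclusion_terms = c("retrotransposon", "transposon")) {
  stopifnot(inherits(profile, "fam_profile"))
  if (is.na(profile$score_threshold)) {
    abort("profile threshold not set; run calibrate_threshold() first")
  }
  # transcript dedup: one record per locus, longest sequence kept
  proteins <- proteins |>
    mutate(locus = sub("\\.[0-9]+$", "", .data$id),
           len = nchar(gsub("-", "", .data$seq, fixed = TRUE))) |>
    group_by(.data$locus) |>
    slice_max(.data$len, n = 1, with_ties = FALSE) |>
    ungroup()

  ann <- setNames(gene_set$annotation, gene_set$gene_id)
  hits <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    sc <- scan_protein(proteins$seq[i], profile)
    mutate(sc, id = proteins$id[i], locus = proteins$locus[i])
  })
  hits$annotation <- unname(ann[hits$locus])
  hits$annotation[is.na(hits$annotation)] <- ""
  kw_re <- paste(sapply(keywords, .regex_escape), collapse = "|")
  ex_re <- paste(sapply(exclusion_terms, .regex_escape), collapse = "|")
  hits <- hits |>
    mutate(
      profile_hit = .data$best_score >= profile$score_threshold,
      keyword_hit = grepl(kw_re, .data$annotation, ignore.case = TRUE),
      excluded_term = grepl(ex_re, .data$annotation, ignore.case = TRUE),
      provenance = dplyr::case_when(
        profile_hit & keyword_hit ~ "both",
        profile_hit ~ "profile",
        keyword_hit ~ "keyword",
        TRUE ~ "none"
      )
    ) |>
    filter(.data$profile_hit | .data$keyword_hit)

  excluded_annotation <- filter(hits, .data$excluded_term)
  rest <- filter(hits, !.data$excluded_term)
  excluded_partial <- filter(rest, .data$coverage < profile$min_coverage)
  accepted <- filter(rest, .data$coverage >= profile$min_coverage)
  keep_cols <- c("id", "locus", "best_score", "coverage", "provenance", "annotation")
  structure(list(
    accepted = select(accepted, dplyr::all_of(keep_cols)),
    excluded_partial = select(excluded_partial, dplyr::all_of(keep_cols)),
    excluded_annotation = select(excluded_annotation, dplyr::all_of(keep_cols)),
    threshold = profile$score_threshold,
    min_coverage = profile$min_coverage
  ), class = "fam_screen")
}

#' @noRd
.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @exportS3Method generics::tidy
tidy.fam_screen <- function(x, ...) {
  bind_rows(
    mutate(x$accepted, status = "accepted"),
    mutate(x$excluded_partial, status = "excluded_partial"),
    mutate(x$excluded_annotation, status = "excluded_annotation")
  )
}

#' @exportS3Method generics::glance
glance.fam_screen <- function(x, ...) {
  tibble(n_accepted = nrow(x$accepted),
         n_excluded_partial = nrow(x$excluded_partial),
         n_excluded_annotation = nrow(x$excluded_annotation),
         score_threshold = x$threshold,
         min_coverage = x$min_coverage)
}

#' @export
print.fam_screen <- function(x, ...) {
  cat(sprintf("<fam_screen> %d accepted, %d partial-domain excluded, %d annotation-excluded\n",
              nrow(x$accepted), nrow(x$excluded_partial),
              nrow(x$excluded_annotation)))
  invisible(x)
}
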