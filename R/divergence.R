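# Expression-fate classification of duplicated paralog pairs:
# D (just duplicated), NOF (nonfunctionalization), SF (subfunctionalization),
# NF (neofunctionalization).

#' Classify the expression fate of a paralog pair
#'
#' Decision cascade over the two collapsed expression profiles (same tissue
#' order required):
#' 1. NOF if one copy is below `expressed_threshold` in every tissue;
#' 2. D if the log2 profiles correlate at or above `corr_min` and every
#'    per-tissue ratio is within `same_fold`;
#' 3. SF if both expressed-tissue sets are nonempty and their Jaccard overlap
#'    is below 0.25 (complementary patterns);
#' 4. NF if one copy exceeds the other by at least `same_fold` in one or more
#'    tissues while the expressed-tissue sets share at least half of their
#'    union;
#' 5. otherwise unclassified.
#'
#' @param profile_a,profile_b Named numeric vectors of collapsed signals over
#'   identical tissue sets.
#' @param expressed_threshold Signal above which a tissue counts as expressed.
#' @param same_fold Ratio within which profiles count as "the same" and gain
#'   fold for NF (default 2).
#' @param corr_min Minimum Pearson correlation of log2 profiles for D
#'   (default 0.9).
#' @return A one-row tibble of class `fam_fate`: `fate`, `silenced_copy`,
#'   `gain_copy`, `gain_tissues`, `correlation`, `jaccard`.
#' @export
classify_fate <- function(profile_a, profile_b, expressed_threshold,
                          same_fold = 2, corr_min = 0.9) {
  if (!identical(names(profile_a), names(profile_b))) {
    abort("profiles must be over the identical tissue list")
  }
  la <- log2(profile_a); lb <- log2(profile_b)
  expr_a <- profile_a >= expressed_threshold
  expr_b <- profile_b >= expressed_threshold
  correlation <- if (sd(la) < 1e-8 || sd(lb) < 1e-8) {
    1  # a flat profile has no shape to disagree with; ratios decide
  } else {
    cor(la, lb)
  }
  uni <- sum(expr_a | expr_b)
  jaccard <- if (uni == 0) NA_real_ else sum(expr_a & expr_b) / uni
  ratios <- la - lb
  res <- function(fate, silenced = NA_character_, gain = NA_character_,
                  gain_tissues = character(0)) {
    structure(tibble(fate = fate, silenced_copy = silenced, gain_copy = gain,
                     gain_tissues = list(gain_tissues),
                     correlation = correlation, jaccard = jaccard),
              class = c("fam_fate", class(tibble())))
  }
  if (!any(expr_a) && !any(expr_b)) return(res("unclassified"))
  if (!any(expr_b)) return(res("NOF", silenced = "b"))
  if (!any(expr_a)) return(res("NOF", silenced = "a"))
  if (correlation >= corr_min && all(abs(ratios) <= log2(same_fold))) {
    return(res("D"))
  }
  if (jaccard < 0.25) return(res("SF"))
  gain_b <- names(profile_a)[ratios <= -log2(same_fold)]
  gain_a <- names(profile_a)[ratios >= log2(same_fold)]
  if (jaccard >= 0.5) {
    if (length(gain_b) > 0 && length(gain_b) >= length(gain_a)) {
      return(res("NF", gain = "b", gain_tissues = gain_b))
    }
    if (length(gain_a) > 0) {
      return(res("NF", gain = "a", gain_tissues = gain_a))
    }
  }
  res("unclassified")
}

#' Classify fates for a table of pairs
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param expr Long expression tibble covering the genes; pairs with either
#'   copy absent are returned `unclassified` (no expression data).
#' @param expressed_threshold Threshold passed to [classify_fate()]; `NULL`
#'   uses twice the 25th percentile of collapsed signals.
#' @param ... Further arguments to [classify_fate()].
#' @return `pairs` with fate columns appended.
#' @export
classify_fates <- function(pairs, expr, expressed_threshold = NULL, ...) {
  means <- collapse_replicates(expr)
  thr <- expressed_threshold %||% (2 * quantile(means$signal, 0.25, names = FALSE))
  wide <- tidyr::pivot_wider(means, names_from = "sample", values_from = "signal")
  prof <- as.matrix(wide[, -1])
  rownames(prof) <- wide$gene_id
  res <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(a, b) {
    if (!a %in% rownames(prof) || !b %in% rownames(prof)) {
      return(tibble(fate = "unclassified", silenced_copy = NA_character_,
                    gain_copy = NA_character_, gain_tissues = list(character(0)),
                    correlation = NA_real_, jaccard = NA_real_))
    }
    classify_fate(prof[a, ], prof[b, ], expressed_threshold = thr, ...)
  })
  dplyr::bind_cols(pairs, res)
}

#' Summarize fate calls
#'
#' @param calls A character vector of fates, or a tibble with a `fate`
#'   column.
#' @return A one-row tibble with counts `D`, `NOF`, `SF`, `NF`,
#'   `unclassified`.
#' @export
fate_summary <- function(calls) {
  fates <- if (is.character(calls)) calls else calls$fate
  lv <- c("D", "NOF", "SF", "NF", "unclassified")
  fates[!fates %in% lv] <- "unclassified"
  cnt <- table(factor(fates, levels = lv))
  as_tibble(as.list(cnt))
}

#' Fate composition bar plot
#' @param calls Fate calls (vector or tibble with `fate`).
#' @return A ggplot object.
#' @export
plot_fate_summary <- function(calls) {
  cnt <- fate_summary(calls)
  df <- tidyr::pivot_longer(cnt, dplyr::everything(),
                            names_to = "fate", values_to = "n")
  df$fate <- factor(df$fate, levels = c("D", "NOF", "SF", "NF", "unclassified"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fate, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "divergence fate", y = "paralog pairs") +
    ggplot2::theme_minimal()
}
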