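# Expression profiling: replicate collapsing, hierarchical grouping,
# preferential / tissue-specific / treatment-differential calling, and the
# delta-delta-Ct calculator. Input everywhere is the long tidy form
# (gene_id, sample, replicate, signal).

#' @noRd
.check_expr <- function(expr, need_replicates = FALSE) {
  need <- c("gene_id", "sample", "replicate", "signal")
  if (inherits(expr, "fam_expression")) expr <- expr$expr
  missing <- setdiff(need, names(expr))
  if (length(missing) > 0) {
    abort(paste("expression data lacks column(s):", paste(missing, collapse = ", ")))
  }
  if (any(is.na(expr$signal))) abort("missing replicate signal values")
  if (any(expr$signal <= 0)) abort("expression signals must be positive")
  if (need_replicates) {
    reps <- count(expr, .data$gene_id, .data$sample)
    if (any(reps$n < 2)) abort("testing operations need >= 2 replicates per sample")
  }
  expr
}

#' Collapse replicates to per-sample means
#'
#' @param expr Long expression tibble (or `fam_expression`).
#' @return A tibble `gene_id`, `sample`, `signal` (arithmetic mean).
#' @export
collapse_replicates <- function(expr) {
  expr <- .check_expr(expr)
  expr |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(signal = mean(.data$signal), .groups = "drop")
}

#' Hierarchical expression grouping
#'
#' Log2-transforms the collapsed matrix, computes Euclidean distances between
#' gene profiles, and cuts a complete-linkage dendrogram into k groups.
#'
#' @param expr Long expression tibble.
#' @param k Number of groups (default 5).
#' @return A list of class `fam_expr_clust`: `groups` (tibble `gene_id`,
#'   `group`), `hclust` (the dendrogram), `k`.
#' @export
cluster_expression <- function(expr, k = 5) {
  means <- collapse_replicates(expr)
  wide <- tidyr::pivot_wider(means, names_from = "sample", values_from = "signal")
  mat <- log2(as.matrix(wide[, -1]))
  rownames(mat) <- wide$gene_id
  if (k > nrow(mat)) abort("k exceeds the number of genes")
  hc <- hclust(dist(mat), method = "complete")
  groups <- cutree(hc, k = k)
  structure(list(
    groups = tibble(gene_id = names(groups), group = unname(groups)),
    hclust = hc, k = k
  ), class = "fam_expr_clust")
}

#' @exportS3Method generics::tidy
tidy.fam_expr_clust <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.fam_expr_clust <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$groups),
         largest_group = max(table(x$groups$group)))
}

# Welch t of the target sample's log2 replicates vs pooled other replicates.
#' @noRd
.welch_p <- function(target, others) {
  if (sd(target) == 0 && sd(others) == 0) {
    return(if (mean(target) == mean(others)) 1 else 0)
  }
  tryCatch(t.test(target, others)$p.value, error = function(e) NA_real_)
}

#' Preferentially expressed genes
#'
#' A gene is preferential in sample s when its mean signal there exceeds
#' twice its mean in every other sample and a Welch t-test of its log2
#' replicates in s against its pooled log2 replicates elsewhere gives
#' p < alpha.
#'
#' @param expr Long expression tibble with replicates.
#' @param fold Fold gate (default 2).
#' @param alpha Significance gate (default 0.05).
#' @return A tibble of calls: `gene_id`, `sample`, `type`, `fold`, `p_value`.
#' @export
preferential_genes <- function(expr, fold = 2, alpha = 0.05) {
  expr <- .check_expr(expr, need_replicates = TRUE)
  means <- collapse_replicates(expr)
  calls <- list()
  for (g in unique(means$gene_id)) {
    gm <- filter(means, .data$gene_id == g)
    top <- gm$sample[which.max(gm$signal)]
    others_mean <- gm$signal[gm$sample != top]
    if (!all(gm$signal[gm$sample == top] > fold * others_mean)) next
    reps <- filter(expr, .data$gene_id == g)
    pv <- .welch_p(log2(reps$signal[reps$sample == top]),
                   log2(reps$signal[reps$sample != top]))
    if (!is.na(pv) && pv < alpha) {
      calls[[length(calls) + 1L]] <- tibble(
        gene_id = g, sample = top, type = "preferential",
        fold = gm$signal[gm$sample == top] / max(others_mean),
        p_value = pv)
    }
  }
  if (length(calls) == 0) {
    return(tibble(gene_id = character(), sample = character(),
                  type = character(), fold = numeric(), p_value = numeric()))
  }
  bind_rows(calls)
}

#' Tissue-specific genes
#'
#' A gene is specific to sample s when its collapsed signal is at or above
#' `expressed_threshold` in s and below it in every other sample. The default
#' threshold is twice the 25th percentile of all collapsed signals.
#'
#' @param expr Long expression tibble.
#' @param expressed_threshold Signal threshold for "expressed"; `NULL` uses
#'   the default above.
#' @return A tibble of calls (`type = "tissue_specific"`, `p_value = NA`).
#' @export
tissue_specific_genes <- function(expr, expressed_threshold = NULL) {
  means <- collapse_replicates(expr)
  thr <- expressed_threshold %||% (2 * quantile(means$signal, 0.25, names = FALSE))
  means |>
    group_by(.data$gene_id) |>
    filter(sum(.data$signal >= thr) == 1) |>
    filter(.data$signal >= thr) |>
    ungroup() |>
    mutate(type = "tissue_specific",
           fold = NA_real_, p_value = NA_real_) |>
    select("gene_id", "sample", "type", "fold", "p_value")
}

#' Treatment differential expression
#'
#' Fold is the ratio of treated to control mean signal; a gene is called up
#' when fold > `fold` and down when fold < 1/`fold`, in both cases with a
#' Welch t-test of log2 replicate signals giving p < alpha.
#'
#' @param expr Long expression tibble containing both conditions.
#' @param treatment,control Sample labels.
#' @param fold Fold gate (default 2).
#' @param alpha Significance gate (default 0.05).
#' @return A tibble of calls with `type` in up/down.
#' @export
treatment_de <- function(expr, treatment, control, fold = 2, alpha = 0.05) {
  expr <- .check_expr(expr, need_replicates = TRUE)
  have <- unique(expr$sample)
  if (!treatment %in% have || !control %in% have) {
    abort("treatment or control sample absent from the expression data")
  }
  expr <- filter(expr, .data$sample %in% c(treatment, control))
  calls <- expr |>
    group_by(.data$gene_id) |>
    summarise(
      fc = mean(.data$signal[.data$sample == treatment]) /
        mean(.data$signal[.data$sample == control]),
      p_value = .welch_p(log2(.data$signal[.data$sample == treatment]),
                         log2(.data$signal[.data$sample == control])),
      .groups = "drop") |>
    filter((.data$fc > fold | .data$fc < 1 / fold), .data$p_value < alpha) |>
    mutate(sample = treatment,
           type = ifelse(.data$fc > fold, "up", "down")) |>
    select("gene_id", "sample", "type", fold = "fc", "p_value")
  calls
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change `2^-ddCt` with
#' `ddCt = (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)`,
#' the reference being the internal control (e.g. Actin1) and the calibrator
#' the baseline sample.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return Fold change (numeric, vectorized).
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal) {
  if (any(!is.finite(c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)))) {
    abort("Ct values must be finite")
  }
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' Expression heatmap
#'
#' @param expr Long expression tibble.
#' @param log2_transform Plot log2 signals (default TRUE).
#' @return A ggplot object (tiles: samples x genes).
#' @export
plot_expression_heatmap <- function(expr, log2_transform = TRUE) {
  means <- collapse_replicates(expr)
  if (log2_transform) means$signal <- log2(means$signal)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                      fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log2_transform) "log2 signal" else "signal") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
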