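# End-to-end orchestration of the survey on the synthetic study design:
# generate ground truth, then screen, call duplications, build the tree,
# extract motifs, profile expression, estimate Ka/Ks, classify fates, and
# bundle a report.

#' Run the full gene-family survey pipeline
#'
#' Generates a synthetic genome, family sequences and expression data from
#' `config`, then runs the requested stages and returns a report bundle with
#' every stage's table plus the planted ground truth. With `out_dir` set,
#' per-stage TSVs and the newick tree are also written (deterministic:
#' identical config and seeds give identical files).
#'
#' @param config A [simulation_config()].
#' @param stages Which stages to run (default all).
#' @param out_dir Optional output directory for TSV/newick files.
#' @param n_bootstrap Bootstrap replicates for the tree (default 1000).
#' @param k_subfamilies Number of subfamilies to cut (default 5).
#' @param max_intervening Tandem rule (default 5 intervening genes).
#' @param max_pair_distance Segmental rule (default 500000 bp).
#' @param fold,alpha Expression-calling gates (default 2-fold, p < 0.05).
#' @return A list of class `fam_survey`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         stages = c("screen", "duplication", "phylogeny",
                                    "motifs", "expression", "selection",
                                    "divergence"),
                         out_dir = NULL,
                         n_bootstrap = 1000,
                         k_subfamilies = 5,
                         max_intervening = 5,
                         max_pair_distance = 500000,
                         fold = 2, alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(config = config, stages = stages)
  run_stage <- function(name, code) {
    if (!name %in% stages) return(NULL)
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  need <- function(what, field) {
    if (is.null(res[[field]])) {
      abort(sprintf("stage '%s' requires the '%s' stage output", what, field))
    }
    res[[field]]
  }

  # ground truth is the pipeline's input surrogate, always generated
  res$genome <- simulate_genome(config)
  res$sequences <- simulate_family_sequences(config, res$genome)
  genes <- res$genome$genes
  seqs <- res$sequences

  res$screen <- run_stage("screen", {
    profile <- build_profile(seqs$seed_alignment)
    profile <- calibrate_threshold(profile, seqs$proteins$seq,
                                   seed = config$seed + 10L)
    candidates <- bind_rows(
      select(seqs$proteins, "id", "seq"),
      select(seqs$decoys, "id", "seq")
    )
    screen(candidates, genes, profile)
  })

  res$duplication <- run_stage("duplication", {
    clusters <- find_tandem_clusters(genes, max_intervening = max_intervening)
    pairs <- find_segmental_pairs(genes, res$genome$blocks,
                                  max_pair_distance = max_pair_distance)
    list(clusters = clusters, pairs = pairs,
         summary = duplication_summary(clusters, pairs,
                                       family_size = sum(genes$is_family)))
  })

  res$phylogeny <- run_stage("phylogeny", {
    tree <- bootstrap_support(seqs$alignment, n_reps = n_bootstrap,
                              seed = config$seed + 11L)
    list(tree = tree,
         subfamilies = cut_subfamilies(tree, k = k_subfamilies),
         cherries = close_paralog_pairs(tree))
  })

  res$motifs <- run_stage("motifs", {
    windows <- find_conserved_motifs(seqs$alignment)
    pats <- config$motifs_to_plant
    nms <- names(pats) %||% paste0("motif", seq_along(pats))
    hits <- purrr::map_dfr(seq_along(pats), function(p) {
      purrr::map_dfr(seq_len(nrow(seqs$proteins)), function(i) {
        mutate(match_pattern(seqs$proteins$seq[i], pats[[p]]),
               gene_id = seqs$proteins$id[i], motif = nms[p])
      })
    })
    list(windows = windows, hits = hits)
  })

  res$expression <- run_stage("expression", {
    pairs <- seqs$pair_truth
    planted <- .plan_expression_truth(config, seqs, pairs)
    sim <- simulate_expression(config,
                               genes = planted$expr_genes,
                               preferential = planted$preferential,
                               specific = planted$specific,
                               fates = planted$fates)
    trt <- simulate_treatment_expression(config,
                                         genes = planted$expr_genes,
                                         responders = planted$responders,
                                         treatment = "light", control = "dark")
    thr <- sim$truth$expressed_threshold
    list(sim = sim, treatment = trt, planted = planted,
         expressed_threshold = thr,
         groups = cluster_expression(sim$expr, k = 5),
         preferential = preferential_genes(sim$expr, fold = fold, alpha = alpha),
         tissue_specific = tissue_specific_genes(sim$expr,
                                                 expressed_threshold = thr),
         de = treatment_de(trt$expr, "light", "dark", fold = fold, alpha = alpha))
  })

  res$selection <- run_stage("selection", {
    kaks_table(seqs$pair_truth, seqs$cds)
  })

  res$divergence <- run_stage("divergence", {
    sel <- need("divergence", "selection")
    expr_res <- need("divergence", "expression")
    calls <- classify_fates(sel, expr_res$sim$expr,
                            expressed_threshold = expr_res$expressed_threshold)
    list(calls = calls, summary = fate_summary(calls))
  })

  res$summary <- .survey_summary(res)
  out <- structure(res, class = "fam_survey")
  if (!is.null(out_dir)) write_survey(out, out_dir)
  out
}

# Decide what the expression simulator plants: divergence fates over the
# designated paralog pairs in the published composition (2 D, 4 NOF, 5 SF,
# 6 NF, extras cycling), two "no probe" pairs left out of the matrix, and a
# handful of preferential / tissue-specific genes in root, stamen and
# endosperm plus light-responsive genes.
#' @noRd
.plan_expression_truth <- function(config, seqs, pairs) {
  fam_ids <- seqs$proteins$id
  n_pairs <- nrow(pairs)
  fates <- character(0)
  if (n_pairs > 0) {
    base <- c(rep("D", 2), rep("NOF", 4), rep("SF", 5), rep("NF", 6))
    fates <- rep(c(base, "NF", "SF", "NOF", "D"), length.out = n_pairs)
    fates <- fates[seq_len(n_pairs)]
  }
  n_noprobe <- min(2L, n_pairs)
  noprobe_idx <- if (n_noprobe > 0) seq(n_pairs - n_noprobe + 1L, n_pairs) else integer(0)
  fate_tbl <- NULL
  if (n_pairs > 0) {
    keep <- setdiff(seq_len(n_pairs), noprobe_idx)
    fate_tbl <- tibble(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                       fate = fates[keep])
  }
  noprobe_genes <- c(pairs$gene_a[noprobe_idx], pairs$gene_b[noprobe_idx])
  expr_genes <- setdiff(fam_ids, noprobe_genes)
  paired <- unique(c(fate_tbl$gene_a, fate_tbl$gene_b))
  free <- setdiff(expr_genes, paired)
  pref_tissues <- c("R", "R", "Sta", "Sta", "E2")
  pref_tissues <- pref_tissues[pref_tissues %in% config$tissues]
  n_pref <- min(length(pref_tissues), length(free))
  preferential <- if (n_pref > 0) {
    tibble(gene = free[seq_len(n_pref)], tissue = pref_tissues[seq_len(n_pref)],
           fold = config$preferential_fold)
  } else NULL
  if (n_pref > 0) free <- free[-seq_len(n_pref)]
  spec_tissues <- intersect(c("R", "FL2"), config$tissues)
  n_spec <- min(length(spec_tissues), length(free))
  specific <- if (n_spec > 0) {
    tibble(gene = free[seq_len(n_spec)], tissue = spec_tissues[seq_len(n_spec)])
  } else NULL
  responders <- tibble(
    gene = head(expr_genes, 10),
    fold = 4,
    direction = rep(c("up", "down"), c(8, 2))[seq_len(min(10, length(expr_genes)))]
  )
  list(expr_genes = expr_genes, fates = fate_tbl, preferential = preferential,
       specific = specific, responders = responders,
       noprobe_pairs = pairs[noprobe_idx, , drop = FALSE])
}

#' @noRd
.survey_summary <- function(res) {
  s <- tibble(family_size = sum(res$genome$genes$is_family))
  if (!is.null(res$screen)) {
    s$n_accepted <- nrow(res$screen$accepted)
    s$n_excluded_partial <- nrow(res$screen$excluded_partial)
    s$n_excluded_annotation <- nrow(res$screen$excluded_annotation)
  }
  if (!is.null(res$duplication)) {
    s$n_tandem_clusters <- nrow(res$duplication$clusters)
    s$n_tandem_genes <- res$duplication$summary$n_tandem_genes
    s$n_segmental_pairs <- nrow(distinct(res$duplication$pairs,
                                         .data$gene_a, .data$gene_b))
    s$n_segmental_genes <- res$duplication$summary$n_segmental_genes
    s$fraction_duplicated <- res$duplication$summary$fraction_duplicated
  }
  if (!is.null(res$phylogeny)) {
    s$n_subfamilies <- length(unique(res$phylogeny$subfamilies$subfamily))
    s$n_cherries <- nrow(res$phylogeny$cherries)
  }
  if (!is.null(res$motifs)) s$n_motif_windows <- nrow(res$motifs$windows)
  if (!is.null(res$expression)) {
    s$n_preferential <- nrow(res$expression$preferential)
    s$n_tissue_specific <- nrow(res$expression$tissue_specific)
    s$n_de <- nrow(res$expression$de)
  }
  if (!is.null(res$selection)) {
    ok <- !is.na(res$selection$ratio)
    s$n_pairs_kaks <- sum(ok)
    s$max_ratio <- if (any(ok)) max(res$selection$ratio[ok]) else NA_real_
    s$all_purifying <- if (any(ok)) all(res$selection$purifying[ok]) else NA
  }
  if (!is.null(res$divergence)) {
    s <- dplyr::bind_cols(s, res$divergence$summary)
  }
  s
}

#' Write the survey report bundle
#'
#' @param survey A `fam_survey` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_survey <- function(survey, out_dir) {
  stopifnot(inherits(survey, "fam_survey"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  w(survey$genome$genes, "genes.tsv")
  w(survey$genome$blocks, "blocks.tsv")
  if (!is.null(survey$screen)) w(tidy(survey$screen), "screen.tsv")
  if (!is.null(survey$duplication)) {
    cl <- survey$duplication$clusters
    cl$genes <- vapply(cl$genes, paste, "", collapse = ",")
    w(cl, "tandem_clusters.tsv")
    w(survey$duplication$pairs, "segmental_pairs.tsv")
  }
  if (!is.null(survey$phylogeny)) {
    write_newick(survey$phylogeny$tree, file.path(out_dir, "tree.nwk"))
    w(survey$phylogeny$subfamilies, "subfamilies.tsv")
    w(survey$phylogeny$cherries, "cherries.tsv")
  }
  if (!is.null(survey$motifs)) {
    w(select(survey$motifs$windows, -"pattern"), "motif_windows.tsv")
    w(survey$motifs$hits, "motif_hits.tsv")
  }
  if (!is.null(survey$expression)) {
    w(survey$expression$preferential, "preferential.tsv")
    w(survey$expression$tissue_specific, "tissue_specific.tsv")
    w(survey$expression$de, "treatment_de.tsv")
  }
  if (!is.null(survey$divergence)) {
    calls <- survey$divergence$calls
    calls$gain_tissues <- vapply(calls$gain_tissues, paste, "", collapse = ",")
    w(calls, "paralog_table.tsv")
  }
  w(survey$summary, "summary.tsv")
  invisible(out_dir)
}

#' @export
print.fam_survey <- function(x, ...) {
  cat("<fam_survey>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fam_survey <- function(x, ...) x$summary
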