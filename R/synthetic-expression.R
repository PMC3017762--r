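# Replicate expression simulation with planted preferential genes,
# tissue-specific genes, paralog divergence fates, and treatment responders.
# Baselines are log-normal; replicate noise is multiplicative log-normal with
# a stated CV. Non-planted genes are flat across tissues so planted effects
# are the only true signal.

#' @noRd
.replicate_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a replicate expression matrix
#'
#' Generates positive signals for `genes` x `tissues` x replicates. Planted
#' preferential genes exceed every other tissue by the given fold; planted
#' tissue-specific genes sit at background outside their tissue; planted
#' paralog fates follow the four divergence models (D: copies share one
#' profile; NOF: one copy at background everywhere; SF: expressed tissues
#' split complementarily; NF: one copy gains `fate_gain_fold` in 1-3 tissues).
#'
#' @param config A [simulation_config()].
#' @param genes Character vector of gene ids (default: generic ids,
#'   `config$n_family` of them).
#' @param preferential Optional tibble (`gene`, `tissue`, `fold`).
#' @param specific Optional tibble (`gene`, `tissue`).
#' @param fates Optional tibble (`gene_a`, `gene_b`, `fate`) with fate in
#'   D/NOF/SF/NF.
#' @param seed Seed override (default `config$seed + 2`).
#' @return A list of class `fam_expression`: `expr` (long tibble `gene_id`,
#'   `sample`, `replicate`, `signal`) and `truth` (planted effects plus the
#'   per-gene, per-tissue true mean log2 levels and the background threshold).
#' @export
simulate_expression <- function(config, genes = NULL, preferential = NULL,
                                specific = NULL, fates = NULL,
                                seed = config$seed + 2L) {
  stopifnot(inherits(config, "fam_config"))
  if (is.null(genes)) genes <- sprintf("gene%03d", seq_len(config$n_family))
  tissues <- config$tissues
  with_seed(seed, {
    base <- rnorm(length(genes), config$baseline_log2_mean, config$baseline_log2_sd)
    mu <- matrix(base, nrow = length(genes), ncol = length(tissues),
                 dimnames = list(genes, tissues))
    bg <- config$background_log2

    if (!is.null(preferential)) {
      for (i in seq_len(nrow(preferential))) {
        g <- preferential$gene[i]
        mu[g, preferential$tissue[i]] <- mu[g, preferential$tissue[i]] +
          log2(preferential$fold[i])
      }
    }
    if (!is.null(specific)) {
      for (i in seq_len(nrow(specific))) {
        g <- specific$gene[i]
        mu[g, ] <- bg
        mu[g, specific$tissue[i]] <- config$baseline_log2_mean + 2
      }
    }
    if (!is.null(fates)) {
      for (i in seq_len(nrow(fates))) {
        a <- fates$gene_a[i]; b <- fates$gene_b[i]
        # the copies inherit one ancestral tissue profile: a base level plus
        # per-tissue effects, floored well above background so expressed
        # tissues never straddle the threshold
        lev <- max(rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd / 2),
                   bg + 4)
        prof <- pmax(lev + rnorm(length(tissues), 0, 1.5), bg + 2.5)
        switch(fates$fate[i],
          D = { mu[a, ] <- prof; mu[b, ] <- prof },
          NOF = { mu[a, ] <- prof; mu[b, ] <- bg },
          SF = {
            half <- sample(length(tissues), floor(length(tissues) / 2))
            mu[a, ] <- bg; mu[b, ] <- bg
            mu[a, half] <- prof[half]; mu[b, -half] <- prof[-half]
          },
          NF = {
            mu[a, ] <- prof; mu[b, ] <- prof
            gain <- sample(length(tissues), sample(1:3, 1))
            mu[b, gain] <- prof[gain] + log2(config$fate_gain_fold)
          },
          abort(sprintf("unknown fate '%s'", fates$fate[i]))
        )
      }
    }

    expr <- tidyr::expand_grid(gene_id = genes, sample = tissues,
                               replicate = seq_len(config$n_replicates))
    expr$signal <- 2^mu[cbind(expr$gene_id, expr$sample)] *
      .replicate_noise(nrow(expr), config$replicate_cv)
    truth <- list(preferential = preferential, specific = specific,
                  fates = fates, mu_log2 = mu,
                  expressed_threshold = 2^(bg + 1.5))
    structure(list(expr = expr, truth = truth), class = "fam_expression")
  })
}

#' Simulate treatment-vs-control expression
#'
#' One treated and one control sample (with replicates); responder genes are
#' shifted by the stated fold in the stated direction.
#'
#' @param config A [simulation_config()].
#' @param genes Gene ids.
#' @param responders Tibble (`gene`, `fold`, `direction` in up/down).
#' @param treatment,control Sample labels.
#' @param seed Seed override.
#' @return A list of class `fam_expression` (long `expr` + `truth`).
#' @export
simulate_treatment_expression <- function(config, genes, responders,
                                          treatment = "treated",
                                          control = "control",
                                          seed = config$seed + 3L) {
  stopifnot(inherits(config, "fam_config"))
  with_seed(seed, {
    base <- rnorm(length(genes), config$baseline_log2_mean, config$baseline_log2_sd)
    mu <- matrix(base, nrow = length(genes), ncol = 2,
                 dimnames = list(genes, c(control, treatment)))
    if (!is.null(responders) && nrow(responders) > 0) {
      shift <- ifelse(responders$direction == "up", 1, -1) * log2(responders$fold)
      mu[cbind(responders$gene, treatment)] <-
        mu[cbind(responders$gene, control)] + shift
    }
    expr <- tidyr::expand_grid(gene_id = genes, sample = c(control, treatment),
                               replicate = seq_len(config$n_replicates))
    expr$signal <- 2^mu[cbind(expr$gene_id, expr$sample)] *
      .replicate_noise(nrow(expr), config$replicate_cv)
    structure(list(expr = expr,
                   truth = list(responders = responders, mu_log2 = mu)),
              class = "fam_expression")
  })
}
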