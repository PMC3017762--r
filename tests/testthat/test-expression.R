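make_expr <- function(mu_log2, n_rep = 3, cv = 0.1, seed = 1) {
  # mu_log2: genes x samples matrix of true log2 means
  set.seed(seed)
  long <- tidyr::expand_grid(gene_id = rownames(mu_log2),
                             sample = colnames(mu_log2),
                             replicate = seq_len(n_rep))
  sdlog <- sqrt(log(1 + cv^2))
  long$signal <- 2^mu_log2[cbind(long$gene_id, long$sample)] *
    rlnorm(nrow(long), -sdlog^2 / 2, sdlog)
  long
}

test_that("replicate collapsing is the arithmetic mean", {
  expr <- tibble::tibble(gene_id = "g", sample = "R", replicate = 1:2,
                         signal = c(10, 12))
  expect_equal(collapse_replicates(expr)$signal, 11)
  single <- tibble::tibble(gene_id = "g", sample = "R", replicate = 1,
                           signal = 7)
  expect_equal(collapse_replicates(single)$signal, 7)

  set.seed(2)
  mu <- matrix(rnorm(12, 8), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expr2 <- make_expr(mu, n_rep = 4)
  got <- collapse_replicates(expr2)
  want <- tapply(expr2$signal, list(expr2$gene_id, expr2$sample), mean)
  expect_equal(got$signal, want[cbind(got$gene_id, got$sample)],
               ignore_attr = TRUE)
})

test_that("complete-linkage grouping separates blocks and matches the oracle", {
  # two blocks of identical profiles
  mu <- rbind(matrix(4, 5, 6), matrix(10, 5, 6))
  rownames(mu) <- paste0("g", 1:10); colnames(mu) <- paste0("s", 1:6)
  expr <- make_expr(mu, cv = 0.02)
  cl <- cluster_expression(expr, k = 2)
  part <- setNames(cl$groups$group, cl$groups$gene_id)[paste0("g", 1:10)]
  expect_equal(length(unique(part[1:5])), 1)
  expect_equal(length(unique(part[6:10])), 1)
  expect_false(part[["g1"]] == part[["g10"]])

  # duplicate rows always co-cluster
  expr_dup <- dplyr::bind_rows(
    expr,
    dplyr::mutate(dplyr::filter(expr, gene_id == "g1"), gene_id = "g1copy"))
  cl2 <- cluster_expression(expr_dup, k = 3)
  p2 <- setNames(cl2$groups$group, cl2$groups$gene_id)
  expect_equal(p2[["g1"]], p2[["g1copy"]])

  # against a hand-rolled complete-linkage agglomerator
  set.seed(4)
  mu3 <- matrix(rnorm(200, 8, 2), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  expr3 <- make_expr(mu3, n_rep = 2, cv = 0.01)
  for (k in c(3, 5)) {
    cl3 <- cluster_expression(expr3, k = k)
    means <- collapse_replicates(expr3)
    wide <- tidyr::pivot_wider(means, names_from = "sample",
                               values_from = "signal")
    m <- log2(as.matrix(wide[, -1])); rownames(m) <- wide$gene_id
    want <- oracle_complete_linkage(m, k)
    got <- setNames(cl3$groups$group, cl3$groups$gene_id)[rownames(m)]
    expect_true(same_partition(unname(got), want))
  }
  expect_error(cluster_expression(expr3, k = 100), "k exceeds")
})

test_that("gene order does not change the grouping", {
  set.seed(6)
  mu <- matrix(rnorm(60, 8, 2), 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  expr <- make_expr(mu, cv = 0.05)
  cl1 <- cluster_expression(expr, k = 3)
  expr_rev <- dplyr::arrange(expr, dplyr::desc(gene_id))
  cl2 <- cluster_expression(expr_rev, k = 3)
  g1 <- setNames(cl1$groups$group, cl1$groups$gene_id)[sprintf("g%02d", 1:10)]
  g2 <- setNames(cl2$groups$group, cl2$groups$gene_id)[sprintf("g%02d", 1:10)]
  expect_true(same_partition(unname(g1), unname(g2)))
})

test_that("preferential calling enforces both the fold and the p gate", {
  tissues <- paste0("s", 1:6)
  mu <- matrix(8, 3, 6, dimnames = list(c("hit", "flat", "weak"), tissues))
  mu["hit", "s1"] <- 8 + log2(10)
  mu["weak", "s1"] <- 8 + log2(1.5)
  expr <- make_expr(mu, n_rep = 3, cv = 0.1, seed = 7)
  calls <- preferential_genes(expr)
  expect_equal(calls$gene_id, "hit")
  expect_equal(calls$sample, "s1")
  expect_gt(calls$fold, 2)
  expect_lt(calls$p_value, 0.05)
})

test_that("tissue-specific calling uses the expressed threshold", {
  tissues <- paste0("s", 1:5)
  mu <- matrix(3, 3, 5, dimnames = list(c("root_only", "on", "off"), tissues))
  mu["root_only", "s1"] <- 10
  mu["on", ] <- 10
  expr <- make_expr(mu, seed = 8)
  calls <- tissue_specific_genes(expr, expressed_threshold = 2^6)
  expect_equal(calls$gene_id, "root_only")
  expect_equal(calls$sample, "s1")
})

test_that("treatment DE calls up and down with gates", {
  mu <- matrix(8, 3, 2, dimnames = list(c("up10", "near", "down4"),
                                        c("dark", "light")))
  mu["up10", "light"] <- 8 + log2(10)
  mu["near", "light"] <- 8 + log2(1.8)
  mu["down4", "light"] <- 8 - log2(4)
  expr <- make_expr(mu, n_rep = 3, cv = 0.1, seed = 9)
  calls <- treatment_de(expr, treatment = "light", control = "dark")
  expect_setequal(calls$gene_id, c("up10", "down4"))
  expect_equal(calls$type[calls$gene_id == "up10"], "up")
  expect_equal(calls$type[calls$gene_id == "down4"], "down")
  expect_error(treatment_de(expr, "light", "absent"), "absent")
})

test_that("ddCt folds follow 2^-ddCt", {
  expect_equal(ddct_relative_expression(20, 18, 22, 20), 1)
  expect_equal(ddct_relative_expression(19, 18, 22, 20), 2)
  expect_equal(ddct_relative_expression(21.2, 18, 20, 20), 2^-3.2)
  expect_error(ddct_relative_expression(NA, 1, 1, 1), "finite")
})
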