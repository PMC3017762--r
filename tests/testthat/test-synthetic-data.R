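cfg_small <- simulation_config(seed = 42, n_chromosomes = 4,
                               genes_per_chromosome = 40, n_family = 20,
                               tandem_cluster_sizes = c(3, 2, 2),
                               n_segmental_pairs = 3,
                               n_segmental_tandem_overlap = 1,
                               ancestor_codon_length = 120)

test_that("genome simulation plants the requested tandem composition", {
  g <- simulate_genome(cfg_small)
  expect_equal(sum(g$genes$is_family), 20)
  cl <- find_tandem_clusters(g$genes)
  expect_equal(sort(cl$n_genes), c(2, 2, 3))
  # planted clusters recovered exactly
  truth <- split(g$tandem_truth$gene_id, g$tandem_truth$cluster_id)
  found <- lapply(cl$genes, sort)
  expect_setequal(vapply(found, paste, "", collapse = ","),
                  vapply(lapply(truth, sort), paste, "", collapse = ","))
})

test_that("genome simulation is deterministic and supports empty families", {
  g1 <- simulate_genome(cfg_small)
  g2 <- simulate_genome(cfg_small)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$blocks, g2$blocks)

  empty <- simulation_config(seed = 1, n_family = 0,
                             tandem_cluster_sizes = integer(0),
                             n_segmental_pairs = 0,
                             n_segmental_tandem_overlap = 0)
  g0 <- simulate_genome(empty)
  expect_equal(sum(g0$genes$is_family), 0)
})

test_that("infeasible placements are refused", {
  expect_error(
    simulate_genome(simulation_config(seed = 1, n_chromosomes = 1,
                                      genes_per_chromosome = 8, n_family = 8,
                                      tandem_cluster_sizes = c(4, 4),
                                      n_segmental_pairs = 0,
                                      n_segmental_tandem_overlap = 0)),
    "infeasible")
})

test_that("codon pair simulation respects omega = 0 and the Ks target", {
  p0 <- simulate_codon_pair(400, omega = 0, target_ks = 0.3, seed = 5)
  expect_equal(p0$truth$n_nonsyn, 0)
  k0 <- kaks_ng86(p0)
  # pathway averaging can attribute tiny fractional nonsynonymous counts to
  # doubly-hit codons even when no nonsynonymous substitution occurred
  expect_lt(k0$ka, 0.01)
  expect_gt(k0$ks, 0.15)

  # same seed reproduces; different seed differs
  expect_identical(simulate_codon_pair(100, 0.5, 0.4, seed = 9),
                   simulate_codon_pair(100, 0.5, 0.4, seed = 9))
  expect_false(identical(simulate_codon_pair(100, 0.5, 0.4, seed = 9)$cds_a,
                         simulate_codon_pair(100, 0.5, 0.4, seed = 10)$cds_a))

  # calibration: NG86 Ks lands near the target on a long sequence
  k <- kaks_ng86(simulate_codon_pair(2000, 0.2, 0.5, seed = 11))
  expect_lt(abs(k$ks - 0.5), 0.1)
})

test_that("simulated pairs never contain stop codons", {
  p <- simulate_codon_pair(300, omega = 1, target_ks = 1.0, seed = 13)
  for (s in c(p$cds_a, p$cds_b)) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
  }
})

test_that("expression simulation realizes planted effects by construction", {
  cfg <- simulation_config(seed = 8)
  genes <- sprintf("g%02d", 1:30)
  pref <- tibble::tibble(gene = "g01", tissue = "Sta", fold = 10)
  fates <- tibble::tibble(gene_a = "g02", gene_b = "g03", fate = "NOF")
  sim <- simulate_expression(cfg, genes, preferential = pref, fates = fates)
  mu <- sim$truth$mu_log2
  # planted preferential gene exceeds every other tissue 10-fold in expectation
  expect_gt(min(mu["g01", "Sta"] - mu["g01", colnames(mu) != "Sta"]),
            log2(10) - 1e-9)
  # NOF silent copy below the expression threshold everywhere
  thr <- log2(sim$truth$expressed_threshold)
  expect_true(all(mu["g03", ] < thr))
  expect_true(all(mu["g02", ] > thr))
  # determinism
  expect_identical(sim$expr,
                   simulate_expression(cfg, genes, preferential = pref,
                                       fates = fates)$expr)
})

test_that("motif planting writes each pattern into family proteins only", {
  proteins <- tibble::tibble(
    id = c("fam1", "fam2", "out1"),
    seq = replicate(3, paste(rep("A", 60), collapse = ""))
  )
  pats <- c("NLVxYL", "FFNWY")
  out <- plant_motifs(proteins, pats, positions = c(5, 30),
                      family_ids = c("fam1", "fam2"), seed = 3)
  for (p in pats) {
    expect_equal(nrow(match_pattern(out$seq[1], p)), 1)
    expect_equal(nrow(match_pattern(out$seq[2], p)), 1)
    expect_equal(nrow(match_pattern(out$seq[3], p)), 0)
  }
  expect_equal(out$seq[3], proteins$seq[3])
  # K(R) alternatives instantiate one member of the set
  kr <- plant_motifs(proteins[1, ], "GGK(R)GG", positions = 10, seed = 1)
  expect_true(substr(kr$seq, 12, 12) %in% c("K", "R"))
})
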