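test_that("tandem chaining follows the intervening-gene rule", {
  # family genes at ranks 1 and 3 (1 intervening) chain; rank 10 (6
  # intervening from rank 3) does not, and singletons are dropped
  fam <- rep(FALSE, 12)
  fam[c(1, 3, 10)] <- TRUE
  genes <- make_genes("chr01", seq(1000, by = 5000, length.out = 12), fam)
  cl <- find_tandem_clusters(genes, max_intervening = 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$genes[[1]], genes$gene_id[c(1, 3)])

  # exactly 5 intervening still chains, 6 does not
  fam2 <- rep(FALSE, 10)
  fam2[c(1, 7)] <- TRUE
  genes2 <- make_genes("chr02", seq(1000, by = 5000, length.out = 10), fam2)
  expect_equal(nrow(find_tandem_clusters(genes2)), 1)
  fam3 <- rep(FALSE, 10)
  fam3[c(1, 8)] <- TRUE
  genes3 <- make_genes("chr03", seq(1000, by = 5000, length.out = 10), fam3)
  expect_equal(nrow(find_tandem_clusters(genes3)), 0)

  expect_equal(nrow(find_tandem_clusters(make_genes("chr04", c(1, 5000),
                                                    c(FALSE, FALSE)))), 0)
})

test_that("cluster membership survives insertions that keep gaps <= 5", {
  fam <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  genes <- make_genes("chr01", seq(1000, by = 4000, length.out = 6), fam)
  before <- find_tandem_clusters(genes)$genes[[1]]
  # insert two more non-family genes between the 2nd and 3rd family member
  extra <- make_genes("chr01", c(17500, 18500), c(FALSE, FALSE))
  extra$gene_id <- c("ins1", "ins2")
  after <- find_tandem_clusters(dplyr::bind_rows(genes, extra))$genes[[1]]
  expect_setequal(before, after)
})

test_that("orientation flags mixed-strand clusters", {
  genes <- make_genes("chr01", c(1000, 3000), c(TRUE, TRUE),
                      strand = c("+", "-"))
  expect_false(find_tandem_clusters(genes)$same_orientation)
  genes$strand <- "+"
  expect_true(find_tandem_clusters(genes)$same_orientation)
})

test_that("segmental pairs respect blocks and the distance rule", {
  # chrA: anchor . family . anchor ; chrB: anchor . family . anchor
  ga <- make_genes("chrA", c(1e5, 2e5, 3e5), c(FALSE, TRUE, FALSE))
  gb <- make_genes("chrB", c(1e5, 2e5, 3e5), c(FALSE, TRUE, FALSE))
  genes <- dplyr::bind_rows(ga, gb)
  blocks <- tibble::tibble(block_id = "B1",
                           gene_a = ga$gene_id[c(1, 3)],
                           gene_b = gb$gene_id[c(1, 3)])
  got <- find_segmental_pairs(genes, blocks)
  expect_equal(nrow(got), 1)
  expect_setequal(c(got$gene_a, got$gene_b), c(ga$gene_id[2], gb$gene_id[2]))

  # member 600 kb from every anchor is refused
  ga2 <- make_genes("chrC", c(1e5, 7.2e5, 14e5), c(FALSE, TRUE, FALSE))
  genes2 <- dplyr::bind_rows(ga2, gb)
  blocks2 <- tibble::tibble(block_id = "B2",
                            gene_a = ga2$gene_id[c(1, 3)],
                            gene_b = gb$gene_id[c(1, 3)])
  expect_equal(nrow(find_segmental_pairs(genes2, blocks2)), 0)

  # unknown anchor id is a validation error
  blocks3 <- tibble::tibble(block_id = "B3", gene_a = "nope", gene_b = "nah")
  expect_error(find_segmental_pairs(genes, blocks3), "unknown")
})

test_that("one gene can participate in two blocks", {
  ga <- make_genes("chrA", c(1e5, 2e5, 3e5), c(FALSE, TRUE, FALSE))
  gb <- make_genes("chrB", c(1e5, 2e5, 3e5), c(FALSE, TRUE, FALSE))
  gc_ <- make_genes("chrC", c(1e5, 2e5, 3e5), c(FALSE, TRUE, FALSE))
  genes <- dplyr::bind_rows(ga, gb, gc_)
  blocks <- dplyr::bind_rows(
    tibble::tibble(block_id = "B1", gene_a = ga$gene_id[c(1, 3)],
                   gene_b = gb$gene_id[c(1, 3)]),
    tibble::tibble(block_id = "B2", gene_a = ga$gene_id[c(1, 3)],
                   gene_b = gc_$gene_id[c(1, 3)])
  )
  got <- find_segmental_pairs(genes, blocks)
  expect_equal(nrow(got), 2)
  expect_equal(sum(c(got$gene_a, got$gene_b) == ga$gene_id[2]), 2)
})

test_that("duplication summary unions without double counting", {
  clusters <- tibble::tibble(cluster = "c1", chromosome = "chr01",
                             n_genes = 3L,
                             genes = list(c("g1", "g2", "g3")),
                             same_orientation = TRUE)
  pairs <- tibble::tibble(gene_a = c("g3", "g4"), gene_b = c("g5", "g6"),
                          block_id = c("B1", "B2"))
  s <- duplication_summary(clusters, pairs, family_size = 9)
  expect_equal(s$n_tandem_genes, 3)
  expect_equal(s$n_segmental_genes, 4)
  expect_equal(s$n_either, 6)   # g3 counted once
  expect_equal(s$fraction_duplicated, 6 / 9)

  z <- duplication_summary(clusters[0, ], pairs[0, ], family_size = 0)
  expect_equal(unlist(z), c(n_tandem_genes = 0, n_segmental_genes = 0,
                            n_either = 0, fraction_duplicated = 0))
})

test_that("the study-design composition yields 44 genes in 14 clusters", {
  g <- simulate_genome(simulation_config(seed = 2))
  cl <- find_tandem_clusters(g$genes)
  expect_equal(nrow(cl), 14)
  expect_equal(sum(cl$n_genes), 44)
  expect_equal(sort(cl$n_genes), sort(c(9, 4, 4, 3, 3, 3, 3, 3, 2, 2, 2, 2, 2, 2)))
  # planted segmental pairs all recovered
  sp <- find_segmental_pairs(g$genes, g$blocks)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(g$segmental_truth$gene_a, g$segmental_truth$gene_b) %in%
                    key(sp$gene_a, sp$gene_b)))
})
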