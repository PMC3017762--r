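# A tiny planted domain: profile from near-identical seed sequences.
domain_seed <- function(n = 20) {
  core <- "MKVLNWYDEQRFFNWYLLGADQF"
  tibble::tibble(id = sprintf("s%02d", seq_len(n)), seq = core)
}

test_that("profile log-odds match closed forms", {
  # single column, all L, vanishing pseudocount: log2(20) bits
  aln <- tibble::tibble(id = c("a", "b"), seq = c("L", "L"))
  prof <- build_profile(aln, pseudocount = 1e-9)
  expect_equal(unname(prof$log_odds["L", 1]), log2(20), tolerance = 1e-6)

  # uniform column: all log-odds 0
  aln20 <- tibble::tibble(id = sprintf("s%02d", 1:20),
                          seq = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  prof20 <- build_profile(aln20, pseudocount = 0)
  expect_true(all(abs(prof20$log_odds) < 1e-12))

  # pseudocount 1 over 20 sequences, all L: p(L) = 21/40
  profL <- build_profile(tibble::tibble(id = sprintf("s%02d", 1:20),
                                        seq = rep("L", 20)), pseudocount = 1)
  expect_equal(unname(profL$log_odds["L", 1]), log2(20 * 21 / 40))

  expect_error(build_profile(tibble::tibble(id = c("a", "b"), seq = c("-", "-"))),
               "gap")
})

test_that("profile scanning scores consensus and truncated fragments", {
  prof <- build_profile(domain_seed())
  consensus <- prof$consensus
  full <- scan_protein(consensus, prof)
  expect_equal(full$coverage, 1.0)
  expect_equal(full$best_score, sum(apply(prof$log_odds, 2, max)))
  expect_equal(full$best_start, 1L)

  # only the first 40% of the consensus present: coverage 0.4
  frag <- substr(consensus, 1, floor(nchar(consensus) * 0.4))
  part <- scan_protein(frag, prof)
  expect_lt(abs(part$coverage - 0.4), 0.05)

  # random proteins score below a calibrated threshold almost surely
  prof <- calibrate_threshold(prof, rep(consensus, 5), n_shuffle = 40, seed = 2)
  set.seed(9)
  rand_scores <- replicate(20, {
    scan_protein(paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                              200, TRUE), collapse = ""), prof)$best_score
  })
  expect_lt(mean(rand_scores >= prof$score_threshold), 0.2)
})

test_that("screen unions evidence, dedups transcripts, and excludes", {
  prof <- calibrate_threshold(build_profile(domain_seed()),
                              domain_seed()$seq[1:5], n_shuffle = 20, seed = 4)
  consensus <- prof$consensus
  pad <- strrep("A", 30)
  proteins <- tibble::tibble(
    id = c("fam1.1", "fam1.2", "fam2.1", "part1", "retro1", "kw1", "rand1"),
    seq = c(paste0(pad, consensus),                        # locus fam1, long
            consensus,                                     # locus fam1, short
            paste0(consensus, pad),                        # fam2
            substr(consensus, 1, 9),                       # partial domain
            paste0(consensus, pad),                        # retro-annotated
            paste0(pad, pad),                              # keyword only
            strrep("Q", 50))                               # nothing
  )
  genes <- make_genes("chr01", seq(1000, 7000, by = 1000),
                      is_family = rep(FALSE, 7))
  genes$gene_id <- c("fam1", "fam1x", "fam2.1", "part1", "retro1", "kw1", "rand1")
  genes$annotation <- c("peptide transporter", "", "expressed protein",
                        "peptide transporter, partial", "retrotransposon protein",
                        "putative peptide transporter", "expressed protein")
  res <- screen(proteins, genes, prof)

  # one entry per locus, the longest transcript kept
  expect_true("fam1.1" %in% res$accepted$id)
  expect_false("fam1.2" %in% tidy(res)$id)
  expect_true("fam2.1" %in% res$accepted$id)
  expect_equal(res$accepted$provenance[res$accepted$id == "fam1.1"], "both")
  expect_true("part1" %in% res$excluded_partial$id)
  expect_true("retro1" %in% res$excluded_annotation$id)
  # keyword-only hit without the domain is partial-domain excluded
  expect_true("kw1" %in% res$excluded_partial$id)
  expect_false("rand1" %in% tidy(res)$id)
  # the three result sets are disjoint
  ids <- tidy(res)$id
  expect_equal(anyDuplicated(ids), 0)
})

test_that("raising the score threshold never adds accepted genes", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 4,
                           genes_per_chromosome = 40, n_family = 12,
                           tandem_cluster_sizes = c(2, 2),
                           n_segmental_pairs = 2,
                           n_segmental_tandem_overlap = 1,
                           ancestor_codon_length = 120)
  g <- simulate_genome(cfg)
  sq <- simulate_family_sequences(cfg, g)
  prof <- calibrate_threshold(build_profile(sq$seed_alignment),
                              sq$proteins$seq, n_shuffle = 2, seed = 6)
  cand <- rbind(sq$proteins[, c("id", "seq")], sq$decoys[, c("id", "seq")])
  base <- screen(cand, g$genes, prof)
  for (bump in c(5, 20, 100)) {
    prof2 <- prof
    prof2$score_threshold <- prof$score_threshold + bump
    harder <- screen(cand, g$genes, prof2)
    expect_true(all(harder$accepted$id %in% base$accepted$id))
  }
})
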