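test_that("p-distance handles identity, mismatches, and pairwise deletion", {
  expect_equal(protein_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(protein_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(protein_distance(c(a = "A-AA", b = "ATAA"))["a", "b"], 0)
  expect_error(protein_distance(c(a = "A---", b = "-TTT")), "comparable")
})

test_that("NJ recovers a hand-built additive 4-taxon matrix exactly", {
  # topology AB|CD, internal branch 1, pendant branches A=2 B=3 C=4 D=5
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 2 + 3
  d["A", "C"] <- d["C", "A"] <- 2 + 1 + 4
  d["A", "D"] <- d["D", "A"] <- 2 + 1 + 5
  d["B", "C"] <- d["C", "B"] <- 3 + 1 + 4
  d["B", "D"] <- d["D", "B"] <- 3 + 1 + 5
  d["C", "D"] <- d["D", "C"] <- 4 + 5
  tr <- neighbor_joining(d)
  got <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(got, d, tolerance = 1e-12)
  # the AB|CD split is present
  want <- ape::unroot(ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);"))
  expect_equal(as.numeric(ape::dist.topo(tr, want)), 0)
})

test_that("NJ on 3 taxa gives the closed-form star", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is invariant to taxon order and matches the ape oracle", {
  set.seed(31)
  for (i in 1:10) {
    ra <- random_additive(sample(5:8, 1))
    tr1 <- neighbor_joining(ra$d)
    perm <- sample(nrow(ra$d))
    tr2 <- neighbor_joining(ra$d[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
    # independent oracle: ape's NJ on the same additive matrix
    expect_equal(as.numeric(ape::dist.topo(tr1, ape::nj(ra$d))), 0)
    expect_equal(as.numeric(ape::dist.topo(tr1, ra$tree)), 0)
  }
})

test_that("bootstrap gives full support to a saturated split", {
  # two 3-leaf clades separated by many diagnostic columns
  left <- strrep("A", 40)
  right <- strrep("W", 40)
  aln <- c(A = paste0(left, "CDE"), B = paste0(left, "CDF"),
           C = paste0(left, "CEF"), D = paste0(right, "CDE"),
           E = paste0(right, "CDF"), F = paste0(right, "CEF"))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 3)
  supports <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(100 %in% supports)
  # same seed, same supports; n_reps = 0 leaves supports absent
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  expect_null(bootstrap_support(aln, n_reps = 0, seed = 3)$node.label)
})

test_that("subfamily cutting removes the longest stems", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):5,(C:0.1,D:0.1):5);")
  part <- cut_subfamilies(tr, k = 2)
  expect_equal(length(unique(part$subfamily)), 2)
  expect_equal(part$subfamily[part$gene_id == "A"],
               part$subfamily[part$gene_id == "B"])
  expect_false(part$subfamily[part$gene_id == "A"] ==
                 part$subfamily[part$gene_id == "C"])

  # k = leaf count on a star-like tree: singletons
  star <- ape::read.tree(text = "((A:1,B:1):0.001,(C:1,D:1):0.001);")
  solo <- cut_subfamilies(star, k = 4)
  expect_equal(length(unique(solo$subfamily)), 4)

  # five planted clades with long stems are recovered, labelled by size
  txt <- "(((a1:.1,a2:.1):.1,a3:.1):3,((b1:.1,b2:.1):3,((c1:.1,c2:.1):3,((d1:.1,d2:.1):3,(e1:.1,e2:.1):3):.2):.2):.2);"
  tr5 <- ape::read.tree(text = txt)
  p5 <- cut_subfamilies(tr5, k = 5)
  expect_equal(length(unique(p5$subfamily)), 5)
  grp <- split(p5$gene_id, p5$subfamily)
  expect_true(all(vapply(grp, function(g) length(unique(substr(g, 1, 1))), 1L) == 1))
  expect_equal(p5$subfamily[p5$gene_id == "a1"], "I")  # largest clade first
})

test_that("cherries and ortholog pairs are extracted from topology", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ch <- close_paralog_pairs(tr)
  expect_equal(nrow(ch), 2)
  expect_setequal(paste(ch$gene_a, ch$gene_b), c("A B", "C D"))

  cat1 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1,E:1);")
  expect_equal(nrow(close_paralog_pairs(cat1)), 1)

  sp <- c(A = "rice", B = "arabidopsis", C = "rice", D = "rice")
  orth <- ortholog_pairs(tr, sp)
  expect_equal(nrow(orth), 1)
  expect_setequal(c(orth$gene_a, orth$gene_b), c("A", "B"))
  expect_error(ortholog_pairs(tr, sp[1:2]), "species")
})

test_that("planted cherries in a larger random tree are all recovered", {
  set.seed(77)
  n_pairs <- 12
  # build a tree whose tips come in sister pairs
  base <- ape::rtree(n_pairs)
  base$tip.label <- sprintf("p%02d", seq_len(n_pairs))
  txt <- ape::write.tree(base)
  for (i in seq_len(n_pairs)) {
    lab <- sprintf("p%02d", i)
    txt <- sub(paste0(lab, ":"), sprintf("(%sa:0.01,%sb:0.01):", lab, lab), txt)
  }
  tr <- ape::read.tree(text = txt)
  ch <- close_paralog_pairs(tr)
  expect_equal(nrow(ch), n_pairs)
})
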