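# Shared fixtures and independent oracles used across the suite.

# A tiny gene table builder (1-based inclusive coordinates).
make_genes <- function(chrom, starts, is_family, strand = "+",
                       annotation = "hypothetical protein") {
  n <- length(starts)
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
    chromosome = chrom,
    start = as.integer(starts),
    end = as.integer(starts + 999L),
    strand = rep(strand, length.out = n),
    annotation = rep(annotation, length.out = n),
    is_family = is_family
  )
}

# Independent pathway-enumeration oracle for NG86 difference counting:
# recursive depth-first walk over all substitution orders, skipping
# intermediates that are stop codons; falls back to all orders if every
# pathway is blocked.
oracle_pair_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  walk <- function(cur, target, skip_stops) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(diffs) == 0)

      return(list(list(syn = 0, nonsyn = 0)))
    out <- list()
    for (pos in diffs) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      if (skip_stops && code[[nxt]] == "*" && nxt != target) next
      step_syn <- as.integer(code[[nxt]] == code[[cur]])
      for (tail in walk(nxt, target, skip_stops)) {
        out[[length(out) + 1L]] <- list(syn = tail$syn + step_syn,
                                        nonsyn = tail$nonsyn + (1 - step_syn))
      }
    }
    out
  }
  paths <- walk(c1, c2, skip_stops = TRUE)
  if (length(paths) == 0) paths <- walk(c1, c2, skip_stops = FALSE)
  c(syn = mean(vapply(paths, `[[`, 0, "syn")),
    nonsyn = mean(vapply(paths, `[[`, 0, "nonsyn")))
}

# Independent brute-force degenerate-pattern matcher.
oracle_match <- function(protein, elements) {
  chars <- strsplit(protein, "")[[1]]
  L <- length(elements)
  hits <- integer(0)
  for (s in seq_len(max(0, length(chars) - L + 1))) {
    ok <- TRUE
    for (j in seq_len(L)) {
      el <- elements[[j]]
      if (identical(el, "x")) next
      if (!chars[s + j - 1] %in% el) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Hand-rolled complete-linkage agglomeration returning the k-group partition.
oracle_complete_linkage <- function(mat, k) {
  groups <- as.list(seq_len(nrow(mat)))
  d <- as.matrix(dist(mat))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        dd <- max(d[groups[[i]], groups[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  part <- integer(nrow(mat))
  for (i in seq_along(groups)) part[groups[[i]]] <- i
  part
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1))]))
}

# A random unrooted additive tree and its exact distance matrix.
random_additive <- function(n) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
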