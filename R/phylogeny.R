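# Distance computation, neighbor joining, bootstrap supports, subfamily
# cutting, and cherry (sister-pair) extraction. Trees are ape "phylo"
# objects; NJ itself is implemented here with deterministic tie-breaking.

#' Pairwise protein distance matrix
#'
#' p-distance with pairwise deletion: for each pair, the fraction of
#' mismatching columns among columns where neither row has a gap. The
#' optional Kimura correction transforms p to -ln(1 - p - p^2/5).
#'
#' @param alignment Alignment (tibble with `id`/`seq`, named vector, or
#'   character matrix).
#' @param model `"p"` (default) or `"kimura"`.
#' @return A symmetric labelled distance matrix with zero diagonal.
#' @export
protein_distance <- function(alignment, model = c("p", "kimura")) {
  model <- match.arg(model)
  m <- aln_matrix(alignment)
  n <- nrow(m)
  labels <- rownames(m)
  ok <- m != GAP_CHAR & m != "X"
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      labels[i], labels[j]))
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d[i, j] <- d[j, i] <- if (model == "p") p else {
        arg <- 1 - p - p^2 / 5
        if (arg <= 0) abort(sprintf("Kimura correction saturated for '%s'/'%s'",
                                    labels[i], labels[j]))
        -log(arg)
      }
    }
  }
  d
}

# Core NJ agglomeration. Returns the newick string and the canonical split
# keys of all internal edges. Tie-breaks on equal Q by the lexicographically
# smallest (representative_i, representative_j) pair, where a cluster's
# representative is its smallest leaf label.
#' @noRd
nj_core <- function(d, labels = rownames(d), collect_splits = TRUE) {
  n <- length(labels)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  ref_label <- min(labels)
  all_set <- labels
  active <- seq_len(n)
  nwk <- labels                       # newick fragment per active cluster
  leafsets <- as.list(labels)         # leaves per active cluster
  rep_lab <- labels                   # representative label per cluster
  D <- d
  splits <- character(0)
  canon <- function(set) {
    side <- if (ref_label %in% set) setdiff(all_set, set) else set
    paste(sort(side), collapse = "|")
  }
  while (length(active) > 3) {
    na <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (na - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    reps <- cbind(pmin(rep_lab[active[cand[, 1]]], rep_lab[active[cand[, 2]]]),
                  pmax(rep_lab[active[cand[, 1]]], rep_lab[active[cand[, 2]]]))
    pick <- order(reps[, 1], reps[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ai <- active[i]; aj <- active[j]
    dij <- Dm[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (na - 2))
    vj <- dij - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    # new cluster
    new_id <- length(nwk) + 1L
    nwk[new_id] <- sprintf("(%s:%s,%s:%s)", nwk[ai], format(vi, digits = 15),
                           nwk[aj], format(vj, digits = 15))
    leafsets[[new_id]] <- c(leafsets[[ai]], leafsets[[aj]])
    rep_lab[new_id] <- min(rep_lab[ai], rep_lab[aj])
    if (collect_splits && length(leafsets[[new_id]]) <= n - 2) {
      splits <- c(splits, canon(leafsets[[new_id]]))
    }
    others <- active[-c(i, j)]
    dnew <- (D[ai, others] + D[aj, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    D[new_id, others] <- dnew
    D[others, new_id] <- dnew
    active <- c(others, new_id)
  }
  # join the last three clusters to a central node
  x <- active[1]; y <- active[2]; z <- active[3]
  vx <- max((D[x, y] + D[x, z] - D[y, z]) / 2, 0)
  vy <- max((D[x, y] + D[y, z] - D[x, z]) / 2, 0)
  vz <- max((D[x, z] + D[y, z] - D[x, y]) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nwk[x], format(vx, digits = 15),
                    nwk[y], format(vy, digits = 15),
                    nwk[z], format(vz, digits = 15))
  list(newick = newick, splits = splits)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration with the usual branch-length formulas,
#' negative branch lengths clamped to zero, and a deterministic tie-break
#' (lexicographically smallest representative-label pair) so the result does
#' not depend on input order.
#'
#' @param dm Symmetric labelled distance matrix (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  res <- nj_core(dm)
  ape::read.tree(text = res$newick)
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates each internal edge of the original tree with
#' the percentage of replicates containing the same bipartition. Supports are
#' stored in `node.label` (empty for the root).
#'
#' @param alignment Alignment of the tree's taxa.
#' @param n_reps Number of bootstrap replicates (default 1000); 0 returns the
#'   plain tree without supports.
#' @param seed Integer seed.
#' @param model Distance model passed to [protein_distance()].
#' @return An [ape::phylo] tree with integer supports as node labels.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1L,
                              model = "p") {
  m <- aln_matrix(alignment)
  if (ncol(m) < 2) abort("bootstrap needs an alignment with >= 2 columns")
  d0 <- protein_distance(m, model = model)
  res0 <- nj_core(d0)
  tree <- ape::read.tree(text = res0$newick)
  if (n_reps == 0) return(tree)

  # precompute per-pair per-column mismatch/comparable indicators so each
  # replicate's distance matrix is two matrix-vector products
  n <- nrow(m); L <- ncol(m)
  ok <- m != GAP_CHAR & m != "X"
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  comp <- ok[pairs[, 1], , drop = FALSE] & ok[pairs[, 2], , drop = FALSE]
  mism <- (m[pairs[, 1], , drop = FALSE] != m[pairs[, 2], , drop = FALSE]) & comp
  storage.mode(comp) <- "double"
  storage.mode(mism) <- "double"

  counts <- integer(0)
  labels <- rownames(m)
  with_seed(seed, {
    tally <- new.env(parent = emptyenv())
    for (rep in seq_len(n_reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      nc <- comp %*% w
      if (any(nc == 0)) next  # replicate dropped: some pair not comparable
      p <- (mism %*% w) / nc
      d <- matrix(0, n, n, dimnames = list(labels, labels))
      d[pairs] <- p
      d <- d + t(d)
      sp <- nj_core(d)$splits
      for (s in sp) {
        tally[[s]] <- (tally[[s]] %||% 0L) + 1L
      }
    }
    counts <- setNames(
      vapply(ls(tally), function(s) tally[[s]], integer(1)),
      ls(tally))
  })

  # map internal nodes of the returned tree to canonical split keys
  ref_label <- min(labels)
  parts <- ape::prop.part(tree)
  tip_lab <- tree$tip.label
  node_keys <- vapply(seq_along(parts), function(i) {
    set <- tip_lab[parts[[i]]]
    side <- if (ref_label %in% set) setdiff(labels, set) else set
    paste(sort(side), collapse = "|")
  }, "")
  support <- round(100 * counts[node_keys] / n_reps)
  support[is.na(support)] <- 0
  lab <- as.character(support)
  lab[1] <- ""  # root of the stored (arbitrarily rooted) tree: not a split
  trivial <- lengths(parts) >= length(labels) - 1 | lengths(parts) < 2
  lab[trivial] <- ""
  tree$node.label <- lab
  tree
}

#' Cut a tree into subfamilies
#'
#' Removes the k-1 internal edges of greatest length (ties broken by higher
#' support, then by label order), falling back to pendant edges when the tree
#' has fewer internal edges than cuts; the leaf sets of the resulting
#' components are the subfamilies, labelled with Roman numerals I..k by
#' decreasing size.
#'
#' @param tree An [ape::phylo] tree.
#' @param k Number of subfamilies (default 5).
#' @return A tibble `gene_id`, `subfamily`.
#' @export
cut_subfamilies <- function(tree, k = 5) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (k < 1) abort("k must be >= 1")
  if (k > ntip) abort("k cannot exceed the number of leaves")
  edges <- tree$edge
  lens <- tree$edge.length %||% rep(1, nrow(edges))
  supp <- rep(NA_real_, nrow(edges))
  if (!is.null(tree$node.label)) {
    child_internal <- edges[, 2] > ntip
    supp[child_internal] <-
      suppressWarnings(as.numeric(tree$node.label[edges[child_internal, 2] - ntip]))
  }
  is_internal <- edges[, 1] > ntip & edges[, 2] > ntip
  # smallest tip label below each edge, for the final deterministic tie-break
  below <- .tips_below(tree)
  min_lab <- vapply(edges[, 2], function(nd) min(below[[nd]]), "")
  ord <- order(!is_internal, -lens, -ifelse(is.na(supp), -1, supp), min_lab)

  nodes <- seq_len(max(edges))
  removed <- logical(nrow(edges))
  comp_of <- function() {
    adj <- vector("list", length(nodes))
    for (e in which(!removed)) {
      adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
      adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
    }
    comp <- rep(NA_integer_, length(nodes))
    cid <- 0L
    for (s in nodes) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
    comp
  }
  n_parts <- 1L
  for (e in ord) {
    if (n_parts >= k) break
    removed[e] <- TRUE
    comp <- comp_of()
    tip_comp <- comp[seq_len(ntip)]
    if (any(!seq_len(max(comp)) %in% tip_comp)) {
      removed[e] <- FALSE  # would strand a leafless component
      next
    }
    n_parts <- length(unique(tip_comp))
  }
  comp <- comp_of()[seq_len(ntip)]
  sizes <- sort(table(comp), decreasing = TRUE)
  label_of <- setNames(roman_labels(length(sizes)), names(sizes))
  tibble(gene_id = tree$tip.label,
         subfamily = unname(label_of[as.character(comp)]))
}

#' @noRd
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  # edges in post order: process children before parents
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Close paralog pairs (cherries)
#'
#' Leaf pairs on a common terminal node: internal nodes whose two children
#' are both leaves. Leaves hanging directly off a multifurcating root are not
#' sisters and are never paired.
#'
#' @param tree An [ape::phylo] tree.
#' @return A tibble `gene_a`, `gene_b` (sorted within pair).
#' @export
close_paralog_pairs <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  out <- list()
  for (nd in unique(edges[, 1])) {
    children <- edges[edges[, 1] == nd, 2]
    tips <- children[children <= ntip]
    if (length(children) == 2 && length(tips) == 2) {
      pair <- sort(tree$tip.label[tips])
      out[[length(out) + 1L]] <- tibble(gene_a = pair[1], gene_b = pair[2])
    }
  }
  if (length(out) == 0) return(tibble(gene_a = character(), gene_b = character()))
  arrange(bind_rows(out), .data$gene_a)
}

#' Cross-species ortholog pairs
#'
#' Cherries whose two leaves belong to different species.
#'
#' @param tree An [ape::phylo] tree.
#' @param species_of_leaf Named character vector mapping leaf label to species.
#' @return A tibble `gene_a`, `gene_b`, `species_a`, `species_b`.
#' @export
ortholog_pairs <- function(tree, species_of_leaf) {
  cherries <- close_paralog_pairs(tree)
  missing <- setdiff(c(cherries$gene_a, cherries$gene_b), names(species_of_leaf))
  if (length(missing) > 0) {
    abort(paste("no species for leaf/leaves:", paste(head(missing, 5), collapse = ", ")))
  }
  cherries |>
    mutate(species_a = unname(species_of_leaf[.data$gene_a]),
           species_b = unname(species_of_leaf[.data$gene_b])) |>
    filter(.data$species_a != .data$species_b)
}
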