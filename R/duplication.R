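# Duplication detection: tandem clusters from gene order, segmental pairs
# from collinearity blocks.

#' Find tandem duplication clusters
#'
#' Maximal runs of family genes on one chromosome in which each pair of
#' consecutive family members is separated by at most `max_intervening`
#' intervening gene models (of any type). Chaining is transitive, so clusters
#' can grow beyond two members.
#'
#' @param gene_set Gene tibble (sorted or not; it is validated and sorted).
#' @param max_intervening Maximum intervening genes between consecutive
#'   members (default 5).
#' @return A tibble, one row per cluster: `cluster`, `chromosome`, `n_genes`,
#'   `genes` (list column of ordered ids), `same_orientation`.
#' @export
find_tandem_clusters <- function(gene_set, max_intervening = 5) {
  genes <- validate_gene_set(gene_set)
  out <- list()
  for (chrom in unique(genes$chromosome)) {
    chr <- filter(genes, .data$chromosome == chrom)
    fam_idx <- which(chr$is_family)
    if (length(fam_idx) < 2) next
    gaps <- diff(fam_idx) - 1L
    run_id <- cumsum(c(0L, gaps > max_intervening))
    for (r in split(fam_idx, run_id)) {
      if (length(r) < 2) next
      out[[length(out) + 1L]] <- tibble(
        chromosome = chrom,
        n_genes = length(r),
        genes = list(chr$gene_id[r]),
        same_orientation = length(unique(chr$strand[r])) == 1
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(cluster = character(), chromosome = character(),
                  n_genes = integer(), genes = list(),
                  same_orientation = logical()))
  }
  res$cluster <- sprintf("cluster%02d", seq_len(nrow(res)))
  select(res, "cluster", "chromosome", "n_genes", "genes", "same_orientation")
}

#' Find segmental duplication pairs
#'
#' A family gene pair is called segmental when, for some collinearity block,
#' its members lie on the block's two chromosomes inside the anchor span and
#' each within `max_pair_distance` of the block's nearest anchor gene on its
#' side. A gene may participate in several pairs (one per block).
#'
#' @param gene_set Gene tibble.
#' @param blocks Anchor-pair tibble (`block_id`, `gene_a`, `gene_b`), anchors
#'   referring to genes present in `gene_set`.
#' @param max_pair_distance Maximum distance (bp) between a member and its
#'   nearest anchor (default 500000, i.e. 500 kb).
#' @return A tibble: `gene_a`, `gene_b`, `block_id`.
#' @export
find_segmental_pairs <- function(gene_set, blocks, max_pair_distance = 500000) {
  genes <- validate_gene_set(gene_set)
  unknown <- setdiff(unique(c(blocks$gene_a, blocks$gene_b)), genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste("block file references unknown gene(s):",
                paste(head(unknown, 5), collapse = ", ")))
  }
  pos <- (genes$start + genes$end) / 2
  names(pos) <- genes$gene_id
  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  fam <- filter(genes, .data$is_family)

  side_candidates <- function(anchor_ids) {
    chrom <- unique(chrom_of[anchor_ids])
    if (length(chrom) != 1) return(character(0))
    apos <- pos[anchor_ids]
    span <- range(apos)
    cand <- fam$gene_id[fam$chromosome == chrom]
    cand <- cand[pos[cand] >= span[1] & pos[cand] <= span[2]]
    cand[vapply(cand, function(g) min(abs(pos[g] - apos)) <= max_pair_distance,
                logical(1))]
  }

  out <- purrr::map_dfr(split(blocks, blocks$block_id), function(blk) {
    a_side <- side_candidates(blk$gene_a)
    b_side <- side_candidates(blk$gene_b)
    if (length(a_side) == 0 || length(b_side) == 0) return(NULL)
    tidyr::expand_grid(gene_a = a_side, gene_b = b_side) |>
      mutate(block_id = blk$block_id[1])
  })
  if (nrow(out) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  block_id = character()))
  }
  arrange(out, .data$block_id, .data$gene_a, .data$gene_b)
}

#' Summarize duplication involvement
#'
#' @param clusters Tandem cluster tibble from [find_tandem_clusters()].
#' @param pairs Segmental pair tibble from [find_segmental_pairs()].
#' @param family_size Total number of family genes.
#' @return A one-row tibble: `n_tandem_genes`, `n_segmental_genes`,
#'   `n_either` (set union, no double counting), `fraction_duplicated`.
#' @export
duplication_summary <- function(clusters, pairs, family_size) {
  tandem_genes <- unique(unlist(clusters$genes))
  seg_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  either <- union(tandem_genes, seg_genes)
  tibble(
    n_tandem_genes = length(tandem_genes),
    n_segmental_genes = length(seg_genes),
    n_either = length(either),
    fraction_duplicated = if (family_size > 0) length(either) / family_size else 0
  )
}
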