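# Synthetic study design: a genome carrying a gene family with planted tandem
# clusters and segmental pairs, mirroring the structure a family survey
# expects to find. Everything is deterministic under the config seed.

#' Default whole-life tissue panel
#'
#' 24 developmental samples (13 vegetative, 11 reproductive) spanning
#' germinating seed to late endosperm, labelled as in rice whole-life
#' expression atlases.
#' @export
whole_life_tissues <- function() {
  c("S", "Se1", "Se2", "Sh", "R", "L1", "L2", "She1", "She2", "Ste1", "Ste2",
    "FL1", "FL2", "P1", "P2", "P3", "P4", "P5", "H", "Sta", "Spi",
    "E1", "E2", "E3")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study design. The defaults are the
#' conditions of the survey this package generalizes: a family of 84 genes on
#' 12 chromosomes, 44 of them in 14 tandem clusters (one of nine genes, two of
#' four, five of three, six of two), 11 segmental pairs covering 21 genes
#' (one gene participating twice, nine pair members also tandem-duplicated),
#' three planted conserved motifs, a 24-sample whole-life expression panel
#' with 3 replicates and 15% replicate CV.
#'
#' @param seed Integer seed; fully determines every generated object.
#' @param n_chromosomes,genes_per_chromosome Genome dimensions.
#' @param n_family Family size (tandem cluster members included).
#' @param tandem_cluster_sizes Integer vector of planted cluster sizes (all >= 2).
#' @param n_segmental_pairs Number of planted segmental pairs.
#' @param n_segmental_tandem_overlap How many segmental pair members are drawn
#'   from tandem clusters.
#' @param ancestor_codon_length Length of the ancestral CDS, in codons.
#' @param target_omega,target_ks Per-pair Ka/Ks (omega) and synonymous
#'   divergence targets for simulated codon pairs; recycled over pairs.
#' @param motifs_to_plant Degenerate motif patterns planted in every family
#'   protein (x = wildcard, `K(R)` = two-residue alternative).
#' @param tissues Sample labels of the expression panel.
#' @param n_replicates Replicates per sample (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale distribution of
#'   per-gene baseline signals.
#' @param replicate_cv Coefficient of variation of multiplicative replicate noise.
#' @param preferential_fold Fold by which planted preferential genes exceed
#'   every other tissue.
#' @param fate_gain_fold Fold gain planted for neofunctionalized copies.
#' @param background_log2 Log2 signal of silenced ("background") expression.
#' @return A list of class `fam_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 12L,
                              genes_per_chromosome = 60L,
                              n_family = 84L,
                              tandem_cluster_sizes = c(9, 4, 4, 3, 3, 3, 3, 3,
                                                       2, 2, 2, 2, 2, 2),
                              n_segmental_pairs = 11L,
                              n_segmental_tandem_overlap = 9L,
                              ancestor_codon_length = 300L,
                              target_omega = 0.15,
                              target_ks = 0.8,
                              motifs_to_plant = c(
                                motif1 = "NLVxYL",
                                motif2 = "LYLxxxGxGGxK(R)xxxxxFGADQFD",
                                motif3 = "FFNWY"),
                              tissues = whole_life_tissues(),
                              n_replicates = 3L,
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 1.5,
                              replicate_cv = 0.15,
                              preferential_fold = 10,
                              fate_gain_fold = 8,
                              background_log2 = 3) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_family = as.integer(n_family),
    tandem_cluster_sizes = as.integer(tandem_cluster_sizes),
    n_segmental_pairs = as.integer(n_segmental_pairs),
    n_segmental_tandem_overlap = as.integer(n_segmental_tandem_overlap),
    ancestor_codon_length = as.integer(ancestor_codon_length),
    target_omega = target_omega,
    target_ks = target_ks,
    motifs_to_plant = motifs_to_plant,
    tissues = tissues,
    n_replicates = as.integer(n_replicates),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    replicate_cv = replicate_cv,
    preferential_fold = preferential_fold,
    fate_gain_fold = fate_gain_fold,
    background_log2 = background_log2
  )
  if (any(cfg$tandem_cluster_sizes < 2)) abort("tandem cluster sizes must be >= 2")
  if (sum(cfg$tandem_cluster_sizes) > cfg$n_family) {
    abort("tandem cluster sizes exceed the family size")
  }
  if (cfg$target_omega < 0) abort("target omega must be >= 0")
  if (cfg$n_replicates < 2) abort("need >= 2 replicates per sample")
  structure(cfg, class = "fam_config")
}

#' Simulate a genome with planted duplications
#'
#' Places family genes on chromosomes so each requested tandem cluster has at
#' most 5 non-family genes between consecutive members and clusters are
#' separated by more than 5 intervening genes; segmental pairs are placed on
#' distinct chromosomes with an accompanying anchor-pair block table.
#'
#' @param config A [simulation_config()].
#' @return A list of class `fam_genome` with elements `genes` (sorted gene
#'   tibble), `blocks` (anchor-pair tibble), and ground truth tibbles
#'   `tandem_truth` (cluster_id, gene_id) and `segmental_truth`
#'   (pair_id, gene_a, gene_b, block_id).
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "fam_config"))
  with_seed(config$seed, .simulate_genome_impl(config))
}

#' @noRd
.simulate_genome_impl <- function(config) {
  n_chr <- config$n_chromosomes
  g_per <- config$genes_per_chromosome
  chroms <- sprintf("chr%02d", seq_len(n_chr))
  sizes <- sort(config$tandem_cluster_sizes, decreasing = TRUE)
  n_single <- config$n_family - sum(sizes)

  # Units to place: clusters first (largest first), then singleton family
  # genes. Each chromosome keeps a cursor of the next free gene rank; units
  # are padded by >5 intervening genes so distinct placements never merge.
  pad <- 8L
  cursor <- setNames(rep(2L, n_chr), chroms)
  units <- c(lapply(seq_along(sizes), function(i) list(type = "cluster", id = i, size = sizes[i])),
             lapply(seq_len(n_single), function(i) list(type = "single", id = i, size = 1L)))
  placements <- list()  # per family gene: chrom, rank, cluster_id
  for (u in units) {
    if (u$type == "cluster") {
      gaps <- sample(0:3, u$size - 1L, replace = TRUE)
      need <- u$size + sum(gaps)
    } else {
      gaps <- integer(0)
      need <- 1L
    }
    room <- g_per - cursor - need
    ok <- room >= 0
    if (!any(ok)) abort("infeasible placement: family does not fit on the genome")
    jitter <- runif(n_chr)
    chrom <- names(which.max(ifelse(ok, room + jitter, -Inf)))  # spread load
    start_rank <- cursor[[chrom]]
    ranks <- start_rank + cumsum(c(0L, gaps + 1L))
    cluster_id <- if (u$type == "cluster") sprintf("TC%02d", u$id) else NA_character_
    placements[[length(placements) + 1L]] <-
      tibble(chromosome = chrom, rank = ranks, cluster_id = cluster_id)
    cursor[[chrom]] <- max(ranks) + pad
  }
  fam <- bind_rows(placements)
  if (nrow(fam) == 0) {
    fam <- tibble(chromosome = character(), rank = integer(),
                  cluster_id = character())
  }

  # Materialize every gene model on every chromosome.
  genes <- purrr::map_dfr(chroms, function(chrom) {
    len <- sample(seq(1500L, 4500L, by = 3L), g_per, replace = TRUE)
    gap <- sample(5000:20000, g_per, replace = TRUE)
    start <- 10000L + cumsum(c(0L, (len + gap)[-g_per]))
    tibble(
      gene_id = sprintf("%sg%03d", chrom, seq_len(g_per)),
      chromosome = chrom, rank = seq_len(g_per),
      start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), g_per, replace = TRUE)
    )
  })
  fam$gene_id <- sprintf("%sg%03d", fam$chromosome, fam$rank)
  genes$is_family <- genes$gene_id %in% fam$gene_id
  genes <- left_join(genes, select(fam, "gene_id", "cluster_id"), by = "gene_id")

  # Tandem members share one strand, except the last 2-gene cluster which
  # carries one inverted member (families do show rare inverted tandems).
  flip_cluster <- sprintf("TC%02d", length(sizes))
  genes <- genes |>
    group_by(.data$cluster_id) |>
    mutate(strand = ifelse(!is.na(.data$cluster_id), .data$strand[1], .data$strand)) |>
    ungroup()
  flip_rows <- which(!is.na(genes$cluster_id) & genes$cluster_id == flip_cluster)
  if (length(flip_rows) >= 2) {
    genes$strand[flip_rows[2]] <- setdiff(c("+", "-"), genes$strand[flip_rows[1]])
  }

  ann_pool <- c("hypothetical protein", "expressed protein",
                "kinase domain containing protein", "zinc finger protein",
                "MYB family transcription factor")
  genes$annotation <- sample(ann_pool, nrow(genes), replace = TRUE)
  genes$annotation[genes$is_family] <- sample(
    c("peptide transporter PTR family protein",
      "proton-dependent oligopeptide transport family protein"),
    sum(genes$is_family), replace = TRUE)
  # a few retrotransposon annotations among non-family genes, for screening
  retro <- sample(which(!genes$is_family), 4L)
  genes$annotation[retro] <- "retrotransposon protein, putative"

  seg <- .plan_segmental_pairs(genes, config)
  truth_tandem <- genes |>
    filter(!is.na(.data$cluster_id)) |>
    select(cluster_id = "cluster_id", gene_id = "gene_id")
  out <- list(
    genes = validate_gene_set(select(genes, -"rank", -"cluster_id")),
    blocks = seg$blocks,
    tandem_truth = truth_tandem,
    segmental_truth = seg$pairs
  )
  structure(out, class = "fam_genome")
}

# Choose segmental pair members (some overlapping tandem clusters, one gene in
# two pairs) and write tight anchor blocks around each member.
#' @noRd
.plan_segmental_pairs <- function(genes, config) {
  n_pairs <- config$n_segmental_pairs
  if (n_pairs == 0) {
    return(list(pairs = tibble(pair_id = character(), gene_a = character(),
                               gene_b = character(), block_id = character()),
                blocks = tibble(block_id = character(), gene_a = character(),
                                gene_b = character())))
  }
  fam <- filter(genes, .data$is_family)
  singles <- filter(fam, is.na(.data$cluster_id))
  tandems <- fam |>
    filter(!is.na(.data$cluster_id)) |>
    group_by(.data$cluster_id) |>
    dplyr::slice(1) |>  # one representative per cluster keeps blocks apart
    ungroup()
  n_overlap <- min(config$n_segmental_tandem_overlap, nrow(tandems), n_pairs)
  n_plain <- n_pairs - n_overlap
  # plain pairs: 2 share a hub gene when possible (a gene can sit in two blocks)
  need_singles <- n_overlap + max(0L, 2L * n_plain - 1L)
  if (nrow(singles) < need_singles) abort("infeasible placement: not enough singleton family genes for segmental pairs")
  pool <- singles[sample.int(nrow(singles)), ]
  a_side <- character(n_pairs); b_side <- character(n_pairs)
  si <- 1L
  for (i in seq_len(n_overlap)) {
    a_side[i] <- tandems$gene_id[i]
    b_side[i] <- pool$gene_id[si]; si <- si + 1L
  }
  if (n_plain > 0) {
    hub <- pool$gene_id[si]; si <- si + 1L
    for (j in seq_len(n_plain)) {
      idx <- n_overlap + j
      a_side[idx] <- if (j <= 2) hub else pool$gene_id[si]
      if (j > 2) si <- si + 1L
      b_side[idx] <- pool$gene_id[si]; si <- si + 1L
    }
  }
  # pair members must sit on different chromosomes; swap in replacements where needed
  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  for (i in seq_len(n_pairs)) {
    while (chrom_of[[a_side[i]]] == chrom_of[[b_side[i]]] && si <= nrow(pool)) {
      b_side[i] <- pool$gene_id[si]; si <- si + 1L
    }
    if (chrom_of[[a_side[i]]] == chrom_of[[b_side[i]]]) {
      abort("infeasible placement: could not put segmental pair on distinct chromosomes")
    }
  }
  pairs <- tibble(pair_id = sprintf("SP%02d", seq_len(n_pairs)),
                  gene_a = a_side, gene_b = b_side,
                  block_id = sprintf("B%02d", seq_len(n_pairs)))
  # anchors: the immediate non-family neighbours of each member, paired across
  # the two chromosomes (upstream with upstream, downstream with downstream)
  blocks <- purrr::pmap_dfr(pairs, function(pair_id, gene_a, gene_b, block_id) {
    fa <- .flanking_nonfamily(genes, gene_a)
    fb <- .flanking_nonfamily(genes, gene_b)
    tibble(block_id = block_id,
           gene_a = c(fa$up, fa$down),
           gene_b = c(fb$up, fb$down))
  })
  list(pairs = pairs, blocks = blocks)
}

#' @noRd
.flanking_nonfamily <- function(genes, gene_id) {
  g <- genes[genes$gene_id == gene_id, ]
  chr <- genes[genes$chromosome == g$chromosome, ]
  chr <- arrange(chr, .data$start)
  i <- which(chr$gene_id == gene_id)
  up <- max(which(!chr$is_family[seq_len(i - 1L)]))
  down <- i + min(which(!chr$is_family[-seq_len(i)]))
  list(up = chr$gene_id[up], down = chr$gene_id[down])
}
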