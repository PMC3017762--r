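# Codon-level sequence simulation: a continuous-time-like proposal process
# with an omega acceptance step on nonsynonymous changes, used both for
# standalone Ka/Ks benchmark pairs and for whole-family sequence sets.

# Neighbour lookup tables derived from CODON_NEIGHBORS, flattened for speed.
NEIGH_TGT <- lapply(CODON_NEIGHBORS, function(nb) vapply(nb, `[[`, "", "target"))
NEIGH_CLS <- lapply(CODON_NEIGHBORS, function(nb) vapply(nb, `[[`, "", "class"))
# transitions: A<->G, C<->T
NEIGH_TS <- lapply(names(CODON_NEIGHBORS), function(cod) {
  nb <- CODON_NEIGHBORS[[cod]]
  vapply(nb, function(e) {
    from <- substr(cod, e$pos, e$pos)
    paste0(sort(c(from, e$nt)), collapse = "") %in% c("AG", "CT")
  }, logical(1))
}) |> setNames(names(CODON_NEIGHBORS))

# Evolve a codon vector until `n_syn_target` synonymous substitutions have
# been accepted. Nonsynonymous proposals are accepted with relative rate
# omega; proposals creating stop codons are always rejected.
#' @noRd
evolve_codons <- function(codons, n_syn_target, omega, kappa = 1) {
  n_syn <- 0L
  n_nonsyn <- 0L
  p_non <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1
  n <- length(codons)
  while (n_syn < n_syn_target) {
    i <- sample.int(n, 1L)
    cod <- codons[i]
    w <- ifelse(NEIGH_TS[[cod]], kappa, 1)
    k <- sample.int(9L, 1L, prob = w)
    cls <- NEIGH_CLS[[cod]][k]
    if (cls == "stop") next
    if (cls == "nonsyn") {
      if (p_non < 1 && runif(1) > p_non) next
      n_nonsyn <- n_nonsyn + 1L
    } else {
      if (p_syn < 1 && runif(1) > p_syn) next
      n_syn <- n_syn + 1L
    }
    codons[i] <- NEIGH_TGT[[cod]][k]
  }
  list(codons = codons, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' @noRd
random_ancestor_codons <- function(n_codons) {
  sample(SENSE_CODONS, n_codons, replace = TRUE)
}

#' Simulate a diverged codon-alignment pair
#'
#' Evolves two copies from a random ancestral CDS under a nucleotide proposal
#' kernel (optionally transition-biased via `kappa`) with nonsynonymous
#' acceptance probability `omega`. The total synonymous divergence is
#' calibrated so that the pair's expected Ks equals `target_ks`; stop codons
#' are never introduced.
#'
#' @param ancestor_length Ancestor length in codons.
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param target_ks Target synonymous substitutions per synonymous site (> 0).
#' @param seed Integer seed.
#' @param kappa Transition/transversion proposal bias (1 = unbiased).
#' @return A list of class `fam_codon_pair` with `cds_a`, `cds_b` (ungapped,
#'   equal-length, in-frame CDS strings) and a `truth` list recording the
#'   simulation parameters and realized substitution counts.
#' @export
simulate_codon_pair <- function(ancestor_length, omega, target_ks, seed,
                                kappa = 1) {
  stopifnot(omega >= 0, target_ks > 0, ancestor_length >= 1)
  with_seed(seed, {
    anc <- random_ancestor_codons(ancestor_length)
    s_total <- sum(CODON_SYN_SITES[anc])
    per_lineage <- round(target_ks * s_total / 2)
    a <- evolve_codons(anc, per_lineage, omega, kappa)
    b <- evolve_codons(anc, per_lineage, omega, kappa)
    structure(list(
      cds_a = paste(a$codons, collapse = ""),
      cds_b = paste(b$codons, collapse = ""),
      truth = list(omega = omega, target_ks = target_ks, kappa = kappa,
                   syn_sites_ancestor = s_total,
                   n_syn = a$n_syn + b$n_syn,
                   n_nonsyn = a$n_nonsyn + b$n_nonsyn)
    ), class = "fam_codon_pair")
  })
}

#' Plant degenerate motifs into proteins
#'
#' Writes a concrete instantiation of each degenerate pattern into every
#' family protein at the same (hence homologous) positions. Fixed pattern
#' positions get the fixed residue, alternative sets (`K(R)`) get one member
#' chosen at random per protein, and wildcards keep the residue already
#' present. Non-family proteins are left untouched.
#'
#' @param proteins Tibble with `id` and `seq` columns.
#' @param patterns Character vector of degenerate patterns (see
#'   [parse_motif_pattern()]).
#' @param positions 1-based start positions, one per pattern.
#' @param family_ids Ids of the proteins to modify (default: all).
#' @param seed Integer seed for the alternative-set choices.
#' @return The proteins tibble with motifs planted.
#' @export
plant_motifs <- function(proteins, patterns, positions,
                         family_ids = proteins$id, seed = 1L) {
  stopifnot(length(patterns) == length(positions))
  parsed <- lapply(patterns, parse_motif_pattern)
  with_seed(seed, {
    proteins$seq <- purrr::map2_chr(proteins$id, proteins$seq, function(id, seq) {
      if (!id %in% family_ids) return(seq)
      for (m in seq_along(parsed)) {
        pat <- parsed[[m]]
        pos <- positions[m]
        if (pos + length(pat$elements) - 1L > nchar(seq)) {
          abort(sprintf("motif '%s' does not fit in protein '%s'", patterns[m], id))
        }
        chars <- strsplit(seq, "")[[1]]
        for (j in seq_along(pat$elements)) {
          el <- pat$elements[[j]]
          if (length(el) == 1 && el == "x") next
          chars[pos + j - 1L] <- if (length(el) == 1) el else sample(el, 1L)
        }
        seq <- paste(chars, collapse = "")
      }
      seq
    })
    proteins
  })
}

# --- whole-family sequence set -------------------------------------------

# Per-branch divergence (in Ks units) of the simulated family tree. The pair
# branches split the configured pair Ks evenly so designated paralog pairs
# are the closest relatives (cherries) in the true tree.
.FAM_KS <- list(subfamily_stem = 0.9, unit = 0.35, singleton_tip = 0.15)

#' Simulate family coding sequences with planted structure
#'
#' Evolves one CDS per family gene down a known tree: five subfamilies
#' (sizes in the proportions 30:21:16:11:6), within them one subtree per
#' tandem cluster / segmental pair / singleton, with designated paralog pairs
#' diverged by the configured pair Ks at the configured omega. Conserved
#' motifs are planted at homologous positions (as synonymously re-encoded
#' codons, so CDS and protein stay consistent). Decoy non-family proteins,
#' including partial-domain fragments, are generated for screening tests.
#'
#' @param config A [simulation_config()].
#' @param genome A `fam_genome` from [simulate_genome()].
#' @return A list of class `fam_sequences`: `cds`, `proteins` (family,
#'   aligned by construction), `decoys` (non-family proteins), `alignment`,
#'   `seed_alignment` (domain window of the family alignment),
#'   `domain_window` (start/end in protein coordinates), `pair_truth`
#'   (designated paralog pairs with type and targets), and `subfamily_truth`.
#' @export
simulate_family_sequences <- function(config, genome) {
  stopifnot(inherits(config, "fam_config"), inherits(genome, "fam_genome"))
  with_seed(config$seed + 1L, .simulate_family_sequences_impl(config, genome))
}

#' @noRd
.simulate_family_sequences_impl <- function(config, genome) {
  genes <- genome$genes
  fam_ids <- genes$gene_id[genes$is_family]
  clusters <- split(genome$tandem_truth$gene_id, genome$tandem_truth$cluster_id)
  seg <- genome$segmental_truth
  in_cluster <- unlist(clusters, use.names = FALSE)
  seg_only <- setdiff(unique(c(seg$gene_a, seg$gene_b)), in_cluster)
  singles <- setdiff(fam_ids, c(in_cluster, seg_only))

  # units: each tandem cluster, each segmental-only pair, each singleton
  seg_units <- list()
  used <- character(0)
  for (i in seq_len(nrow(seg))) {
    a <- seg$gene_a[i]; b <- seg$gene_b[i]
    if (a %in% seg_only && b %in% seg_only && !a %in% used && !b %in% used) {
      seg_units[[length(seg_units) + 1L]] <- c(a, b)
      used <- c(used, a, b)
    }
  }
  seg_single <- setdiff(seg_only, used)
  units <- c(unname(lapply(clusters, identity)), seg_units,
             as.list(c(seg_single, singles)))
  unit_sizes <- lengths(units)

  # allocate units to 5 subfamilies with target proportions 30:21:16:11:6
  target <- config$n_family * c(30, 21, 16, 11, 6) / 84
  fill <- numeric(5)
  unit_subfam <- integer(length(units))
  for (i in order(unit_sizes, decreasing = TRUE)) {
    j <- which.max(target - fill)
    unit_subfam[i] <- j
    fill[j] <- fill[j] + unit_sizes[i]
  }

  L <- config$ancestor_codon_length
  root <- random_ancestor_codons(L)
  omega <- config$target_omega
  pair_half <- config$target_ks / 2
  ks_n <- function(codons, ks) round(ks * sum(CODON_SYN_SITES[codons]))

  gene_codons <- list()
  pair_truth <- list()
  subfam_of <- character(0)
  for (sf in 1:5) {
    sf_anc <- evolve_codons(root, ks_n(root, .FAM_KS$subfamily_stem), omega)$codons
    for (ui in which(unit_subfam == sf)) {
      u <- units[[ui]]
      u_anc <- evolve_codons(sf_anc, ks_n(sf_anc, .FAM_KS$unit), omega)$codons
      if (length(u) == 1) {
        gene_codons[[u]] <- evolve_codons(u_anc, ks_n(u_anc, .FAM_KS$singleton_tip),
                                          omega)$codons
      } else {
        # members in designated pairs, each pair from a shared parent
        ids <- u
        p <- 1L
        while (length(ids) >= 2) {
          pa <- evolve_codons(u_anc, ks_n(u_anc, .FAM_KS$singleton_tip), omega)$codons
          gene_codons[[ids[1]]] <- evolve_codons(pa, ks_n(pa, pair_half), omega)$codons
          gene_codons[[ids[2]]] <- evolve_codons(pa, ks_n(pa, pair_half), omega)$codons
          type <- if (!is.null(names(clusters)) && ids[1] %in% in_cluster) "tandem" else "segmental"
          pair_truth[[length(pair_truth) + 1L]] <-
            tibble(gene_a = ids[1], gene_b = ids[2], type = type,
                   target_omega = omega, target_ks = config$target_ks)
          ids <- ids[-(1:2)]
          p <- p + 1L
        }
        if (length(ids) == 1) {
          gene_codons[[ids]] <- evolve_codons(u_anc, ks_n(u_anc, .FAM_KS$singleton_tip),
                                              omega)$codons
        }
      }
      subfam_of <- c(subfam_of, setNames(rep(roman_labels(5)[sf], length(u)), u))
    }
  }
  # plant motifs at fixed positions inside the domain window, at codon level
  domain <- list(start = 21L, end = min(180L, L))
  motif_pos <- .motif_positions(config$motifs_to_plant, domain)
  for (gid in names(gene_codons)) {
    gene_codons[[gid]] <- .plant_motif_codons(gene_codons[[gid]],
                                              config$motifs_to_plant, motif_pos)
  }

  cds <- tibble(id = names(gene_codons),
                seq = vapply(gene_codons, paste, "", collapse = ""),
                moltype = "cds")
  proteins <- tibble(id = cds$id,
                     seq = vapply(gene_codons,
                                  function(x) paste(CODON_AA[x], collapse = ""), ""),
                     moltype = "protein")
  # order rows by genome position for reproducibility
  ord <- match(fam_ids, proteins$id)
  proteins <- proteins[ord, ]
  cds <- cds[ord, ]

  seed_alignment <- mutate(proteins,
    seq = substr(.data$seq, domain$start, domain$end))

  decoys <- .make_decoys(genes, proteins, domain, config)

  structure(list(
    cds = cds, proteins = proteins, decoys = decoys,
    alignment = select(proteins, "id", "seq"),
    seed_alignment = select(seed_alignment, "id", "seq"),
    domain_window = domain,
    pair_truth = bind_rows(pair_truth),
    subfamily_truth = tibble(gene_id = names(subfam_of),
                             subfamily = unname(subfam_of))
  ), class = "fam_sequences")
}

#' @noRd
.motif_positions <- function(patterns, domain) {
  lens <- vapply(patterns, function(p) length(parse_motif_pattern(p)$elements), 1L)
  pos <- integer(length(patterns))
  cur <- domain$start + 4L
  for (i in seq_along(patterns)) {
    pos[i] <- cur
    cur <- cur + lens[i] + 10L
  }
  if (cur > domain$end) abort("motifs do not fit inside the domain window")
  pos
}

# Overwrite the codons under a motif with codons encoding the pattern.
#' @noRd
.plant_motif_codons <- function(codons, patterns, positions) {
  for (m in seq_along(patterns)) {
    pat <- parse_motif_pattern(patterns[m])
    for (j in seq_along(pat$elements)) {
      el <- pat$elements[[j]]
      if (length(el) == 1 && el == "x") next
      aa <- if (length(el) == 1) el else sample(el, 1L)
      choices <- SENSE_CODONS[CODON_AA[SENSE_CODONS] == aa]
      codons[positions[m] + j - 1L] <- sample(choices, 1L)
    }
  }
  codons
}

# Non-family decoy proteins for screening: random proteins for most
# non-family genes is overkill; we generate a modest panel plus 7
# partial-domain fragments and keep the retrotransposon-annotated genes.
#' @noRd
.make_decoys <- function(genes, proteins, domain, config) {
  nonfam <- genes$gene_id[!genes$is_family]
  retro <- genes$gene_id[grepl("retrotransposon", genes$annotation)]
  n_random <- min(30L, length(setdiff(nonfam, retro)))
  picked <- setdiff(nonfam, retro)[seq_len(n_random)]
  rand_prot <- vapply(seq_len(n_random), function(i) {
    paste(sample(AA_ALPHABET, config$ancestor_codon_length, replace = TRUE),
          collapse = "")
  }, "")
  # partial-domain fragments: 40-60% of one family member's domain
  n_partial <- min(7L, nrow(proteins))
  frag_src <- proteins$seq[seq_len(n_partial)]
  frags <- vapply(seq_along(frag_src), function(i) {
    dom <- substr(frag_src[i], domain$start, domain$end)
    keep <- floor(nchar(dom) * runif(1, 0.4, 0.6))
    substr(dom, 1, keep)
  }, "")
  frag_ids <- paste0("partial", seq_len(n_partial))
  # retro decoys carry a full domain so only the annotation rule excludes them
  retro_prot <- vapply(seq_along(retro),
                       function(i) proteins$seq[(i %% nrow(proteins)) + 1L], "")
  tibble(
    id = c(picked, frag_ids, retro),
    seq = c(rand_prot, frags, retro_prot),
    moltype = "protein",
    kind = c(rep("random", n_random), rep("partial", n_partial),
             rep("retro", length(retro)))
  )
}
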