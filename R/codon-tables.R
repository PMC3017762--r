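# Genetic-code machinery shared by the NG86 estimator and the codon simulator.
# Tables are built once at load time from the standard code.

CODONS <- as.vector(outer(outer(NT_ALPHABET, NT_ALPHABET, paste0),
                          NT_ALPHABET, paste0))
CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[CODONS]), CODONS)
})
STOP_CODONS <- names(CODON_AA)[CODON_AA == "*"]
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

#' @noRd
codon_index <- setNames(seq_along(CODONS), CODONS)

# For each codon, the 9 single-nucleotide neighbours: target codon and class.
# A change producing a stop codon is classed "stop"; NG86 site counting treats
# it as nonsynonymous so that S + N = 3 per codon.
CODON_NEIGHBORS <- local({
  lapply(CODONS, function(cod) {
    nts <- strsplit(cod, "")[[1]]
    out <- vector("list", 9L)
    k <- 0L
    for (pos in 1:3) {
      for (nt in setdiff(NT_ALPHABET, nts[pos])) {
        k <- k + 1L
        alt <- nts
        alt[pos] <- nt
        tgt <- paste(alt, collapse = "")
        cls <- if (CODON_AA[[tgt]] == "*") "stop"
               else if (CODON_AA[[tgt]] == CODON_AA[[cod]]) "syn" else "nonsyn"
        out[[k]] <- list(pos = pos, nt = nt, target = tgt, class = cls)
      }
    }
    out
  }) |> setNames(CODONS)
})

# NG86 synonymous site count per codon (stops treated as nonsynonymous
# targets); nonsynonymous sites are 3 - S by construction.
CODON_SYN_SITES <- vapply(CODONS, function(cod) {
  if (CODON_AA[[cod]] == "*") return(NA_real_)
  cls <- vapply(CODON_NEIGHBORS[[cod]], `[[`, "", "class")
  sum(cls == "syn") / 3
}, numeric(1))

# Average (syn, nonsyn) step counts over all minimal mutational pathways
# between two codons, excluding pathways that pass through a stop codon.
# If every pathway is blocked, all pathways are used (standard fallback).
#' @noRd
.pathway_cache <- new.env(parent = emptyenv())

#' @noRd
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .pathway_cache[[key]]
  if (!is.null(hit)) return(hit)
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  perms <- .permutations(diff_pos)
  tally <- function(skip_stops) {
    acc <- c(syn = 0, nonsyn = 0)
    used <- 0L
    for (ord in perms) {
      cur <- p1
      steps <- c(syn = 0, nonsyn = 0)
      ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- p2[pos]
        from <- paste(cur, collapse = "")
        to <- paste(nxt, collapse = "")
        if (skip_stops && CODON_AA[[to]] == "*" && to != c2) {
          ok <- FALSE
          break
        }
        cls <- if (CODON_AA[[to]] == CODON_AA[[from]]) "syn" else "nonsyn"
        steps[[cls]] <- steps[[cls]] + 1
        cur <- nxt
      }
      if (ok) {
        acc <- acc + steps
        used <- used + 1L
      }
    }
    list(acc = acc, used = used)
  }
  res <- tally(skip_stops = TRUE)
  if (res$used == 0L) res <- tally(skip_stops = FALSE)
  out <- res$acc / res$used
  assign(key, out, envir = .pathway_cache)
  out
}

#' @noRd
.permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) abort(sprintf("CDS length %d is not divisible by 3", n))
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' @noRd
translate_cds <- function(cds) {
  codons <- split_codons(gsub("-", "", cds, fixed = TRUE))
  paste(CODON_AA[codons], collapse = "")
}
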