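# Independent brute-force oracles, written in plain base R loops so they
# share no code path with the implementation they check.

# upper hypergeometric tail by explicit combinatorial enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  i <- seq(from = k, to = min(n, K))
  i <- i[i >= max(0, n - (N - K))]
  if (length(i) == 0) {
    return(0)
  }
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# textbook Benjamini-Hochberg step-up, computed from the definition
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  list(p_adj = out, significant = out <= alpha)
}

# linear-scan interval overlap (half-open)
scan_fragments <- function(chrom, start, end, fragments) {
  hits <- character(0)
  for (j in seq_len(nrow(fragments))) {
    if (fragments$chrom[j] == chrom &&
      fragments$start[j] < end && start < fragments$end[j]) {
      hits <- c(hits, fragments$fragment_id[j])
    }
  }
  hits
}

# full re-derivation of the candidate-gene filter with nested loops over raw
# records; returns a named list (disease|index_snp -> sorted gene keys)
brute_force_candidates <- function(data,
                                   r2_threshold = 0.8,
                                   score_threshold = 5,
                                   expression_threshold = 1,
                                   enhancer_states = chromhmm_states()$enhancer,
                                   promoter_states = chromhmm_states()$promoter) {
  frags <- as.data.frame(data$fragments)
  segs <- as.data.frame(data$segments)
  genes <- as.data.frame(data$genes)
  expr <- as.data.frame(data$expression)
  ints <- as.data.frame(data$interactions)
  snps <- as.data.frame(data$snps)

  frag_row <- function(id) frags[frags$fragment_id == id, ]
  has_state <- function(frag_id, ct, states) {
    f <- frag_row(frag_id)
    for (j in seq_len(nrow(segs))) {
      if (segs$cell_type[j] == ct && segs$chrom[j] == f$chrom &&
        segs$start[j] < f$end && f$start < segs$end[j] &&
        segs$state[j] %in% states) {
        return(TRUE)
      }
    }
    FALSE
  }
  genes_in_frag <- function(frag_id) {
    f <- frag_row(frag_id)
    out <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == f$chrom && genes$tss[j] >= f$start &&
        genes$tss[j] < f$end) {
        out <- c(out, genes$gene_id[j])
      }
    }
    out
  }
  is_expressed <- function(gene_id) {
    any(toupper(expr$gene_id) == toupper(gene_id) &
      expr$value >= expression_threshold)
  }

  out <- list()
  keys <- unique(paste(snps$disease, snps$index_snp_id, sep = "|"))
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    members <- snps[snps$disease == parts[1] &
      snps$index_snp_id == parts[2] & snps$r2 >= r2_threshold, ]
    block_frags <- character(0)
    for (j in seq_len(nrow(members))) {
      block_frags <- c(block_frags, scan_fragments(members$chrom[j],
        members$pos[j] - 1, members$pos[j], frags))
    }
    block_frags <- unique(block_frags)
    found <- character(0)
    for (j in seq_len(nrow(ints))) {
      if (ints$score[j] < score_threshold) next
      ends <- list(
        c(ints$bait_id[j], ints$oe_id[j]),
        c(ints$oe_id[j], ints$bait_id[j])
      )
      for (e in ends) {
        if (!(e[1] %in% block_frags)) next
        ct <- ints$cell_type[j]
        if (!has_state(e[1], ct, enhancer_states)) next
        if (!has_state(e[2], ct, promoter_states)) next
        for (g in genes_in_frag(e[2])) {
          if (is_expressed(g)) found <- c(found, toupper(g))
        }
      }
    }
    out[[key]] <- sort(unique(found))
  }
  out
}

candidate_sets <- function(candidates) {
  split(candidates$gene_key,
    paste(candidates$disease, candidates$index_snp_id, sep = "|"))
}
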