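# Core locus-to-gene filter: LD blocks around GWAS index SNPs, restriction
# fragments carrying associated SNPs, chromatin-state calls per fragment and
# cell type, and the enhancer-promoter interaction filter that yields
# candidate causal genes.

as_granges <- function(chrom, start, end, levels = unique(chrom)) {
  # internal bridge from 0-based half-open to GRanges 1-based closed;
  # explicit shared seqlevels keep cross-object overlap calls quiet
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = levels),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
}

#' Group GWAS SNPs into LD blocks and attach restriction fragments
#'
#' One block is built per (index SNP, disease); the block keeps the index SNP
#' itself plus every proxy with r-squared at or above the threshold, records
#' the genomic span of its members and the set of restriction fragments that
#' any member SNP falls in.
#'
#' @param snps SNP tibble ([read_table()] with schema `"snps"`); positions are
#'   1-based.
#' @param fragments Validated fragment map.
#' @param r2_threshold Minimum r-squared for a proxy to join its index SNP's
#'   block (default 0.8).
#' @return Tibble with one row per block: `index_snp_id`, `disease`, `chrom`,
#'   `span_start`/`span_end` (0-based half-open), list-columns `members`
#'   (SNP tibbles) and `fragment_ids`.
#' @export
build_ld_blocks <- function(snps, fragments, r2_threshold = 0.8) {
  validate_snps(snps)
  members <- snps[snps$r2 >= r2_threshold, ]
  blocks <- members %>%
    dplyr::group_by(.data$index_snp_id, .data$disease) %>%
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      span_start = min(.data$pos) - 1,
      span_end = max(.data$pos),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
  blocks$fragment_ids <- lapply(blocks$members, function(m) {
    hits <- assign_fragments(m$chrom, m$pos - 1, m$pos, fragments)
    sort(unique(unlist(hits)))
  })
  dplyr::arrange(blocks, .data$disease, .data$index_snp_id)
}

#' Find the restriction fragments overlapping query intervals
#'
#' Overlap is computed on half-open intervals: a query `[start, end)` overlaps
#' a fragment `[fs, fe)` iff `start < fe && fs < end`. A point query for a
#' 1-based SNP position `p` is the interval `[p - 1, p)`. Queries outside the
#' covered region return an empty vector, not an error.
#'
#' @param chrom,start,end Parallel vectors of query intervals
#'   (0-based half-open).
#' @param fragments Validated fragment map.
#' @return A list (one element per query) of overlapping fragment ids.
#' @export
assign_fragments <- function(chrom, start, end, fragments) {
  lvls <- union(unique(chrom), unique(fragments$chrom))
  query <- as_granges(chrom, start, end, levels = lvls)
  subject <- as_granges(fragments$chrom, fragments$start, fragments$end,
    levels = lvls)
  hits <- GenomicRanges::findOverlaps(query, subject)
  out <- rep(list(character(0)), length(query))
  if (length(hits) > 0) {
    by_query <- split(
      fragments$fragment_id[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits)
    )
    out[as.integer(names(by_query))] <- lapply(by_query, unname)
  }
  out
}

#' Call enhancer / promoter activity per fragment and cell type
#'
#' A fragment has enhancer (promoter) activity in a cell type iff at least
#' `min_overlap` bp of the fragment intersects a single segment whose state is
#' in the enhancer (promoter) state set for that cell type. States outside the
#' supplied vocabulary trigger one warning and count as neither.
#'
#' @param fragments Validated fragment map.
#' @param segments State segmentation tibble (all cell types stacked).
#' @param enhancer_states,promoter_states Character vectors of state labels;
#'   defaults follow the Roadmap 15-state mnemonics ([chromhmm_states()]).
#' @param min_overlap Minimum single-segment overlap in bp (default 1, i.e.
#'   any overlap).
#' @param state_vocabulary States considered known; defaults to the 15-state
#'   mnemonics plus the two role sets.
#' @return Tibble `fragment_id` x `cell_type` with logicals `has_enhancer`,
#'   `has_promoter`, covering every fragment for every cell type present in
#'   `segments`.
#' @export
call_fragment_states <- function(fragments, segments,
                                 enhancer_states = chromhmm_states()$enhancer,
                                 promoter_states = chromhmm_states()$promoter,
                                 min_overlap = 1,
                                 state_vocabulary = NULL) {
  if (is.null(state_vocabulary)) {
    state_vocabulary <- unique(c(chromhmm_states()$all, enhancer_states,
      promoter_states))
  }
  unknown <- setdiff(unique(segments$state), state_vocabulary)
  if (length(unknown) > 0) {
    warn(sprintf(
      "unknown chromatin state label(s) treated as neither enhancer nor promoter: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  cell_types <- sort(unique(segments$cell_type))
  lvls <- union(unique(fragments$chrom), unique(segments$chrom))
  frag_gr <- as_granges(fragments$chrom, fragments$start, fragments$end,
    levels = lvls)
  out <- lapply(cell_types, function(ct) {
    seg <- segments[segments$cell_type == ct, ]
    seg_gr <- as_granges(seg$chrom, seg$start, seg$end, levels = lvls)
    hits <- GenomicRanges::findOverlaps(frag_gr, seg_gr, minoverlap = min_overlap)
    qh <- S4Vectors::queryHits(hits)
    state <- seg$state[S4Vectors::subjectHits(hits)]
    tibble::tibble(
      fragment_id = fragments$fragment_id,
      cell_type = ct,
      has_enhancer = fragments$fragment_id %in%
        fragments$fragment_id[qh[state %in% enhancer_states]],
      has_promoter = fragments$fragment_id %in%
        fragments$fragment_id[qh[state %in% promoter_states]]
    )
  })
  dplyr::bind_rows(out)
}

interaction_long <- function(interactions) {
  # each unordered pair viewed from both orientations (snp side vs gene side)
  a <- interactions %>%
    dplyr::transmute(
      snp_frag = .data$bait_id, gene_frag = .data$oe_id,
      score = .data$score, cell_type = .data$cell_type
    )
  b <- interactions %>%
    dplyr::transmute(
      snp_frag = .data$oe_id, gene_frag = .data$bait_id,
      score = .data$score, cell_type = .data$cell_type
    )
  dplyr::bind_rows(a, b)
}

#' Filter interactions to candidate causal genes
#'
#' Implements the locus-to-gene filter: for each LD block, keep interactions
#' at or above the score threshold whose block-side fragment has enhancer
#' activity and whose partner fragment has promoter activity in the same cell
#' type; extract the genes whose TSS lies in the promoter fragment; and keep
#' only genes expressed (value >= `expression_threshold`) in at least one of
#' the configured cell types. The filter is orientation-free: the block-side
#' fragment may be the bait or the other end.
#'
#' @param blocks LD blocks from [build_ld_blocks()].
#' @param interactions Interaction tibble from [read_interactions()].
#' @param state_calls Per-fragment state calls from [call_fragment_states()].
#' @param genes Gene tibble from [read_bed()] with `kind = "genes"`.
#' @param expression Expression tibble (`gene_id`, `cell_type`, `value`).
#' @param fragments Validated fragment map.
#' @param score_threshold Minimum interaction score (default 5, the
#'   conventional CHICAGO significance cut).
#' @param expression_threshold Minimum expression value for a gene to count as
#'   expressed (default 1).
#' @param cell_types Cell types whose expression can rescue a gene (default:
#'   all cell types in `expression`).
#' @param gene_mode `"tss"` (default) assigns a gene to the fragment holding
#'   its transcription start site; `"body"` assigns by any gene-body overlap.
#' @param block_mode `"snp"` (default) requires the enhancer fragment to
#'   contain an associated SNP; `"span"` accepts any fragment overlapping the
#'   LD-block span.
#' @return Tibble of candidate genes, one row per (gene, index SNP, disease),
#'   with list-columns `cell_types` (cell types with a supporting
#'   interaction), `expressed_in`, and `evidence` (the supporting interactions
#'   with their enhancer and promoter fragments).
#' @export
filter_candidates <- function(blocks, interactions, state_calls, genes,
                              expression, fragments,
                              score_threshold = 5,
                              expression_threshold = 1,
                              cell_types = NULL,
                              gene_mode = c("tss", "body"),
                              block_mode = c("snp", "span")) {
  gene_mode <- match.arg(gene_mode)
  block_mode <- match.arg(block_mode)
  if (is.null(cell_types)) cell_types <- sort(unique(expression$cell_type))

  if (gene_mode == "tss") {
    gene_frags <- assign_fragments(genes$chrom, genes$tss, genes$tss + 1,
      fragments)
  } else {
    gene_frags <- assign_fragments(genes$chrom, genes$start, genes$end,
      fragments)
  }
  genes_by_frag <- tibble::tibble(
    gene_id = rep(genes$gene_id, lengths(gene_frags)),
    fragment_id = unlist(gene_frags)
  )

  expressed_tbl <- expression %>%
    dplyr::filter(.data$cell_type %in% .env$cell_types,
      .data$value >= .env$expression_threshold) %>%
    dplyr::group_by(gene_key = normalize_symbol(.data$gene_id)) %>%
    dplyr::summarise(expressed_in = list(sort(unique(.data$cell_type))),
      .groups = "drop")

  pairs <- interaction_long(
    interactions[interactions$score >= score_threshold, , drop = FALSE]
  ) %>%
    dplyr::inner_join(
      state_calls %>% dplyr::select("fragment_id", "cell_type",
        snp_has_enh = "has_enhancer"),
      by = c(snp_frag = "fragment_id", "cell_type")
    ) %>%
    dplyr::inner_join(
      state_calls %>% dplyr::select("fragment_id", "cell_type",
        gene_has_prom = "has_promoter"),
      by = c(gene_frag = "fragment_id", "cell_type")
    ) %>%
    dplyr::filter(.data$snp_has_enh, .data$gene_has_prom)

  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    block <- blocks[i, ]
    if (block_mode == "snp") {
      block_frags <- block$fragment_ids[[1]]
    } else {
      block_frags <- unlist(assign_fragments(block$chrom, block$span_start,
        block$span_end, fragments))
    }
    hits <- pairs[pairs$snp_frag %in% block_frags, , drop = FALSE]
    if (nrow(hits) == 0) next
    cand <- hits %>%
      dplyr::inner_join(genes_by_frag, by = c(gene_frag = "fragment_id"),
        relationship = "many-to-many") %>%
      dplyr::mutate(gene_key = normalize_symbol(.data$gene_id)) %>%
      dplyr::inner_join(expressed_tbl, by = "gene_key")
    if (nrow(cand) == 0) next
    out[[i]] <- cand %>%
      dplyr::group_by(.data$gene_id, .data$gene_key) %>%
      dplyr::summarise(
        cell_types = list(sort(unique(.data$cell_type))),
        expressed_in = .data$expressed_in[1],
        evidence = list(tibble::tibble(
          snp_fragment = snp_frag, promoter_fragment = gene_frag,
          score = score, cell_type = cell_type
        )),
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        index_snp_id = block$index_snp_id,
        disease = block$disease,
        .before = 1
      )
  }
  result <- dplyr::bind_rows(out)
  if (nrow(result) == 0) {
    return(tibble::tibble(
      index_snp_id = character(), disease = character(),
      gene_id = character(), gene_key = character(),
      cell_types = list(), expressed_in = list(), evidence = list()
    ))
  }
  dplyr::arrange(result, .data$disease, .data$index_snp_id, .data$gene_key)
}

#' Flatten candidate genes to an evidence-level table for writing
#'
#' @param candidates Candidate tibble from [filter_candidates()].
#' @return Tibble with one row per candidate x supporting interaction, stable
#'   column order.
#' @export
candidates_to_table <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      disease = character(), index_snp_id = character(),
      gene_id = character(), snp_fragment = character(),
      promoter_fragment = character(), score = double(),
      cell_type = character(), expressed_in = character()
    ))
  }
  candidates %>%
    dplyr::mutate(expressed_in = vapply(.data$expressed_in, paste,
      "", collapse = ",")) %>%
    dplyr::select("disease", "index_snp_id", "gene_id", "expressed_in",
      "evidence") %>%
    tidyr::unnest("evidence") %>%
    dplyr::select("disease", "index_snp_id", "gene_id", "snp_fragment",
      "promoter_fragment", "score", "cell_type", "expressed_in") %>%
    dplyr::arrange(.data$disease, .data$index_snp_id, .data$gene_id,
      .data$snp_fragment, .data$promoter_fragment, .data$cell_type)
}
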