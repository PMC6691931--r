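# Agreement between chromatin-interaction candidates and the gene reported by
# the source GWAS, per locus. Each locus lands in exactly one category:
#   NO_CHIC_GENES  no candidate genes at all
#   "0"            candidates found but the reported gene is not among them
#   "1"            the reported gene is the only candidate
#   "2-5"          reported gene among 2-5 candidates
#   "6+"           reported gene among 6 or more candidates

LOCUS_CATEGORIES <- c("NO_CHIC_GENES", "0", "1", "2-5", "6+")

split_reported <- function(reported_gene) {
  normalize_symbol(strsplit(reported_gene, ",", fixed = TRUE)[[1]])
}

#' Categorise one locus by candidate / reported-gene agreement
#'
#' A locus whose source GWAS listed several comma-separated genes counts as
#' recovered if any of them is among the candidates. Symbols are compared
#' case-insensitively. A missing or blank reported gene makes the comparison
#' not applicable (`NA` category, excluded from summaries).
#'
#' @param candidate_genes Character vector of candidate gene symbols for the
#'   locus (may be empty).
#' @param reported_gene Reported gene symbol(s), comma-separated, or
#'   `NA`/empty.
#' @return One of `"NO_CHIC_GENES"`, `"0"`, `"1"`, `"2-5"`, `"6+"`, or `NA`.
#' @export
categorize_locus <- function(candidate_genes, reported_gene) {
  if (is.na(reported_gene) || !nzchar(trimws(reported_gene))) {
    return(NA_character_)
  }
  cand <- unique(normalize_symbol(candidate_genes))
  if (length(cand) == 0) {
    return("NO_CHIC_GENES")
  }
  recovered <- any(split_reported(reported_gene) %in% cand)
  if (!recovered) {
    return("0")
  }
  if (length(cand) == 1) {
    return("1")
  }
  if (length(cand) <= 5) {
    return("2-5")
  }
  "6+"
}

#' Categorise every locus
#'
#' @param blocks LD blocks from [build_ld_blocks()] (defines the locus set,
#'   including loci with no candidates).
#' @param candidates Candidate tibble from [filter_candidates()].
#' @param reported Reported-gene tibble (`index_snp_id`, `disease`,
#'   `reported_gene`).
#' @return Tibble with one row per locus: `index_snp_id`, `disease`,
#'   `reported_gene`, `n_candidates`, `category`.
#' @export
categorize_loci <- function(blocks, candidates, reported) {
  loci <- blocks %>%
    dplyr::select("index_snp_id", "disease") %>%
    dplyr::left_join(
      reported %>% dplyr::select("index_snp_id", "disease", "reported_gene"),
      by = c("index_snp_id", "disease")
    )
  cand_sets <- candidates %>%
    dplyr::group_by(.data$index_snp_id, .data$disease) %>%
    dplyr::summarise(genes = list(unique(.data$gene_key)), .groups = "drop")
  loci <- dplyr::left_join(loci, cand_sets,
    by = c("index_snp_id", "disease"))
  loci$genes <- lapply(loci$genes, function(g) if (is.null(g)) character(0) else g)
  loci$n_candidates <- lengths(loci$genes)
  loci$category <- vapply(seq_len(nrow(loci)), function(i) {
    categorize_locus(loci$genes[[i]],
      if (is.na(loci$reported_gene[i])) NA_character_ else loci$reported_gene[i])
  }, "")
  loci %>%
    dplyr::select("index_snp_id", "disease", "reported_gene", "n_candidates",
      "category") %>%
    dplyr::arrange(.data$disease, .data$index_snp_id)
}

#' Summarise locus categories per disease and overall
#'
#' @param loci Tibble from [categorize_loci()].
#' @return Tibble `disease` x `category` x `n`, including an `"all"` row set;
#'   loci with a not-applicable comparison (`NA` category) are excluded.
#'   Counts within a disease sum to the number of categorised loci.
#' @export
summarize_categories <- function(loci) {
  loci <- loci[!is.na(loci$category), ]
  loci$category <- factor(loci$category, levels = LOCUS_CATEGORIES)
  per_disease <- loci %>%
    dplyr::count(.data$disease, .data$category, .drop = FALSE,
      name = "n")
  overall <- loci %>%
    dplyr::count(.data$category, .drop = FALSE, name = "n") %>%
    dplyr::mutate(disease = "all", .before = 1)
  dplyr::bind_rows(per_disease, overall) %>%
    dplyr::mutate(category = as.character(.data$category)) %>%
    dplyr::arrange(.data$disease,
      factor(.data$category, levels = LOCUS_CATEGORIES))
}
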