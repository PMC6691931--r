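# Pathway-level refinement: one-sided Fisher's exact over-representation test
# per pathway and disease, Benjamini-Hochberg FDR across pathways, cell-type
# specificity labels, and the refined / pathway-expanded gene and drug lists.

#' One-sided Fisher's exact over-representation test
#'
#' Tests whether a query gene list over-represents a pathway within a gene
#' universe. Both lists are intersected with the universe first; the p value
#' is the upper hypergeometric tail P(X >= k) with k overlap genes, K pathway
#' genes, n query genes and N universe genes.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param pathway_genes Character vector of pathway member symbols.
#' @param universe Character vector defining the testable gene universe.
#' @return List with `k`, `K`, `n`, `N`, `p_raw` and `overlap_genes`.
#' @export
fisher_enrichment <- function(query_genes, pathway_genes, universe) {
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0) stop_validation("empty gene universe")
  query <- intersect(unique(normalize_symbol(query_genes)), universe)
  pathway <- intersect(unique(normalize_symbol(pathway_genes)), universe)
  overlap <- intersect(query, pathway)
  k <- length(overlap)
  K <- length(pathway)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_raw = p, overlap_genes = sort(overlap))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return List with `p_adj` (monotone step-up adjusted values, capped at 1)
#'   and `significant` (`p_adj <= alpha`).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_validation("p values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = p_adj <= alpha)
}

#' Cell-type specificity label for a pathway
#'
#' Given which single-cell-type enrichment runs found the pathway
#' significant, returns `"Both"` when all did, the cell-type name when
#' exactly one did, and `"Pooled-only"` when none did (the pathway then owes
#' its significance to the pooled gene list alone).
#'
#' @param significant_in Named logical vector, one element per cell type.
#' @return A single label string.
#' @export
cell_type_label <- function(significant_in) {
  hits <- names(significant_in)[significant_in]
  if (length(hits) == length(significant_in) && length(hits) > 1) {
    return("Both")
  }
  if (length(hits) == 1) {
    return(hits)
  }
  "Pooled-only"
}

enrich_one_run <- function(query_genes, pathways, universe, alpha) {
  res <- lapply(seq_len(nrow(pathways)), function(i) {
    fisher_enrichment(query_genes, pathways$genes[[i]], universe)
  })
  adj <- bh_adjust(vapply(res, `[[`, 0, "p_raw"), alpha)
  tibble::tibble(
    pathway_id = pathways$pathway_id,
    pathway_name = pathways$name,
    k = vapply(res, `[[`, 0L, "k"),
    K = vapply(res, `[[`, 0L, "K"),
    n = vapply(res, `[[`, 0L, "n"),
    N = vapply(res, `[[`, 0L, "N"),
    p_raw = vapply(res, `[[`, 0, "p_raw"),
    p_adj = adj$p_adj,
    significant = adj$significant,
    overlap_genes = lapply(res, `[[`, "overlap_genes")
  )
}

#' Pathway enrichment of candidate genes, per disease
#'
#' Runs the Fisher/BH over-representation analysis on each disease's pooled
#' candidate gene list, and additionally on the per-cell-type gene lists
#' (genes with a supporting interaction in that cell type only run) to label
#' each significant pathway's cell-type specificity. The default universe is
#' every gene appearing in the supplied pathway collection, mirroring a
#' knowledge-base universe; pass an explicit `universe` (e.g. all annotated
#' or all expressed genes) to override.
#'
#' @param candidates Candidate tibble from [filter_candidates()].
#' @param pathways Pathway tibble from [read_gmt()].
#' @param universe Optional character vector of universe genes.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param drug_table Optional drug-target table; when given, the output
#'   reports how many overlap genes are drug targets.
#' @return Tibble with one row per disease x pathway: test margins, raw and
#'   adjusted p, `significant`, `overlap_genes` (list), `n_snp_associations`
#'   (distinct index SNPs contributing at least one overlap gene),
#'   `n_target_genes` (if `drug_table` given) and `cell_type_label`.
#' @export
enrich_pathways <- function(candidates, pathways, universe = NULL,
                            alpha = 0.05, drug_table = NULL) {
  if (is.null(universe)) {
    universe <- unique(unlist(pathways$genes))
  }
  target_keys <- if (is.null(drug_table)) {
    character(0)
  } else {
    unique(normalize_symbol(drug_table$gene_id))
  }
  if (nrow(candidates) == 0) {
    out <- tibble::tibble(
      disease = character(), pathway_id = character(),
      pathway_name = character(), k = integer(), K = integer(),
      n = integer(), N = integer(), p_raw = double(), p_adj = double(),
      significant = logical(), overlap_genes = list(),
      cell_type_label = character(), n_snp_associations = integer()
    )
    if (!is.null(drug_table)) out$n_target_genes <- integer()
    return(out)
  }
  cell_types <- sort(unique(unlist(candidates$cell_types)))
  out <- lapply(sort(unique(candidates$disease)), function(dis) {
    cand <- candidates[candidates$disease == dis, , drop = FALSE]
    pooled <- enrich_one_run(unique(cand$gene_key), pathways, universe, alpha)
    per_ct <- lapply(cell_types, function(ct) {
      in_ct <- vapply(cand$cell_types, function(x) ct %in% x, TRUE)
      enrich_one_run(unique(cand$gene_key[in_ct]), pathways, universe, alpha)
    })
    names(per_ct) <- cell_types
    pooled$cell_type_label <- vapply(seq_len(nrow(pooled)), function(i) {
      if (!pooled$significant[i]) {
        return(NA_character_)
      }
      sig <- vapply(per_ct, function(r) r$significant[i], TRUE)
      cell_type_label(sig)
    }, "")
    pooled$n_snp_associations <- vapply(pooled$overlap_genes, function(g) {
      length(unique(cand$index_snp_id[cand$gene_key %in% g]))
    }, 0L)
    if (!is.null(drug_table)) {
      pooled$n_target_genes <- vapply(pooled$overlap_genes, function(g) {
        sum(g %in% target_keys)
      }, 0L)
    }
    dplyr::mutate(pooled, disease = dis, .before = 1)
  })
  dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$disease, .data$p_adj, .data$pathway_id)
}

#' Refine candidates by significant pathways and expand the drug search space
#'
#' The refined gene list keeps only candidates that belong to at least one
#' significant pathway; the pathway-expanded list is the union of all genes
#' of significant pathways, enlarging the repositioning search space beyond
#' the interaction-supported candidates. Both lists are mapped to drugs; the
#' pathway-target columns count expanded genes (and their drugs) that are
#' drug targets but not already refined candidates.
#'
#' @param candidates Candidate tibble from [filter_candidates()].
#' @param enrichment Enrichment tibble from [enrich_pathways()].
#' @param pathways Pathway tibble from [read_gmt()].
#' @param drug_table Drug-target table.
#' @param disease_terms Disease-name variant list ([read_disease_terms()]).
#' @param match_mode Indication matching mode, see [classify_current_use()].
#' @param groups Optional approval-status filter, see [map_drug_targets()].
#' @return List with `refined` (per-disease tibble of refined and expanded
#'   gene sets), `drug_calls` (classified drugs hitting refined genes) and
#'   `summary` (one row per disease plus "All": refined gene/target/drug
#'   counts, current vs repositionable split, and potential pathway targets
#'   and drugs).
#' @export
refine_and_expand <- function(candidates, enrichment, pathways, drug_table,
                              disease_terms,
                              match_mode = c("substring", "token"),
                              groups = NULL) {
  match_mode <- match.arg(match_mode)
  pathway_genes <- stats::setNames(
    lapply(pathways$genes, normalize_symbol), pathways$pathway_id
  )
  diseases <- sort(unique(candidates$disease))
  refined <- lapply(diseases, function(dis) {
    sig <- enrichment[enrichment$disease == dis & enrichment$significant, ]
    sig_genes <- sort(unique(unlist(pathway_genes[sig$pathway_id])))
    cand_genes <- sort(unique(candidates$gene_key[candidates$disease == dis]))
    tibble::tibble(
      disease = dis,
      n_significant_pathways = nrow(sig),
      refined_genes = list(intersect(cand_genes, sig_genes)),
      pathway_expanded_genes = list(sig_genes)
    )
  })
  refined <- dplyr::bind_rows(refined)
  if (nrow(refined) == 0) {
    refined <- tibble::tibble(
      disease = character(), n_significant_pathways = integer(),
      refined_genes = list(), pathway_expanded_genes = list()
    )
  }

  refined_pairs <- tibble::tibble(
    disease = rep(refined$disease, lengths(refined$refined_genes)),
    gene_key = as.character(unlist(refined$refined_genes))
  )
  refined_cand <- dplyr::inner_join(candidates, refined_pairs,
    by = c("disease", "gene_key"))
  drug_calls <- map_drug_targets(refined_cand, drug_table, groups = groups) %>%
    classify_current_use(disease_terms, mode = match_mode)
  summary <- summarize_targets(drug_calls, refined_cand)

  # expanded pathway targets beyond the refined candidates themselves
  expansion_row <- function(dis) {
    if (identical(dis, "All")) {
      expanded <- sort(unique(unlist(refined$pathway_expanded_genes)))
      ref_genes <- unique(unlist(refined$refined_genes))
    } else {
      expanded <- refined$pathway_expanded_genes[[match(dis, refined$disease)]]
      ref_genes <- refined$refined_genes[[match(dis, refined$disease)]]
    }
    extra <- setdiff(expanded, ref_genes)
    dt <- drug_table
    if (!is.null(groups)) {
      keep <- vapply(strsplit(dt$groups, ",", fixed = TRUE),
        function(g) any(trimws(g) %in% groups), TRUE)
      dt <- dt[keep, , drop = FALSE]
    }
    dt_keys <- normalize_symbol(dt$gene_id)
    tibble::tibble(
      disease = dis,
      n_pathway_targets = length(intersect(extra, dt_keys)),
      n_pathway_drugs = length(unique(dt$drug_id[dt_keys %in% extra]))
    )
  }
  expansion <- dplyr::bind_rows(lapply(c(diseases, "All"), expansion_row))
  summary <- dplyr::left_join(summary, expansion, by = "disease")
  list(refined = refined, drug_calls = drug_calls, summary = summary)
}

#' Flatten enrichment results to a writable table
#' @param enrichment Tibble from [enrich_pathways()].
#' @return Tibble with `overlap_genes` collapsed to a comma-separated column.
#' @export
enrichment_to_table <- function(enrichment) {
  enrichment %>%
    dplyr::mutate(overlap_genes = vapply(.data$overlap_genes, paste, "",
      collapse = ","))
}
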