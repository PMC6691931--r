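# Join candidate genes to a DrugBank-like drug-target table, split the drugs
# hitting each disease's candidates into currently-used therapies versus
# repositioning opportunities, and summarise per disease.

#' Map candidate genes to drugs targeting them
#'
#' Gene symbols are matched case-insensitively. A drug hitting several
#' candidate genes appears once per disease with all hit targets recorded.
#'
#' @param candidates Candidate tibble from [filter_candidates()] (or any
#'   tibble with `disease` and `gene_id`).
#' @param drug_table Drug-target tibble ([read_table()] schema
#'   `"drug_targets"`).
#' @param groups Optional approval-status filter, e.g. `"approved"`; a drug
#'   row is kept if any of its comma-separated groups is in this set. `NULL`
#'   (default) keeps all rows.
#' @return Tibble with one row per (disease, drug): `disease`, `drug_id`,
#'   `drug_name`, `indication`, list-column `target_genes` (candidate genes
#'   hit), `n_targets`.
#' @export
map_drug_targets <- function(candidates, drug_table, groups = NULL) {
  if (!is.null(groups)) {
    keep <- vapply(strsplit(drug_table$groups, ",", fixed = TRUE),
      function(g) any(trimws(g) %in% groups), TRUE)
    drug_table <- drug_table[keep, , drop = FALSE]
  }
  cand <- candidates %>%
    dplyr::transmute(.data$disease, gene_key = normalize_symbol(.data$gene_id)) %>%
    dplyr::distinct()
  drug_table %>%
    dplyr::mutate(gene_key = normalize_symbol(.data$gene_id)) %>%
    dplyr::inner_join(cand, by = "gene_key",
      relationship = "many-to-many") %>%
    dplyr::group_by(.data$disease, .data$drug_id) %>%
    dplyr::summarise(
      drug_name = dplyr::first(.data$drug_name),
      indication = dplyr::first(.data$indication),
      target_genes = list(sort(unique(.data$gene_key))),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_targets = lengths(.data$target_genes)) %>%
    dplyr::arrange(.data$disease, .data$drug_id)
}

match_indication <- function(indication, terms, mode) {
  ind <- tolower(indication)
  if (!nzchar(trimws(ind))) {
    return(NA_character_)
  }
  if (mode == "substring") {
    hit <- terms[vapply(terms, function(t) grepl(t, ind, fixed = TRUE), TRUE)]
  } else {
    ind_tokens <- strsplit(gsub("[^a-z0-9]+", " ", ind), " +")[[1]]
    hit <- terms[vapply(terms, function(t) {
      tok <- strsplit(gsub("[^a-z0-9]+", " ", t), " +")[[1]]
      all(tok %in% ind_tokens)
    }, TRUE)]
  }
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Flag drugs already used for the disease
#'
#' A drug is currently used for a disease when one of the disease's name
#' variants matches its free-text indication field. The default `"substring"`
#' mode is a plain case-insensitive substring test; `"token"` mode matches
#' when every word of a term occurs in the indication regardless of order or
#' intervening words (so "juvenile arthritis" matches "juvenile idiopathic
#' arthritis").
#'
#' @param drug_calls Tibble from [map_drug_targets()].
#' @param disease_terms Named list of lower-cased term vectors
#'   ([read_disease_terms()]).
#' @param mode `"substring"` (default) or `"token"`.
#' @return `drug_calls` with columns `currently_used` (logical) and
#'   `matched_term` (`NA` when not matched); the two are always consistent.
#' @export
classify_current_use <- function(drug_calls, disease_terms,
                                 mode = c("substring", "token")) {
  mode <- match.arg(mode)
  drug_calls$matched_term <- vapply(seq_len(nrow(drug_calls)), function(i) {
    terms <- disease_terms[[drug_calls$disease[i]]]
    if (is.null(terms)) {
      return(NA_character_)
    }
    match_indication(drug_calls$indication[i], terms, mode)
  }, "")
  drug_calls$currently_used <- !is.na(drug_calls$matched_term)
  drug_calls
}

#' Summarise drug-target findings per disease
#'
#' Per disease and overall ("All"): number of candidate genes, number that
#' are drug targets, number of distinct drugs, currently-used drugs and
#' repositionable drugs. The split is exhaustive and disjoint, so
#' `n_drugs = n_current + n_repositionable` always holds. In the "All" row
#' genes and drugs are counted once across diseases; a drug counts as
#' currently used overall if it is currently used for any disease where it
#' was identified.
#'
#' @param drug_calls Classified tibble from [classify_current_use()].
#' @param candidates Candidate tibble (for candidate-gene counts).
#' @return Summary tibble with one row per disease plus "All".
#' @export
summarize_targets <- function(drug_calls, candidates) {
  diseases <- sort(unique(candidates$disease))
  cand_keys <- tibble::tibble(
    disease = candidates$disease,
    gene_key = normalize_symbol(candidates$gene_id)
  ) %>% dplyr::distinct()
  row_for <- function(dis) {
    if (identical(dis, "All")) {
      genes <- unique(cand_keys$gene_key)
      calls <- drug_calls %>%
        dplyr::group_by(.data$drug_id) %>%
        dplyr::summarise(
          currently_used = any(.data$currently_used),
          target_genes = list(sort(unique(unlist(.data$target_genes)))),
          .groups = "drop"
        )
    } else {
      genes <- cand_keys$gene_key[cand_keys$disease == dis]
      calls <- drug_calls[drug_calls$disease == dis, , drop = FALSE]
    }
    target_genes <- unique(unlist(calls$target_genes))
    tibble::tibble(
      disease = dis,
      n_genes = length(genes),
      n_target_genes = length(intersect(genes, target_genes)),
      n_drugs = nrow(calls),
      n_current = sum(calls$currently_used),
      n_repositionable = sum(!calls$currently_used)
    )
  }
  dplyr::bind_rows(lapply(c(diseases, "All"), row_for))
}

#' Flatten drug calls to a writable table
#' @param drug_calls Classified tibble from [classify_current_use()].
#' @return Tibble with `target_genes` collapsed to a comma-separated column.
#' @export
drug_calls_to_table <- function(drug_calls) {
  drug_calls %>%
    dplyr::mutate(target_genes = vapply(.data$target_genes, paste, "",
      collapse = ",")) %>%
    dplyr::arrange(.data$disease, .data$drug_id)
}
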