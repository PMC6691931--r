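# End-to-end orchestration: load inputs, run the locus-to-gene filter, the
# reported-gene comparison, the drug-target join and the pathway refinement,
# and write deterministic result tables plus a reproducibility manifest.

#' Pipeline parameters
#'
#' All thresholds and modes of the pipeline in one validated object.
#'
#' @param r2_threshold Minimum r-squared for LD-block membership
#'   (default 0.8).
#' @param score_threshold Minimum interaction score (default 5).
#' @param expression_threshold Minimum expression value (default 1).
#' @param alpha BH-adjusted significance level for pathway enrichment
#'   (default 0.05).
#' @param min_overlap Minimum fragment/segment overlap in bp for a state
#'   call (default 1).
#' @param enhancer_states,promoter_states Chromatin-state sets; defaults from
#'   [chromhmm_states()].
#' @param cell_types Cell types considered; `NULL` uses all present.
#' @param match_mode Indication matching mode (`"substring"` or `"token"`).
#' @param groups Optional approval-status filter for drugs.
#' @param gene_mode Gene-to-fragment assignment (`"tss"` or `"body"`).
#' @param block_mode Enhancer-side fragment selection (`"snp"` or `"span"`).
#' @param universe Enrichment universe: `"gmt"` (all pathway genes, default),
#'   `"annotated"` (all genes in the annotation) or `"expressed"` (all genes
#'   passing the expression threshold in any cell type).
#' @return A validated list of class `pipeline_params`.
#' @export
pipeline_params <- function(r2_threshold = 0.8,
                            score_threshold = 5,
                            expression_threshold = 1,
                            alpha = 0.05,
                            min_overlap = 1,
                            enhancer_states = chromhmm_states()$enhancer,
                            promoter_states = chromhmm_states()$promoter,
                            cell_types = NULL,
                            match_mode = c("substring", "token"),
                            groups = NULL,
                            gene_mode = c("tss", "body"),
                            block_mode = c("snp", "span"),
                            universe = c("gmt", "annotated", "expressed")) {
  params <- list(
    r2_threshold = r2_threshold, score_threshold = score_threshold,
    expression_threshold = expression_threshold, alpha = alpha,
    min_overlap = min_overlap, enhancer_states = enhancer_states,
    promoter_states = promoter_states, cell_types = cell_types,
    match_mode = match.arg(match_mode), groups = groups,
    gene_mode = match.arg(gene_mode), block_mode = match.arg(block_mode),
    universe = match.arg(universe)
  )
  stopifnot(
    params$r2_threshold >= 0, params$r2_threshold <= 1,
    params$score_threshold >= 0, params$alpha >= 0, params$alpha <= 1,
    params$min_overlap >= 1,
    length(params$enhancer_states) > 0, length(params$promoter_states) > 0
  )
  structure(params, class = "pipeline_params")
}

#' Load every pipeline input from a directory
#'
#' Expects the file layout written by [write_fixture()]: `fragments.bed`,
#' `segments_<cell_type>.bed` (one per cell type), `genes.bed`,
#' `interactions.tsv`, `snps.tsv`, `expression.tsv`, `drug_targets.tsv`,
#' `reported_genes.tsv`, `disease_terms.yaml`, `pathways.gmt`.
#'
#' @param dir Input directory.
#' @return Named list of typed tibbles/lists, as consumed by
#'   [run_pipeline()].
#' @export
load_pipeline_inputs <- function(dir) {
  fragments <- read_bed(file.path(dir, "fragments.bed"), "fragments")
  seg_files <- list.files(dir, pattern = "^segments_.*\\.bed$",
    full.names = TRUE)
  if (length(seg_files) == 0) {
    stop_validation("no segments_<cell_type>.bed files in %s", dir)
  }
  segments <- dplyr::bind_rows(lapply(seg_files, function(p) {
    ct <- sub("^segments_(.*)\\.bed$", "\\1", basename(p))
    read_bed(p, "segments", cell_type = ct)
  }))
  list(
    fragments = fragments,
    segments = segments,
    genes = read_bed(file.path(dir, "genes.bed"), "genes"),
    interactions = read_interactions(file.path(dir, "interactions.tsv"),
      fragments),
    snps = read_table(file.path(dir, "snps.tsv"), "snps"),
    expression = read_table(file.path(dir, "expression.tsv"), "expression"),
    drug_table = read_table(file.path(dir, "drug_targets.tsv"),
      "drug_targets"),
    reported = read_table(file.path(dir, "reported_genes.tsv"),
      "reported_genes"),
    disease_terms = read_disease_terms(file.path(dir, "disease_terms.yaml")),
    pathways = read_gmt(file.path(dir, "pathways.gmt"))
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
      conditionMessage(e)), class = "chic2drug_stage_error")
  })
}

#' Run the full pipeline
#'
#' Executes, in order: LD-block construction, fragment state calls, the
#' enhancer-promoter interaction filter, locus categorisation against the
#' reported GWAS genes, the drug-target join with current-use classification,
#' pathway enrichment and the pathway-based refinement. The result is a pure
#' function of `(inputs, params)`; when `out_dir` is given, all result
#' tables are written with deterministic order plus a `manifest.json`
#' recording parameter and input checksums.
#'
#' @param inputs Named list from [load_pipeline_inputs()] or the `data`
#'   element of [generate_fixture()].
#' @param params A [pipeline_params()] object.
#' @param out_dir Optional output directory.
#' @param input_paths Optional named paths used for manifest checksums.
#' @return List with `candidates`, `loci`, `category_summary`, `drug_calls`,
#'   `drug_summary`, `enrichment`, `refinement` (see [refine_and_expand()])
#'   and `manifest`.
#' @export
run_pipeline <- function(inputs, params = pipeline_params(), out_dir = NULL,
                         input_paths = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  blocks <- run_stage("ld_blocks",
    build_ld_blocks(inputs$snps, inputs$fragments, params$r2_threshold))
  state_calls <- run_stage("fragment_states",
    call_fragment_states(inputs$fragments, inputs$segments,
      params$enhancer_states, params$promoter_states, params$min_overlap))
  candidates <- run_stage("candidate_genes",
    filter_candidates(blocks, inputs$interactions, state_calls, inputs$genes,
      inputs$expression, inputs$fragments,
      score_threshold = params$score_threshold,
      expression_threshold = params$expression_threshold,
      cell_types = params$cell_types,
      gene_mode = params$gene_mode, block_mode = params$block_mode))
  loci <- run_stage("gwas_comparison",
    categorize_loci(blocks, candidates, inputs$reported))
  category_summary <- run_stage("gwas_comparison",
    summarize_categories(loci))
  drug_calls <- run_stage("drug_targets",
    map_drug_targets(candidates, inputs$drug_table, groups = params$groups) %>%
      classify_current_use(inputs$disease_terms, mode = params$match_mode))
  drug_summary <- run_stage("drug_targets",
    summarize_targets(drug_calls, candidates))
  universe <- switch(params$universe,
    gmt = NULL,
    annotated = unique(inputs$genes$gene_id),
    expressed = unique(inputs$expression$gene_id[
      inputs$expression$value >= params$expression_threshold])
  )
  enrichment <- run_stage("pathway_enrichment",
    enrich_pathways(candidates, inputs$pathways, universe = universe,
      alpha = params$alpha, drug_table = inputs$drug_table))
  refinement <- run_stage("pathway_refinement",
    refine_and_expand(candidates, enrichment, inputs$pathways,
      inputs$drug_table, inputs$disease_terms,
      match_mode = params$match_mode, groups = params$groups))

  manifest <- list(
    package_version = as.character(utils::packageVersion("chic2drug")),
    params = unclass(params),
    n_loci = nrow(blocks),
    n_candidates = nrow(candidates),
    input_md5 = if (is.null(input_paths)) NULL else {
      paths <- unlist(input_paths)
      as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
    }
  )
  result <- list(
    candidates = candidates, loci = loci,
    category_summary = category_summary,
    drug_calls = drug_calls, drug_summary = drug_summary,
    enrichment = enrichment, refinement = refinement,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all pipeline result tables
#'
#' @param result List from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    candidates = file.path(out_dir, "candidates.tsv"),
    loci = file.path(out_dir, "locus_categories.tsv"),
    category_summary = file.path(out_dir, "category_summary.tsv"),
    drug_calls = file.path(out_dir, "drug_calls.tsv"),
    drug_summary = file.path(out_dir, "drug_summary.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    refined = file.path(out_dir, "refined_genes.tsv"),
    refined_summary = file.path(out_dir, "refined_summary.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(candidates_to_table(result$candidates),
    paths[["candidates"]])
  readr::write_tsv(result$loci, paths[["loci"]])
  readr::write_tsv(result$category_summary, paths[["category_summary"]])
  readr::write_tsv(drug_calls_to_table(result$drug_calls),
    paths[["drug_calls"]])
  readr::write_tsv(result$drug_summary, paths[["drug_summary"]])
  readr::write_tsv(enrichment_to_table(result$enrichment),
    paths[["enrichment"]])
  refined_tbl <- result$refinement$refined %>%
    dplyr::mutate(
      refined_genes = vapply(.data$refined_genes, paste, "", collapse = ","),
      pathway_expanded_genes = vapply(.data$pathway_expanded_genes, paste,
        "", collapse = ",")
    )
  readr::write_tsv(refined_tbl, paths[["refined"]])
  readr::write_tsv(result$refinement$summary, paths[["refined_summary"]])
  jsonlite::write_json(result$manifest, paths[["manifest"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
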