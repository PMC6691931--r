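test_that("the over-representation p value has the right degenerate limits", {
  u <- sprintf("G%02d", 1:20)
  # zero overlap is certain under X >= 0
  r <- fisher_enrichment(u[1:4], u[11:15], u)
  expect_equal(r$k, 0)
  expect_identical(r$p_raw, 1)
  expect_identical(fisher_enrichment(character(0), u[1:5], u)$p_raw, 1)
  # pathway equal to the universe: k = n, p = 1
  full <- fisher_enrichment(u[1:4], u, u)
  expect_equal(full$k, full$n)
  expect_identical(full$p_raw, 1)
  expect_error(fisher_enrichment(u[1:4], u[1:5], character(0)), "universe")
})

test_that("the Fisher tail matches enumeration and fisher.test", {
  u <- sprintf("G%02d", 1:20)
  r <- fisher_enrichment(u[c(1, 2, 3, 11)], u[1:5], u) # k=3, K=5, n=4, N=20
  expect_equal(r$k, 3)
  expect_equal(r$p_raw, hyper_tail_oracle(3, 5, 4, 20), tolerance = 1e-12)
  ft <- stats::fisher.test(matrix(c(3, 1, 2, 14), 2), alternative = "greater")
  expect_equal(r$p_raw, ft$p.value, tolerance = 1e-12)
  expect_equal(r$overlap_genes, sort(u[1:3]))
})

test_that("BH adjustment reproduces the step-up reference", {
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)
  expect_equal(bh_adjust(rep(0.2, 5))$p_adj, rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05))$p_adj,
    c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05), alpha = 0.045)$significant,
    c(TRUE, TRUE, FALSE, FALSE))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("cell-type specificity labels partition the outcomes", {
  expect_equal(cell_type_label(c(GM12878 = TRUE, Tcell = TRUE)), "Both")
  expect_equal(cell_type_label(c(GM12878 = TRUE, Tcell = FALSE)), "GM12878")
  expect_equal(cell_type_label(c(GM12878 = FALSE, Tcell = TRUE)), "Tcell")
  expect_equal(cell_type_label(c(GM12878 = FALSE, Tcell = FALSE)),
    "Pooled-only")
})

test_that("enrichment on the fixture finds exactly the planted pathways", {
  fx <- default_fixture()
  enr <- default_result()$enrichment
  truth <- fx$truth$pathways
  planted <- truth[truth$enriched, ]
  for (i in seq_len(nrow(planted))) {
    row <- enr[enr$pathway_id == planted$pathway_id[i] &
      enr$disease == planted$disease[i], ]
    expect_true(row$significant, info = planted$pathway_id[i])
  }
  # nothing else is significant
  sig <- enr[enr$significant, ]
  expect_setequal(paste(sig$disease, sig$pathway_id),
    paste(planted$disease, planted$pathway_id))
  # every significant pathway carries exactly one label
  expect_true(all(sig$cell_type_label %in%
    c("Both", "GM12878", "Tcell", "Pooled-only")))
  expect_false(any(is.na(sig$cell_type_label)))
  # SNP associations contributing overlap genes are counted per pathway
  expect_true(all(sig$n_snp_associations >= 1))
})

test_that("cell-type labels reflect the single-cell-type runs", {
  # construct a candidate set where one pathway's genes are GM12878-only
  cand <- tibble::tibble(
    disease = "RA",
    index_snp_id = sprintf("rs%d", 1:8),
    gene_id = sprintf("GENE%d", 1:8),
    gene_key = sprintf("GENE%d", 1:8),
    cell_types = c(rep(list(c("GM12878", "Tcell")), 4),
      rep(list("GM12878"), 4))
  )
  pathways <- tibble::tibble(
    pathway_id = c("P_SHARED", "P_BONLY"),
    name = c("shared", "b-only"),
    genes = list(sprintf("GENE%d", 1:4), sprintf("GENE%d", 5:8))
  )
  universe <- c(sprintf("GENE%d", 1:8), sprintf("BG%03d", 1:200))
  enr <- enrich_pathways(cand, pathways, universe = universe, alpha = 0.05)
  expect_true(all(enr$significant))
  expect_equal(enr$cell_type_label[enr$pathway_id == "P_SHARED"], "Both")
  expect_equal(enr$cell_type_label[enr$pathway_id == "P_BONLY"], "GM12878")
})

test_that("refinement shrinks to pathway members and expands to full pathways", {
  fx <- default_fixture()
  res <- default_result()
  ref <- res$refinement$refined
  truth <- fx$truth$refinement
  for (d in truth$disease) {
    expect_equal(ref$refined_genes[[match(d, ref$disease)]],
      truth$refined_genes[[match(d, truth$disease)]], info = d)
    expect_equal(ref$pathway_expanded_genes[[match(d, ref$disease)]],
      truth$expanded_genes[[match(d, truth$disease)]], info = d)
    # containment in the original candidates
    cand_d <- unique(res$candidates$gene_key[res$candidates$disease == d])
    expect_true(all(ref$refined_genes[[match(d, ref$disease)]] %in% cand_d))
  }
  # the summary keeps the drug split identity after refinement too
  s <- res$refinement$summary
  expect_equal(s$n_drugs, s$n_current + s$n_repositionable)
  expect_true(all(s$n_pathway_targets >= 0))
})

test_that("refinement limit cases behave", {
  cand <- tibble::tibble(
    disease = "RA", index_snp_id = "rs1",
    gene_id = c("A", "B"), gene_key = c("A", "B"),
    cell_types = rep(list("Tcell"), 2)
  )
  pathways <- tibble::tibble(pathway_id = "P1", name = "p",
    genes = list(c("A", "B", "C")))
  drug_table <- tibble::tibble(drug_id = "D1", drug_name = "d",
    gene_id = "A", groups = "approved", indication = "")
  terms <- list(RA = "rheumatoid arthritis")

  # no significant pathway: empty refined and expanded sets
  enr_none <- tibble::tibble(disease = "RA", pathway_id = "P1",
    significant = FALSE)
  r0 <- refine_and_expand(cand, enr_none, pathways, drug_table, terms)
  expect_length(r0$refined$refined_genes[[1]], 0)
  expect_length(r0$refined$pathway_expanded_genes[[1]], 0)

  # all candidates inside one significant pathway: refinement is the identity
  enr_all <- tibble::tibble(disease = "RA", pathway_id = "P1",
    significant = TRUE)
  r1 <- refine_and_expand(cand, enr_all, pathways, drug_table, terms)
  expect_equal(r1$refined$refined_genes[[1]], c("A", "B"))
  expect_equal(r1$refined$pathway_expanded_genes[[1]], c("A", "B", "C"))
})
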