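test_that("LD-block membership applies the r-squared threshold", {
  snps <- tibble::tibble(
    snp_id = c("rs1", "rs1_p1", "rs1_p2"),
    chrom = "chr1",
    pos = c(2000, 2500, 3000),
    r2 = c(1, 0.95, 0.79),
    index_snp_id = "rs1",
    disease = "RA"
  )
  blocks <- build_ld_blocks(snps, mini_fragments(), r2_threshold = 0.8)
  expect_equal(nrow(blocks), 1)
  expect_setequal(blocks$members[[1]]$snp_id, c("rs1", "rs1_p1"))
  expect_equal(blocks$fragment_ids[[1]], "F1")

  lone <- snps[1, ]
  blocks1 <- build_ld_blocks(lone, mini_fragments())
  expect_equal(nrow(blocks1$members[[1]]), 1)

  orphan <- snps
  orphan$index_snp_id <- "rs_missing"
  expect_error(build_ld_blocks(orphan, mini_fragments()), "unknown index")
})

test_that("random LD blocks match a brute-force membership scan", {
  withr::local_seed(31)
  n <- 200
  snps <- tibble::tibble(
    snp_id = c("rsA", "rsB", sprintf("p%03d", 1:n)),
    chrom = "chr1",
    pos = c(2000, 10000, sample(1:16000, n, replace = TRUE)),
    r2 = c(1, 1, round(runif(n, 0, 1), 3)),
    index_snp_id = c("rsA", "rsB", sample(c("rsA", "rsB"), n, replace = TRUE)),
    disease = "RA"
  )
  for (thr in c(0.5, 0.8, 0.95)) {
    blocks <- build_ld_blocks(snps, mini_fragments(), r2_threshold = thr)
    for (i in seq_len(nrow(blocks))) {
      expected <- snps$snp_id[snps$r2 >= thr &
        snps$index_snp_id == blocks$index_snp_id[i]]
      expect_setequal(blocks$members[[i]]$snp_id, expected)
    }
  }
})

test_that("fragment assignment uses half-open overlap", {
  fr <- mini_fragments()
  # 1-based SNP position 1500 -> the [0,4000) fragment
  expect_equal(assign_fragments("chr1", 1499, 1500, fr)[[1]], "F1")
  # interval straddling a fragment boundary hits both
  expect_setequal(assign_fragments("chr1", 3900, 4100, fr)[[1]],
    c("F1", "F2"))
  # boundary point belongs to the right-hand fragment only
  expect_equal(assign_fragments("chr1", 4000, 4001, fr)[[1]], "F2")
  expect_equal(assign_fragments("chr1", 3999, 4000, fr)[[1]], "F1")
  # outside the covered region: empty, not an error
  expect_length(assign_fragments("chr9", 0, 100, fr)[[1]], 0)
  expect_length(assign_fragments("chr1", 20000, 20100, fr)[[1]], 0)
})

test_that("random interval queries equal a linear scan", {
  withr::local_seed(13)
  fr <- default_fixture()$data$fragments
  n <- 300
  chroms <- sample(unique(fr$chrom), n, replace = TRUE)
  start <- sample(0:200000, n, replace = TRUE)
  width <- sample(1:10000, n, replace = TRUE)
  got <- assign_fragments(chroms, start, start + width, fr)
  for (i in seq_len(n)) {
    expect_setequal(got[[i]],
      scan_fragments(chroms[i], start[i], start[i] + width[i], fr))
  }
})

test_that("fragment state calls follow the configured state sets", {
  fr <- mini_fragments()
  calls <- call_fragment_states(fr, mini_segments())
  expect_equal(calls$has_enhancer, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$has_promoter, c(FALSE, FALSE, TRUE, FALSE))

  both <- tibble::tibble(
    chrom = "chr1", start = c(0, 2000), end = c(2000, 4000),
    state = c("1_TssA", "7_Enh"), cell_type = "Tcell"
  )
  calls2 <- call_fragment_states(fr, both)
  expect_true(calls2$has_enhancer[1] && calls2$has_promoter[1])

  expect_warning(
    calls3 <- call_fragment_states(fr, mini_segments(states = rep("99_Odd", 4))),
    "unknown"
  )
  expect_false(any(calls3$has_enhancer) || any(calls3$has_promoter))
})

test_that("min_overlap filters marginal state overlaps", {
  fr <- mini_fragments()
  sliver <- tibble::tibble(
    chrom = "chr1", start = 3990, end = 4000, state = "7_Enh",
    cell_type = "Tcell"
  )
  expect_true(call_fragment_states(fr, sliver)$has_enhancer[1])
  expect_false(call_fragment_states(fr, sliver,
    min_overlap = 50)$has_enhancer[1])
})

test_that("the interaction filter keeps only the expressed enhancer-promoter gene", {
  # three interactions from the SNP fragment F1 (enhancer): F1-F2 has no
  # promoter, F1-F3 holds an expressed gene, F1-F4 holds an unexpressed one;
  # only the F3 gene survives
  fr <- mini_fragments()
  segments <- mini_segments(states = c("7_Enh", "15_Quies", "1_TssA", "1_TssA"))
  genes <- tibble::tibble(
    gene_id = c("GENE1", "GENE2", "GENE3"),
    chrom = "chr1",
    start = c(5000, 9000, 13000), end = c(7000, 11000, 15000),
    strand = "+",
    tss = c(5000, 9000, 13000)
  )
  expression <- tibble::tibble(
    gene_id = c("GENE1", "GENE2", "GENE3"),
    cell_type = "Tcell",
    value = c(10, 8, 0)
  )
  snps <- tibble::tibble(
    snp_id = "rs1", chrom = "chr1", pos = 2000, r2 = 1,
    index_snp_id = "rs1", disease = "RA"
  )
  interactions <- dplyr::bind_rows(
    mini_interaction("F1", "F2"),
    mini_interaction("F1", "F3"),
    mini_interaction("F1", "F4")
  )
  blocks <- build_ld_blocks(snps, fr)
  calls <- call_fragment_states(fr, segments)
  cand <- filter_candidates(blocks, interactions, calls, genes,
    expression, fr)
  expect_equal(cand$gene_id, "GENE2")
  expect_equal(cand$index_snp_id, "rs1")
  expect_equal(cand$cell_types[[1]], "Tcell")
  expect_equal(cand$evidence[[1]]$promoter_fragment, "F3")

  # enhancer on both ends but no promoter: nothing survives
  enh_only <- mini_segments(states = c("7_Enh", "15_Quies", "7_Enh", "15_Quies"))
  cand2 <- filter_candidates(blocks, interactions,
    call_fragment_states(fr, enh_only), genes, expression, fr)
  expect_equal(nrow(cand2), 0)

  # sub-threshold scores drop out
  cand3 <- filter_candidates(blocks, interactions, calls, genes, expression,
    fr, score_threshold = 10)
  expect_equal(nrow(cand3), 0)
})

test_that("state filtering requires enhancer and promoter in the same cell type", {
  fr <- mini_fragments()
  segments <- dplyr::bind_rows(
    mini_segments(states = c("7_Enh", "15_Quies", "15_Quies", "15_Quies"),
      cell_type = "Tcell"),
    mini_segments(states = c("15_Quies", "15_Quies", "1_TssA", "15_Quies"),
      cell_type = "GM12878")
  )
  genes <- tibble::tibble(gene_id = "GENE1", chrom = "chr1", start = 9000,
    end = 11000, strand = "+", tss = 9000)
  expression <- tibble::tibble(gene_id = "GENE1",
    cell_type = c("Tcell", "GM12878"), value = 10)
  snps <- tibble::tibble(snp_id = "rs1", chrom = "chr1", pos = 2000, r2 = 1,
    index_snp_id = "rs1", disease = "RA")
  interactions <- dplyr::bind_rows(
    mini_interaction("F1", "F3", cell_type = "Tcell"),
    mini_interaction("F1", "F3", cell_type = "GM12878")
  )
  cand <- filter_candidates(build_ld_blocks(snps, fr), interactions,
    call_fragment_states(fr, segments), genes, expression, fr)
  # enhancer only in Tcell, promoter only in GM12878: no same-cell-type pair
  expect_equal(nrow(cand), 0)
})

test_that("pooled candidates equal the union of per-cell-type runs", {
  fx <- default_fixture()
  data <- fx$data
  pooled <- run_pipeline(data)$candidates
  per_ct <- lapply(c("GM12878", "Tcell"), function(ct) {
    d <- data
    d$segments <- d$segments[d$segments$cell_type == ct, ]
    d$interactions <- d$interactions[d$interactions$cell_type == ct, ]
    d$expression <- d$expression[d$expression$cell_type == ct, ]
    run_pipeline(d)$candidates
  })
  key <- function(x) unique(paste(x$disease, x$index_snp_id, x$gene_key))
  expect_setequal(key(pooled), union(key(per_ct[[1]]), key(per_ct[[2]])))
})

test_that("every candidate's evidence re-validates under the brute-force checker", {
  fx <- default_fixture()
  brute <- brute_force_candidates(fx$data)
  got <- candidate_sets(default_result()$candidates)
  for (key in names(got)) {
    expect_true(all(sort(unique(got[[key]])) %in% brute[[key]]), info = key)
  }
})
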