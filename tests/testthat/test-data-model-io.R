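test_that("fragment BED parsing enforces the partition invariant", {
  path <- withr::local_tempfile(lines = "chr1\t0\t4000\tF1")
  fr <- read_bed(path, "fragments")
  expect_equal(nrow(fr), 1)
  expect_equal(fr$start, 0)
  expect_equal(fr$end, 4000)
  expect_equal(fr$fragment_id, "F1")

  overlapping <- withr::local_tempfile(
    lines = c("chr1\t0\t4000\tF1", "chr1\t3000\t7000\tF2")
  )
  expect_error(read_bed(overlapping, "fragments"), "overlap")

  gapped <- withr::local_tempfile(
    lines = c("chr1\t0\t4000\tF1", "chr1\t5000\t7000\tF2")
  )
  expect_error(read_bed(gapped, "fragments"), "gap")

  malformed <- withr::local_tempfile(lines = "chr1\tx\t4000\tF1")
  expect_error(read_bed(malformed, "fragments"), ":1:")
})

test_that("random fragment maps survive a write/read round trip", {
  withr::local_seed(42)
  lens <- sample(500:8000, 1000, replace = TRUE)
  ends <- cumsum(lens)
  fr <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 500),
    start = c(ends[1:500] - lens[1:500],
      ends[501:1000] - ends[500] - lens[501:1000]),
    end = c(ends[1:500], ends[501:1000] - ends[500]),
    fragment_id = sprintf("F%04d", 1:1000)
  )
  path <- withr::local_tempfile()
  write_bed(fr, path, "fragments")
  expect_equal(read_bed(path, "fragments"), fr)
  # and the second write is byte-identical
  path2 <- withr::local_tempfile()
  write_bed(read_bed(path, "fragments"), path2, "fragments")
  expect_identical(readLines(path2), readLines(path))
})

test_that("gene BED derives the TSS from the strand", {
  path <- withr::local_tempfile(lines = c(
    "chr1\t100\t900\tGENEA\t0\t+",
    "chr1\t2000\t2500\tGENEB\t0\t-"
  ))
  genes <- read_bed(path, "genes")
  expect_equal(genes$tss, c(100, 2499))
  bad <- withr::local_tempfile(lines = "chr1\t100\t900\tGENEA\t0\t*")
  expect_error(read_bed(bad, "genes"), "strand")
})

test_that("interaction parsing resolves fragments and canonicalises pairs", {
  fr <- mini_fragments()
  path <- withr::local_tempfile()
  readr::write_tsv(mini_interaction("F1", "F3", score = 6.2), path)
  ints <- read_interactions(path, fr)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$bait_id, "F1")
  expect_equal(ints$oe_id, "F3")
  expect_equal(ints$score, 6.2)
  expect_equal(ints$cell_type, "Tcell")

  # flipped orientation resolves to the same canonical record
  readr::write_tsv(mini_interaction("F3", "F1", score = 6.2), path)
  expect_equal(read_interactions(path, fr), ints)

  # symmetric duplicates collapse to the strongest call
  readr::write_tsv(dplyr::bind_rows(
    mini_interaction("F1", "F3", score = 6.2),
    mini_interaction("F3", "F1", score = 7.5)
  ), path)
  expect_equal(read_interactions(path, fr)$score, 7.5)

  readr::write_tsv(mini_interaction("F1", "F1"), path)
  expect_error(read_interactions(path, fr), "same fragment")

  stray <- mini_interaction("F1", "F3")
  stray$oe_start <- 8100
  readr::write_tsv(stray, path)
  expect_error(read_interactions(path, fr), "8100")
})

test_that("random interaction tables survive a round trip", {
  withr::local_seed(7)
  fr <- default_fixture()$data$fragments
  idx <- matrix(sample(nrow(fr), 1000, replace = TRUE), ncol = 2)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE][1:400, ]
  ints <- tibble::tibble(
    bait_chrom = fr$chrom[idx[, 1]], bait_start = fr$start[idx[, 1]],
    bait_end = fr$end[idx[, 1]], bait_id = fr$fragment_id[idx[, 1]],
    oe_chrom = fr$chrom[idx[, 2]], oe_start = fr$start[idx[, 2]],
    oe_end = fr$end[idx[, 2]], oe_id = fr$fragment_id[idx[, 2]],
    score = round(runif(nrow(idx), 0, 12), 3),
    cell_type = sample(c("GM12878", "Tcell"), nrow(idx), replace = TRUE)
  )
  path <- withr::local_tempfile()
  write_interactions(ints, path)
  back <- read_interactions(path, fr)
  path2 <- withr::local_tempfile()
  write_interactions(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("GMT parsing validates gene lists and round-trips", {
  path <- withr::local_tempfile(
    lines = c("P1\tCD40 signalling\tTRAF1\tTRAF6", "P2\tOther\tIL6R")
  )
  gmt <- read_gmt(path)
  expect_equal(gmt$pathway_id, c("P1", "P2"))
  expect_equal(gmt$genes[[1]], c("TRAF1", "TRAF6"))

  empty <- withr::local_tempfile(lines = c("P1\tCD40 signalling"))
  expect_error(read_gmt(empty), "no genes")

  path2 <- withr::local_tempfile()
  write_gmt(gmt, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("typed TSV tables load with validation", {
  drugs <- withr::local_tempfile(lines = c(
    paste("drug_id", "drug_name", "gene_id", "groups", "indication",
      sep = "\t"),
    paste("DB00001", "adalimumab", "FCGR2A", "approved",
      "For the treatment of rheumatoid arthritis", sep = "\t")
  ))
  dt <- read_table(drugs, "drug_targets")
  expect_equal(dt$drug_name, "adalimumab")
  expect_equal(dt$gene_id, "FCGR2A")

  snps_bad <- withr::local_tempfile(lines = c(
    paste("snp_id", "chrom", "pos", "r2", "index_snp_id", "disease",
      sep = "\t"),
    paste("rs2", "chr1", "150", "0.9", "rs1", "RA", sep = "\t")
  ))
  expect_error(read_table(snps_bad, "snps"), "unknown index")

  snps_r2 <- withr::local_tempfile(lines = c(
    paste("snp_id", "chrom", "pos", "r2", "index_snp_id", "disease",
      sep = "\t"),
    paste("rs1", "chr1", "100", "1.2", "rs1", "RA", sep = "\t")
  ))
  expect_error(read_table(snps_r2, "snps"), "r2")
})
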