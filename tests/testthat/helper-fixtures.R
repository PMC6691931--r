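# Shared fixtures. The default study-sized fixture and its pipeline result
# are built once per test run and reused.

.cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.cache$fixture)) {
    .cache$fixture <- generate_fixture(fixture_config())
  }
  .cache$fixture
}

default_result <- function() {
  if (is.null(.cache$result)) {
    .cache$result <- run_pipeline(default_fixture()$data)
  }
  .cache$result
}

small_fixture <- function(...) {
  generate_fixture(fixture_config(
    n_loci = c(RA = 6L, JIA = 4L), n_background_pathways = 8L, ...
  ))
}

# a hand-built four-fragment world used by several unit tests
mini_fragments <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(0, 4000, 8000, 12000),
    end = c(4000, 8000, 12000, 16000),
    fragment_id = c("F1", "F2", "F3", "F4")
  )
}

mini_segments <- function(states = c("7_Enh", "15_Quies", "1_TssA", "15_Quies"),
                          cell_type = "Tcell") {
  fr <- mini_fragments()
  tibble::tibble(
    chrom = fr$chrom, start = fr$start, end = fr$end,
    state = states, cell_type = cell_type
  )
}

mini_interaction <- function(a, b, score = 6, cell_type = "Tcell") {
  fr <- mini_fragments()
  ia <- match(a, fr$fragment_id)
  ib <- match(b, fr$fragment_id)
  tibble::tibble(
    bait_chrom = "chr1", bait_start = fr$start[ia], bait_end = fr$end[ia],
    bait_id = a,
    oe_chrom = "chr1", oe_start = fr$start[ib], oe_end = fr$end[ib],
    oe_id = b,
    score = score, cell_type = cell_type
  )
}
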