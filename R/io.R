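# Readers and writers for every on-disk format the pipeline touches. All BED
# files are 0-based half-open; TSV tables are headered; writers emit a fixed
# column order and deterministic sort so reruns are byte-identical.

read_lines_checked <- function(path) {
  if (!file.exists(path)) {
    stop_validation("file not found: %s", path)
  }
  readLines(path, warn = FALSE)
}

parse_bed_fields <- function(path, min_fields) {
  lines <- read_lines_checked(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < min_fields) {
      stop_parse(path, keep[i], sprintf(
        "expected >= %d tab-separated fields, got %d", min_fields, length(f)
      ))
    }
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
      is.na(suppressWarnings(as.numeric(f[3])))) {
      stop_parse(path, keep[i], "non-numeric BED coordinates")
    }
  }
  fields
}

#' Read a BED file of restriction fragments, state segments or genes
#'
#' Three BED dialects share a parser: restriction-fragment maps
#' (`chrom start end fragment_id`), ChromHMM-style segmentations
#' (`chrom start end state`, with the cell type supplied by the caller since
#' Roadmap files are per cell type), and gene annotations
#' (`chrom start end gene_id score strand`, from which the transcription start
#' site is derived as the strand-aware 5' end of the body).
#'
#' @param path Path to a BED file (0-based half-open coordinates).
#' @param kind One of `"fragments"`, `"segments"`, `"genes"`.
#' @param cell_type Cell-type label attached to every segment
#'   (required for `kind = "segments"`).
#' @return A tibble of typed records sorted by (chrom, start). Fragment maps
#'   are checked against the partition invariant (sorted, non-overlapping,
#'   gap-free per chromosome).
#' @export
read_bed <- function(path, kind = c("fragments", "segments", "genes"),
                     cell_type = NULL) {
  kind <- match.arg(kind)
  min_fields <- switch(kind, fragments = 4L, segments = 4L, genes = 6L)
  fields <- parse_bed_fields(path, min_fields)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  name <- vapply(fields, `[`, "", 4L)
  out <- switch(kind,
    fragments = {
      fr <- tibble::tibble(
        chrom = chrom, start = start, end = end, fragment_id = name
      )
      validate_fragments(fr)
    },
    segments = {
      if (is.null(cell_type)) {
        stop_validation("cell_type is required when reading state segments")
      }
      seg <- tibble::tibble(
        chrom = chrom, start = start, end = end,
        state = name, cell_type = cell_type
      )
      validate_segments(seg)
    },
    genes = {
      strand <- vapply(fields, `[`, "", 6L)
      if (any(!strand %in% c("+", "-"))) {
        bad <- which(!strand %in% c("+", "-"))[1]
        stop_parse(path, bad, "gene strand must be '+' or '-'")
      }
      genes <- tibble::tibble(
        gene_id = name, chrom = chrom, start = start, end = end,
        strand = strand,
        tss = ifelse(strand == "+", start, end - 1)
      )
      validate_genes(genes)
    }
  )
  dplyr::arrange(tibble::as_tibble(out), .data$chrom, .data$start)
}

#' Write fragments, segments or genes back to BED
#'
#' @param x Tibble as returned by [read_bed()].
#' @param path Output path.
#' @param kind One of `"fragments"`, `"segments"`, `"genes"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, kind = c("fragments", "segments", "genes")) {
  kind <- match.arg(kind)
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  lines <- switch(kind,
    fragments = sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
      as.integer(x$end), x$fragment_id),
    segments = sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
      as.integer(x$end), x$state),
    genes = sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
      as.integer(x$end), x$gene_id, x$strand)
  )
  writeLines(lines, path)
  invisible(path)
}

canonicalize_interactions <- function(x) {
  flip <- x$oe_chrom < x$bait_chrom |
    (x$oe_chrom == x$bait_chrom & x$oe_start < x$bait_start)
  flipped <- x
  flipped[flip, c("bait_chrom", "bait_start", "bait_end", "bait_id")] <-
    x[flip, c("oe_chrom", "oe_start", "oe_end", "oe_id")]
  flipped[flip, c("oe_chrom", "oe_start", "oe_end", "oe_id")] <-
    x[flip, c("bait_chrom", "bait_start", "bait_end", "bait_id")]
  # symmetric duplicates collapse to the strongest call
  flipped %>%
    dplyr::group_by(.data$bait_id, .data$oe_id, .data$cell_type) %>%
    dplyr::summarise(
      dplyr::across(c("bait_chrom", "bait_start", "bait_end",
        "oe_chrom", "oe_start", "oe_end"), dplyr::first),
      score = max(.data$score),
      .groups = "drop"
    ) %>%
    dplyr::select(dplyr::all_of(INTERACTION_COLS)) %>%
    dplyr::arrange(
      .data$bait_chrom, .data$bait_start, .data$oe_chrom, .data$oe_start,
      .data$cell_type
    )
}

#' Read CHICAGO-style interaction calls
#'
#' Expects a headered, ibed-like TSV with columns `bait_chrom bait_start
#' bait_end bait_id oe_chrom oe_start oe_end oe_id score cell_type`. Both ends
#' are resolved against the supplied restriction-fragment map; unresolvable
#' coordinates are an error naming the offending fragment. Interactions are
#' treated as unordered pairs: each is normalised so the lower-coordinate
#' fragment comes first, and symmetric duplicates within a cell type collapse
#' to the call with the larger score.
#'
#' @param path Path to the interaction TSV.
#' @param fragments Validated fragment map ([read_bed()] with
#'   `kind = "fragments"`).
#' @return Tibble of interactions with resolved fragment ids, sorted
#'   canonically. Scores are kept as-is; significance thresholding is a
#'   pipeline parameter, not a loader concern.
#' @export
read_interactions <- function(path, fragments) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    bait_chrom = "c", bait_start = "d", bait_end = "d", bait_id = "c",
    oe_chrom = "c", oe_start = "d", oe_end = "d", oe_id = "c",
    score = "d", cell_type = "c"
  ))
  check_columns(x, INTERACTION_COLS, "interaction table")
  if (any(x$score < 0)) {
    stop_validation("interaction table: negative score")
  }
  same <- x$bait_id == x$oe_id
  if (any(same)) {
    stop_validation(
      "interaction table: bait and other end are the same fragment ('%s')",
      x$bait_id[same][1]
    )
  }
  key <- function(chrom, start, end, id) paste(chrom, start, end, id)
  frag_keys <- key(fragments$chrom, fragments$start, fragments$end,
    fragments$fragment_id)
  for (side in c("bait", "oe")) {
    k <- key(x[[paste0(side, "_chrom")]], x[[paste0(side, "_start")]],
      x[[paste0(side, "_end")]], x[[paste0(side, "_id")]])
    bad <- which(!(k %in% frag_keys))
    if (length(bad) > 0) {
      stop_validation(
        "interaction table: %s fragment %s:%d-%d (%s) not in fragment map",
        side, x[[paste0(side, "_chrom")]][bad[1]],
        x[[paste0(side, "_start")]][bad[1]], x[[paste0(side, "_end")]][bad[1]],
        x[[paste0(side, "_id")]][bad[1]]
      )
    }
  }
  canonicalize_interactions(x)
}

#' Write interaction calls
#' @param x Interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  x <- canonicalize_interactions(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `pathway_id TAB name TAB gene TAB gene ...`. A pathway with
#' an empty gene list is a validation error.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `pathway_id`, `name` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 3) {
      stop_parse(path, i, "GMT line has no genes")
    }
  }
  tibble::tibble(
    pathway_id = vapply(fields, `[`, "", 1L),
    name = vapply(fields, `[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#' @param pathways Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$name[i],
      pathways$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

table_schemas <- function() {
  list(
    snps = readr::cols(
      snp_id = "c", chrom = "c", pos = "d", r2 = "d",
      index_snp_id = "c", disease = "c"
    ),
    expression = readr::cols(gene_id = "c", cell_type = "c", value = "d"),
    drug_targets = readr::cols(
      drug_id = "c", drug_name = "c", gene_id = "c",
      groups = "c", indication = "c"
    ),
    reported_genes = readr::cols(
      index_snp_id = "c", disease = "c", reported_gene = "c"
    )
  )
}

#' Read a headered TSV table of SNPs, expression, drug targets or reported genes
#'
#' SNP positions are 1-based (dbSNP convention). The drug table follows a
#' flat, DrugBank-like layout: one row per drug x target gene, with
#' `groups` a comma-separated set of approval statuses and `indication`
#' free text (possibly empty). `reported_gene` may hold several
#' comma-separated symbols when the source GWAS named more than one gene for
#' a locus. Columns beyond the schema are preserved as annotations.
#'
#' @param path Path to the TSV file.
#' @param schema One of `"snps"`, `"expression"`, `"drug_targets"`,
#'   `"reported_genes"`.
#' @return A validated tibble.
#' @export
read_table <- function(path,
                       schema = c("snps", "expression", "drug_targets",
                         "reported_genes")) {
  schema <- match.arg(schema)
  spec <- table_schemas()[[schema]]
  x <- readr::read_tsv(path, col_types = spec,
    na = character())
  check_columns(x, names(spec$cols), sprintf("%s table", schema))
  switch(schema,
    snps = validate_snps(x),
    expression = {
      if (any(x$value < 0)) stop_validation("expression table: negative value")
    },
    drug_targets = validate_drug_table(x),
    reported_genes = NULL
  )
  x
}

#' Write a TSV table with deterministic column order and sort
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  sort_cols <- intersect(
    c("disease", "index_snp_id", "snp_id", "chrom", "pos", "drug_id",
      "gene_id", "cell_type", "pathway_id"),
    names(x)
  )
  if (length(sort_cols) > 0) {
    x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(sort_cols)))
  }
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read disease-name variant sets
#'
#' YAML mapping from disease code to the list of name variants searched for in
#' drug indication text, e.g. `RA: ["rheumatoid arthritis", ...]`. Terms are
#' lower-cased at load.
#'
#' @param path Path to the YAML file.
#' @return Named list of lower-cased character vectors.
#' @export
read_disease_terms <- function(path) {
  terms <- yaml::read_yaml(path)
  if (length(terms) == 0) stop_validation("disease-term file is empty")
  out <- lapply(terms, function(t) tolower(trimws(unlist(t))))
  if (any(vapply(out, length, 1L) == 0)) {
    stop_validation("disease-term set with no terms")
  }
  out
}
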