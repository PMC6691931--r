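#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# Column contracts for each tabular record type. All genomic coordinates held
# in memory are 0-based half-open (BED convention); SNP positions are the one
# exception and stay 1-based (dbSNP convention), converted only at the point
# of interval overlap.

FRAGMENT_COLS <- c("chrom", "start", "end", "fragment_id")
SEGMENT_COLS <- c("chrom", "start", "end", "state", "cell_type")
GENE_COLS <- c("gene_id", "chrom", "start", "end", "strand", "tss")
SNP_COLS <- c("snp_id", "chrom", "pos", "r2", "index_snp_id", "disease")
EXPRESSION_COLS <- c("gene_id", "cell_type", "value")
INTERACTION_COLS <- c(
  "bait_chrom", "bait_start", "bait_end", "bait_id",
  "oe_chrom", "oe_start", "oe_end", "oe_id",
  "score", "cell_type"
)
DRUG_COLS <- c("drug_id", "drug_name", "gene_id", "groups", "indication")

#' Default chromatin-state vocabularies
#'
#' Role-specific subsets of the Roadmap Epigenomics 15-state ChromHMM
#' mnemonics. `enhancer` and `promoter` are the defaults used when deciding
#' whether a restriction fragment carries enhancer or promoter (TSS) activity;
#' both are ordinary character vectors and can be replaced wholesale in any
#' configuration.
#'
#' @return Named list with elements `all` (the 15 mnemonics), `enhancer` and
#'   `promoter`.
#' @examples
#' chromhmm_states()$enhancer
#' @export
chromhmm_states <- function() {
  list(
    all = c(
      "1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG",
      "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk",
      "12_EnhBiv", "13_ReprPC", "14_ReprPCWk", "15_Quies"
    ),
    enhancer = c("6_EnhG", "7_Enh", "12_EnhBiv"),
    promoter = c("1_TssA", "2_TssAFlnk", "10_TssBiv")
  )
}

stop_parse <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", path, line, msg), class = "chic2drug_parse_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "chic2drug_validation_error")
}

check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop_validation(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    )
  }
  invisible(x)
}

check_intervals <- function(x, what) {
  bad <- which(!(x$end > x$start))
  if (length(bad) > 0) {
    stop_validation("%s: interval end must exceed start (row %d)", what, bad[1])
  }
  if (any(!nzchar(x$chrom))) {
    stop_validation("%s: empty chromosome name", what)
  }
  invisible(x)
}

#' Validate a restriction-fragment map
#'
#' Fragments must, within each chromosome, be sorted, non-overlapping and tile
#' the covered region without gaps, and carry unique fragment identifiers.
#'
#' @param fragments Tibble with columns `chrom`, `start`, `end`, `fragment_id`.
#' @return The input, invisibly, sorted by (chrom, start); errors otherwise.
#' @export
validate_fragments <- function(fragments) {
  check_columns(fragments, FRAGMENT_COLS, "fragment map")
  check_intervals(fragments, "fragment map")
  if (anyDuplicated(fragments$fragment_id)) {
    dup <- fragments$fragment_id[duplicated(fragments$fragment_id)][1]
    stop_validation("fragment map: duplicate fragment_id '%s'", dup)
  }
  fragments <- dplyr::arrange(fragments, .data$chrom, .data$start)
  by_chrom <- split(fragments, fragments$chrom)
  for (fr in by_chrom) {
    if (nrow(fr) < 2) next
    gap <- fr$start[-1] - fr$end[-nrow(fr)]
    if (any(gap < 0)) {
      i <- which(gap < 0)[1]
      stop_validation(
        "fragment map: fragments %s and %s overlap on %s",
        fr$fragment_id[i], fr$fragment_id[i + 1], fr$chrom[1]
      )
    }
    if (any(gap > 0)) {
      i <- which(gap > 0)[1]
      stop_validation(
        "fragment map: gap between fragments %s and %s on %s",
        fr$fragment_id[i], fr$fragment_id[i + 1], fr$chrom[1]
      )
    }
  }
  invisible(fragments)
}

validate_segments <- function(segments) {
  check_columns(segments, SEGMENT_COLS, "state segmentation")
  check_intervals(segments, "state segmentation")
  for (ct in unique(segments$cell_type)) {
    seg <- dplyr::arrange(
      segments[segments$cell_type == ct, ], .data$chrom, .data$start
    )
    by_chrom <- split(seg, seg$chrom)
    for (s in by_chrom) {
      if (nrow(s) < 2) next
      if (any(s$start[-1] < s$end[-nrow(s)])) {
        stop_validation(
          "state segmentation: overlapping segments for cell type '%s' on %s",
          ct, s$chrom[1]
        )
      }
    }
  }
  invisible(segments)
}

validate_snps <- function(snps) {
  check_columns(snps, SNP_COLS, "SNP table")
  if (any(snps$r2 < 0 | snps$r2 > 1)) {
    stop_validation("SNP table: r2 outside [0, 1]")
  }
  is_index <- snps$snp_id == snps$index_snp_id
  if (any(is_index & snps$r2 != 1)) {
    stop_validation("SNP table: an index SNP must have r2 = 1 with itself")
  }
  known <- paste(snps$snp_id[is_index], snps$disease[is_index])
  ref <- paste(snps$index_snp_id, snps$disease)
  if (!all(ref %in% known)) {
    bad <- snps$index_snp_id[!(ref %in% known)][1]
    stop_validation("SNP table: proxy references unknown index SNP '%s'", bad)
  }
  invisible(snps)
}

validate_genes <- function(genes) {
  check_columns(genes, GENE_COLS, "gene table")
  check_intervals(genes, "gene table")
  inside <- genes$tss >= genes$start & genes$tss < genes$end
  if (any(!inside)) {
    stop_validation(
      "gene table: TSS outside gene body for '%s'",
      genes$gene_id[!inside][1]
    )
  }
  invisible(genes)
}

validate_drug_table <- function(drugs) {
  check_columns(drugs, DRUG_COLS, "drug-target table")
  key <- paste(drugs$drug_id, tolower(drugs$gene_id))
  if (anyDuplicated(key)) {
    stop_validation(
      "drug-target table: duplicate drug/gene pair '%s'",
      key[duplicated(key)][1]
    )
  }
  invisible(drugs)
}

#' Normalise a gene symbol for matching
#'
#' Symbols are compared case-insensitively after trimming whitespace, so that
#' e.g. "Pgap3" and "PGAP3" refer to the same gene.
#'
#' @param x Character vector of gene symbols.
#' @return Normalised symbols (upper case, trimmed).
#' @export
normalize_symbol <- function(x) {
  toupper(trimws(x))
}
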