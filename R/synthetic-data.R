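# Deterministic synthetic-data generator. Every locus is built to one of
# eight archetypes so each branch of the filtering strategy has loci with a
# known outcome:
#   POSITIVE        enhancer SNP fragment, interacting promoter fragment,
#                   expressed gene; the reported GWAS gene is NOT recovered
#   NO_ENHANCER     the SNP fragment carries no enhancer state
#   NO_PROMOTER     the partner fragment carries no promoter state
#   NOT_EXPRESSED   the gene falls below the expression threshold everywhere
#   NO_INTERACTION  the interaction score is below the significance threshold
#   REPORTED_ONLY   single candidate equal to the reported gene
#   REPORTED_MULTI  reported gene among 3 candidates (incl. a multi-gene
#                   promoter fragment)
#   REPORTED_MANY   reported gene among 6 candidates
# The last three vary candidate counts so every locus-agreement category
# (1, 2-5, 6+) is populated; POSITIVE populates category 0 and the four
# failure archetypes populate NO_CHIC_GENES.

ARCHETYPES <- c(
  "POSITIVE", "NO_ENHANCER", "NO_PROMOTER", "NOT_EXPRESSED",
  "NO_INTERACTION", "REPORTED_ONLY", "REPORTED_MULTI", "REPORTED_MANY"
)

# fragment slots used inside each locus block (1-based within the block)
LOCUS_LAYOUT <- list(
  snp = 10L, filler = c(20L, 25L), distractor_gene = 30L,
  promoter_main = 40L, promoter_extra = c(42L, 44L, 46L, 48L, 50L)
)

#' Configuration for the synthetic fixture
#'
#' Defaults describe a study-sized fixture: three diseases with 30/16/14
#' loci, eight LD proxies per locus, ~4 kb restriction fragments (the CHi-C
#' resolution scale), two cell types, an LD cut of r-squared >= 0.8, an
#' interaction-score cut of 5 and an expression cut of 1.
#'
#' @param n_loci Named integer vector: loci per disease.
#' @param n_proxies LD proxies simulated per index SNP, placed within
#'   +/- 50 kb with r-squared uniform on `[0.5, 1]` so the 0.8 cut is
#'   exercised on both sides.
#' @param fragment_mean_bp Mean restriction-fragment length (default 4000).
#' @param locus_fragments Fragments allocated per locus block (default 60).
#' @param r2_threshold,score_threshold,expression_threshold The pipeline
#'   thresholds the fixture is built around.
#' @param cell_types Two cell-type labels (default GM12878 and Tcell).
#' @param archetype_mix Named proportions over the eight locus archetypes;
#'   must sum to 1.
#' @param n_background_pathways Unenriched pathways drawn from a background
#'   gene pool (default 25).
#' @param pathway_extra_genes Non-candidate genes added to each planted
#'   enriched pathway (default 6), giving the pathway-expansion step
#'   something to find.
#' @param multi_gene_promoter Plant a second TSS in the main promoter
#'   fragment of REPORTED_MULTI loci (default `TRUE`).
#' @param seed RNG seed; identical config + seed gives byte-identical output.
#' @return A validated configuration list of class `fixture_config`.
#' @export
fixture_config <- function(n_loci = c(RA = 30L, PsA = 16L, JIA = 14L),
                           n_proxies = 8L,
                           fragment_mean_bp = 4000,
                           locus_fragments = 60L,
                           r2_threshold = 0.8,
                           score_threshold = 5,
                           expression_threshold = 1,
                           cell_types = c("GM12878", "Tcell"),
                           archetype_mix = c(
                             POSITIVE = 0.15, NO_ENHANCER = 0.12,
                             NO_PROMOTER = 0.12, NOT_EXPRESSED = 0.12,
                             NO_INTERACTION = 0.12, REPORTED_ONLY = 0.13,
                             REPORTED_MULTI = 0.14, REPORTED_MANY = 0.10
                           ),
                           n_background_pathways = 25L,
                           pathway_extra_genes = 6L,
                           multi_gene_promoter = TRUE,
                           seed = 1L) {
  config <- list(
    n_loci = n_loci, n_proxies = as.integer(n_proxies),
    fragment_mean_bp = fragment_mean_bp,
    locus_fragments = as.integer(locus_fragments),
    r2_threshold = r2_threshold, score_threshold = score_threshold,
    expression_threshold = expression_threshold, cell_types = cell_types,
    archetype_mix = archetype_mix,
    n_background_pathways = as.integer(n_background_pathways),
    pathway_extra_genes = as.integer(pathway_extra_genes),
    multi_gene_promoter = isTRUE(multi_gene_promoter),
    seed = as.integer(seed)
  )
  if (is.null(names(config$n_loci)) || any(config$n_loci < 0)) {
    stop_validation("n_loci must be a named vector of non-negative counts")
  }
  if (!setequal(names(config$archetype_mix), ARCHETYPES)) {
    stop_validation("archetype_mix must name exactly the known archetypes")
  }
  if (abs(sum(config$archetype_mix) - 1) > 1e-8 ||
    any(config$archetype_mix < 0)) {
    stop_validation("archetype_mix proportions must be non-negative and sum to 1")
  }
  if (config$locus_fragments < max(LOCUS_LAYOUT$promoter_extra) + 2L) {
    stop_validation(
      "locus_fragments too small to hold the locus layout (need >= %d)",
      max(LOCUS_LAYOUT$promoter_extra) + 2L
    )
  }
  if (config$n_proxies < 0 || config$fragment_mean_bp < 1500) {
    stop_validation("infeasible fixture configuration")
  }
  if (length(config$cell_types) != 2) {
    stop_validation("exactly two cell types are supported by the generator")
  }
  structure(config, class = "fixture_config")
}

archetype_counts <- function(n, mix) {
  raw <- n * mix[ARCHETYPES]
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

disease_term_sets <- function(diseases) {
  defaults <- list(
    RA = c("rheumatoid arthritis"),
    PsA = c("psoriatic arthritis"),
    JIA = c("juvenile idiopathic arthritis", "juvenile arthritis")
  )
  out <- lapply(diseases, function(d) {
    if (!is.null(defaults[[d]])) defaults[[d]] else tolower(paste(d, "disease"))
  })
  stats::setNames(out, diseases)
}

#' Generate the complete synthetic dataset with planted ground truth
#'
#' Builds an internally consistent toy study: a restriction-fragment map
#' tiling one synthetic chromosome per disease, GWAS index SNPs with LD
#' proxies, ChromHMM-style state tracks for two cell types, genes with TSS
#' annotations, an expression table, interaction calls, a DrugBank-like
#' drug-target table, disease-name variant sets, and a pathway collection
#' with one guaranteed-enriched pathway per disease. The returned ground
#' truth records, for every locus, the archetype, the candidate genes the
#' filter must recover and the expected locus-agreement category; for every
#' pathway whether it is enriched; and for every drug whether it should come
#' out currently-used, repositionable, or absent.
#'
#' @param config A [fixture_config()].
#' @return List with elements `data` (all input tibbles/lists), `truth`
#'   (`loci`, `pathways`, `drugs`, `refinement`) and `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, build_fixture(config))
}

build_fixture <- function(config) {
  diseases <- names(config$n_loci)
  cts <- config$cell_types
  L <- config$locus_fragments
  enh_set <- chromhmm_states()$enhancer
  prom_set <- chromhmm_states()$promoter

  frag_list <- list(); seg_list <- list(); gene_list <- list()
  expr_list <- list(); int_list <- list(); snp_list <- list()
  reported_list <- list(); truth_loci <- list()
  locus_counter <- 0L

  for (di in seq_along(diseases)) {
    d <- diseases[di]
    n <- config$n_loci[[d]]
    if (n == 0) next
    chrom <- sprintf("chr%d", di)
    archetypes <- sample(rep(ARCHETYPES, archetype_counts(n, config$archetype_mix)))

    lens <- pmax(1500, round(stats::rnorm(n * L, config$fragment_mean_bp,
      config$fragment_mean_bp / 6)))
    ends <- cumsum(lens)
    starts <- ends - lens
    frag_ids <- sprintf("%s_F%05d", chrom, seq_len(n * L))
    frag_list[[d]] <- tibble::tibble(
      chrom = chrom, start = starts, end = ends, fragment_id = frag_ids
    )
    chrom_len <- ends[length(ends)]
    fr <- function(slot) {
      list(start = starts[slot], end = ends[slot], id = frag_ids[slot])
    }

    for (li in seq_len(n)) {
      locus_counter <- locus_counter + 1L
      base <- (li - 1L) * L
      arch <- archetypes[li]
      index_id <- sprintf("rs%d", 100000L + locus_counter)
      gid <- function(j) sprintf("%s_L%02d_G%d", d, li, j)

      has_enh <- !(arch == "NO_ENHANCER")
      has_prom <- !(arch == "NO_PROMOTER")
      expressed <- !(arch == "NOT_EXPRESSED")
      interacting <- !(arch == "NO_INTERACTION")
      n_extra <- switch(arch, REPORTED_MULTI = 2L, REPORTED_MANY = 5L, 0L)

      # SNPs: index in the middle of the SNP fragment, proxies within 50 kb
      snp_frag <- fr(base + LOCUS_LAYOUT$snp)
      index_pos <- floor((snp_frag$start + snp_frag$end) / 2) + 1L
      proxy_pos <- pmin(pmax(index_pos +
        sample(-50000:50000, config$n_proxies, replace = TRUE), 1L), chrom_len)
      snp_list[[locus_counter]] <- tibble::tibble(
        snp_id = c(index_id, sprintf("%s_p%02d", index_id,
          seq_len(config$n_proxies))),
        chrom = chrom,
        pos = c(index_pos, proxy_pos),
        r2 = c(1, round(stats::runif(config$n_proxies, 0.5, 1), 4)),
        index_snp_id = index_id,
        disease = d
      )

      # chromatin states, identical structure in both cell types
      enh_state <- if (has_enh) enh_set[1 + (li %% length(enh_set))] else "15_Quies"
      prom_state <- if (has_prom) prom_set[1 + (li %% length(prom_set))] else "15_Quies"
      prom_slots <- base + c(LOCUS_LAYOUT$promoter_main,
        utils::head(LOCUS_LAYOUT$promoter_extra, n_extra))
      seg_rows <- lapply(cts, function(ct) {
        tibble::tibble(
          chrom = chrom,
          start = c(snp_frag$start, starts[base + LOCUS_LAYOUT$filler],
            starts[prom_slots]),
          end = c(snp_frag$end, ends[base + LOCUS_LAYOUT$filler],
            ends[prom_slots]),
          state = c(enh_state, "4_Tx", "9_Het",
            rep(prom_state, length(prom_slots))),
          cell_type = ct
        )
      })
      seg_list[[length(seg_list) + 1L]] <- dplyr::bind_rows(seg_rows)

      # genes: main candidate, extras, plus a non-interacting distractor
      multi <- arch == "REPORTED_MULTI" && config$multi_gene_promoter
      gene_specs <- list(list(id = gid(1),
        slot = base + LOCUS_LAYOUT$promoter_main, offset = 500L, ct = "both"))
      if (n_extra > 0) {
        for (j in seq_len(n_extra)) {
          slot <- if (multi && j == 1) {
            base + LOCUS_LAYOUT$promoter_main
          } else {
            base + LOCUS_LAYOUT$promoter_extra[j]
          }
          offset <- if (multi && j == 1) 700L else 500L
          gene_specs[[j + 1]] <- list(
            id = gid(j + 1), slot = slot, offset = offset,
            ct = c("both", cts)[1 + (j %% 3)]
          )
        }
      }
      distractor_id <- sprintf("%s_L%02d_GX", d, li)
      gene_specs[[length(gene_specs) + 1]] <- list(
        id = distractor_id, slot = base + LOCUS_LAYOUT$distractor_gene,
        offset = 500L, ct = "both"
      )
      gene_rows <- lapply(seq_along(gene_specs), function(gi) {
        gs <- gene_specs[[gi]]
        tss <- starts[gs$slot] + gs$offset
        strand <- if (gi %% 2 == 1) "+" else "-"
        tibble::tibble(
          gene_id = gs$id, chrom = chrom,
          start = if (strand == "+") tss else tss + 1L - 8000L,
          end = if (strand == "+") tss + 8000L else tss + 1L,
          strand = strand, tss = tss
        )
      })
      gene_list[[length(gene_list) + 1L]] <- dplyr::bind_rows(gene_rows)

      # expression: candidates expressed per their cell-type spec (unless the
      # archetype plants them below threshold); distractor always expressed
      expr_rows <- lapply(gene_specs, function(gs) {
        on <- expressed || gs$id == distractor_id
        vals <- vapply(cts, function(ct) {
          if (on && (gs$ct == "both" || gs$ct == ct)) {
            round(stats::runif(1, 5, 100), 3)
          } else {
            0.2
          }
        }, 0)
        tibble::tibble(gene_id = gs$id, cell_type = cts, value = vals)
      })
      expr_list[[length(expr_list) + 1L]] <- dplyr::bind_rows(expr_rows)

      # interactions: SNP fragment <-> each promoter fragment, plus one
      # distractor pair with no regulatory states
      thr <- config$score_threshold
      int_rows <- lapply(gene_specs[seq_len(1 + n_extra)], function(gs) {
        int_cts <- if (gs$ct == "both") cts else gs$ct
        pf <- fr(gs$slot)
        tibble::tibble(
          bait_chrom = chrom, bait_start = snp_frag$start,
          bait_end = snp_frag$end, bait_id = snp_frag$id,
          oe_chrom = chrom, oe_start = pf$start, oe_end = pf$end,
          oe_id = pf$id,
          score = if (interacting) {
            round(stats::runif(length(int_cts), thr + 0.5, thr + 5), 3)
          } else {
            round(stats::runif(length(int_cts), 0.5, max(thr - 0.5, 0.6)), 3)
          },
          cell_type = int_cts
        )
      })
      f20 <- fr(base + LOCUS_LAYOUT$filler[1])
      f25 <- fr(base + LOCUS_LAYOUT$filler[2])
      int_rows[[length(int_rows) + 1L]] <- tibble::tibble(
        bait_chrom = chrom, bait_start = f20$start, bait_end = f20$end,
        bait_id = f20$id, oe_chrom = chrom, oe_start = f25$start,
        oe_end = f25$end, oe_id = f25$id,
        score = round(stats::runif(length(cts), thr + 0.5, thr + 5), 3),
        cell_type = cts
      )
      int_rows <- dplyr::bind_rows(int_rows)
      # collapse duplicate pairs from shared promoter fragments (multi-gene)
      int_rows <- int_rows %>%
        dplyr::group_by(.data$bait_id, .data$oe_id, .data$cell_type) %>%
        dplyr::slice(1) %>%
        dplyr::ungroup()
      if (locus_counter %% 2 == 0) {
        # write half the loci in the flipped orientation; the loader
        # canonicalises unordered pairs
        int_rows <- int_rows %>% dplyr::rename(
          bait_chrom = "oe_chrom", bait_start = "oe_start",
          bait_end = "oe_end", bait_id = "oe_id",
          oe_chrom = "bait_chrom", oe_start = "bait_start",
          oe_end = "bait_end", oe_id = "bait_id"
        )
      }
      int_list[[length(int_list) + 1L]] <- int_rows

      # reported GWAS gene and the locus ground truth
      expected <- switch(arch,
        POSITIVE = gid(1),
        REPORTED_ONLY = gid(1),
        REPORTED_MULTI = c(gid(1), gid(2), gid(3)),
        REPORTED_MANY = sprintf("%s_L%02d_G%d", d, li, 1:6),
        character(0)
      )
      reported <- switch(arch,
        POSITIVE = distractor_id,
        REPORTED_ONLY = if (li %% 3 == 0) tolower(gid(1)) else gid(1),
        REPORTED_MULTI = if (li %% 4 == 0) {
          paste(distractor_id, gid(1), sep = ",")
        } else {
          gid(1)
        },
        gid(1)
      )
      expected_category <- switch(arch,
        POSITIVE = "0", REPORTED_ONLY = "1", REPORTED_MULTI = "2-5",
        REPORTED_MANY = "6+", "NO_CHIC_GENES"
      )
      reported_list[[locus_counter]] <- tibble::tibble(
        index_snp_id = index_id, disease = d, reported_gene = reported
      )
      truth_loci[[locus_counter]] <- tibble::tibble(
        index_snp_id = index_id, disease = d, archetype = arch,
        expected_genes = list(normalize_symbol(expected)),
        expected_category = expected_category
      )
    }
  }

  truth_loci <- dplyr::bind_rows(truth_loci)
  data <- list(
    fragments = validate_fragments(dplyr::bind_rows(frag_list)),
    segments = dplyr::bind_rows(seg_list),
    genes = dplyr::bind_rows(gene_list),
    expression = dplyr::bind_rows(expr_list),
    interactions = canonicalize_interactions(dplyr::bind_rows(int_list)),
    snps = dplyr::bind_rows(snp_list),
    reported = dplyr::bind_rows(reported_list),
    disease_terms = disease_term_sets(diseases)
  )

  # drugs and pathways are built around the planted candidates
  kb <- build_knowledge_base(truth_loci, diseases, config)
  data$drug_table <- kb$drug_table
  data$pathways <- kb$pathways

  list(
    data = data,
    truth = list(
      loci = truth_loci,
      pathways = kb$truth_pathways,
      drugs = kb$truth_drugs,
      refinement = kb$truth_refinement
    ),
    config = config
  )
}

build_knowledge_base <- function(truth_loci, diseases, config) {
  drug_rows <- list(); truth_drugs <- list()
  planted_pathways <- list(); truth_refinement <- list()
  indications <- c(
    "Indicated for the treatment of melanoma.",
    "Used in the management of essential hypertension.",
    "",
    "Indicated for relapsing forms of multiple sclerosis."
  )
  for (d in diseases) {
    loci_d <- truth_loci[truth_loci$disease == d, ]
    cand <- unique(unlist(loci_d$expected_genes))
    pathway_cand <- unique(unlist(
      loci_d$expected_genes[loci_d$archetype %in%
        c("REPORTED_ONLY", "REPORTED_MULTI", "REPORTED_MANY")]
    ))
    distractors <- sprintf("%s_L%02d_GX", d,
      seq_len(min(2, config$n_loci[[d]])))
    extras <- sprintf("PWG_%s_%d", d, seq_len(config$pathway_extra_genes))
    term <- disease_term_sets(d)[[1]][1]

    pick <- function(i) cand[((i - 1) %% max(length(cand), 1)) + 1]
    rows <- list(); truths <- list()
    add_drug <- function(id, name, genes, indication, groups, expected) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        drug_id = id, drug_name = name, gene_id = genes,
        groups = groups, indication = indication
      )
      truths[[length(truths) + 1L]] <<- tibble::tibble(
        drug_id = id, disease = d, expected = expected
      )
    }
    if (length(cand) > 0) {
      for (i in 1:2) {
        add_drug(sprintf("DB_%s_CUR%d", d, i), sprintf("%s-current-%d", d, i),
          pick(i), sprintf("Indicated for the treatment of %s.", term),
          "approved", "current")
      }
      for (i in 1:3) {
        add_drug(sprintf("DB_%s_REP%d", d, i), sprintf("%s-repo-%d", d, i),
          pick(i + 2), indications[i],
          if (i == 3) "experimental" else "approved", "repositionable")
      }
      add_drug(sprintf("DB_%s_MULTI", d), sprintf("%s-multi", d),
        unique(c(pick(1), pick(4))), indications[4], "approved",
        "repositionable")
    }
    for (i in seq_along(distractors)) {
      add_drug(sprintf("DB_%s_ABS%d", d, i), sprintf("%s-absent-%d", d, i),
        distractors[i], sprintf("Indicated for the treatment of %s.", term),
        "approved", "absent")
    }
    for (i in 1:2) {
      add_drug(sprintf("DB_%s_PWY%d", d, i), sprintf("%s-pathway-%d", d, i),
        extras[i], "Indicated for the treatment of plaque psoriasis.",
        "approved", "absent")
    }
    drug_rows[[d]] <- dplyr::bind_rows(rows)
    truth_drugs[[d]] <- dplyr::bind_rows(truths)

    planted_pathways[[d]] <- tibble::tibble(
      pathway_id = sprintf("PW_%s", d),
      name = sprintf("%s planted signalling", d),
      genes = list(unique(c(pathway_cand, extras)))
    )
    truth_refinement[[d]] <- tibble::tibble(
      disease = d,
      refined_genes = list(sort(normalize_symbol(pathway_cand))),
      expanded_genes = list(sort(normalize_symbol(c(pathway_cand, extras))))
    )
  }

  bg_pool <- sprintf("BG%04d", seq_len(300))
  bg <- lapply(seq_len(config$n_background_pathways), function(k) {
    tibble::tibble(
      pathway_id = sprintf("PW_BG%02d", k),
      name = sprintf("Background pathway %02d", k),
      genes = list(sort(sample(bg_pool, sample(10:30, 1))))
    )
  })
  pathways <- dplyr::bind_rows(c(planted_pathways, bg))
  truth_pathways <- tibble::tibble(
    pathway_id = pathways$pathway_id,
    disease = c(diseases, rep(NA_character_, config$n_background_pathways)),
    enriched = c(rep(TRUE, length(diseases)),
      rep(FALSE, config$n_background_pathways))
  )
  list(
    drug_table = dplyr::bind_rows(drug_rows),
    pathways = pathways,
    truth_pathways = truth_pathways,
    truth_drugs = dplyr::bind_rows(truth_drugs),
    truth_refinement = dplyr::bind_rows(truth_refinement)
  )
}

#' Write a generated fixture to disk
#'
#' Emits every input file of the pipeline plus `ground_truth.json`. Output is
#' deterministic: the same fixture writes byte-identical files.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data <- fixture$data
  paths <- c(
    fragments = file.path(dir, "fragments.bed"),
    genes = file.path(dir, "genes.bed"),
    interactions = file.path(dir, "interactions.tsv"),
    snps = file.path(dir, "snps.tsv"),
    expression = file.path(dir, "expression.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    reported_genes = file.path(dir, "reported_genes.tsv"),
    disease_terms = file.path(dir, "disease_terms.yaml"),
    pathways = file.path(dir, "pathways.gmt"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_bed(data$fragments, paths[["fragments"]], "fragments")
  for (ct in unique(data$segments$cell_type)) {
    p <- file.path(dir, sprintf("segments_%s.bed", ct))
    write_bed(data$segments[data$segments$cell_type == ct, ], p, "segments")
    paths[[paste0("segments_", ct)]] <- p
  }
  write_bed(data$genes, paths[["genes"]], "genes")
  write_interactions(data$interactions, paths[["interactions"]])
  write_table(data$snps, paths[["snps"]])
  write_table(data$expression, paths[["expression"]])
  write_table(data$drug_table, paths[["drug_targets"]])
  write_table(data$reported, paths[["reported_genes"]])
  yaml::write_yaml(data$disease_terms, paths[["disease_terms"]])
  write_gmt(data$pathways, paths[["pathways"]])
  truth <- fixture$truth
  jsonlite::write_json(
    list(
      loci = truth$loci, pathways = truth$pathways, drugs = truth$drugs,
      refinement = truth$refinement
    ),
    paths[["ground_truth"]],
    dataframe = "columns", auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
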