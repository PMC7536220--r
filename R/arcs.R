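#' Label-retaining-cell signature arc
#'
#' The bulk/microarray analysis arc: pools every non-focus group into one
#' reference class, fits the differential model with a patient covariate and
#' no fold-change limit (FDR only), then runs gene-list enrichment of the
#' resulting differential signature against a pathway collection. Samples
#' without patient labels are analysed without the covariate, with a loud
#' warning.
#'
#' @param x Log2-scale [expr_mat()] (or matrix) of the bulk cohort.
#' @param group Per-sample group labels (>= 2 groups).
#' @param focus_group The group contrasted against the pooled rest.
#' @param sets A [gene_sets()] collection for the enrichment step.
#' @param patient Optional per-sample patient ids.
#' @param q_max FDR threshold for the differential call.
#' @return A list: `de` (a `de_result`), `signature` (tidy gene table),
#'   `enrichment` (the [gene_list_enrichment()] tibble, empty with a warning
#'   when no gene is differential), and `report` (per-stage record counts).
#' @export
run_lrc_arc <- function(x, group, focus_group, sets, patient = NULL,
                        q_max = 0.05) {
  group <- as.character(group)
  stopifnot(focus_group %in% group)
  pooled <- ifelse(group == focus_group, focus_group, "rest")
  if (is.null(patient)) {
    warning("no patient labels supplied; fitting without the covariate")
  }
  de <- de_analysis(x, pooled, contrast = c(focus_group, "rest"),
                    covariate = patient, q_max = q_max, fc_limit = FALSE)
  sig <- tidy(de)
  hits <- sig$gene[sig$differential]
  enr <- if (length(hits) == 0L) {
    warning("no differential genes; enrichment table is empty")
    tibble::tibble(pathway = character(), n_pathway = integer(),
                   n_list = integer(), n_overlap = integer(),
                   p = numeric(), q = numeric(),
                   overlap_genes = list())
  } else {
    gene_list_enrichment(hits, universe = sig$gene, sets = sets)
  }
  list(de = de, signature = sig, enrichment = enr,
       report = tibble::tibble(
         stage = c("genes_tested", "genes_differential",
                   "pathways_tested"),
         n = c(nrow(sig), length(hits), length(sets))
       ))
}

#' Disseminated-cancer-cell pathway activation arc
#'
#' The single-cell arc: restrict the matrix to protein-coding genes, derive
#' the expressed mask (log2 value strictly greater than the threshold),
#' test every (cell, pathway) contingency table, summarize across the cell
#' cohort, and partition the enriched pathways' genes into private and
#' shared core genes.
#'
#' @param x Log2-scale single-cell [expr_mat()].
#' @param sets Candidate pathway [gene_sets()] (e.g. the hits of
#'   [run_lrc_arc()]).
#' @param annotation Optional feature annotation tibble (`feature_id`,
#'   `biotype`) for the protein-coding filter; omit when the matrix is
#'   already filtered.
#' @param cells Optional subset of cells to analyse (default: all).
#' @param expressed_threshold Strict log2 threshold defining "expressed".
#' @param alpha Per-cell significance level for the fraction view.
#' @param q_max Combined-q threshold flagging a pathway enriched.
#' @param min_fraction Core-gene rule: minimum fraction of cells expressing
#'   a gene ("at least half" = 0.5, inclusive).
#' @return A list: `cell_pathway` ([per_cell_pathway_test()] table),
#'   `summary` ([summarize_pathway_enrichment()] table), `partition`
#'   ([core_gene_partition()] of the enriched pathways, `NULL` when none),
#'   and `report`.
#' @export
run_dcc_arc <- function(x, sets, annotation = NULL, cells = NULL,
                        expressed_threshold = 0, alpha = 0.05,
                        q_max = 0.05, min_fraction = 0.5) {
  if (length(sets) == 0L) stop("empty pathway collection", call. = FALSE)
  n_before <- nrow(x)
  if (!is.null(annotation)) {
    x <- filter_biotype(x, annotation, biotype = "protein_coding")
  }
  mask <- expressed_mask(x, threshold = expressed_threshold)
  if (!is.null(cells)) mask <- mask[, cells, drop = FALSE]
  tbl <- per_cell_pathway_test(mask, sets)
  summ <- summarize_pathway_enrichment(tbl, alpha = alpha, q_max = q_max)
  enriched <- summ$pathway[summ$enriched]
  part <- if (length(enriched) > 0L) {
    core_gene_partition(
      gene_sets(unclass(sets)[enriched], source = attr(sets, "source")),
      mask, min_fraction = min_fraction
    )
  } else NULL
  list(cell_pathway = tbl, summary = summ, partition = part,
       report = tibble::tibble(
         stage = c("features_in", "features_universe", "cells",
                   "pathways_tested", "pathways_enriched"),
         n = c(n_before, nrow(mask), ncol(mask), length(sets),
               length(enriched))
       ))
}

#' Stimulation-vs-lineage concordance arc
#'
#' Evaluates the full [concordance_grid()] between a family of stimulation
#' contrast signatures and a family of lineage contrast signatures.
#'
#' @param stim,lineage Named lists of signature tibbles.
#' @param selection Gene selection for the correlation
#'   (`"intersection"`/`"union"`).
#' @return The long-format grid tibble.
#' @export
run_concordance_arc <- function(stim, lineage,
                                selection = c("intersection", "union")) {
  concordance_grid(stim, lineage, selection = match.arg(selection))
}

#' Copy-number frequency profile arc
#'
#' Filters aberration calls (size, unknown chromosomes, blacklist),
#' annotates them with cytoband ranges, and computes the group-stratified
#' cumulative gain/loss frequency profile over the cytoband bins.
#'
#' @param calls Call tibble (see [read_cna_calls()]).
#' @param cytobands Cytoband tibble (see [read_cytobands()]); also defines
#'   the profile bins and the valid chromosomes.
#' @param roster Cell/group roster tibble.
#' @param blacklist Optional blacklist tibble; `default_blacklist(cytobands)`
#'   is used when `NULL` and `use_default_blacklist` is `TRUE`.
#' @param use_default_blacklist Logical.
#' @param min_length Minimum call length (bp).
#' @return A list: `calls` (filtered, band-annotated), `profile`
#'   ([cumulative_frequency()] tibble), and `report` (drop counts).
#' @export
run_cna_arc <- function(calls, cytobands, roster, blacklist = NULL,
                        use_default_blacklist = TRUE, min_length = 1e6) {
  cytobands <- .validate_cytobands(cytobands)
  if (is.null(blacklist) && use_default_blacklist) {
    blacklist <- default_blacklist(cytobands)
  }
  kept <- filter_aberrations(calls, min_length = min_length,
                             blacklist = blacklist,
                             chromosomes = unique(cytobands$chrom))
  drops <- attr(kept, "drop_counts")
  kept <- map_to_cytobands(kept, cytobands)
  bins <- dplyr::select(cytobands, -"stain")
  profile <- cumulative_frequency(kept, roster, bins)
  list(calls = kept, profile = profile,
       report = tibble::tibble(
         stage = c("calls_in", names(drops), "calls_out"),
         n = c(nrow(validate_cna_calls(calls)), unname(drops), nrow(kept))
       ))
}
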