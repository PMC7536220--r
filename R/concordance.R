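#' Overlap of two differential gene lists
#'
#' Counts the common differentially expressed genes of two contrast
#' signatures and quantifies the randomness of the overlap with the upper
#' hypergeometric tail over the universe of genes measured on both
#' platforms.
#'
#' @param sig_a,sig_b Contrast signatures: tibbles with columns `gene`,
#'   `log2fc` and logical `differential` (gene symbols unique within each).
#' @param universe Gene universe; defaults to the genes present in both
#'   signatures (overlap can only occur there).
#' @return One-row tibble: `num` (intersection size), `n_a`, `n_b`,
#'   `n_universe`, `p_overlap`. An empty differential list gives
#'   `num = 0, p_overlap = 1` with a warning.
#' @export
signature_overlap <- function(sig_a, sig_b, universe = NULL) {
  sig_a <- .check_signature(sig_a)
  sig_b <- .check_signature(sig_b)
  if (is.null(universe)) universe <- intersect(sig_a$gene, sig_b$gene)
  universe <- unique(universe)
  da <- intersect(sig_a$gene[sig_a$differential], universe)
  db <- intersect(sig_b$gene[sig_b$differential], universe)
  num <- length(intersect(da, db))
  if (length(da) == 0L || length(db) == 0L) {
    warning("a differential list is empty over the universe; p_overlap = 1")
    p <- 1
  } else {
    p <- .hyper_tail(num, length(universe), length(da), length(db))
  }
  tibble::tibble(num = num, n_a = length(da), n_b = length(db),
                 n_universe = length(universe), p_overlap = p)
}

.check_signature <- function(sig) {
  sig <- tibble::as_tibble(sig)
  stopifnot(all(c("gene", "log2fc", "differential") %in% names(sig)))
  if (anyDuplicated(sig$gene)) {
    stop("gene symbols must be unique within a signature", call. = FALSE)
  }
  sig
}

#' Fold-change concordance between two contrast signatures
#'
#' Pairs two contrasts (e.g. a cytokine-stimulation contrast and a mammary
#' lineage contrast), selects the genes differential in both (default) or in
#' either (restricted to genes measured in both), and computes the
#' non-centered correlation of their log2 fold changes together with its
#' Student-t p-value and the differential-list overlap statistics.
#'
#' @inheritParams signature_overlap
#' @param selection `"intersection"` (genes differential in both signatures)
#'   or `"union"` (differential in either, measured in both).
#' @return One-row tibble: `num`, `p_overlap`, `n_cor` (genes entering the
#'   correlation), `nc_cor`, `p_cor`, `n_universe`, `selection`. Fewer than 3
#'   selected genes give `nc_cor = NaN` with a warning.
#' @export
foldchange_concordance <- function(sig_a, sig_b,
                                   selection = c("intersection", "union"),
                                   universe = NULL) {
  selection <- match.arg(selection)
  sig_a <- .check_signature(sig_a)
  sig_b <- .check_signature(sig_b)
  measured <- intersect(sig_a$gene, sig_b$gene)
  ov <- signature_overlap(sig_a, sig_b, universe)
  da <- sig_a$gene[sig_a$differential]
  db <- sig_b$gene[sig_b$differential]
  genes <- if (selection == "intersection") {
    intersect(intersect(da, db), measured)
  } else {
    intersect(union(da, db), measured)
  }
  if (length(genes) < 3L) {
    warning("fewer than 3 genes selected; concordance undefined")
    nc <- NaN
    pc <- NA_real_
  } else {
    x <- sig_a$log2fc[match(genes, sig_a$gene)]
    y <- sig_b$log2fc[match(genes, sig_b$gene)]
    nc <- noncentered_cor(x, y)
    pc <- if (is.nan(nc)) NA_real_ else cor_pvalue(nc, length(genes))$p.value
  }
  tibble::tibble(num = ov$num, p_overlap = ov$p_overlap,
                 n_cor = length(genes), nc_cor = nc, p_cor = pc,
                 n_universe = ov$n_universe, selection = selection)
}

#' Concordance grid over two families of signatures
#'
#' Evaluates [foldchange_concordance()] for every (stimulation, lineage)
#' signature pair and returns one long-format row per pair. Per-pair
#' failures are recorded as `NA` rows rather than aborting the grid.
#'
#' @param stim,lineage Named lists of contrast signatures (see
#'   [signature_overlap()] for the required columns).
#' @inheritParams foldchange_concordance
#' @return A tibble: `stim`, `lineage`, then the [foldchange_concordance()]
#'   columns.
#' @export
concordance_grid <- function(stim, lineage,
                             selection = c("intersection", "union"),
                             universe = NULL) {
  selection <- match.arg(selection)
  stopifnot(length(stim) >= 1L, length(lineage) >= 1L)
  if (is.null(names(stim)) || is.null(names(lineage))) {
    stop("`stim` and `lineage` must be named lists", call. = FALSE)
  }
  stim_list <- stim
  lineage_list <- lineage
  grid <- tidyr::expand_grid(stim = names(stim_list),
                             lineage = names(lineage_list))
  purrr::pmap_dfr(grid, function(stim, lineage) {
    res <- tryCatch(
      foldchange_concordance(stim_list[[stim]], lineage_list[[lineage]],
                             selection = selection, universe = universe),
      error = function(e) {
        warning(sprintf("pair (%s, %s) failed: %s", stim, lineage,
                        conditionMessage(e)))
        tibble::tibble(num = NA_integer_, p_overlap = NA_real_,
                       n_cor = NA_integer_, nc_cor = NA_real_,
                       p_cor = NA_real_, n_universe = NA_integer_,
                       selection = selection)
      }
    )
    dplyr::mutate(res, stim = stim, lineage = lineage, .before = 1L)
  })
}
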