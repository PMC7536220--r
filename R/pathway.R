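#' Gene-set collections
#'
#' A gene-set collection is a named list of character vectors of gene
#' symbols with a `source` tag. Symbols are upper-cased on construction
#' (symbols are the join key against expression matrices; no alias
#' resolution is attempted), empty sets and duplicate names are rejected.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param source Single string tagging the origin (e.g. a database name).
#' @return A `gene_set_collection`.
#' @export
gene_sets <- function(sets, source = NA_character_) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a fully named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("pathway names must be unique", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene sets are not allowed", call. = FALSE)
  }
  structure(sets, source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %d-%d), source: %s\n",
              length(x), min(lengths(x)), max(lengths(x)),
              attr(x, "source")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT format: one set per line, tab-separated `name`,
#' `description`, then member gene symbols. Parsing is delegated to
#' [fgsea::gmtPathways()]; symbols are upper-cased.
#'
#' @param path Path to a `.gmt` file.
#' @param source Source tag; defaults to the file name.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path, source = basename(path)) {
  gene_sets(fgsea::gmtPathways(path), source = source)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_sets()] collection (or named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets, "source") %||% "na", sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Expressed-gene mask of a single-cell matrix
#'
#' A gene is expressed in a cell when its log2 normalized value is strictly
#' greater than `threshold` (default 0, i.e. any positive signal counts; a
#' value of exactly 0 does not).
#'
#' @param x A log2-scale [expr_mat()].
#' @param threshold Strict lower bound on the log2 value.
#' @return Logical genes x cells matrix with the threshold recorded as
#'   `attr(, "threshold")`.
#' @export
expressed_mask <- function(x, threshold = 0) {
  if (!inherits(x, "expr_mat") || !is_log2(x)) {
    stop("expressed_mask() needs a log2-scale expr_mat", call. = FALSE)
  }
  m <- .as_values(x) > threshold
  attr(m, "threshold") <- threshold
  m
}

#' Gene-list enrichment against a pathway collection
#'
#' One-sided Fisher exact test, per pathway, of the 2x2 table crossing
#' list-membership with pathway-membership over a gene universe, with BH
#' adjustment across pathways. Pathways with no gene in the universe yield
#' an `NA` row with a warning.
#'
#' @param genes Character vector of hit genes (e.g. a differential list);
#'   must be a subset of `universe`.
#' @param universe Character vector of all tested genes.
#' @param sets A [gene_sets()] collection.
#' @return A tibble: `pathway`, `n_pathway` (pathway size in the universe),
#'   `n_list`, `n_overlap`, `p`, `q`, `overlap_genes` (list-column), sorted
#'   by `p`.
#' @export
gene_list_enrichment <- function(genes, universe, sets) {
  universe <- unique(toupper(universe))
  genes <- unique(toupper(genes))
  if (length(genes) == 0L || length(universe) == 0L) {
    stop("empty gene list or universe", call. = FALSE)
  }
  if (!all(genes %in% universe)) {
    stop("`genes` must be a subset of `universe`", call. = FALSE)
  }
  N <- length(universe)
  nl <- length(genes)
  rows <- purrr::imap_dfr(unclass(sets), function(members, nm) {
    inu <- intersect(members, universe)
    K <- length(inu)
    if (K == 0L) {
      warning(sprintf("pathway '%s' has no gene in the universe", nm))
      return(tibble::tibble(pathway = nm, n_pathway = 0L, n_list = nl,
                            n_overlap = NA_integer_, p = NA_real_,
                            overlap_genes = list(character())))
    }
    ov <- intersect(genes, inu)
    a <- length(ov)
    p <- fisher_exact_2x2(a, nl - a, K - a, N - nl - K + a,
                          alternative = "greater")$p.value
    tibble::tibble(pathway = nm, n_pathway = K, n_list = nl,
                   n_overlap = a, p = p, overlap_genes = list(sort(ov)))
  })
  rows$q <- NA_real_
  ok <- !is.na(rows$p)
  rows$q[ok] <- bh_adjust(rows$p[ok])
  dplyr::arrange(dplyr::relocate(rows, "q", .after = "p"), .data$p)
}

#' Per-cell pathway membership enrichment
#'
#' For every cell and every pathway, builds the 2x2 contingency table
#' crossing expressed/not-expressed with pathway member/non-member over the
#' gene universe, and tests enrichment of members among expressed genes with
#' a one-tailed Fisher exact test. This is the per-cell pathway-activation
#' readout used for bone-marrow disseminated cancer cells.
#'
#' @param mask Logical genes x cells matrix from [expressed_mask()].
#' @param sets A [gene_sets()] collection (intersected with the universe).
#' @param universe Gene universe; defaults to the mask's rownames (after any
#'   biotype filtering upstream).
#' @return A tibble with one row per (cell, pathway): `cell`, `pathway`,
#'   counts `a` (expressed member), `b` (expressed non-member), `c`
#'   (not-expressed member), `d` (not-expressed non-member), `n_universe`,
#'   and the one-tailed `p`. Pathways with empty universe intersection give
#'   `NA` rows with a warning.
#' @export
per_cell_pathway_test <- function(mask, sets, universe = rownames(mask)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  universe <- intersect(toupper(rownames(mask)), unique(toupper(universe)))
  rn <- toupper(rownames(mask))
  mask <- mask[match(universe, rn), , drop = FALSE]
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  n_expr <- colSums(mask)                     # per-cell expressed count
  purrr::imap_dfr(unclass(sets), function(members, nm) {
    member <- universe %in% members
    K <- sum(member)
    if (K == 0L) {
      warning(sprintf("pathway '%s' has no gene in the universe", nm))
      return(tibble::tibble(cell = colnames(mask), pathway = nm,
                            a = NA_integer_, b = NA_integer_,
                            c = NA_integer_, d = NA_integer_,
                            n_universe = N, p = NA_real_))
    }
    a <- colSums(mask & member)
    b <- n_expr - a
    cc <- K - a
    d <- N - K - b
    # one-tailed Fisher = upper hypergeometric tail of cell a
    p <- .hyper_tail(a, N, K, n_expr)
    tibble::tibble(cell = colnames(mask), pathway = nm,
                   a = as.integer(a), b = as.integer(b),
                   c = as.integer(cc), d = as.integer(d),
                   n_universe = N, p = p)
  })
}

#' Cohort-level summary of per-cell pathway enrichment
#'
#' Aggregates a per-cell pathway table to one row per pathway, reporting two
#' complementary views: the fraction of cells individually significant at
#' `alpha`, and a Fisher-combined p-value across cells with BH adjustment
#' across pathways. A pathway is flagged enriched when its combined q-value
#' is at most `q_max`.
#'
#' @param tbl Output of [per_cell_pathway_test()].
#' @param alpha Per-cell significance level for the fraction view.
#' @param q_max Combined-q threshold for the `enriched` flag.
#' @return A tibble: `pathway`, `n_cells`, `frac_significant`, `p_combined`,
#'   `q_combined`, `enriched`, sorted by `p_combined`.
#' @export
summarize_pathway_enrichment <- function(tbl, alpha = 0.05, q_max = 0.05) {
  stopifnot(all(c("cell", "pathway", "p") %in% names(tbl)))
  out <- tbl |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      frac_significant = mean(.data$p < alpha),
      p_combined = .combine_fisher_p(.data$p),
      .groups = "drop"
    )
  out$q_combined <- bh_adjust(out$p_combined)
  out$enriched <- out$q_combined <= q_max
  dplyr::arrange(out, .data$p_combined)
}

#' Core-gene partition of enriched pathways
#'
#' Keeps the pathway genes expressed in at least `min_fraction` of the cells
#' (inclusive; "at least half" keeps a gene seen in exactly 20 of 40 cells)
#' and partitions them into pathway-private genes (member of exactly one of
#' the examined pathways) and shared genes annotated with their partner
#' pathways. This is the Venn-style core-gene view of the enriched pathways.
#'
#' @param sets A [gene_sets()] collection restricted to the pathways under
#'   examination (e.g. the enriched ones).
#' @param mask Logical genes x cells mask from [expressed_mask()] for the
#'   cell cohort of interest.
#' @param min_fraction Minimum fraction of cells expressing the gene.
#' @return A tibble: `gene`, `n_expressed`, `n_cells`, `fraction`,
#'   `pathways` (list-column), `n_pathways`, `status`
#'   (`"private"`/`"shared"`).
#' @export
core_gene_partition <- function(sets, mask, min_fraction = 0.5) {
  if (length(sets) == 0L) stop("empty pathway subset", call. = FALSE)
  stopifnot(is.matrix(mask), is.logical(mask))
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  n_cells <- ncol(mask)
  rn <- toupper(rownames(mask))
  all_genes <- sort(unique(unlist(sets)))
  n_expr <- stats::setNames(rep(0L, length(all_genes)), all_genes)
  present <- all_genes %in% rn
  n_expr[present] <- as.integer(
    rowSums(mask[match(all_genes[present], rn), , drop = FALSE])
  )
  frac <- n_expr / n_cells
  keep <- all_genes[frac >= min_fraction]
  membership <- lapply(stats::setNames(keep, keep), function(g) {
    sort(names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
  })
  tibble::tibble(
    gene = keep,
    n_expressed = unname(n_expr[keep]),
    n_cells = n_cells,
    fraction = unname(frac[keep]),
    pathways = unname(membership),
    n_pathways = unname(lengths(membership)),
    status = unname(ifelse(lengths(membership) == 1L, "private", "shared"))
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
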