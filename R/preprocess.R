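#' Log2-transform a raw expression matrix
#'
#' Applies `log2(value + offset)` and marks the matrix as log2 scale. A
#' matrix already on the log2 scale is refused, so the transform cannot be
#' applied twice by accident.
#'
#' @param x An [expr_mat()] (or plain numeric matrix) of non-negative raw
#'   values.
#' @param offset Pseudo-value added before the log (default 1).
#' @return A log2-scale `expr_mat`.
#' @export
log2_transform <- function(x, offset = 1) {
  if (inherits(x, "expr_mat") && is_log2(x)) {
    stop("matrix is already log2 scale; refusing to transform twice",
         call. = FALSE)
  }
  if (!inherits(x, "expr_mat")) x <- expr_mat(x, log2 = FALSE)
  v <- .as_values(x)
  if (any(v < 0)) stop("raw values must be non-negative", call. = FALSE)
  .rewrap(log2(v + offset), x, log2 = TRUE)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share one common distribution: sorted
#' values are replaced by the across-sample mean at each rank, then restored
#' to each sample's original rank order. Ties receive the mean of their tied
#' rank targets. Delegates to [limma::normalizeQuantiles()] with
#' `ties = TRUE`; missing values are rejected rather than imputed.
#'
#' @param x An [expr_mat()] or numeric matrix with at least one sample.
#' @return The normalized matrix with the same class and annotations.
#' @export
quantile_normalize <- function(x) {
  wrap <- inherits(x, "expr_mat")
  v <- if (wrap) .as_values(x) else x
  if (anyNA(v)) stop("missing values are not allowed; handle them upstream",
                     call. = FALSE)
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  if (wrap) .rewrap(out, x) else out
}

#' Collapse replicated probes to their per-sample median
#'
#' Rows sharing one probe id (e.g. technical on-chip replicates of the same
#' oligo) are replaced by a single row holding the per-sample median.
#'
#' @param x An [expr_mat()] or matrix at probe level.
#' @param probe_id Character vector of probe ids, one per row; defaults to
#'   the rownames.
#' @return A matrix with one row per unique probe id (first-appearance
#'   order).
#' @export
collapse_replicate_probes <- function(x, probe_id = rownames(x)) {
  wrap <- inherits(x, "expr_mat")
  v <- if (wrap) .as_values(x) else x
  if (is.null(probe_id) || length(probe_id) != nrow(v)) {
    stop("`probe_id` must provide one id per row", call. = FALSE)
  }
  ids <- unique(probe_id)
  if (length(ids) == nrow(v)) {
    rownames(v) <- probe_id
    return(if (wrap) .rewrap(v, x) else v)
  }
  out <- matrix(NA_real_, length(ids), ncol(v),
                dimnames = list(ids, colnames(v)))
  idx <- split(seq_len(nrow(v)), factor(probe_id, levels = ids))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    out[i, ] <- if (length(rows) == 1L) v[rows, ] else
      apply(v[rows, , drop = FALSE], 2L, stats::median)
  }
  if (wrap) .rewrap(out, x) else out
}

#' Disambiguate probes mapping to the same gene
#'
#' For gene-level lists and display, each gene keeps exactly one probe: the
#' one with the smallest raw p-value. Ties are broken by larger absolute log2
#' fold change, then by lexicographically smaller probe id, so the choice is
#' deterministic. Probes without a gene symbol are set aside in an
#' `"unannotated"` bucket and excluded from the gene-level output.
#'
#' @param stats Tibble of per-probe statistics with columns `probe`, `p` and
#'   `log2fc` (plus anything else, carried along).
#' @param annotation Tibble mapping `feature_id` to `gene_symbol`; `NA` or
#'   missing symbols mark unannotated probes. If `stats` already has a `gene`
#'   column, `annotation` may be omitted.
#' @return A tibble with one row per gene (column `gene` first), sorted by
#'   gene; the dropped unannotated probes are attached as
#'   `attr(, "unannotated")`.
#' @export
disambiguate_probes <- function(stats, annotation = NULL) {
  stats <- tibble::as_tibble(stats)
  stopifnot(all(c("probe", "p", "log2fc") %in% names(stats)))
  if (!"gene" %in% names(stats)) {
    if (is.null(annotation)) {
      stop("provide `annotation` or a `gene` column in `stats`",
           call. = FALSE)
    }
    annotation <- tibble::as_tibble(annotation)
    stats <- dplyr::left_join(
      stats,
      dplyr::select(annotation, probe = "feature_id", gene = "gene_symbol"),
      by = "probe"
    )
  }
  unann <- dplyr::filter(stats, is.na(.data$gene) | .data$gene == "")
  out <- stats |>
    dplyr::filter(!is.na(.data$gene) & .data$gene != "") |>
    dplyr::arrange(.data$gene, .data$p, dplyr::desc(abs(.data$log2fc)),
                   .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::relocate("gene")
  attr(out, "unannotated") <- unann
  out
}

#' Filter features by biotype
#'
#' Restricts the matrix to features of one biotype (default
#' `"protein_coding"`, the universe used for per-cell pathway enrichment).
#' Features absent from the annotation are dropped with a warning.
#'
#' @param x An [expr_mat()] or matrix.
#' @param annotation Tibble with columns `feature_id` and `biotype`.
#' @param biotype Biotype to keep.
#' @return The filtered matrix; an empty result is an error.
#' @export
filter_biotype <- function(x, annotation, biotype = "protein_coding") {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("feature_id", "biotype") %in% names(annotation)))
  feats <- rownames(x)
  covered <- feats %in% annotation$feature_id
  if (any(!covered)) {
    warning(sprintf("%d features missing from the annotation were dropped",
                    sum(!covered)))
  }
  keep_ids <- annotation$feature_id[annotation$biotype == biotype]
  keep <- covered & feats %in% keep_ids
  if (!any(keep)) {
    stop(sprintf("no features of biotype '%s' remain", biotype),
         call. = FALSE)
  }
  x[keep, , drop = FALSE]
}

#' Select the most variable genes
#'
#' Ranks genes by their across-sample variance (descending) and returns the
#' top `n` gene ids; ties are broken lexicographically so the selection is
#' deterministic. `n` larger than the gene count returns all genes.
#'
#' @param x A log2-scale [expr_mat()] or matrix.
#' @param n Number of genes to return (e.g. 500 for ordination input).
#' @return Character vector of gene ids, most variable first.
#' @export
select_top_variable <- function(x, n) {
  if (!is.finite(n) || n <= 0) stop("`n` must be positive", call. = FALSE)
  .require_log2(x, "select_top_variable")
  v <- if (inherits(x, "expr_mat")) .as_values(x) else x
  vars <- apply(v, 1L, stats::var)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord][seq_len(min(n, nrow(v)))]
}

#' Remove a known additive covariate effect for display
#'
#' Fits, per gene, the additive least-squares model
#' `value ~ group + covariate` and subtracts the fitted covariate term
#' (treatment coding: the reference covariate level is untouched), leaving
#' the group structure intact. This is the display-side compensation for
#' patient or batch shifts; inference should instead keep the covariate in
#' the model (see [fit_linear_de()]). The result matches
#' [limma::removeBatchEffect()] up to a per-gene additive constant (that
#' function centers the removed effect).
#'
#' @param x An [expr_mat()] or matrix.
#' @param covariate Per-sample covariate labels (patient or batch).
#' @param group Per-sample group labels to protect.
#' @return The compensated matrix. A covariate with a single level is
#'   returned unchanged; a covariate perfectly confounded with the groups is
#'   an error (the two effects are not identifiable).
#' @export
remove_known_effect <- function(x, covariate, group) {
  wrap <- inherits(x, "expr_mat")
  v <- if (wrap) .as_values(x) else x
  covariate <- as.factor(covariate)
  group <- as.factor(group)
  stopifnot(length(covariate) == ncol(v), length(group) == ncol(v))
  if (nlevels(covariate) < 2L) return(x)
  X <- stats::model.matrix(~ group + covariate)
  expected <- nlevels(group) + nlevels(covariate) - 1L
  if (qr(X)$rank < expected) {
    stop("covariate is confounded with the groups: effects are not identifiable",
         call. = FALSE)
  }
  B <- qr.coef(qr(X), t(v))                       # coefficients x genes
  cov_cols <- grep("^covariate", colnames(X))
  fitted_cov <- X[, cov_cols, drop = FALSE] %*% B[cov_cols, , drop = FALSE]
  out <- v - t(fitted_cov)
  dimnames(out) <- dimnames(v)
  if (wrap) .rewrap(out, x) else out
}
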