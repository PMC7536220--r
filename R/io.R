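#' Expression matrix I/O
#'
#' TSV layout: features in rows, samples in columns, header row, first
#' column `feature_id`. Sparse input is accepted as an MTX triplet
#' (`matrix.mtx`, `features.tsv`, `samples.tsv`) via [read_expr_mtx()] and
#' densified, since every downstream operation works on log2 values with
#' exact zeros.
#'
#' @param path TSV path.
#' @param samples Optional per-sample annotation tibble (or TSV path) with a
#'   `sample` column.
#' @param log2 Logical; whether the stored values are log2 scale.
#' @return An [expr_mat()].
#' @export
read_expr_tsv <- function(path, samples = NULL, log2 = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (is.character(samples)) {
    samples <- readr::read_tsv(samples, show_col_types = FALSE)
  }
  expr_mat(m, samples = samples, log2 = log2)
}

#' @rdname read_expr_tsv
#' @param x An [expr_mat()] or matrix.
#' @export
write_expr_tsv <- function(x, path) {
  v <- if (inherits(x, "expr_mat")) .as_values(x) else x
  tab <- tibble::as_tibble(v, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(v)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname read_expr_tsv
#' @param mtx,features Paths of the MatrixMarket triplet file and the
#'   feature-id TSV (one id per line, no header).
#' @export
read_expr_mtx <- function(mtx, features, samples, log2 = TRUE) {
  m <- as.matrix(Matrix::readMM(mtx))
  feats <- readr::read_tsv(features, col_names = "feature_id",
                           show_col_types = FALSE)$feature_id
  samp <- readr::read_tsv(samples, show_col_types = FALSE)
  if (!"sample" %in% names(samp)) names(samp)[1] <- "sample"
  rownames(m) <- feats
  colnames(m) <- samp$sample
  expr_mat(m, samples = samp, log2 = log2)
}

#' Contrast-signature I/O
#'
#' TSV with columns `gene`, `log2fc`, `t`, `p`, `q`, `differential` (0/1);
#' only `gene`, `log2fc` and `differential` are required on read.
#'
#' @param path TSV path.
#' @return A signature tibble with a logical `differential` column.
#' @export
read_signature_tsv <- function(path) {
  sig <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "log2fc", "differential") %in% names(sig)))
  sig$differential <- as.logical(sig$differential)
  .check_signature(sig)
}

#' @rdname read_signature_tsv
#' @param sig A signature tibble (e.g. `tidy()` of a [de_analysis()]).
#' @export
write_signature_tsv <- function(sig, path) {
  sig <- tibble::as_tibble(sig)
  keep <- intersect(c("gene", "log2fc", "t", "p", "q", "differential"),
                    names(sig))
  out <- sig[keep]
  if ("differential" %in% names(out)) {
    out$differential <- as.integer(out$differential)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a feature annotation table
#'
#' TSV with columns `feature_id`, `gene_symbol`, `biotype` and optional
#' `tags`; missing symbols are kept as `NA` (the explicit "unannotated"
#' marker).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_feature_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("feature_id", "gene_symbol", "biotype") %in% names(ann)))
  ann
}
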