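#' Expression matrix with sample annotations
#'
#' A light container for a genes-by-samples grid of expression values: a
#' numeric matrix with feature rownames and sample colnames, a tibble of
#' per-sample annotations (`sample` plus, typically, `group`, `patient`,
#' `batch`), and a flag recording whether values are on the log2 scale.
#' Every downstream operation that assumes log2-scale input checks the flag,
#' so a raw matrix cannot silently flow into a log-scale analysis.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Both
#'   dimnames are required; sample names must be unique.
#' @param samples Optional tibble/data frame of per-sample annotations with a
#'   `sample` column matching `colnames(values)`. Defaults to the bare sample
#'   names.
#' @param log2 Logical flag; `TRUE` when `values` are already log2 scale.
#' @return An `expr_mat` object (a classed numeric matrix).
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' x <- expr_mat(m)
#' log2_transform(x)
#' @export
expr_mat <- function(values, samples = NULL, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids are not allowed", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(sample = colnames(values))
  } else {
    samples <- tibble::as_tibble(samples)
    if (!"sample" %in% names(samples)) {
      stop("`samples` must contain a `sample` column", call. = FALSE)
    }
    if (!setequal(samples$sample, colnames(values)) ||
        anyDuplicated(samples$sample)) {
      stop("`samples$sample` must match the matrix colnames exactly",
           call. = FALSE)
    }
    samples <- samples[match(colnames(values), samples$sample), ]
  }
  structure(values,
            samples = samples,
            log2 = isTRUE(log2),
            class = c("expr_mat", class(values)))
}

#' @rdname expr_mat
#' @param x An `expr_mat` (or coercible matrix).
#' @export
sample_info <- function(x) {
  si <- attr(x, "samples")
  if (is.null(si)) tibble::tibble(sample = colnames(x)) else si
}

#' @rdname expr_mat
#' @export
is_log2 <- function(x) isTRUE(attr(x, "log2"))

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x), if (is_log2(x)) "log2" else "raw"))
  si <- sample_info(x)
  ann <- setdiff(names(si), "sample")
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

# rebuild an expr_mat after a row/column operation, keeping annotations
.rewrap <- function(values, template, log2 = is_log2(template)) {
  si <- sample_info(template)
  expr_mat(values, samples = si[match(colnames(values), si$sample), ],
           log2 = log2)
}

#' @export
`[.expr_mat` <- function(x, i, j, ..., drop = TRUE) {
  v <- .as_values(x)
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  out <- v[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  .rewrap(out, x)
}

.as_values <- function(x) {
  out <- unclass(x)
  attr(out, "samples") <- NULL
  attr(out, "log2") <- NULL
  out
}

.require_log2 <- function(x, op) {
  if (inherits(x, "expr_mat") && !is_log2(x)) {
    stop(sprintf("%s() requires a log2-scale matrix; run log2_transform() first", op),
         call. = FALSE)
  }
  invisible(x)
}
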