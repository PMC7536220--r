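#' Per-gene linear model fit for a two-group contrast
#'
#' Fits, gene by gene, the weighted least-squares model
#' `value ~ 0 + group (+ covariate)` and extracts the contrast coefficient
#' (log2 fold change, first group minus second), the residual mean square
#' `s2` and the residual degrees of freedom. Additive covariates (typically
#' patient id) are adjusted for in the model itself; per-sample weights
#' default to 1.
#'
#' @param x A log2-scale [expr_mat()] or matrix (genes x samples).
#' @param group Per-sample group labels.
#' @param contrast Character vector of two group levels, `c(A, B)` for the
#'   contrast A - B; defaults to the first two levels.
#' @param covariate Optional per-sample covariate labels (e.g. patient id).
#' @param weights Optional per-sample positive weights.
#' @return A `de_fit` object: per-gene tibble (`gene`, `log2fc`, `s2`), the
#'   residual df, the contrast's unscaled variance `v_c`, and design
#'   metadata.
#' @seealso [moderated_t()], [de_analysis()]
#' @export
fit_linear_de <- function(x, group, contrast = NULL, covariate = NULL,
                          weights = NULL) {
  .require_log2(x, "fit_linear_de")
  v <- if (inherits(x, "expr_mat")) .as_values(x) else x
  group <- as.factor(group)
  stopifnot(length(group) == ncol(v))
  if (is.null(contrast)) contrast <- levels(group)[1:2]
  stopifnot(length(contrast) == 2L, all(contrast %in% levels(group)))
  if (any(table(group)[contrast] < 2L)) {
    stop("each contrast group needs at least 2 samples", call. = FALSE)
  }
  eng <- .de_engine(v, group, covariate, weights)
  cvec <- .contrast_vector(eng$design, group, contrast)
  co <- .engine_contrast(eng, cvec)
  structure(
    list(
      genes = tibble::tibble(gene = rownames(v), log2fc = co$coef,
                             s2 = eng$s2),
      df_residual = eng$df,
      v_c = co$v_c,
      contrast = paste(contrast, collapse = " vs "),
      n = ncol(v),
      design_columns = colnames(eng$design)
    ),
    class = "de_fit"
  )
}

# shared least-squares engine: one QR for all genes
.de_engine <- function(v, group, covariate = NULL, weights = NULL) {
  n <- ncol(v)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  df_terms <- data.frame(group = as.factor(group))
  form <- ~ 0 + group
  if (!is.null(covariate)) {
    df_terms$covariate <- as.factor(covariate)
    if (nlevels(df_terms$covariate) > 1L) form <- ~ 0 + group + covariate
  }
  X <- stats::model.matrix(form, data = df_terms)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop(sprintf("rank-deficient design; confounded columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sw <- sqrt(weights)
  Xw <- X * sw
  Yw <- t(v) * sw                       # samples x genes
  qw <- qr(Xw)
  B <- qr.coef(qw, Yw)                  # p x genes
  res <- Yw - Xw %*% B
  df <- n - ncol(X)
  s2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(Yw))
  list(design = X, xtx_inv = chol2inv(qr.R(qw)), coef = B, s2 = unname(s2),
       df = df, group = df_terms$group)
}

.contrast_vector <- function(design, group, contrast) {
  cvec <- stats::setNames(rep(0, ncol(design)), colnames(design))
  cols <- paste0("group", contrast)
  if (!all(cols %in% colnames(design))) {
    stop("contrast levels not found in the design", call. = FALSE)
  }
  cvec[cols[1]] <- 1
  cvec[cols[2]] <- -1
  cvec
}

.engine_contrast <- function(eng, cvec) {
  list(coef = unname(drop(crossprod(cvec, eng$coef))),
       v_c = drop(t(cvec) %*% eng$xtx_inv %*% cvec))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0^2`) to the per-gene
#' residual variances by the method of moments on `log(s2)`: the mean and
#' variance of the adjusted log variances are matched to their theoretical
#' digamma/trigamma expressions, and the trigamma equation is inverted by
#' Newton iteration. When the spread of `log(s2)` is no larger than the
#' sampling noise alone explains, the prior df has no finite solution and
#' `d0` is capped.
#'
#' @param s2 Per-gene residual variances (zeros and non-finite values are
#'   excluded from estimation).
#' @param df Residual degrees of freedom (scalar or per gene).
#' @param cap Upper cap for `d0` (default 1e6, effectively infinite).
#' @return A `moderation_params` list with `d0`, `s0_2` and `n_genes`.
#' @export
estimate_moderation <- function(s2, df, cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0
  df <- rep_len(df, length(s2))[ok]
  s2 <- s2[ok]
  if (length(s2) < 2L) {
    stop("need at least 2 positive residual variances", call. = FALSE)
  }
  if (length(s2) < 10L) {
    warning("fewer than 10 genes: moderation prior estimate is unstable")
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  if (evar < 1e-14) {
    # degenerate input: no spread at all, the prior is the common variance
    return(structure(list(d0 = cap, s0_2 = exp(mean(log(s2))),
                          n_genes = length(s2)),
                     class = "moderation_params"))
  }
  target <- evar - mean(trigamma(df / 2))
  d0 <- if (!is.finite(target) || target <= trigamma(cap / 2)) {
    cap
  } else {
    min(cap, 2 * .trigamma_inverse(target))
  }
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0_2 = s0_2, n_genes = length(s2)),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("<moderation_params> d0 = %.4g, s0^2 = %.4g (from %d genes)\n",
              x$d0, x$s0_2, x$n_genes))
  invisible(x)
}

#' Moderated (or ordinary) t-statistics for a fitted contrast
#'
#' Shrinks each gene's residual variance towards the prior,
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and forms
#' `t = log2fc / sqrt(s2_post * v_c)` with `d0 + df` degrees of freedom;
#' two-sided p-values come from the Student-t distribution and q-values from
#' [bh_adjust()]. With `moderate = FALSE` the ordinary equal-variance t-test
#' on the model residuals is returned instead (`s2_post = s2`, df = residual
#' df).
#'
#' @param fit A `de_fit` from [fit_linear_de()].
#' @param moderation Optional `moderation_params`; estimated from `fit` when
#'   omitted and `moderate = TRUE`.
#' @param moderate Logical; `FALSE` disables variance moderation.
#' @return A tibble with `gene`, `log2fc`, `s2`, `s2_post`, `t`, `df_total`,
#'   `p`, `q`.
#' @export
moderated_t <- function(fit, moderation = NULL, moderate = TRUE) {
  stopifnot(inherits(fit, "de_fit"))
  g <- fit$genes
  s2 <- g$s2
  df <- fit$df_residual
  if (moderate) {
    if (is.null(moderation)) moderation <- estimate_moderation(s2, df)
    d0 <- moderation$d0
    s2_post <- (d0 * moderation$s0_2 + df * s2) / (d0 + df)
    df_total <- d0 + df
  } else {
    s2_post <- s2
    df_total <- rep(df, length(s2))
  }
  se <- sqrt(s2_post * fit$v_c)
  t <- ifelse(se > 0, g$log2fc / se,
              ifelse(g$log2fc == 0, 0, sign(g$log2fc) * Inf))
  p <- 2 * stats::pt(-abs(t), df = df_total)
  tibble::tibble(
    gene = g$gene, log2fc = g$log2fc, s2 = s2, s2_post = s2_post,
    t = t, df_total = rep_len(df_total, length(t)), p = p, q = bh_adjust(p)
  )
}

#' Flag differentially expressed genes
#'
#' Applies the study's calling rule: a gene is differential when its
#' FDR-adjusted p-value is at most `q_max` (default 0.05) and, when the
#' fold-change limit is enabled, its absolute log2 fold change is at least
#' `min_abs_log2fc` (default `log2(1.5)` = 0.58).
#'
#' @param stats Tibble with columns `log2fc` and `q` (e.g. from
#'   [moderated_t()]).
#' @param q_max Maximum FDR-adjusted p-value.
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @param fc_limit Logical; `FALSE` drops the fold-change condition (the rule
#'   used for the label-retaining-cell signature).
#' @return `stats` with a logical `differential` column appended.
#' @export
call_differential <- function(stats, q_max = 0.05,
                              min_abs_log2fc = log2(1.5), fc_limit = TRUE) {
  stats <- tibble::as_tibble(stats)
  stopifnot(all(c("log2fc", "q") %in% names(stats)))
  stopifnot(q_max > 0, q_max <= 1, min_abs_log2fc >= 0)
  flag <- stats$q <= q_max
  if (fc_limit) flag <- flag & abs(stats$log2fc) >= min_abs_log2fc
  dplyr::mutate(stats, differential = flag & !is.na(flag))
}

#' One-stop differential expression analysis
#'
#' Chains [fit_linear_de()], [estimate_moderation()], [moderated_t()] and
#' [call_differential()] for one contrast and returns a `de_result` holding
#' the flagged gene table, the moderation parameters and the thresholds.
#' Use [generics::tidy()] for the per-gene table and [generics::glance()]
#' for a one-row summary.
#'
#' @inheritParams fit_linear_de
#' @inheritParams call_differential
#' @param moderate Logical; empirical-Bayes variance moderation on/off.
#' @return A `de_result` object.
#' @examples
#' sim <- simulate_bulk_two_group(bulk_sim_config(n_genes = 300), seed = 1)
#' res <- de_analysis(sim$matrix, sample_info(sim$matrix)$group)
#' glance(res)
#' @export
de_analysis <- function(x, group, contrast = NULL, covariate = NULL,
                        weights = NULL, moderate = TRUE, q_max = 0.05,
                        min_abs_log2fc = log2(1.5), fc_limit = TRUE) {
  fit <- fit_linear_de(x, group, contrast, covariate, weights)
  moderation <- if (moderate) {
    estimate_moderation(fit$genes$s2, fit$df_residual)
  } else NULL
  tab <- moderated_t(fit, moderation, moderate = moderate)
  tab <- call_differential(tab, q_max, min_abs_log2fc, fc_limit)
  structure(
    list(table = tab, moderation = moderation, contrast = fit$contrast,
         df_residual = fit$df_residual, n = fit$n,
         thresholds = list(q_max = q_max, min_abs_log2fc = min_abs_log2fc,
                           fc_limit = fc_limit)),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> contrast %s: %d genes, %d differential\n",
              x$contrast, nrow(x$table), sum(x$table$differential)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname de_analysis
#' @param x A `de_result`.
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname de_analysis
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast,
    n_samples = x$n,
    n_genes = nrow(x$table),
    n_differential = sum(x$table$differential),
    df_residual = x$df_residual,
    d0 = if (is.null(x$moderation)) NA_real_ else x$moderation$d0,
    s0_2 = if (is.null(x$moderation)) NA_real_ else x$moderation$s0_2
  )
}

#' All pairwise two-group contrasts
#'
#' Fits one linear model over all groups (plus optional covariate), estimates
#' the moderation prior once from the full-model residuals, then tests every
#' unordered pair of groups with at least two samples each; the BH adjustment
#' runs within each contrast separately, matching per-contrast differential
#' counts. Pairs involving a group with fewer than two samples are skipped
#' with a warning.
#'
#' @inheritParams de_analysis
#' @return A tibble in long format: `contrast`, then the [moderated_t()] /
#'   [call_differential()] columns. The shared `moderation_params` are
#'   attached as an attribute.
#' @export
pairwise_de <- function(x, group, covariate = NULL, weights = NULL,
                        moderate = TRUE, q_max = 0.05,
                        min_abs_log2fc = log2(1.5), fc_limit = TRUE) {
  .require_log2(x, "pairwise_de")
  v <- if (inherits(x, "expr_mat")) .as_values(x) else x
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  eng <- .de_engine(v, group, covariate, weights)
  moderation <- if (moderate) estimate_moderation(eng$s2, eng$df) else NULL
  sizes <- table(group)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < nlevels(group)) {
    warning(sprintf("groups with < 2 samples skipped: %s",
                    paste(setdiff(names(sizes), usable), collapse = ", ")))
  }
  pairs <- utils::combn(usable, 2L, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    cvec <- .contrast_vector(eng$design, group, pr)
    co <- .engine_contrast(eng, cvec)
    fit <- structure(
      list(genes = tibble::tibble(gene = rownames(v), log2fc = co$coef,
                                  s2 = eng$s2),
           df_residual = eng$df, v_c = co$v_c,
           contrast = paste(pr, collapse = " vs "), n = ncol(v)),
      class = "de_fit"
    )
    tab <- moderated_t(fit, moderation, moderate = moderate)
    tab <- call_differential(tab, q_max, min_abs_log2fc, fc_limit)
    dplyr::mutate(tab, contrast = fit$contrast, .before = 1L)
  })
  attr(out, "moderation") <- moderation
  out
}
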