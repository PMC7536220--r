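mk_expr <- function(v, nr, genes = NULL, samples = NULL) {
  m <- matrix(v, nrow = nr)
  rownames(m) <- genes %||% paste0("G", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  expr_mat(m, log2 = TRUE)
}

test_that("linear fit recovers closed-form two-group statistics", {
  set.seed(51)
  x <- mk_expr(rnorm(60), 10)
  grp <- rep(c("A", "B"), each = 3)
  fit <- fit_linear_de(x, grp, contrast = c("A", "B"))
  expect_equal(fit$df_residual, 4L)
  expect_equal(fit$v_c, 2 / 3, tolerance = 1e-12)
  md <- rowMeans(unclass(x)[, 1:3]) - rowMeans(unclass(x)[, 4:6])
  expect_equal(fit$genes$log2fc, unname(md), tolerance = 1e-12)
  # exact values: {1,1,1} vs {2,2,2} -> lfc -1 (A - B), zero variance
  y <- mk_expr(rep(c(1, 2), each = 3), 1)
  f2 <- fit_linear_de(y, grp)
  expect_equal(f2$genes$log2fc, -1)
  expect_equal(f2$genes$s2, 0)
  expect_error(fit_linear_de(x, grp, contrast = c("A", "B"),
                             covariate = grp),
               "confounded|rank")
  expect_error(fit_linear_de(x, c("A", rep("B", 5)), contrast = c("A", "B")),
               "at least 2")
})

test_that("a balanced covariate leaves the contrast coefficient unchanged", {
  set.seed(52)
  x <- mk_expr(rnorm(160), 20)
  grp <- rep(c("A", "B"), each = 4)
  pat <- rep(c("p1", "p2", "p3", "p4"), 2)   # balanced across groups
  plain <- fit_linear_de(x, grp)
  withcov <- fit_linear_de(x, grp, covariate = pat)
  expect_equal(withcov$genes$log2fc, plain$genes$log2fc, tolerance = 1e-9)
  # large known shifts must not move the log2FC either
  shifts <- c(p1 = 40, p2 = -25, p3 = 10, p4 = -80)
  xs <- expr_mat(unclass(x) + matrix(shifts[pat], 20, 8, byrow = TRUE),
                 log2 = TRUE)
  shifted <- fit_linear_de(xs, grp, covariate = pat)
  expect_equal(shifted$genes$log2fc, plain$genes$log2fc, tolerance = 1e-9)
})

test_that("unmoderated p-values equal the equal-variance t-test", {
  set.seed(53)
  x <- mk_expr(rnorm(300), 30)
  grp <- rep(c("A", "B"), each = 5)
  fit <- fit_linear_de(x, grp, contrast = c("A", "B"))
  tab <- moderated_t(fit, moderate = FALSE)
  for (g in seq_len(nrow(x))) {
    ref <- t.test(unclass(x)[g, grp == "A"], unclass(x)[g, grp == "B"],
                  var.equal = TRUE)
    expect_equal(tab$p[g], ref$p.value, tolerance = 1e-10)
    expect_equal(tab$t[g], unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("moderated t matches limma when fed limma's prior", {
  set.seed(54)
  sim <- simulate_bulk_two_group(bulk_sim_config(n_genes = 400), seed = 9)
  grp <- sample_info(sim$matrix)$group
  design <- stats::model.matrix(~ 0 + factor(grp))
  colnames(design) <- c("A", "B")
  lfit <- limma::lmFit(unclass(sim$matrix), design)
  lfit <- limma::contrasts.fit(lfit,
                               limma::makeContrasts(B - A, levels = design))
  eb <- limma::eBayes(lfit)
  fit <- fit_linear_de(sim$matrix, grp, contrast = c("B", "A"))
  prior <- structure(list(d0 = eb$df.prior, s0_2 = eb$s2.prior,
                          n_genes = 400),
                     class = "moderation_params")
  tab <- moderated_t(fit, moderation = prior)
  expect_equal(tab$t, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(tab$p, unname(eb$p.value[, 1]), tolerance = 1e-8)
  # and the package's own prior estimate agrees with limma's
  own <- estimate_moderation(fit$genes$s2, fit$df_residual)
  expect_equal(own$d0, eb$df.prior, tolerance = 0.05)
  expect_equal(own$s0_2, eb$s2.prior, tolerance = 0.05)
})

test_that("moderation prior estimation recovers generating parameters", {
  sim <- simulate_bulk_two_group(bulk_sim_config(n_genes = 5000), seed = 31)
  fit <- fit_linear_de(sim$matrix, sample_info(sim$matrix)$group)
  est <- estimate_moderation(fit$genes$s2, fit$df_residual)
  expect_lt(abs(est$d0 - 4) / 4, 0.2)
  expect_lt(abs(est$s0_2 - 0.05) / 0.05, 0.2)
  # identical variances drive the prior df to the cap
  flat <- estimate_moderation(rep(0.3, 100), df = 4)
  expect_equal(flat$d0, 1e6)
  expect_equal(flat$s0_2, 0.3, tolerance = 1e-4)
  expect_warning(estimate_moderation(runif(5, 0.1, 1), df = 4),
                 "fewer than 10")
})

test_that("moderation limits behave: toggle off and capped prior", {
  set.seed(55)
  x <- mk_expr(rnorm(200, sd = 0.5), 20)
  grp <- rep(c("A", "B"), each = 5)
  fit <- fit_linear_de(x, grp)
  plain <- moderated_t(fit, moderate = FALSE)
  # huge prior df pins every posterior variance at s0^2
  capped <- moderated_t(fit, moderation = structure(
    list(d0 = 1e6, s0_2 = 0.25, n_genes = 20),
    class = "moderation_params"))
  expect_equal(capped$s2_post, rep(0.25, 20), tolerance = 1e-4)
  # exact zero fold change gives p = 1; zero variance with effect gives 0
  fz <- structure(
    list(genes = tibble::tibble(gene = c("g1", "g2"), log2fc = c(0, 1),
                                s2 = c(0.1, 0)),
         df_residual = 8L, v_c = 0.4, contrast = "A vs B", n = 10),
    class = "de_fit")
  tabz <- moderated_t(fz, moderate = FALSE)
  expect_equal(tabz$p, c(1, 0))
})

test_that("differential calling applies the FDR and fold-change rules", {
  st <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       log2fc = c(0.60, 0.50, 2.0, -0.9),
                       q = c(0.04, 0.04, 0.06, 0.01))
  out <- call_differential(st)
  expect_equal(out$differential, c(TRUE, FALSE, FALSE, TRUE))
  nofc <- call_differential(st, fc_limit = FALSE)
  expect_equal(nofc$differential, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("pairwise contrasts share one moderation fit and skip tiny groups", {
  set.seed(56)
  x <- mk_expr(rnorm(40 * 9), 40, samples = paste0("S", 1:9))
  grp <- rep(c("A", "B", "C"), each = 3)
  res <- pairwise_de(x, grp)
  expect_setequal(unique(res$contrast), c("A vs B", "A vs C", "B vs C"))
  expect_s3_class(attr(res, "moderation"), "moderation_params")
  # two groups reduce to the single-contrast route
  x2 <- x[, 1:6]
  r2 <- pairwise_de(x2, grp[1:6])
  single <- de_analysis(x2, grp[1:6], contrast = c("A", "B"))
  expect_equal(r2$log2fc, tidy(single)$log2fc, tolerance = 1e-12)
  expect_equal(r2$p, tidy(single)$p, tolerance = 1e-12)
  # four groups -> 6 contrasts; a singleton group is skipped with a warning
  grp4 <- c(rep(c("A", "B", "C"), each = 3))
  grp4[9] <- "D"
  expect_warning(r4 <- pairwise_de(x, grp4), "skipped")
  expect_equal(length(unique(r4$contrast)), 3L)  # C(3,2) among usable
})

test_that("synthetic bulk DE realizes low FDR and good sensitivity", {
  hits <- purrr::map_dfr(1:3, function(s) {
    sim <- simulate_bulk_two_group(bulk_sim_config(), seed = s)
    res <- de_analysis(sim$matrix, sample_info(sim$matrix)$group,
                       contrast = c("B", "A"))
    tt <- dplyr::left_join(tidy(res), sim$truth$genes, by = "gene")
    called <- dplyr::filter(tt, differential)
    tibble::tibble(fdr = mean(!called$is_de),
                   sens = sum(called$is_de) / sum(tt$is_de))
  })
  expect_lte(max(hits$fdr), 0.10)
  expect_gte(min(hits$sens), 0.6)
})
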