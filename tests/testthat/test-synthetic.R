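test_that("every generator is a pure function of (config, seed)", {
  a <- simulate_single_cell_matrix(seed = 5)
  b <- simulate_single_cell_matrix(seed = 5)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(unclass(a$sets), unclass(b$sets))
  c1 <- simulate_bulk_two_group(seed = 5)
  c2 <- simulate_bulk_two_group(seed = 5)
  expect_identical(unclass(c1$matrix), unclass(c2$matrix))
  s1 <- simulate_signature_pair(seed = 5)
  s2 <- simulate_signature_pair(seed = 5)
  expect_identical(s1$sig_a, s2$sig_a)
  k1 <- simulate_aberration_calls(seed = 5)
  k2 <- simulate_aberration_calls(seed = 5)
  expect_identical(k1$calls, k2$calls)
  # a different seed changes the draw
  expect_false(identical(unclass(a$matrix),
                         unclass(simulate_single_cell_matrix(seed = 6)$matrix)))
})

test_that("single-cell dropout calibration matches the configured rates", {
  cfg <- sc_sim_config(n_genes = 500, groups = c(M0 = 20, HD = 20),
                       patients = c(M0 = 5, HD = 5), n_active = 2,
                       active_groups = "M0")
  sim <- simulate_single_cell_matrix(cfg, seed = 11)
  mask <- expressed_mask(sim$matrix)
  grp <- sample_info(sim$matrix)$group
  members <- unique(unlist(unclass(sim$sets)[sim$truth$active$pathway]))
  in_set <- rownames(mask) %in% members
  # active members in the active group: pi0 + delta within 3 binomial SE
  n_act <- sum(in_set) * sum(grp == "M0")
  p_act <- mean(mask[in_set, grp == "M0"])
  expect_lt(abs(p_act - (cfg$pi0 + cfg$delta)),
            3 * sqrt(0.7 * 0.3 / n_act) + 0.02)
  # background genes track pi0 (allowing the max(0, .) truncation)
  n_bg <- sum(!in_set) * length(grp)
  p_bg <- mean(mask[!in_set, ])
  expect_lt(abs(p_bg - cfg$pi0), 3 * sqrt(0.4 * 0.6 / n_bg) + 0.02)
  # pi0 = 0 silences the matrix entirely
  quiet <- simulate_single_cell_matrix(
    sc_sim_config(n_genes = 50, groups = c(HD = 5), patients = c(HD = 2),
                  pi0 = 0, delta = 0, n_active = 0), seed = 12)
  expect_true(all(unclass(quiet$matrix) == 0))
})

test_that("a zero activation lift leaves members at background rates", {
  cfg <- sc_sim_config(n_genes = 200, groups = c(M0 = 10),
                       patients = c(M0 = 3), delta = 0, n_active = 3)
  sim <- simulate_single_cell_matrix(cfg, seed = 13)
  mask <- expressed_mask(sim$matrix)
  members <- rownames(mask) %in%
    unique(unlist(unclass(sim$sets)[sim$truth$active$pathway]))
  n_pairs <- min(sum(members), sum(!members)) * ncol(mask)
  se <- sqrt(0.4 * 0.6 * (1 / (sum(members) * ncol(mask)) +
                            1 / (sum(!members) * ncol(mask))))
  expect_lt(abs(mean(mask[members, ]) - mean(mask[!members, ])), 2 * se + 0.02)
})

test_that("bulk generator respects its variance and design knobs", {
  # infinite prior df makes every variance s0^2, driving the estimate to cap
  flat <- simulate_bulk_two_group(
    bulk_sim_config(n_genes = 400, d0 = Inf, de_fraction = 0), seed = 14)
  fit <- fit_linear_de(flat$matrix, sample_info(flat$matrix)$group)
  est <- estimate_moderation(fit$genes$s2, fit$df_residual)
  expect_gt(est$d0, 1e3)
  # with no true DE the caller stays near-empty at FDR 0.05
  res <- de_analysis(flat$matrix, sample_info(flat$matrix)$group)
  expect_lte(sum(tidy(res)$differential), 0.05 * 400)
  # paired patients annotate and shift samples
  paired <- simulate_bulk_two_group(
    bulk_sim_config(n_genes = 50, paired_patients = TRUE), seed = 15)
  expect_true("patient" %in% names(sample_info(paired$matrix)))
})

test_that("signature pairs hit rho targets in expectation", {
  exact <- simulate_signature_pair(sig_sim_config(rho_target = 1), seed = 16)
  expect_equal(noncentered_cor(exact$sig_a$log2fc, exact$sig_b$log2fc), 1,
               tolerance = 1e-12)
  rs <- vapply(1:100, function(s) {
    sim <- simulate_signature_pair(sig_sim_config(n_genes = 100,
                                                  rho_target = 0),
                                   seed = s)
    noncentered_cor(sim$sig_a$log2fc, sim$sig_b$log2fc)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  neg <- simulate_signature_pair(sig_sim_config(rho_target = -0.7),
                                 seed = 17)
  expect_lt(noncentered_cor(neg$sig_a$log2fc, neg$sig_b$log2fc), -0.3)
})

test_that("aberration generator edge cases compose with the filter", {
  none <- simulate_aberration_calls(cna_sim_config(event_rate = 0),
                                    seed = 18)
  expect_equal(nrow(none$calls), 0L)
  tiny <- simulate_aberration_calls(
    cna_sim_config(length_meanlog = log(1e4), length_sdlog = 0.1),
    seed = 19)
  expect_gt(nrow(tiny$calls), 0L)
  expect_equal(nrow(filter_aberrations(tiny$calls)), 0L)
  # recorded ground truth equals recomputation from the emitted calls
  sim <- simulate_aberration_calls(seed = 20)
  prof <- cumulative_frequency(sim$calls, sim$roster,
                               dplyr::select(sim$cytobands, -stain))
  expect_equal(prof, sim$truth)
})

test_that("fixture files round-trip bit-identically at a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(d1, seed = 21)
  p2 <- write_fixtures(d2, seed = 21)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = nm)
  }
  # round-trip: matrices, signatures, calls and cytobands reload intact
  sc <- simulate_single_cell_matrix(seed = 21)
  back <- read_expr_tsv(p1[["sc_matrix"]], samples = p1[["sc_samples"]])
  expect_equal(unclass(back), unclass(sc$matrix), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sample_info(back), sample_info(sc$matrix))
  sets <- read_gmt(p1[["gmt"]])
  expect_equal(unclass(sets), unclass(sc$sets), ignore_attr = TRUE)
  cna <- simulate_aberration_calls(seed = 21)
  calls <- read_cna_calls(p1[["calls"]])
  expect_equal(calls, cna$calls)
  expect_equal(read_cytobands(p1[["cytobands"]]), cna$cytobands)
  sig <- read_signature_tsv(p1[["sig_a"]])
  expect_equal(sig, simulate_signature_pair(seed = 21)$sig_a)
})

test_that("MTX triplet input densifies into an annotated matrix", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(c(0, 2.5, 1, 0, 0, 3), 3, 2, sparse = TRUE)
  Matrix::writeMM(m, file.path(d, "matrix.mtx"))
  writeLines(paste0("G", 1:3), file.path(d, "features.tsv"))
  readr::write_tsv(tibble::tibble(sample = c("c1", "c2"),
                                  group = c("M0", "M1")),
                   file.path(d, "samples.tsv"))
  x <- read_expr_mtx(file.path(d, "matrix.mtx"),
                     file.path(d, "features.tsv"),
                     file.path(d, "samples.tsv"))
  expect_true(is_log2(x))
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(unname(unclass(x)[, 2]), c(0, 0, 3))
  expect_equal(sample_info(x)$group, c("M0", "M1"))
})
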