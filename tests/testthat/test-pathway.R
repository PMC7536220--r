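toy_mask <- function(values, genes, cells) {
  m <- matrix(values, length(genes), length(cells),
              dimnames = list(genes, cells))
  x <- expr_mat(m, log2 = TRUE)
  expressed_mask(x)
}

test_that("gene-set collections normalize symbols and validate", {
  gs <- gene_sets(list(a = c("Tp53", "kit"), b = "IL6"), source = "toy")
  expect_equal(gs$a, c("TP53", "KIT"))
  expect_error(gene_sets(list(a = character())), "empty")
  expect_error(gene_sets(list(c("X"))), "named")
  expect_error(gene_sets(list(a = "X", a = "Y")), "unique")
})

test_that("GMT files round-trip through read and write", {
  gs <- gene_sets(list(PW1 = c("A", "B", "C"), PW2 = c("B", "D")),
                  source = "toy")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path, source = "toy")
  expect_equal(unclass(back), unclass(gs), ignore_attr = TRUE)
})

test_that("expressed mask uses a strict threshold on log2 values", {
  mask <- toy_mask(c(0, 0.01, -1, 2), paste0("G", 1:2), paste0("c", 1:2))
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(mask, "threshold"), 0)
  raw <- expr_mat(matrix(1, 1, 1, dimnames = list("G1", "c1")),
                  log2 = FALSE)
  expect_error(expressed_mask(raw), "log2")
})

test_that("gene-list enrichment equals the hypergeometric tail", {
  uni <- paste0("G", 1:10)
  gs <- gene_sets(list(hit = uni[1:5], other = uni[6:9]))
  res <- gene_list_enrichment(uni[1:5], uni, gs)
  expect_equal(res$p[res$pathway == "hit"], 1 / 252, tolerance = 1e-12)
  # zero overlap is never significant one-sided
  res0 <- gene_list_enrichment(uni[6:10], uni,
                               gene_sets(list(hit = uni[1:5])))
  expect_equal(res0$p, 1, tolerance = 1e-12)
  # list = universe carries no information
  resu <- gene_list_enrichment(uni, uni, gs)
  expect_equal(resu$p, rep(1, 2), tolerance = 1e-12)
  expect_error(gene_list_enrichment(character(), uni, gs), "empty")
  expect_warning(gene_list_enrichment(uni[1:2], uni,
                                      gene_sets(list(out = "ZZZ"))),
                 "no gene in the universe")
})

test_that("per-cell contingency tables have consistent margins", {
  set.seed(61)
  genes <- paste0("G", 1:200)
  m <- matrix(rbinom(200 * 8, 1, 0.4) * runif(1600, 0.5, 5), 200, 8,
              dimnames = list(genes, paste0("c", 1:8)))
  mask <- expressed_mask(expr_mat(m, log2 = TRUE))
  gs <- gene_sets(list(p1 = sample(genes, 30), p2 = sample(genes, 50)))
  tbl <- per_cell_pathway_test(mask, gs)
  expect_equal(nrow(tbl), 16L)
  expect_true(all(tbl$a + tbl$b + tbl$c + tbl$d == 200L))
  expect_equal(tbl$a + tbl$b,
               unname(colSums(mask))[match(tbl$cell, colnames(mask))])
  for (pw in c("p1", "p2")) {
    K <- length(intersect(gs[[pw]], genes))
    expect_true(all(tbl$a[tbl$pathway == pw] + tbl$c[tbl$pathway == pw] ==
                      K))
  }
})

test_that("per-cell p-values equal the hypergeometric tail oracle", {
  set.seed(62)
  for (i in 1:100) {
    N <- sample(50:300, 1)
    genes <- paste0("G", seq_len(N))
    vals <- rbinom(N, 1, runif(1, 0.2, 0.7)) * runif(N, 0.5, 4)
    mask <- expressed_mask(expr_mat(matrix(vals, N, 1,
                                           dimnames = list(genes, "c1")),
                                    log2 = TRUE))
    gs <- gene_sets(list(pw = sample(genes, sample(5:40, 1))))
    tbl <- per_cell_pathway_test(mask, gs)
    expect_equal(tbl$p,
                 hypergeometric_tail(N, tbl$a + tbl$c, tbl$a + tbl$b,
                                     tbl$a)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("a cell with no expressed genes is never enriched", {
  mask <- toy_mask(rep(0, 6), paste0("G", 1:3), paste0("c", 1:2))
  gs <- gene_sets(list(pw = c("G1", "G2")))
  tbl <- per_cell_pathway_test(mask, gs)
  expect_equal(tbl$a, c(0L, 0L))
  expect_equal(tbl$p, c(1, 1))
})

test_that("fully-expressed pathway against sparse background is significant", {
  set.seed(63)
  genes <- paste0("G", 1:1000)
  member <- genes[1:20]
  vals <- ifelse(genes %in% member, 1,
                 rbinom(1000, 1, 0.5) * 1)
  mask <- expressed_mask(expr_mat(matrix(vals, 1000, 1,
                                         dimnames = list(genes, "c1")),
                                  log2 = TRUE))
  tbl <- per_cell_pathway_test(mask, gene_sets(list(pw = member)))
  expect_lt(tbl$p, 1e-4)
})

test_that("cohort summary aggregates the two views sensibly", {
  flat <- tibble::tibble(cell = rep(paste0("c", 1:10), 2),
                         pathway = rep(c("a", "b"), each = 10),
                         p = 1)
  s <- summarize_pathway_enrichment(flat)
  expect_equal(s$frac_significant, c(0, 0))
  expect_equal(s$p_combined, c(1, 1))
  expect_false(any(s$enriched))
  strong <- dplyr::mutate(flat, p = ifelse(pathway == "a", 1e-6, 1))
  s2 <- summarize_pathway_enrichment(strong)
  expect_true(s2$enriched[s2$pathway == "a"])
  expect_false(s2$enriched[s2$pathway == "b"])
  expect_equal(s2$frac_significant[s2$pathway == "a"], 1)
})

test_that("a spiked pathway attains the smallest combined q", {
  sim <- simulate_single_cell_matrix(
    sc_sim_config(n_active = 1, groups = c(M0 = 29), patients = c(M0 = 21)),
    seed = 64
  )
  tbl <- per_cell_pathway_test(expressed_mask(sim$matrix), sim$sets)
  s <- summarize_pathway_enrichment(tbl)
  expect_equal(s$pathway[which.min(s$q_combined)],
               sim$truth$active$pathway[1])
})

test_that("core-gene partition applies the inclusive half rule", {
  genes <- paste0("G", 1:4)
  cells <- paste0("c", 1:40)
  vals <- matrix(0, 4, 40, dimnames = list(genes, cells))
  vals[1, 1:20] <- 1   # exactly half -> kept
  vals[2, 1:19] <- 1   # just under half -> dropped
  vals[3, ] <- 1       # everywhere
  vals[4, ] <- 1
  mask <- expressed_mask(expr_mat(vals, log2 = TRUE))
  gs <- gene_sets(list(pw1 = c("G1", "G2", "G3"), pw2 = c("G3", "G4")))
  part <- core_gene_partition(gs, mask, min_fraction = 0.5)
  expect_setequal(part$gene, c("G1", "G3", "G4"))
  expect_equal(part$status[part$gene == "G1"], "private")
  expect_equal(part$status[part$gene == "G3"], "shared")
  expect_equal(part$pathways[part$gene == "G3"][[1]], c("pw1", "pw2"))
  # private sets of different pathways are disjoint by construction
  priv <- part[part$status == "private", ]
  expect_equal(anyDuplicated(priv$gene), 0L)
  expect_error(core_gene_partition(gene_sets(list(a = "G1"))[0], mask),
               "empty")
})
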