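#' Simulation configurations
#'
#' Configuration constructors for the seeded generators. Defaults mirror the
#' structure of the study cohorts the pipeline was built for: 29 M0-stage
#' and 11 M1-stage bone-marrow disseminated cancer cells plus 15 healthy-
#' donor EpCAM+ cells (from 21/5/7 patients), a 12-pathway candidate
#' collection of which 4 are truly activated in the DCC groups, and a
#' small-replicate two-group bulk design with a scaled inverse-chi-square
#' gene-variance law (`d0 = 4`, `s0^2 = 0.05`).
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of cells per group.
#' @param patients Named integer vector of patients per group.
#' @param n_batches Number of processing batches.
#' @param n_pathways,pathway_size Number of pathways and the (min, max) of
#'   their uniform size distribution.
#' @param n_active Number of truly activated pathways.
#' @param active_groups Groups in which the active pathways are spiked.
#' @param pi0 Baseline per-gene expressed probability.
#' @param delta Added expressed probability for active-pathway members in
#'   cells of an active group.
#' @param baseline_range (min, max) of the uniform per-gene baseline log2
#'   level for expressed genes.
#' @param patient_sd,batch_sd,noise_sd SDs of the additive patient, batch
#'   and residual effects (log2 units).
#' @return A config list of the matching class.
#' @name sim_config
NULL

#' @rdname sim_config
#' @export
sc_sim_config <- function(n_genes = 1000,
                          groups = c(M0 = 29, M1 = 11, HD = 15),
                          patients = c(M0 = 21, M1 = 5, HD = 7),
                          n_batches = 2,
                          n_pathways = 12,
                          pathway_size = c(40, 80),
                          n_active = 4,
                          active_groups = c("M0", "M1"),
                          pi0 = 0.4,
                          delta = 0.3,
                          baseline_range = c(1, 6),
                          patient_sd = 0.3,
                          batch_sd = 0.3,
                          noise_sd = 0.5) {
  stopifnot(n_genes >= 1, all(groups >= 1), all(names(patients) ==
              names(groups)), pi0 >= 0, pi0 <= 1, delta >= 0)
  as.list(environment())
}

#' @rdname sim_config
#' @param n_per_group Replicates per group (two groups, `A` and `B`).
#' @param de_fraction Fraction of genes truly differential.
#' @param log2fc True absolute log2 fold change of differential genes.
#' @param d0,s0_2 Prior df and prior variance of the scaled
#'   inverse-chi-square gene-variance law (`d0 = Inf` makes all variances
#'   `s0_2`).
#' @param paired_patients Logical; add a shared per-patient shift to the
#'   i-th sample of each group (a balanced patient covariate).
#' @export
bulk_sim_config <- function(n_genes = 2000, n_per_group = 5,
                            de_fraction = 0.1, log2fc = 1,
                            d0 = 4, s0_2 = 0.05,
                            paired_patients = FALSE, patient_sd = 0.5,
                            baseline_range = c(4, 10)) {
  stopifnot(n_genes >= 1, n_per_group >= 2, de_fraction >= 0,
            de_fraction <= 1, d0 > 0, s0_2 > 0)
  as.list(environment())
}

#' @rdname sim_config
#' @param rho_target Target non-centered correlation between the two
#'   signatures' log2 fold changes.
#' @param de_threshold Absolute log2 fold change that flags a gene
#'   differential in the emitted signatures.
#' @export
sig_sim_config <- function(n_genes = 200, rho_target = 0.8,
                           de_threshold = log2(1.5)) {
  stopifnot(n_genes >= 3, rho_target >= -1, rho_target <= 1)
  as.list(environment())
}

#' @rdname sim_config
#' @param chrom_lengths Named vector of toy chromosome lengths (bp).
#' @param band_width Cytoband width of the toy genome (bp).
#' @param event_rate Poisson mean number of aberration events per cell.
#' @param length_meanlog,length_sdlog Log-normal parameters of event
#'   lengths (the default straddles the 1 Mb size filter).
#' @param gain_prob Probability that an event is a gain (else a loss).
#' @export
cna_sim_config <- function(chrom_lengths = c(chr1 = 1e8, chr2 = 8e7,
                                             chr3 = 6e7),
                           band_width = 1e7,
                           groups = c(M0 = 29, M1 = 11),
                           event_rate = 3,
                           length_meanlog = log(2e6),
                           length_sdlog = 1,
                           gain_prob = 0.5) {
  stopifnot(all(chrom_lengths >= band_width), event_rate >= 0,
            gain_prob >= 0, gain_prob <= 1)
  as.list(environment())
}

#' Simulate a single-cell log2 expression matrix with spiked pathways
#'
#' Zero-inflated log-normal generator on the log2 scale: gene `g` is
#' expressed in cell `c` with probability `pi0`, lifted by `delta` when `g`
#' belongs to a pathway that is active in the cell's group. Expressed values
#' are `max(0, baseline_g + patient + batch + noise)`; non-expressed values
#' are exactly 0 (dropout). Group, patient and batch ride along as sample
#' annotations, and the generator is a pure function of `(config, seed)`.
#'
#' @param config A [sc_sim_config()].
#' @param seed Integer seed (a generator-specific sub-stream is derived
#'   from it, so different generators never share a stream).
#' @return A list: `matrix` (log2-scale [expr_mat()]), `sets` (the pathway
#'   [gene_sets()]), and `truth` (active pathway-group map and generating
#'   parameters).
#' @export
simulate_single_cell_matrix <- function(config = sc_sim_config(), seed = 1) {
  withr::with_seed(.substream(seed, "single_cell"), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    sizes <- sample(config$pathway_size[1]:config$pathway_size[2],
                    config$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(genes, min(s, length(genes))))
    names(sets) <- sprintf("PW%02d", seq_len(config$n_pathways))
    sets <- gene_sets(sets, source = "synthetic")
    active <- names(sets)[seq_len(min(config$n_active, length(sets)))]

    grp <- rep(names(config$groups), config$groups)
    cells <- sprintf("%s_c%02d", grp, unlist(lapply(config$groups, seq_len)))
    patient <- unlist(lapply(names(config$groups), function(g) {
      ids <- sprintf("%s_p%02d", g, seq_len(config$patients[[g]]))
      sort(rep_len(ids, config$groups[[g]]))
    }))
    batch <- sprintf("b%d", rep_len(seq_len(config$n_batches),
                                    length(cells)))

    baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                             config$baseline_range[2])
    patient_eff <- stats::rnorm(length(unique(patient)), 0,
                                config$patient_sd)
    names(patient_eff) <- unique(patient)
    batch_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)
    names(batch_eff) <- sprintf("b%d", seq_len(config$n_batches))

    member_active <- matrix(FALSE, config$n_genes, length(cells),
                            dimnames = list(genes, cells))
    in_active <- genes %in% unique(unlist(sets[active]))
    active_cell <- grp %in% config$active_groups
    member_active[in_active, active_cell] <- TRUE

    prob <- matrix(config$pi0, config$n_genes, length(cells))
    prob[member_active] <- config$pi0 + config$delta
    if (any(prob > 1)) {
      warning("pi0 + delta exceeds 1; clipped")
      prob <- pmin(prob, 1)
    }
    expressed <- matrix(stats::runif(length(prob)) < prob,
                        config$n_genes, length(cells))
    vals <- baseline +
      matrix(patient_eff[patient], config$n_genes, length(cells),
             byrow = TRUE) +
      matrix(batch_eff[batch], config$n_genes, length(cells),
             byrow = TRUE) +
      matrix(stats::rnorm(config$n_genes * length(cells), 0,
                          config$noise_sd),
             config$n_genes, length(cells))
    vals <- pmax(0, vals) * expressed
    dimnames(vals) <- list(genes, cells)

    samples <- tibble::tibble(sample = cells, group = grp,
                              patient = patient, batch = batch)
    list(
      matrix = expr_mat(vals, samples = samples, log2 = TRUE),
      sets = sets,
      truth = list(
        active = tidyr::expand_grid(pathway = active,
                                    group = config$active_groups),
        pi0 = config$pi0, delta = config$delta,
        expressed = expressed
      )
    )
  })
}

#' Simulate a small-replicate two-group bulk matrix
#'
#' Microarray-like generator: per-gene variances are drawn from the scaled
#' inverse-chi-square law `s0_2 * d0 / chisq(d0)` (all equal to `s0_2` when
#' `d0 = Inf`), a `de_fraction` of genes receives a `+/- log2fc` shift in
#' group B, and an optional balanced patient shift is shared by the i-th
#' replicate of each group.
#'
#' @param config A [bulk_sim_config()].
#' @inheritParams simulate_single_cell_matrix
#' @return A list: `matrix` (log2-scale [expr_mat()] with `group` and
#'   optional `patient` annotations) and `truth` (per-gene tibble with
#'   `is_de` and `true_log2fc`, plus the generating `d0`, `s0_2`).
#' @export
simulate_bulk_two_group <- function(config = bulk_sim_config(), seed = 1) {
  withr::with_seed(.substream(seed, "bulk_two_group"), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    n <- 2L * config$n_per_group
    grp <- rep(c("A", "B"), each = config$n_per_group)
    samp <- sprintf("%s%d", grp, rep(seq_len(config$n_per_group), 2L))
    s2 <- if (is.finite(config$d0)) {
      config$s0_2 * config$d0 / stats::rchisq(config$n_genes, config$d0)
    } else {
      rep(config$s0_2, config$n_genes)
    }
    n_de <- round(config$de_fraction * config$n_genes)
    is_de <- seq_len(config$n_genes) <= n_de
    true_lfc <- ifelse(is_de,
                       config$log2fc * sample(c(-1, 1), config$n_genes,
                                              replace = TRUE),
                       0)
    baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                             config$baseline_range[2])
    mu <- outer(baseline, rep(1, n)) +
      outer(true_lfc, as.numeric(grp == "B"))
    vals <- mu + matrix(stats::rnorm(config$n_genes * n), config$n_genes,
                        n) * sqrt(s2)
    patient <- NULL
    if (config$paired_patients) {
      patient <- sprintf("p%d", rep(seq_len(config$n_per_group), 2L))
      shift <- stats::rnorm(config$n_per_group, 0, config$patient_sd)
      vals <- vals + outer(rep(1, config$n_genes),
                           shift[rep(seq_len(config$n_per_group), 2L)])
    }
    dimnames(vals) <- list(genes, samp)
    samples <- tibble::tibble(sample = samp, group = grp)
    if (!is.null(patient)) samples$patient <- patient
    list(
      matrix = expr_mat(vals, samples = samples, log2 = TRUE),
      truth = list(
        genes = tibble::tibble(gene = genes, is_de = is_de,
                               true_log2fc = true_lfc, true_s2 = s2),
        d0 = config$d0, s0_2 = config$s0_2
      )
    )
  })
}

#' Simulate a pair of contrast signatures with controlled concordance
#'
#' Both signatures share a latent standard-normal log2 fold-change vector
#' plus independent noise scaled so that the expected (non-centered)
#' correlation equals `rho_target`; a negative target flips the sign of the
#' shared component in the second signature. Differential flags come from
#' thresholding `|log2fc|` at `de_threshold`.
#'
#' @param config A [sig_sim_config()].
#' @inheritParams simulate_single_cell_matrix
#' @return A list: `sig_a`, `sig_b` (tibbles `gene`, `log2fc`,
#'   `differential`) and `truth` (`rho_target`, the shared latent vector).
#' @export
simulate_signature_pair <- function(config = sig_sim_config(), seed = 1) {
  withr::with_seed(.substream(seed, "signature_pair"), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    rho <- config$rho_target
    f <- stats::rnorm(config$n_genes)
    if (abs(rho) < 1e-12) {
      x <- stats::rnorm(config$n_genes)
      y <- stats::rnorm(config$n_genes)
    } else {
      sigma2 <- (1 - abs(rho)) / abs(rho)
      x <- f + stats::rnorm(config$n_genes, 0, sqrt(sigma2))
      y <- sign(rho) * f + stats::rnorm(config$n_genes, 0, sqrt(sigma2))
    }
    mk <- function(lfc) tibble::tibble(
      gene = genes, log2fc = lfc,
      differential = abs(lfc) >= config$de_threshold
    )
    list(sig_a = mk(x), sig_b = mk(y),
         truth = list(rho_target = rho, latent = f))
  })
}

#' Simulate per-cell aberration calls on a toy genome
#'
#' Per cell, a Poisson number of gain/loss events with log-normal lengths
#' (straddling the 1 Mb size-filter boundary by default) placed uniformly on
#' a toy genome whose cytoband table tiles each chromosome in fixed-width
#' bands, the central two flagged `acen` and the terminal bands `gvar`. The
#' true per-band cohort frequencies of the emitted (unfiltered) calls are
#' recorded by construction.
#'
#' @param config A [cna_sim_config()].
#' @inheritParams simulate_single_cell_matrix
#' @return A list: `calls` (tibble as in [read_cna_calls()]), `cytobands`
#'   (toy table), `roster` (cell/group tibble) and `truth` (per-bin
#'   frequency tibble shaped like [cumulative_frequency()] output).
#' @export
simulate_aberration_calls <- function(config = cna_sim_config(), seed = 1) {
  withr::with_seed(.substream(seed, "aberration_calls"), {
    bands <- purrr::imap_dfr(config$chrom_lengths, function(len, ch) {
      b <- make_genome_bins(stats::setNames(len, ch), config$band_width)
      nb <- nrow(b)
      half <- ceiling(nb / 2)
      nm <- c(sprintf("p%d", rev(seq_len(half))),
              sprintf("q%d", seq_len(nb - half)))
      stain <- rep("gneg", nb)
      stain[c(half, min(half + 1L, nb))] <- "acen"
      stain[c(1L, nb)] <- "gvar"
      dplyr::mutate(b, band = nm, stain = stain)
    })
    grp <- rep(names(config$groups), config$groups)
    cells <- sprintf("%s_c%02d", grp,
                     unlist(lapply(config$groups, seq_len)))
    roster <- tibble::tibble(cell = cells, group = grp)
    n_ev <- stats::rpois(length(cells), config$event_rate)
    total <- sum(n_ev)
    calls <- if (total == 0L) {
      tibble::tibble(cell_id = character(), chrom = character(),
                     start = numeric(), end = numeric(),
                     type = character())
    } else {
      chrom <- sample(names(config$chrom_lengths), total, replace = TRUE,
                      prob = config$chrom_lengths)
      len <- pmin(round(stats::rlnorm(total, config$length_meanlog,
                                      config$length_sdlog)),
                  config$chrom_lengths[chrom])
      len <- pmax(len, 1)
      start <- floor(stats::runif(total, 1,
                                  config$chrom_lengths[chrom] - len + 1))
      tibble::tibble(
        cell_id = rep(cells, n_ev),
        chrom = chrom,
        start = start,
        end = start + len - 1,
        type = ifelse(stats::runif(total) < config$gain_prob,
                      "gain", "loss")
      )
    }
    calls <- validate_cna_calls(calls)
    truth <- cumulative_frequency(calls, roster,
                                  dplyr::select(bands, -"stain"))
    list(calls = calls, cytobands = bands, roster = roster, truth = truth)
  })
}

#' Write a full synthetic fixture set to disk
#'
#' Runs all four generators at one seed and writes every dataset in its
#' external exchange format: single-cell matrix (TSV + sample TSV + GMT +
#' feature annotation TSV), bulk matrix (TSV + sample TSV), signature pair
#' (TSV), aberration calls (TSV), toy cytoband table (UCSC cytoBand.txt
#' format) and a ground-truth JSON. Re-running with the same seed
#' regenerates the files bit-identically.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed passed to every generator.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- simulate_single_cell_matrix(seed = seed)
  bulk <- simulate_bulk_two_group(seed = seed)
  sig <- simulate_signature_pair(seed = seed)
  cna <- simulate_aberration_calls(seed = seed)
  paths <- c(
    sc_matrix = file.path(dir, "sc_matrix.tsv"),
    sc_samples = file.path(dir, "sc_samples.tsv"),
    sc_annotation = file.path(dir, "sc_annotation.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    bulk_matrix = file.path(dir, "bulk_matrix.tsv"),
    bulk_samples = file.path(dir, "bulk_samples.tsv"),
    sig_a = file.path(dir, "signature_a.tsv"),
    sig_b = file.path(dir, "signature_b.tsv"),
    calls = file.path(dir, "cna_calls.tsv"),
    cytobands = file.path(dir, "cytoBand.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expr_tsv(sc$matrix, paths["sc_matrix"])
  readr::write_tsv(sample_info(sc$matrix), paths["sc_samples"])
  readr::write_tsv(
    tibble::tibble(feature_id = rownames(sc$matrix),
                   gene_symbol = rownames(sc$matrix),
                   biotype = "protein_coding"),
    paths["sc_annotation"]
  )
  write_gmt(sc$sets, paths["gmt"])
  write_expr_tsv(bulk$matrix, paths["bulk_matrix"])
  readr::write_tsv(sample_info(bulk$matrix), paths["bulk_samples"])
  readr::write_tsv(sig$sig_a, paths["sig_a"])
  readr::write_tsv(sig$sig_b, paths["sig_b"])
  readr::write_tsv(dplyr::select(cna$calls, -"length"), paths["calls"])
  # UCSC convention: 0-based half-open, no header
  readr::write_tsv(
    dplyr::transmute(cna$cytobands, .data$chrom, start = .data$start - 1,
                     .data$end, .data$band, .data$stain),
    paths["cytobands"], col_names = FALSE
  )
  jsonlite::write_json(
    list(seed = seed,
         sc_active = sc$truth$active,
         bulk = bulk$truth$genes,
         rho_target = sig$truth$rho_target,
         cna_truth = cna$truth),
    paths["truth"], digits = NA
  )
  invisible(paths)
}
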