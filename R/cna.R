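#' Read per-cell copy-number aberration calls
#'
#' BED-like TSV with a header and columns `cell_id`, `chrom`, `start`,
#' `end`, `type` (`gain` or `loss`). Coordinates are stored 1-based closed
#' (cytogenetic convention); set `bed_coords = TRUE` for 0-based half-open
#' input, which is converted on read (`start + 1`, `end` unchanged).
#'
#' @param path TSV path.
#' @param bed_coords Logical; input uses BED coordinates.
#' @return A tibble of calls with a `length` column (`end - start + 1`).
#' @export
read_cna_calls <- function(path, bed_coords = FALSE) {
  calls <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             cell_id = readr::col_character(),
                             chrom = readr::col_character(),
                             start = readr::col_double(),
                             end = readr::col_double(),
                             type = readr::col_character()
                           ))
  if (bed_coords) calls$start <- calls$start + 1
  validate_cna_calls(calls)
}

#' @rdname read_cna_calls
#' @param calls A tibble of calls (1-based closed coordinates).
#' @export
validate_cna_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("cell_id", "chrom", "start", "end", "type") %in%
                  names(calls)))
  if (any(calls$start > calls$end)) {
    stop("calls with start > end", call. = FALSE)
  }
  if (!all(calls$type %in% c("gain", "loss"))) {
    stop("`type` must be 'gain' or 'loss'", call. = FALSE)
  }
  dplyr::mutate(calls, length = .data$end - .data$start + 1)
}

#' Read a UCSC cytoband table
#'
#' `cytoBand.txt` format: tab-separated `chrom`, `chromStart`, `chromEnd`,
#' `name`, `gieStain` without a header, 0-based half-open coordinates
#' (converted to 1-based closed on read). Bands must tile each chromosome
#' without gaps or overlaps.
#'
#' @param path Path to a cytoBand-format file.
#' @return A tibble: `chrom`, `start`, `end`, `band`, `stain`, sorted.
#' @export
read_cytobands <- function(path) {
  tab <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "band", "stain"),
    show_col_types = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), band = readr::col_character(),
      stain = readr::col_character()
    )
  )
  tab$start <- tab$start + 1
  .validate_cytobands(tab)
}

.validate_cytobands <- function(tab) {
  tab <- dplyr::arrange(tibble::as_tibble(tab), .data$chrom, .data$start)
  ok <- tab |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      tiled = .data$start[1] == 1 &&
        all(.data$start[-1] == .data$end[-dplyr::n()] + 1),
      .groups = "drop"
    )
  if (!all(ok$tiled)) {
    stop(sprintf("cytobands do not tile chromosome(s): %s",
                 paste(ok$chrom[!ok$tiled], collapse = ", ")),
         call. = FALSE)
  }
  tab
}

#' Default artifact blacklist from a cytoband table
#'
#' Builds the exclusion regions used before frequency profiling:
#' centromeric/heterochromatic bands (stains `acen`, `gvar`, `stalk`) and a
#' fixed-width flank at each chromosome end (telomeric regions). Any custom
#' blacklist tibble (`chrom`, `start`, `end`, `reason`) can be supplied to
#' the filter instead, e.g. to add recurrent platform artifacts.
#'
#' @param cytobands Tibble from [read_cytobands()].
#' @param telomere_flank Width (bp) of the terminal regions to exclude.
#' @param stains Stain classes to exclude.
#' @return A blacklist tibble: `chrom`, `start`, `end`, `reason`.
#' @export
default_blacklist <- function(cytobands, telomere_flank = 1e6,
                              stains = c("acen", "gvar", "stalk")) {
  cytobands <- .validate_cytobands(cytobands)
  cen <- cytobands |>
    dplyr::filter(.data$stain %in% stains) |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     reason = "centromeric")
  tel <- cytobands |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop") |>
    dplyr::reframe(
      chrom = rep(.data$chrom, 2L),
      start = c(rep(1, dplyr::n()), pmax(1, .data$len - telomere_flank + 1)),
      end = c(pmin(.data$len, rep(telomere_flank, dplyr::n())), .data$len),
      reason = "telomeric"
    )
  dplyr::arrange(dplyr::bind_rows(cen, tel), .data$chrom, .data$start)
}

# total blacklisted overlap (bp) of each call, merging blacklist intervals
.blacklist_overlap <- function(calls, blacklist) {
  out <- numeric(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    bl <- blacklist[blacklist$chrom == ch, , drop = FALSE]
    if (nrow(bl) == 0L) next
    blr <- IRanges::reduce(IRanges::IRanges(bl$start, bl$end))
    cr <- IRanges::IRanges(calls$start[ci], calls$end[ci])
    hits <- IRanges::findOverlaps(cr, blr)
    if (length(hits) == 0L) next
    pint <- IRanges::pintersect(cr[S4Vectors::queryHits(hits)],
                                blr[S4Vectors::subjectHits(hits)])
    ov <- tapply(IRanges::width(pint), S4Vectors::queryHits(hits), sum)
    out[ci[as.integer(names(ov))]] <- as.numeric(ov)
  }
  out
}

#' Filter aberration calls by size and artifact blacklist
#'
#' Drops calls shorter than `min_length` (strictly: a 999,999 bp call is
#' dropped, a 1,000,000 bp call kept), calls on chromosomes absent from
#' `chromosomes` (with a warning), and calls whose overlap with the merged
#' blacklist exceeds `max_blacklist_overlap` of the call's length. Per-rule
#' drop counts are attached as `attr(, "drop_counts")`.
#'
#' The filter is idempotent: re-filtering a filtered set changes nothing.
#'
#' @param calls Call tibble (see [read_cna_calls()]).
#' @param min_length Minimum call length in bp (default 1 Mb).
#' @param blacklist Optional blacklist tibble (`chrom`, `start`, `end`).
#' @param chromosomes Optional character vector of valid chromosome names
#'   (e.g. from the cytoband table).
#' @param max_blacklist_overlap Maximum tolerated blacklisted fraction of a
#'   call's length (default 0.5).
#' @return The filtered calls, with drop counts in `attr(, "drop_counts")`.
#' @export
filter_aberrations <- function(calls, min_length = 1e6, blacklist = NULL,
                               chromosomes = NULL,
                               max_blacklist_overlap = 0.5) {
  calls <- validate_cna_calls(calls)
  n0 <- nrow(calls)
  if (!is.null(chromosomes)) {
    bad <- !calls$chrom %in% chromosomes
    if (any(bad)) {
      warning(sprintf("%d calls on unknown chromosomes dropped", sum(bad)))
    }
    calls <- calls[!bad, , drop = FALSE]
  } else {
    bad <- logical(n0)
  }
  short <- calls$length < min_length
  calls <- calls[!short, , drop = FALSE]
  n_black <- 0L
  if (!is.null(blacklist) && nrow(calls) > 0L) {
    ovfrac <- .blacklist_overlap(calls, tibble::as_tibble(blacklist)) /
      calls$length
    drop <- ovfrac > max_blacklist_overlap
    n_black <- sum(drop)
    calls <- calls[!drop, , drop = FALSE]
  }
  attr(calls, "drop_counts") <- c(unknown_chrom = sum(bad),
                                  too_short = sum(short),
                                  blacklisted = n_black)
  calls
}

#' Map calls to cytoband range annotations
#'
#' Annotates each call with an ISCN-style band range on its chromosome:
#' `"<first_band>-<last_band>"` across all overlapped bands, or the single
#' band name when only one is touched. Calls outside the tiled range are an
#' error.
#'
#' @param calls Call tibble.
#' @param cytobands Tibble from [read_cytobands()].
#' @return `calls` with a `band` column appended.
#' @export
map_to_cytobands <- function(calls, cytobands) {
  calls <- validate_cna_calls(calls)
  cytobands <- .validate_cytobands(cytobands)
  band <- character(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    cb <- cytobands[cytobands$chrom == ch, , drop = FALSE]
    if (nrow(cb) == 0L) {
      stop(sprintf("no cytobands for chromosome %s", ch), call. = FALSE)
    }
    if (any(calls$start[ci] < 1) || any(calls$end[ci] > max(cb$end))) {
      bad <- ci[calls$start[ci] < 1 | calls$end[ci] > max(cb$end)][1]
      stop(sprintf("call %s:%.0f-%.0f lies outside the tiled range", ch,
                   calls$start[bad], calls$end[bad]), call. = FALSE)
    }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(calls$start[ci], calls$end[ci]),
      IRanges::IRanges(cb$start, cb$end)
    )
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    band[ci] <- vapply(sp, function(ix) {
      first <- cb$band[min(ix)]
      last <- cb$band[max(ix)]
      if (first == last) first else paste0(first, "-", last)
    }, character(1))
  }
  dplyr::mutate(calls, band = band)
}

#' Stratified cumulative gain/loss frequency profile
#'
#' For each group, genomic bin and aberration type, the percentage of cells
#' in the group carrying at least one call of that type overlapping the bin
#' (any shared base pair; a cell counts at most once per bin and type, and
#' may count for both gain and loss). Bins are typically the cytoband table
#' itself or fixed-width windows from [make_genome_bins()].
#'
#' @param calls Call tibble (after [filter_aberrations()]).
#' @param roster Tibble with columns `cell` and `group` covering every cell
#'   of the cohort, including cells without calls.
#' @param bins Tibble of bins: `chrom`, `start`, `end` (1-based closed),
#'   optionally `band`.
#' @return A tibble: `group`, `chrom`, `start`, `end` (+ `band` if given),
#'   `gain_pct`, `loss_pct`, `n` (group size).
#' @export
cumulative_frequency <- function(calls, roster, bins) {
  calls <- validate_cna_calls(calls)
  roster <- tibble::as_tibble(roster)
  stopifnot(all(c("cell", "group") %in% names(roster)))
  if (anyDuplicated(roster$cell)) stop("duplicate cells in roster",
                                       call. = FALSE)
  if (!all(calls$cell_id %in% roster$cell)) {
    stop("calls reference cells missing from the roster", call. = FALSE)
  }
  if (any(table(roster$group) == 0L)) stop("empty group", call. = FALSE)
  bins <- dplyr::arrange(tibble::as_tibble(bins), .data$chrom, .data$start)
  bins$.bin <- seq_len(nrow(bins))
  # (cell, bin, type) memberships via interval overlap, deduplicated
  memb <- purrr::map_dfr(unique(bins$chrom), function(ch) {
    ci <- which(calls$chrom == ch)
    bi <- which(bins$chrom == ch)
    if (length(ci) == 0L || length(bi) == 0L) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(calls$start[ci], calls$end[ci]),
      IRanges::IRanges(bins$start[bi], bins$end[bi])
    )
    tibble::tibble(cell = calls$cell_id[ci[S4Vectors::queryHits(hits)]],
                   type = calls$type[ci[S4Vectors::queryHits(hits)]],
                   .bin = bins$.bin[bi[S4Vectors::subjectHits(hits)]])
  })
  if (nrow(memb) == 0L) {
    memb <- tibble::tibble(cell = character(), type = character(),
                           .bin = integer())
  }
  memb <- dplyr::distinct(memb)
  group_sizes <- dplyr::count(roster, .data$group, name = "n")
  scaffold <- tidyr::expand_grid(group = group_sizes$group,
                                 .bin = bins$.bin,
                                 type = c("gain", "loss"))
  counts <- memb |>
    dplyr::left_join(roster, by = "cell") |>
    dplyr::count(.data$group, .data$.bin, .data$type, name = "k")
  out <- scaffold |>
    dplyr::left_join(counts, by = c("group", ".bin", "type")) |>
    dplyr::left_join(group_sizes, by = "group") |>
    dplyr::mutate(pct = 100 * dplyr::coalesce(.data$k, 0L) / .data$n) |>
    dplyr::select(-"k") |>
    tidyr::pivot_wider(names_from = "type", values_from = "pct",
                       names_glue = "{type}_pct") |>
    dplyr::left_join(dplyr::select(bins, -dplyr::any_of("stain")),
                     by = ".bin") |>
    dplyr::relocate("group", "chrom", "start", "end") |>
    dplyr::relocate("n", .after = dplyr::last_col()) |>
    dplyr::arrange(.data$group, .data$chrom, .data$start) |>
    dplyr::select(-".bin")
  out
}

#' Fixed-width genome bins
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param width Bin width in bp.
#' @return A tibble of 1-based closed bins: `chrom`, `start`, `end`.
#' @export
make_genome_bins <- function(chrom_lengths, width = 1e7) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1),
            width >= 1)
  purrr::imap_dfr(chrom_lengths, function(len, ch) {
    starts <- seq(1, len, by = width)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + width - 1, len))
  })
}
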