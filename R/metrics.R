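aberration_runs <- function(calls) {
  nn <- dplyr::arrange(tidy_segments_keep(calls),
                       chrom_factor(.data$chrom), .data$start)
  nn <- dplyr::group_by(nn, .data$chrom)
  nn <- dplyr::mutate(
    nn, run = cumsum(c(TRUE, diff(.data$state) != 0))
  )
  nn <- dplyr::ungroup(nn)
  nn <- nn[nn$state != 0, ]
  if (nrow(nn) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), state = integer(),
                          size_bp = numeric()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(nn, .data$chrom, .data$run),
    start = min(.data$start), end = max(.data$end),
    state = .data$state[[1]], .groups = "drop"
  )
  out <- dplyr::arrange(out, chrom_factor(.data$chrom), .data$start)
  dplyr::mutate(dplyr::select(out, -"run"),
                size_bp = .data$end - .data$start)
}

#' Genome-imbalance summary of a call track
#'
#' Reduces a gain/loss call track to the headline imbalance statistics:
#' the number of aberrations by state (an aberration being a maximal run
#' of adjacent same-state non-neutral segments), megabases gained/lost,
#' and percent of the genome gained/lost/changed. Aberration extent is the
#' probe-tile union of the run (first probe start to last probe end), so a
#' planted event is recovered to within one probe spacing. Chromosomes in
#' `exclude` (default X, reflecting a sex-mismatched reference) contribute
#' neither aberrations nor denominator.
#'
#' @param calls a `cgh_calls` tibble.
#' @param genome genome tibble from [sim_genome()].
#' @param exclude character vector of chromosomes to omit.
#' @return One-row tibble: `n_gains`, `n_losses`, `n_aberrations`,
#'   `mb_gained`, `mb_lost`, `pct_gained`, `pct_lost`, `pct_changed`,
#'   `excluded`.
#' @export
summarize_imbalance <- function(calls, genome, exclude = "X") {
  if (!all(unique(calls$chrom) %in% genome$chrom)) {
    abort("Call track contains chromosomes absent from the genome model.")
  }
  keep_g <- genome[!genome$chrom %in% exclude, ]
  if (nrow(keep_g) == 0) abort("Every chromosome excluded; empty denominator.")
  denom <- sum(keep_g$length)
  runs <- aberration_runs(calls)
  runs <- runs[!runs$chrom %in% exclude, ]
  gained <- sum(runs$size_bp[runs$state > 0])
  lost <- sum(runs$size_bp[runs$state < 0])
  tibble::tibble(
    n_gains = sum(runs$state > 0),
    n_losses = sum(runs$state < 0),
    n_aberrations = nrow(runs),
    mb_gained = gained / 1e6,
    mb_lost = lost / 1e6,
    pct_gained = 100 * gained / denom,
    pct_lost = 100 * lost / denom,
    pct_changed = 100 * (gained + lost) / denom,
    excluded = paste(exclude, collapse = ",")
  )
}

#' Per-aberration size table
#'
#' Lists every aberration (maximal same-state non-neutral run) with its
#' genomic extent, sorted by size.
#'
#' @param calls a `cgh_calls` tibble.
#' @return Tibble `chrom`, `start`, `end`, `state`, `size_bp`, `size_mb`,
#'   sorted by decreasing size.
#' @export
aberration_sizes <- function(calls) {
  runs <- aberration_runs(calls)
  runs <- dplyr::mutate(runs, size_mb = .data$size_bp / 1e6)
  dplyr::arrange(runs, dplyr::desc(.data$size_bp))
}
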