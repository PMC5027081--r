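#' Maximal circular two-sample statistic over one probe series
#'
#' The change-point engine behind [segment_cbs()], exposed for inspection:
#' scans every circular arc of length `min_width` to `n - min_width` and
#' returns the arc maximizing the two-sample mean-difference statistic
#' between arc and complement. Change-points sit after probes `i` and `j`
#' (1-based; `i = 0` or `j = n` mean the respective cut is at the series
#' boundary, i.e. a single interior change-point).
#'
#' @param x numeric vector of (normalized) probe values.
#' @param min_width minimum arc length.
#' @return Tibble `i`, `j`, `stat`; `i = -1` when no admissible arc exists.
#' @export
max_circular_t <- function(x, min_width = 3) {
  res <- cbs_max_stat_cpp(as.numeric(x), as.integer(min_width))
  tibble::tibble(i = res$i, j = res$j, stat = res$stat)
}

cbs_boundaries <- function(x, lo, hi, alpha, n_perm, min_width) {
  n <- hi - lo + 1
  if (n < 2 * min_width) return(integer(0))
  res <- cbs_perm_test_cpp(x[lo:hi], min_width, n_perm, alpha)
  if (res$i < 0 || !res$significant) return(integer(0))
  cuts <- integer(0)
  if (res$i > 0) cuts <- c(cuts, lo - 1L + res$i)
  if (res$j < n) cuts <- c(cuts, lo - 1L + res$j)
  if (length(cuts) == 0) return(integer(0))
  pieces_lo <- c(lo, cuts + 1L)
  pieces_hi <- c(cuts, hi)
  out <- cuts
  for (p in seq_along(pieces_lo)) {
    out <- c(out, cbs_boundaries(x, pieces_lo[p], pieces_hi[p],
                                 alpha, n_perm, min_width))
  }
  sort(unique(out))
}

#' Circular binary segmentation of a normalized profile
#'
#' Recursive change-point detection per chromosome: the maximal circular
#' two-sample statistic is referred to a permutation null (`n_perm`
#' permutations at level `alpha`, with early stopping once significance is
#' impossible); significant arcs split the series in up to three, and
#' recursion continues within each piece. Adjacent segments with equal
#' means (within `merge_tol`) are merged. A chromosome with fewer than
#' `2 * min_width` retained probes stays a single segment.
#'
#' @param profile a `cgh_profile` from [normalize_profile()], or a tibble
#'   with `chrom`, `start`, `end` and a value column named `ratio` (or
#'   `log_ratio`).
#' @param alpha significance level for the permutation test, in (0, 1).
#' @param n_perm permutations per tested split.
#' @param min_width minimum probes per segment arm.
#' @param seed seed for the permutation stream.
#' @param merge_tol tolerance for the equal-mean merge.
#' @return A `cgh_segments` tibble: `chrom`, `start`, `end` (bp, half-open,
#'   probe-tile union), `n_probes`, `seg_mean`, sorted by genome order.
#'   The probe-level values used are retained in the `"probes"` attribute
#'   (needed by the sample-level dichotomization rule).
#' @examples
#' pr <- sim_signal(sim_probes(sim_genome("toy"), 13000),
#'                  tibble::tibble(chrom = "1", start = 0, end = 1.3e6,
#'                                 shift = 1),
#'                  noise_sd = 0.1, seed = 7)
#' seg <- segment_cbs(normalize_profile(pr, quiet = TRUE), n_perm = 200)
#' @export
segment_cbs <- function(profile, alpha = 0.01, n_perm = 1000, min_width = 3,
                        seed = 1L, merge_tol = 1e-10) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  probes <- if (inherits(profile, "cgh_profile")) profile$probes else profile
  if (!"ratio" %in% names(probes)) {
    if (!"log_ratio" %in% names(probes)) {
      abort("`profile` needs a `ratio` or `log_ratio` column.")
    }
    probes$ratio <- probes$log_ratio
  }
  probes <- dplyr::arrange(probes, chrom_factor(.data$chrom), .data$start)
  segs <- withr::with_seed(substream_seed(seed, "cbs"), {
    purrr::map_dfr(split(probes, chrom_factor(probes$chrom)), function(ch) {
      x <- ch$ratio
      n <- length(x)
      cuts <- cbs_boundaries(x, 1L, n, alpha, n_perm, min_width)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, n)
      means <- purrr::map2_dbl(starts, ends, ~ mean(x[.x:.y]))
      # merge adjacent segments whose means coincide
      grp <- cumsum(c(TRUE, abs(diff(means)) > merge_tol))
      g_start <- unname(vapply(split(starts, grp), min, integer(1)))
      g_end <- unname(vapply(split(ends, grp), max, integer(1)))
      tibble::tibble(
        chrom = ch$chrom[[1]],
        start = ch$start[g_start],
        end = ch$end[g_end],
        n_probes = g_end - g_start + 1L,
        seg_mean = purrr::map2_dbl(g_start, g_end, ~ mean(x[.x:.y]))
      )
    })
  })
  new_cgh_segments(segs, probes)
}

#' Construct a `cgh_segments` object
#'
#' Wraps a plain segment table (e.g. imported from a SEG file) so the
#' calling functions accept it. Probe-level values are optional but
#' required for the probe-basis dichotomization rule.
#'
#' @param segments tibble with `chrom`, `start`, `end`, `n_probes`,
#'   `seg_mean`.
#' @param probes optional tibble with `chrom`, `start`, `end`, `ratio`.
#' @return A `cgh_segments` tibble.
#' @export
as_cgh_segments <- function(segments, probes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "n_probes", "seg_mean") %in%
                  names(segments)))
  new_cgh_segments(tibble::as_tibble(segments), probes)
}

new_cgh_segments <- function(segments, probes) {
  structure(segments,
            probes = probes,
            class = c("cgh_segments", class(tibble::tibble())))
}

#' @export
tidy.cgh_segments <- function(x, ...) {
  out <- x
  attr(out, "probes") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

segment_probes <- function(segments) attr(segments, "probes")

#' Write a segment table as a SEG file
#'
#' Tab-delimited SEG (sample, chromosome, 1-based inclusive start/end,
#' probe count, segment mean), the de facto exchange format for segmented
#' copy-number tracks.
#'
#' @param segments a `cgh_segments` (or calls) tibble.
#' @param path output path.
#' @param sample sample identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  out <- tibble::tibble(
    ID = sample,
    chrom = as.character(segments$chrom),
    loc.start = as.integer(segments$start + 1),
    loc.end = as.integer(segments$end),
    num.mark = segments$n_probes,
    seg.mean = segments$seg_mean
  )
  readr::write_tsv(out, path)
  invisible(path)
}
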