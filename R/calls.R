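new_cgh_calls <- function(segments, state, rule, params) {
  out <- dplyr::mutate(tidy_segments_keep(segments), state = as.integer(state))
  structure(out,
            probes = segment_probes(segments),
            rule = rule, params = params,
            class = c("cgh_calls", class(tibble::tibble())))
}

tidy_segments_keep <- function(segments) {
  out <- segments
  attr(out, "probes") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' Fixed-threshold gain/loss calling
#'
#' A segment is called a gain (+1) when its mean is at or above `gain_thr`
#' and it spans at least `min_probes` consecutive probes; a loss (-1) when
#' its mean is at or below `loss_thr` with the same probe support; neutral
#' (0) otherwise. The defaults are the conventional oaCGH settings: mean
#' log2 test:reference thresholds of +/- 0.2 and a minimum of three
#' consecutive probes per segment.
#'
#' @param segments a `cgh_segments` object.
#' @param gain_thr gain threshold (> 0).
#' @param loss_thr loss threshold (< 0).
#' @param min_probes minimum probes per called segment.
#' @return A `cgh_calls` tibble: segment columns plus `state` in
#'   \{-1, 0, +1\}; the rule and parameters travel in attributes.
#' @export
call_threshold <- function(segments, gain_thr = 0.2, loss_thr = -0.2,
                           min_probes = 3) {
  if (!(loss_thr < 0 && 0 < gain_thr) && !(loss_thr == 0 && gain_thr == 0)) {
    abort("Thresholds must satisfy loss_thr < 0 < gain_thr.")
  }
  enough <- segments$n_probes >= min_probes
  state <- ifelse(enough & segments$seg_mean >= gain_thr, 1L,
                  ifelse(enough & segments$seg_mean <= loss_thr, -1L, 0L))
  new_cgh_calls(segments, state, "threshold",
                list(gain_thr = gain_thr, loss_thr = loss_thr,
                     min_probes = min_probes))
}

#' Robust dichotomization by deviation from the sample median
#'
#' Calls a segment a gain (+1) when its mean lies more than `k` mean
#' absolute deviations above the median of the sample's response across all
#' chromosomes, a loss (-1) when more than `k` below, neutral otherwise.
#' The median and deviation are computed from the probe-level normalized
#' ratios by default (`basis = "probe"`), since the rule is defined on the
#' sample's genome-wide response; a segment-mean basis is available for
#' sensitivity checks.
#'
#' @param segments a `cgh_segments` object (probe-level values required for
#'   the probe basis).
#' @param k number of deviations defining the neutral band (default 3).
#' @param basis `"probe"` or `"segment"`.
#' @param scale_stat deviation statistic, see [mad_about_median()].
#' @return A `cgh_calls` tibble; the median and deviation used are stored
#'   in the `"params"` attribute.
#' @export
call_mad <- function(segments, k = 3, basis = c("probe", "segment"),
                     scale_stat = c("mean_abs", "median_abs")) {
  basis <- match.arg(basis)
  scale_stat <- match.arg(scale_stat)
  vals <- if (basis == "probe") {
    pr <- segment_probes(segments)
    if (is.null(pr)) {
      abort("Probe-level values unavailable; use basis = \"segment\" or attach probes via as_cgh_segments().")
    }
    pr$ratio
  } else {
    segments$seg_mean
  }
  if (length(unique(vals)) < 2) {
    abort("Need >= 2 distinct values to dichotomize.")
  }
  ctr <- median(vals)
  dev <- mad_about_median(vals, scale_stat)
  if (dev == 0) abort("Zero deviation; cannot dichotomize a constant sample.")
  state <- ifelse(segments$seg_mean > ctr + k * dev, 1L,
                  ifelse(segments$seg_mean < ctr - k * dev, -1L, 0L))
  new_cgh_calls(segments, state, "mad",
                list(k = k, basis = basis, scale_stat = scale_stat,
                     median = ctr, deviation = dev))
}

#' @export
tidy.cgh_calls <- function(x, ...) tidy_segments_keep(x)

#' @export
glance.cgh_calls <- function(x, ...) {
  tibble::tibble(rule = attr(x, "rule"),
                 n_segments = nrow(x),
                 n_gain = sum(x$state == 1),
                 n_loss = sum(x$state == -1))
}

#' Write non-neutral calls as a BED track
#'
#' BED4 (0-based half-open) with the state in the name field
#' (`gain`/`loss`).
#'
#' @param calls a `cgh_calls` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  nn <- calls[calls$state != 0, ]
  out <- tibble::tibble(chrom = as.character(nn$chrom),
                        start = as.integer(nn$start),
                        end = as.integer(nn$end),
                        name = ifelse(nn$state > 0, "gain", "loss"))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
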