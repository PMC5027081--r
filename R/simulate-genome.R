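#' Build a canine-like genome model
#'
#' Constructs the chromosome table the rest of the pipeline works against.
#' The `"canine"` preset mimics the dog karyotype relevant to two-color
#' aCGH: 38 acrocentric autosomes with lengths decaying geometrically from
#' about 122 Mb down to about 24 Mb (roughly the CanFam2 scale, ~2.4 Gb in
#' total) plus a large X chromosome. The `"toy"` preset is a four-chromosome
#' miniature (about 1000 probes at the default 13 kb spacing) intended for
#' fast tests and examples.
#'
#' @param preset `"canine"`, `"toy"`, or `NULL` to build a custom genome
#'   from `n_autosomes`/`length_scale`.
#' @param n_autosomes number of autosomes for a custom genome (each of
#'   length `length_scale`; X is appended with the same length).
#' @param length_scale chromosome length in bp for custom genomes.
#' @param seed accepted for interface symmetry with the stochastic
#'   generators; construction is deterministic.
#' @return A tibble with columns `chrom` and `length` (bp), autosomes first
#'   and X last, with the total autosomal length in the
#'   `"autosomal_bp"` attribute.
#' @examples
#' sim_genome("toy")
#' sum(sim_genome("canine")$length)
#' @export
sim_genome <- function(preset = c("canine", "toy"), n_autosomes = NULL,
                       length_scale = NULL, seed = NULL) {
  if (!is.null(n_autosomes)) {
    if (n_autosomes < 1) abort("`n_autosomes` must be >= 1.")
    length_scale <- length_scale %||% 1e6
    if (any(length_scale <= 0)) abort("Chromosome lengths must be positive.")
    lens <- rep_len(length_scale, n_autosomes)
    out <- tibble::tibble(
      chrom = c(as.character(seq_len(n_autosomes)), "X"),
      length = c(lens, length_scale[[1]])
    )
  } else {
    preset <- match.arg(preset)
    if (preset == "canine") {
      r <- log(122 / 24) / 37
      auto <- round(122e6 * exp(-r * (0:37)), -4)
      out <- tibble::tibble(
        chrom = c(as.character(1:38), "X"),
        length = c(auto, 126e6)
      )
    } else {
      out <- tibble::tibble(
        chrom = c("1", "2", "3", "X"),
        length = c(5.2e6, 3.9e6, 2.6e6, 1.3e6)
      )
    }
  }
  stopifnot(!anyDuplicated(out$chrom), all(out$length > 0))
  attr(out, "autosomal_bp") <- sum(out$length[out$chrom != "X"])
  class(out) <- c("cgh_genome", class(out))
  out
}

#' Lay an evenly spaced probe grid over a genome
#'
#' Probes are modelled as half-open tiles of width `spacing` starting at 0
#' on every chromosome, emulating an oligonucleotide array with features
#' spaced ~13 kb across the genome (about 180,000 probes on the canine
#' preset). A chromosome shorter than `spacing` still receives one probe.
#'
#' @param genome genome tibble from [sim_genome()].
#' @param spacing inter-probe spacing in bp (> 0).
#' @return Tibble `probe_id`, `chrom`, `start`, `end`, sorted by
#'   (chromosome order, start); 0-based half-open coordinates.
#' @examples
#' nrow(sim_probes(sim_genome("toy")))
#' @export
sim_probes <- function(genome, spacing = 13000) {
  if (spacing <= 0) abort("`spacing` must be positive.")
  purrr::pmap_dfr(
    list(genome$chrom, genome$length),
    function(chrom, len) {
      k <- max(1L, floor(len / spacing))
      start <- (seq_len(k) - 1) * spacing
      tibble::tibble(
        probe_id = sprintf("P_%s_%06d", chrom, seq_len(k)),
        chrom = chrom,
        start = start,
        end = pmin(start + spacing, len)
      )
    }
  )
}

validate_cna <- function(cna, probes = NULL) {
  if (is.null(cna) || nrow(cna) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), shift = numeric()))
  }
  stopifnot(all(c("chrom", "start", "end", "shift") %in% names(cna)))
  if (any(cna$start >= cna$end)) abort("CNA intervals need start < end.")
  if (any(cna$shift == 0)) abort("CNA shifts must be nonzero (signed log2).")
  split_chrom <- split(cna, cna$chrom)
  for (ch in split_chrom) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)])) {
      abort(sprintf("Overlapping CNA intervals on chromosome %s.",
                    ch$chrom[[1]]))
    }
  }
  cna
}

#' Simulate two-color probe signals with planted copy-number aberrations
#'
#' Generates the red/green processed-signal pairs the pipeline ingests. The
#' green (reference) channel is lognormal around `baseline_signal`; the red
#' (test) channel is `green * 2^(shift + noise)`, so the per-probe log2
#' ratio equals the planted shift plus Gaussian noise exactly, and the
#' construction is exactly inverted by [normalize_profile()] at zero noise.
#' A probe belongs to a CNA when its midpoint falls inside the interval.
#'
#' @param probes probe grid from [sim_probes()].
#' @param cna tibble of planted aberrations: `chrom`, `start`, `end`
#'   (bp, half-open), `shift` (signed log2 magnitude; > 0 gain, < 0 loss).
#'   Intervals must not overlap.
#' @param noise_sd per-probe Gaussian noise SD in log2 units.
#' @param baseline_signal median green-channel intensity (arbitrary units).
#' @param seed RNG seed.
#' @return The probe tibble with `r_signal` and `g_signal` columns; the
#'   planted truth is attached as the `"truth"` attribute.
#' @examples
#' pr <- sim_probes(sim_genome("toy"))
#' cna <- tibble::tibble(chrom = "1", start = 0, end = 1.3e6, shift = 0.58)
#' sig <- sim_signal(pr, cna, noise_sd = 0, seed = 1)
#' range(log2(sig$r_signal / sig$g_signal))
#' @export
sim_signal <- function(probes, cna = NULL, noise_sd = 0.15,
                       baseline_signal = 1000, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (baseline_signal <= 0) abort("`baseline_signal` must be positive.")
  cna <- validate_cna(cna)
  n <- nrow(probes)
  mid <- (probes$start + probes$end) / 2
  shift <- numeric(n)
  if (nrow(cna) > 0) {
    for (i in seq_len(nrow(cna))) {
      hit <- probes$chrom == cna$chrom[[i]] &
        mid >= cna$start[[i]] & mid < cna$end[[i]]
      shift[hit] <- cna$shift[[i]]
    }
  }
  out <- withr::with_seed(substream_seed(seed, "signal"), {
    g <- baseline_signal * 2^rnorm(n, 0, 0.25)
    r <- g * 2^(shift + rnorm(n, 0, noise_sd))
    dplyr::mutate(probes, r_signal = r, g_signal = g)
  })
  attr(out, "truth") <- cna
  out
}

#' Planted truth attached to a simulated dataset
#'
#' @param x an object produced by one of the `sim_*()` generators.
#' @return The machine-readable truth record (a tibble), or `NULL`.
#' @export
sim_truth <- function(x) attr(x, "truth")
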