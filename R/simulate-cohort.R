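#' Shared marker grid for cross-sample comparison
#'
#' Samples segmented independently have no common feature space; a fixed
#' grid of genomic bins supplies one. Bins tile each non-excluded
#' chromosome from 0 in steps of `bin_size` (last bin truncated at the
#' chromosome end).
#'
#' @param genome genome tibble from [sim_genome()].
#' @param bin_size bin width in bp (default 1 Mb).
#' @param exclude chromosomes left out of the grid (default `"X"`, matching
#'   the sex-mismatched reference design of the assay).
#' @return Tibble `marker`, `chrom`, `start`, `end`.
#' @export
make_marker_grid <- function(genome, bin_size = 1e6, exclude = "X") {
  if (bin_size <= 0) abort("`bin_size` must be positive.")
  g <- genome[!genome$chrom %in% exclude, ]
  if (nrow(g) == 0) abort("All chromosomes excluded from the grid.")
  grid <- purrr::pmap_dfr(list(g$chrom, g$length), function(chrom, len) {
    start <- seq(0, len - 1, by = bin_size)
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + bin_size, len))
  })
  dplyr::mutate(grid,
                marker = sprintf("%s:%09d", .data$chrom, as.integer(.data$start)),
                .before = 1)
}

#' Default copy-number signatures for the seven reference subtypes
#'
#' Each subtype in the reference cohorts (AML, T-CLL, B-CLL, ALL, B-LSA,
#' T-LSA, HM) is described by a set of aberration templates with population
#' frequencies. Templates reported for canine cohorts are encoded at their
#' published rates (e.g. CDKN2A-region loss in >55% of T-LSA; CFA 13 gain
#' in 25% of B-LSA; recurrent multi-chromosome losses in HM). Because those
#' scattered rates alone under-determine seven separable classes, every
#' subtype additionally carries two hallmark whole-chromosome templates at
#' 0.9 frequency, standing in for the aggregate multi-aberration structure
#' that makes real subtype clusters cohere; see the package vignette.
#'
#' For non-canine genomes (e.g. the toy preset) a programmatic set of
#' signatures is generated instead: the autosomal extent is cut into
#' `2 * n_subtypes` slices and each subtype gets one gain and one loss
#' slice at 0.9 frequency.
#'
#' @param genome genome tibble; defaults to the canine preset.
#' @param n_subtypes used only for programmatic signatures.
#' @return Tibble `subtype`, `chrom`, `start`, `end`, `shift`, `freq`.
#' @export
subtype_signatures <- function(genome = sim_genome("canine"), n_subtypes = 7) {
  canine <- identical(nrow(genome), 39L) && identical(genome$chrom[1], "1") &&
    identical(genome$chrom[39], "X")
  len <- function(ch) genome$length[match(ch, genome$chrom)]
  if (canine) {
    whole <- function(subtype, ch, shift, freq) {
      tibble::tibble(subtype = subtype, chrom = ch, start = 0,
                     end = len(ch), shift = shift, freq = freq)
    }
    part <- function(subtype, ch, start, end, shift, freq) {
      tibble::tibble(subtype = subtype, chrom = ch, start = start,
                     end = end, shift = shift, freq = freq)
    }
    gain <- 0.58   # log2(3/2), single-copy gain
    loss <- -1.0   # log2(1/2), single-copy loss
    sig <- dplyr::bind_rows(
      # published recurrent aberrations at quoted cohort frequencies
      part("T-LSA", "11", 40e6, 48e6, loss, 0.55),        # CDKN2A region
      part("T-LSA", "22", 0, len("22") / 2, loss, 0.20),
      whole("T-LSA", "29", gain, 0.40),
      whole("B-LSA", "13", gain, 0.25),
      whole("B-LSA", "14", loss, 0.10),
      part("B-LSA", "3", 0, len("3") / 2, loss, 0.10),
      part("ALL", "1", 0.6 * len("1"), len("1"), loss, 0.20),
      whole("ALL", "12", gain, 0.15),
      whole("ALL", "25", gain, 0.10),
      whole("ALL", "35", loss, 0.15),
      whole("HM", "16", loss, 0.60),
      whole("HM", "31", loss, 0.60),
      whole("HM", "12", loss, 0.40),
      whole("HM", "14", loss, 0.40),
      whole("HM", "36", loss, 0.40),
      whole("HM", "13", gain, 0.40),
      # hallmark templates giving each class a separable core profile
      whole("AML", "6", gain, 0.90), whole("AML", "18", loss, 0.90),
      whole("T-CLL", "5", loss, 0.90), whole("T-CLL", "21", gain, 0.90),
      whole("B-CLL", "8", gain, 0.90), whole("B-CLL", "26", loss, 0.90),
      whole("ALL", "2", gain, 0.90), whole("ALL", "30", loss, 0.90),
      whole("B-LSA", "4", gain, 0.90), whole("B-LSA", "33", loss, 0.90),
      whole("T-LSA", "9", gain, 0.90), whole("T-LSA", "17", loss, 0.90),
      whole("HM", "24", gain, 0.90), whole("HM", "37", loss, 0.90)
    )
  } else {
    auto <- genome[genome$chrom != "X", ]
    bounds <- c(0, cumsum(auto$length))
    cuts <- seq(0, bounds[length(bounds)], length.out = 2 * n_subtypes + 1)
    labels <- c("AML", "T-CLL", "B-CLL", "ALL", "B-LSA", "T-LSA", "HM")
    labels <- rep_len(labels, n_subtypes)
    slice_of <- function(lo, hi) {
      idx <- findInterval(lo, bounds, rightmost.closed = TRUE)
      tibble::tibble(chrom = auto$chrom[idx], start = lo - bounds[idx],
                     end = pmin(hi - bounds[idx], auto$length[idx]))
    }
    sig <- purrr::map_dfr(seq_len(n_subtypes), function(i) {
      up <- slice_of(cuts[2 * i - 1], cuts[2 * i])
      dn <- slice_of(cuts[2 * i], cuts[2 * i + 1])
      dplyr::bind_rows(
        dplyr::mutate(up, subtype = labels[i], shift = 0.58, freq = 0.9),
        dplyr::mutate(dn, subtype = labels[i], shift = -1.0, freq = 0.9)
      )
    })
    sig <- dplyr::select(sig, "subtype", "chrom", "start", "end",
                         "shift", "freq")
  }
  stopifnot(all(sig$freq >= 0 & sig$freq <= 1))
  sig
}

#' Simulate a subtype-labeled reference cohort of segmented marker values
#'
#' Emulates a labeled cohort of tumors with genome-wide segmented
#' copy-number values on a common marker grid (the substrate of
#' co-clustering classification). For every sample and every template of
#' its subtype's signature, a Bernoulli draw at the template frequency
#' decides carriage; marker values are the sum of carried shifts over
#' markers whose midpoints fall in the template interval, plus Gaussian
#' noise.
#'
#' @param signatures tibble from [subtype_signatures()].
#' @param n_per_subtype samples per subtype (>= 2 for a usable cohort).
#' @param grid marker grid from [make_marker_grid()]; defaults to 1 Mb bins
#'   on the genome implied by the signatures' chromosomes.
#' @param noise_sd marker-level Gaussian noise SD (log2 units).
#' @param seed RNG seed.
#' @param prefix sample-id prefix.
#' @return Tibble with `sample_id`, `subtype`, then one numeric column per
#'   marker; the carriage truth table is in the `"truth"` attribute and the
#'   grid in `"grid"`.
#' @export
sim_cohort <- function(signatures = subtype_signatures(),
                       n_per_subtype = 20,
                       grid = NULL, noise_sd = 0.3, seed = 1L,
                       prefix = "S") {
  if (nrow(signatures) == 0) abort("Empty signature list.")
  subtypes <- unique(signatures$subtype)
  if (length(subtypes) < 2) abort("Need at least 2 subtypes.")
  if (n_per_subtype < 2) abort("`n_per_subtype` must be >= 2.")
  grid <- grid %||% make_marker_grid(sim_genome("canine"))
  mid <- (grid$start + grid$end) / 2
  tpl_markers <- purrr::map(seq_len(nrow(signatures)), function(i) {
    which(grid$chrom == signatures$chrom[[i]] &
            mid >= signatures$start[[i]] & mid < signatures$end[[i]])
  })
  n_mark <- nrow(grid)
  withr::with_seed(substream_seed(seed, paste0("cohort", prefix)), {
    rows <- list(); truth <- list(); k <- 0
    for (st in subtypes) {
      tpl_idx <- which(signatures$subtype == st)
      for (s in seq_len(n_per_subtype)) {
        k <- k + 1
        id <- sprintf("%s_%s_%03d", prefix, st, s)
        carried <- tpl_idx[rbinom(length(tpl_idx), 1,
                                  signatures$freq[tpl_idx]) == 1]
        v <- rnorm(n_mark, 0, noise_sd)
        for (t in carried) {
          v[tpl_markers[[t]]] <- v[tpl_markers[[t]]] + signatures$shift[[t]]
        }
        rows[[k]] <- v
        truth[[k]] <- tibble::tibble(sample_id = id, subtype = st,
                                     template = list(carried))
      }
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- grid$marker
    truth <- dplyr::bind_rows(truth)
    out <- dplyr::bind_cols(truth[c("sample_id", "subtype")],
                            tibble::as_tibble(mat))
    attr(out, "truth") <- truth
    attr(out, "grid") <- grid
    out
  })
}
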