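category_to_copy <- function(cat) {
  ifelse(cat == ">4", 5L, suppressWarnings(as.integer(cat)))
}

#' Modal copy number of a FISH enumeration
#'
#' The copy-number category holding the largest cell count, with ties
#' broken toward the category nearest the diploid count (2) and then
#' toward the lower copy number. Enumerations below the minimum cell count
#' (default 50 scored cells) are rejected.
#'
#' @param counts either a long tibble `copy`, `n` for one locus, or a
#'   named vector of counts over \{"0","1","2","3","4",">4"\}.
#' @param min_cells minimum cells scored.
#' @return Integer modal copy (0..5, 5 meaning ">4").
#' @export
modal_copy <- function(counts, min_cells = 50) {
  if (is.data.frame(counts)) {
    n <- counts$n
    copy <- category_to_copy(as.character(counts$copy))
  } else {
    n <- as.numeric(counts)
    copy <- category_to_copy(names(counts))
  }
  if (anyNA(copy)) abort("Unrecognized copy-number category.")
  if (sum(n) < min_cells) {
    abort(sprintf(
      "Only %d cells scored; copy number must be scored in at least %d cells.",
      sum(n), min_cells))
  }
  top <- copy[n == max(n)]
  top[order(abs(top - 2), top)][[1]]
}

#' Copy-number state implied by a modal FISH count
#'
#' @param modal modal copy category (0..5; 5 meaning ">4").
#' @param ploidy baseline copy number (default 2; configurable because
#'   hypodiploid lines shift the reference point).
#' @return -1, 0 or +1.
#' @export
fish_state <- function(modal, ploidy = 2) {
  if (any(ploidy < 1)) abort("`ploidy` must be >= 1.")
  as.integer(sign(modal - ploidy))
}

#' Locus table packaged with the pipeline
#'
#' Genomic intervals (CanFam2) of the 20 cancer-gene BAC probes used for
#' FISH verification of array calls.
#'
#' @return Tibble `locus`, `clone`, `chrom`, `start`, `end`.
#' @export
fish_loci <- function() {
  readr::read_tsv(system.file("extdata", "fish_loci_canfam2.tsv",
                              package = "oacgh"),
                  show_col_types = FALSE)
}

#' Concordance between FISH enumeration and dichotomized array calls
#'
#' For each locus, the FISH modal copy is reduced to a \{-1, 0, +1\} state
#' against the baseline ploidy and compared with the state of the array
#' segment containing the locus midpoint (BAC inserts are far smaller than
#' segments, so the midpoint identifies the segment).
#'
#' @param fish_counts long tibble `locus`, `copy`, `n` (e.g. from
#'   [sim_fish_counts()] or a scored count table).
#' @param calls a `cgh_calls` tibble.
#' @param loci tibble `locus`, `chrom`, `start`, `end`.
#' @param ploidy baseline copy number.
#' @param min_cells minimum cells per locus.
#' @return Tibble `locus`, `modal_copy`, `fish_state`, `array_state`,
#'   `concordant`; the overall concordant fraction is in the
#'   `"concordance"` attribute and via `glance()`-style summary
#'   `attr(x, "concordance")`.
#' @export
fish_concordance <- function(fish_counts, calls, loci, ploidy = 2,
                             min_cells = 50) {
  missing_loci <- setdiff(unique(fish_counts$locus), loci$locus)
  if (length(missing_loci) > 0) {
    abort(sprintf("No interval for locus '%s'.", missing_loci[[1]]))
  }
  recs <- purrr::map_dfr(unique(fish_counts$locus), function(lc) {
    cnt <- fish_counts[fish_counts$locus == lc, ]
    iv <- loci[loci$locus == lc, ]
    mid <- (iv$start[[1]] + iv$end[[1]]) / 2
    seg <- calls[calls$chrom == as.character(iv$chrom[[1]]) &
                   calls$start <= mid & mid < calls$end, ]
    if (nrow(seg) == 0) {
      abort(sprintf("Locus '%s' midpoint falls outside the call track.", lc))
    }
    mc <- modal_copy(cnt, min_cells = min_cells)
    fs <- fish_state(mc, ploidy)
    tibble::tibble(locus = lc, modal_copy = mc, fish_state = fs,
                   array_state = seg$state[[1]],
                   concordant = fs == seg$state[[1]])
  })
  attr(recs, "concordance") <- mean(recs$concordant)
  recs
}
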