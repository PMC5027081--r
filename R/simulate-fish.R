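fish_categories <- function() c("0", "1", "2", "3", "4", ">4")

copy_to_category <- function(copy) {
  ifelse(copy >= 5, ">4", as.character(copy))
}

#' Simulate per-cell FISH enumeration counts
#'
#' For each locus, cells are scored into copy-number categories
#' {0, 1, 2, 3, 4, >4}. A cell reports the true category with probability
#' `p`; the miscall mass `1 - p` is split evenly between the two adjacent
#' categories (at the boundary categories the single existing neighbour
#' takes the whole mass).
#'
#' @param truth tibble with `locus`, `copy` (integer 0..5, 5 meaning ">4"),
#'   and optionally per-locus `p`.
#' @param n_cells cells scored per locus (>= 1).
#' @param p default per-cell concordance probability in (0, 1].
#' @param seed RNG seed.
#' @return Long tibble `locus`, `copy` (category label), `n`; counts sum to
#'   `n_cells` per locus. Truth is attached as the `"truth"` attribute.
#' @export
sim_fish_counts <- function(truth, n_cells = 50, p = 0.9, seed = 1L) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (!"p" %in% names(truth)) truth$p <- p
  if (any(truth$p <= 0 | truth$p > 1)) abort("`p` must lie in (0, 1].")
  if (any(truth$copy < 0 | truth$copy > 5)) {
    abort("True copy categories must be integers 0..5 (5 = '>4').")
  }
  cats <- fish_categories()
  out <- withr::with_seed(substream_seed(seed, "fish"), {
    purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      k <- truth$copy[[i]] + 1L
      prob <- numeric(6)
      prob[k] <- truth$p[[i]]
      rest <- 1 - truth$p[[i]]
      nb <- intersect(c(k - 1L, k + 1L), 1:6)
      prob[nb] <- prob[nb] + rest / length(nb)
      n <- as.integer(rmultinom(1, n_cells, prob))
      tibble::tibble(locus = truth$locus[[i]], copy = cats, n = n)
    })
  })
  attr(out, "truth") <- truth
  out
}
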