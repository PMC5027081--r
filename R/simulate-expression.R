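#' Simulate a normalized log2 expression matrix with planted structure
#'
#' Emulates the input of the expression companion analyses: an
#' already-normalized, gene-by-sample log2 intensity matrix containing a
#' block of planted differential rows (shifted by `effect_log2` in the case
#' group, alternating sign) on a near-constant background. With equal group
#' sizes the across-sample SD of a planted row is about `|effect_log2| / 2`,
#' so the conventional SD filter separates planted from background rows.
#'
#' @param n_genes total rows.
#' @param groups named integer vector of samples per role, e.g.
#'   `c(case = 5, baseline = 6)`; at least two groups with >= 1 sample.
#' @param n_diff number of planted differential rows (first `n_diff` rows).
#' @param effect_log2 log2 shift applied to case samples of planted rows.
#' @param within_sd within-group noise SD (log2 units).
#' @param base_level background log2 intensity.
#' @param seed RNG seed.
#' @return Tibble `gene_id` plus one column per sample; sample roles in the
#'   `"roles"` attribute (named character vector), planted gene ids in
#'   `"truth"`.
#' @export
sim_expression <- function(n_genes = 5000, groups = c(case = 5, baseline = 6),
                           n_diff = 1200, effect_log2 = 5, within_sd = 0.2,
                           base_level = 8, seed = 1L) {
  if (length(groups) < 2 || any(groups < 1)) {
    abort("Need >= 2 groups with >= 1 sample each.")
  }
  if (n_diff > n_genes) abort("`n_diff` cannot exceed `n_genes`.")
  roles <- rep(names(groups), groups)
  samples <- paste0(roles, "_", unlist(lapply(groups, seq_len)))
  n_s <- length(samples)
  withr::with_seed(substream_seed(seed, "expression"), {
    mat <- matrix(rnorm(n_genes * n_s, base_level, within_sd),
                  nrow = n_genes, ncol = n_s)
    if (n_diff > 0) {
      sgn <- rep_len(c(1, -1), n_diff)
      case_cols <- roles == names(groups)[[1]]
      mat[seq_len(n_diff), case_cols] <-
        mat[seq_len(n_diff), case_cols] + sgn * effect_log2
    }
    colnames(mat) <- samples
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    out <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                            tibble::as_tibble(mat))
    attr(out, "roles") <- setNames(roles, samples)
    attr(out, "truth") <- gene_id[seq_len(n_diff)]
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' Builds a long Ct table (sample, gene, replicate Cts, role) with planted
#' per-gene log2 expression differences between cases and baseline samples,
#' so that the comparative Ct method recovers `2^(-ddct)` fold changes.
#' A gene's Ct drops by one cycle per doubling of transcript.
#'
#' @param genes character vector of target genes (reference gene added).
#' @param ddct named list/vector of planted ddCt values per target gene for
#'   the case sample (negative = upregulated).
#' @param reference reference gene name.
#' @param n_baseline number of baseline samples.
#' @param n_rep technical replicates per (sample, gene).
#' @param rep_sd replicate noise SD in cycles.
#' @param base_ct baseline cycle number.
#' @param seed RNG seed.
#' @return Tibble `sample`, `role`, `gene`, `ct` with `n_rep` rows per
#'   (sample, gene); planted values in the `"truth"` attribute.
#' @export
sim_ct_table <- function(genes = c("MYC", "KIT", "FLT3", "PTEN"),
                         ddct = c(MYC = -1, KIT = 2, FLT3 = -log2(17),
                                  PTEN = 3),
                         reference = "RPL32", n_baseline = 2, n_rep = 3,
                         rep_sd = 0, base_ct = 25, seed = 1L) {
  samples <- c("case_1", paste0("baseline_", seq_len(n_baseline)))
  roles <- c("case", rep("baseline", n_baseline))
  withr::with_seed(substream_seed(seed, "ct"), {
    out <- purrr::map_dfr(seq_along(samples), function(i) {
      purrr::map_dfr(c(genes, reference), function(g) {
        ct0 <- base_ct
        if (roles[i] == "case" && g %in% names(ddct)) {
          ct0 <- ct0 + ddct[[g]]
        }
        tibble::tibble(sample = samples[i], role = roles[i], gene = g,
                       ct = ct0 + rnorm(n_rep, 0, rep_sd))
      })
    })
    attr(out, "truth") <- tibble::tibble(gene = names(ddct),
                                         ddct = as.numeric(ddct),
                                         fold = 2^(-as.numeric(ddct)))
    attr(out, "reference") <- reference
    out
  })
}
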