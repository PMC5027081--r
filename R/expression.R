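expr_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- tibble::as_tibble(x)
  id_col <- intersect(c("gene_id", "probe_id", "gene"), names(x))[1]
  if (is.na(id_col)) abort("Expression table needs a gene/probe id column.")
  m <- as.matrix(x[, setdiff(names(x), id_col)])
  rownames(m) <- x[[id_col]]
  m
}

expr_rebuild <- function(m, template) {
  id_col <- intersect(c("gene_id", "probe_id", "gene"), names(template))[1]
  out <- dplyr::bind_cols(
    tibble::tibble(!!id_col := rownames(m)),
    tibble::as_tibble(m)
  )
  attr(out, "roles") <- attr(template, "roles")
  out
}

#' Median-center an expression matrix across arrays
#'
#' Subtracts each sample column's median so every array has median log2
#' intensity 0. Idempotent.
#'
#' @param mat expression tibble (gene id column + sample columns) or
#'   matrix.
#' @return Same shape as the input.
#' @export
median_center <- function(mat) {
  m <- expr_matrix(mat)
  m <- sweep(m, 2, apply(m, 2, median))
  if (is.matrix(mat)) m else expr_rebuild(m, mat)
}

#' Remove low-variability rows
#'
#' Drops rows whose across-sample standard deviation (n - 1 denominator)
#' is strictly below `threshold`; rows exactly at the threshold are kept.
#' The conventional setting removes probe sets with SD < 2 across all
#' arrays.
#'
#' @param mat expression tibble or matrix.
#' @param threshold SD threshold (> 0).
#' @return Filtered input (possibly empty, with a warning).
#' @export
sd_filter <- function(mat, threshold = 2) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  m <- expr_matrix(mat)
  keep <- apply(m, 1, sd) >= threshold
  if (!any(keep)) warn("sd_filter removed every row.")
  if (is.matrix(mat)) return(m[keep, , drop = FALSE])
  out <- mat[keep, ]
  attr(out, "roles") <- attr(mat, "roles")
  out
}

#' Signed fold change against a pooled baseline
#'
#' Per gene and case sample, the log2 difference to the mean of the
#' baseline samples is reported as a signed fold: `2^d` for `d >= 0` and
#' `-2^(-d)` for `d < 0` (so 2-fold down is -2, matching the
#' "downregulated k-fold" convention). Set `signed = FALSE` for plain
#' ratios `2^d`.
#'
#' @param mat expression tibble or matrix (log2 scale).
#' @param baseline character vector of baseline sample names; defaults to
#'   samples whose `"roles"` attribute equals `"baseline"`.
#' @param case case sample names; defaults to all non-baseline samples.
#' @param signed use the signed-fold convention.
#' @return Long tibble `gene_id`, `sample`, `delta_log2`, `fold`.
#' @export
fold_change <- function(mat, baseline = NULL, case = NULL, signed = TRUE) {
  m <- expr_matrix(mat)
  roles <- attr(mat, "roles")
  baseline <- baseline %||% names(roles)[roles == "baseline"]
  if (length(baseline) < 1) abort("Need >= 1 baseline sample.")
  if (!all(baseline %in% colnames(m))) abort("Unknown baseline sample.")
  case <- case %||% setdiff(colnames(m), baseline)
  ref <- rowMeans(m[, baseline, drop = FALSE])
  purrr::map_dfr(case, function(s) {
    d <- m[, s] - ref
    tibble::tibble(
      gene_id = rownames(m), sample = s, delta_log2 = unname(d),
      fold = if (signed) unname(ifelse(d >= 0, 2^d, -2^(-d))) else unname(2^d)
    )
  })
}

#' Genes changed beyond a fold cutoff
#'
#' Filters a [fold_change()] table to rows with `|fold| > cutoff` (default
#' the conventional 5-fold lists) and tags the direction.
#'
#' @param fc tibble from [fold_change()].
#' @param cutoff fold cutoff (strict).
#' @return Tibble `sample`, `gene_id`, `fold`, `direction` ("up"/"down").
#' @export
fold_change_hits <- function(fc, cutoff = 5) {
  hit <- fc[abs(fc$fold) > cutoff, ]
  dplyr::arrange(
    tibble::tibble(sample = hit$sample, gene_id = hit$gene_id,
                   fold = hit$fold,
                   direction = ifelse(hit$fold > 0, "up", "down")),
    .data$sample, dplyr::desc(abs(.data$fold)))
}

#' Unsupervised clustering of expression samples
#'
#' Ward/Euclidean tree over the sample columns of a (typically
#' variability-filtered) expression matrix.
#'
#' @param mat expression tibble or matrix.
#' @return An `hclust` over samples.
#' @export
cluster_expression <- function(mat) {
  m <- expr_matrix(mat)
  if (ncol(m) < 2) abort("Need >= 2 samples to cluster.")
  ward_cluster(t(m))
}

#' Relative quantification by the comparative Ct method
#'
#' Technical replicates are averaged per (sample, gene); then
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt_case - mean(dCt_baseline)`, and the fold change is
#' `2^(-ddCt)`.
#'
#' @param ct long tibble `sample`, `role` ("case"/"baseline"), `gene`,
#'   `ct` (replicate rows allowed).
#' @param target target gene(s); defaults to every non-reference gene.
#' @param reference reference gene (must be present in all samples).
#' @return Tibble `sample`, `gene`, `dct`, `ddct`, `fold` for case
#'   samples.
#' @export
ddct <- function(ct, target = NULL, reference = "RPL32") {
  if (any(ct$ct <= 0)) abort("Ct values must be positive cycles.")
  avg <- dplyr::summarise(dplyr::group_by(ct, .data$sample, .data$role,
                                          .data$gene),
                          ct = mean(.data$ct), .groups = "drop")
  samples <- unique(avg$sample)
  ref <- avg[avg$gene == reference, ]
  if (!setequal(ref$sample, samples)) {
    abort(sprintf("Reference gene '%s' missing in some samples.", reference))
  }
  target <- target %||% setdiff(unique(avg$gene), reference)
  ref_ct <- setNames(ref$ct, ref$sample)
  purrr::map_dfr(target, function(g) {
    tg <- avg[avg$gene == g, ]
    if (nrow(tg) == 0) abort(sprintf("Target gene '%s' absent.", g))
    dct <- setNames(tg$ct - ref_ct[tg$sample], tg$sample)
    role <- setNames(tg$role, tg$sample)
    base_mean <- mean(dct[role == "baseline"])
    cases <- names(dct)[role == "case"]
    dd <- unname(dct[cases] - base_mean)
    tibble::tibble(sample = cases, gene = g, dct = unname(dct[cases]),
                   ddct = dd, fold = 2^(-dd))
  })
}
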