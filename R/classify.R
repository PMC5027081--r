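#' Project segment means onto a shared marker grid
#'
#' Each grid bin takes the length-weighted mean of the segment means
#' overlapping it; bins with no overlapping segment take 0 (copy-neutral by
#' convention). This puts independently segmented samples into one feature
#' space for clustering.
#'
#' @param segments a `cgh_segments` (or calls) tibble.
#' @param grid marker grid from [make_marker_grid()].
#' @param value column of `segments` to project (default `seg_mean`).
#' @return The grid tibble with a `value` column.
#' @export
project_to_grid <- function(segments, grid, value = "seg_mean") {
  if (nrow(grid) == 0) abort("Empty marker grid.")
  seg <- tibble::as_tibble(segments)[, c("chrom", "start", "end", value)]
  names(seg) <- c("chrom", "s_start", "s_end", "v")
  out <- dplyr::mutate(grid, value = 0)
  for (ch in unique(grid$chrom)) {
    gi <- which(out$chrom == ch)
    si <- seg[seg$chrom == ch, ]
    if (nrow(si) == 0) next
    for (k in gi) {
      ovl <- pmin(out$end[k], si$s_end) - pmax(out$start[k], si$s_start)
      w <- pmax(ovl, 0)
      if (sum(w) > 0) out$value[k] <- sum(w * si$v) / sum(w)
    }
  }
  out
}

#' Scale a cohort matrix of segmented values
#'
#' Per-sample mode (default): each sample's marker vector is centered at
#' its median and divided by its mean absolute deviation, the same robust
#' centering/scaling used for probe normalization. Per-marker mode:
#' column z-scores.
#'
#' @param cohort tibble with `sample_id`, optionally `subtype`, then
#'   numeric marker columns.
#' @param mode `"sample"` or `"marker"`.
#' @return The cohort tibble with marker columns replaced by scaled values.
#' @export
scale_cohort <- function(cohort, mode = c("sample", "marker")) {
  mode <- match.arg(mode)
  meta <- intersect(c("sample_id", "subtype"), names(cohort))
  mcols <- setdiff(names(cohort), meta)
  m <- as.matrix(cohort[, mcols])
  if (mode == "sample") {
    for (i in seq_len(nrow(m))) {
      ctr <- median(m[i, ])
      s <- mean(abs(m[i, ] - ctr))
      if (s == 0) {
        abort(sprintf("Zero dispersion in sample '%s'; cannot scale.",
                      cohort$sample_id[[i]]))
      }
      m[i, ] <- (m[i, ] - ctr) / s
    }
  } else {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("Zero dispersion in marker '%s'; cannot scale.",
                    mcols[which(sds == 0)[1]]))
    }
    m <- scale(m)[, , drop = FALSE]
  }
  dplyr::bind_cols(cohort[, meta], tibble::as_tibble(m))
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' operating on squared Euclidean distances (the `ward.D2` convention:
#' merge heights are the square root of the variance increase). Thin,
#' validated wrapper around [stats::hclust()] so every clustering in the
#' pipeline shares one entry point.
#'
#' @param x numeric matrix (rows = objects) or a tibble whose numeric
#'   columns are the features; row labels are taken from `sample_id` or
#'   rownames.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(x) {
  m <- cohort_matrix(x)
  if (nrow(m) < 2) abort("Need >= 2 rows to cluster.")
  if (anyNA(m)) abort("Missing values are not allowed in clustering input.")
  hclust(dist(m), method = "ward.D2")
}

cohort_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- tibble::as_tibble(x)
  meta <- intersect(c("sample_id", "subtype"), names(x))
  m <- as.matrix(x[, setdiff(names(x), meta)])
  if ("sample_id" %in% meta) rownames(m) <- x$sample_id
  m
}

#' Assign subtypes to query samples by co-clustering vote
#'
#' Cuts a joint dendrogram of labeled cohort samples and unlabeled queries
#' into `k` flat clusters. Each query takes the majority subtype among the
#' labeled members of its cluster; when its cluster holds no labeled member
#' or the vote ties, it falls back to the subtype of its nearest labeled
#' neighbour (Euclidean) and the `fallback` flag is set.
#'
#' @param fit `hclust` over the stacked data (from [ward_cluster()]).
#' @param data the matrix/tibble that was clustered (row order must match
#'   `fit$labels`).
#' @param labels named character vector: subtype per labeled sample id;
#'   samples absent from `labels` (or `NA`) are queries.
#' @param k number of flat clusters (defaults to the number of distinct
#'   subtypes); must be between 2 and the leaf count.
#' @return Tibble `sample_id`, `subtype` (assigned), `cluster`,
#'   `vote_frac` (winning share among labeled cluster members; `NA` on
#'   fallback), `fallback`.
#' @export
assign_subtype <- function(fit, data, labels, k = NULL) {
  m <- cohort_matrix(data)
  ids <- fit$labels
  if (is.null(ids)) ids <- rownames(m)
  lab <- labels[ids]
  names(lab) <- ids
  k <- k %||% length(unique(labels[!is.na(labels)]))
  if (k > length(ids)) abort("`k` exceeds the number of leaves.")
  if (k < 2) abort("`k` must be >= 2.")
  cl <- cutree(fit, k = k)
  queries <- ids[is.na(lab)]
  labeled <- ids[!is.na(lab)]
  purrr::map_dfr(queries, function(q) {
    members <- ids[cl == cl[[q]]]
    votes <- table(lab[intersect(members, labeled)])
    if (length(votes) > 0 && sum(votes == max(votes)) == 1) {
      tibble::tibble(sample_id = q,
                     subtype = names(votes)[which.max(votes)],
                     cluster = unname(cl[[q]]),
                     vote_frac = max(votes) / sum(votes),
                     fallback = FALSE)
    } else {
      d <- sqrt(colSums((t(m[labeled, , drop = FALSE]) - m[q, ])^2))
      tibble::tibble(sample_id = q,
                     subtype = unname(lab[labeled[which.min(d)]]),
                     cluster = unname(cl[[q]]),
                     vote_frac = NA_real_,
                     fallback = TRUE)
    }
  })
}

#' Co-clustering classification of query profiles against a labeled cohort
#'
#' The full classification flow: stack queries (segmented-value vectors on
#' the cohort's marker grid) with the labeled cohort, scale, cluster with
#' Ward/Euclidean, cut, and vote. See [assign_subtype()].
#'
#' @param cohort labeled cohort tibble (`sample_id`, `subtype`, markers),
#'   e.g. from [sim_cohort()].
#' @param queries tibble of query samples: `sample_id` plus the same marker
#'   columns.
#' @param k cut size; defaults to the number of cohort subtypes.
#' @param scale_mode passed to [scale_cohort()]; `"none"` skips scaling.
#' @return Tibble of assignments (see [assign_subtype()]).
#' @export
classify_cohort <- function(cohort, queries, k = NULL,
                            scale_mode = c("sample", "marker", "none")) {
  scale_mode <- match.arg(scale_mode)
  mcols <- setdiff(names(cohort), c("sample_id", "subtype"))
  if (!all(mcols %in% names(queries))) {
    abort("Queries lack the cohort's marker columns.")
  }
  stacked <- dplyr::bind_rows(
    cohort[, c("sample_id", mcols)],
    queries[, c("sample_id", mcols)]
  )
  if (anyDuplicated(stacked$sample_id)) {
    abort("Sample ids must be unique across cohort and queries.")
  }
  if (scale_mode != "none") stacked <- scale_cohort(stacked, scale_mode)
  fit <- ward_cluster(stacked)
  labels <- setNames(cohort$subtype, cohort$sample_id)
  assign_subtype(fit, stacked, labels, k = k)
}

#' Cluster call tracks of individual samples
#'
#' Projects each sample's dichotomized \{-1, 0, +1\} track onto a shared
#' grid (state at the bin midpoint) and clusters the resulting dichotomous
#' vectors with Ward/Euclidean.
#'
#' @param tracks named list of `cgh_calls` objects (one per sample).
#' @param grid marker grid from [make_marker_grid()].
#' @return List with `fit` (an `hclust`) and `matrix` (samples x markers
#'   of states).
#' @export
cluster_cell_lines <- function(tracks, grid) {
  m <- t(vapply(tracks, function(tr) {
    mid <- (grid$start + grid$end) / 2
    st <- integer(nrow(grid))
    for (i in seq_len(nrow(tr))) {
      hit <- grid$chrom == tr$chrom[[i]] & mid >= tr$start[[i]] &
        mid < tr$end[[i]]
      st[hit] <- tr$state[[i]]
    }
    as.numeric(st)
  }, numeric(nrow(grid))))
  rownames(m) <- names(tracks)
  colnames(m) <- grid$marker
  list(fit = ward_cluster(m), matrix = m)
}
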