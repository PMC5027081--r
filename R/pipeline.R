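#' Default end-to-end configuration
#'
#' The toy-preset configuration used by the packaged smoke workflow:
#' simulate signals with planted aberrations, normalize, segment, call
#' under both rules, summarize imbalance, and classify the sample against
#' a simulated labeled cohort.
#'
#' @return Path to the packaged YAML configuration.
#' @export
default_pipeline_config <- function() {
  system.file("extdata", "toy_pipeline.yaml", package = "oacgh")
}

#' Run the whole copy-number workflow from one configuration
#'
#' Executes simulate -> normalize -> segment -> call (both rules) -> stats
#' -> classify, writing plain-text outputs (`probes.tsv`, `truth.tsv`,
#' `normalization.tsv`, `segments.seg`, `calls_threshold.bed`,
#' `calls_mad.bed`, `imbalance.tsv`, `aberrations.tsv`,
#' `assignment.tsv`, `linkage.tsv`) into `out_dir`. All randomness derives
#' from `seed`, so two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config path to a YAML file (see [default_pipeline_config()]) or
#'   an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @param seed global seed fanned out to the per-stage substreams.
#' @return Invisibly, a list with the intermediate objects (`probes`,
#'   `profile`, `segments`, `calls_threshold`, `calls_mad`, `imbalance`,
#'   `assignment`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("oacgh_run_"), seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  genome <- if (!is.null(cfg$genome$preset)) {
    sim_genome(cfg$genome$preset)
  } else {
    sim_genome(n_autosomes = cfg$genome$n_autosomes,
               length_scale = cfg$genome$length_scale)
  }
  probes <- sim_probes(genome, spacing = cfg$spacing %||% 13000)
  cna <- if (length(cfg$cna) > 0) {
    dplyr::bind_rows(lapply(cfg$cna, tibble::as_tibble))
  } else {
    NULL
  }
  sig <- sim_signal(probes, cna, noise_sd = cfg$noise_sd %||% 0.15,
                    baseline_signal = cfg$baseline_signal %||% 1000,
                    seed = seed)
  readr::write_tsv(sig, p("probes.tsv"))
  readr::write_tsv(sim_truth(sig) %||% tibble::tibble(), p("truth.tsv"))

  profile <- normalize_profile(sig, quiet = TRUE)
  readr::write_tsv(glance(profile), p("normalization.tsv"))

  sc <- cfg$segmentation %||% list()
  segs <- segment_cbs(profile, alpha = sc$alpha %||% 0.01,
                      n_perm = sc$n_perm %||% 1000,
                      min_width = sc$min_width %||% 3, seed = seed)
  write_seg(segs, p("segments.seg"), sample = cfg$sample_id %||% "sample")

  cc <- cfg$calling %||% list()
  calls_thr <- call_threshold(segs, gain_thr = cc$gain_thr %||% 0.2,
                              loss_thr = cc$loss_thr %||% -0.2,
                              min_probes = cc$min_probes %||% 3)
  calls_mad <- call_mad(segs, k = cc$k_mad %||% 3)
  write_calls_bed(calls_thr, p("calls_threshold.bed"))
  write_calls_bed(calls_mad, p("calls_mad.bed"))

  exclude <- unlist(cfg$exclude_chrom %||% "X")
  imb <- dplyr::bind_rows(
    dplyr::mutate(summarize_imbalance(calls_thr, genome, exclude),
                  rule = "threshold", .before = 1),
    dplyr::mutate(summarize_imbalance(calls_mad, genome, exclude),
                  rule = "mad", .before = 1)
  )
  readr::write_tsv(imb, p("imbalance.tsv"))
  readr::write_tsv(aberration_sizes(calls_thr), p("aberrations.tsv"))

  cl <- cfg$classify %||% list()
  grid <- make_marker_grid(genome, bin_size = (cl$bin_mb %||% 1) * 1e6,
                           exclude = exclude)
  cohort <- sim_cohort(subtype_signatures(genome),
                       n_per_subtype = cl$n_per_subtype %||% 8,
                       grid = grid, noise_sd = cl$noise_sd %||% 0.3,
                       seed = substream_seed(seed, "pipeline-cohort"))
  query_vals <- project_to_grid(segs, grid)
  query <- dplyr::bind_cols(
    tibble::tibble(sample_id = cfg$sample_id %||% "sample"),
    tibble::as_tibble(setNames(as.list(query_vals$value), grid$marker))
  )
  assignment <- classify_cohort(cohort, query, k = cl$k %||% NULL)
  readr::write_tsv(assignment, p("assignment.tsv"))

  fit <- ward_cluster(scale_cohort(dplyr::bind_rows(
    cohort[, c("sample_id", grid$marker)], query)))
  linkage <- tibble::tibble(merge1 = fit$merge[, 1], merge2 = fit$merge[, 2],
                            height = fit$height)
  readr::write_tsv(linkage, p("linkage.tsv"))
  writeLines(fit$labels[fit$order], p("leaf_order.txt"))

  invisible(list(probes = sig, profile = profile, segments = segs,
                 calls_threshold = calls_thr, calls_mad = calls_mad,
                 imbalance = imb, assignment = assignment, out_dir = out_dir))
}
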