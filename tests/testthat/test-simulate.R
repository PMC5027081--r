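test_that("genome construction follows the karyotype layout", {
  g <- sim_genome("canine")
  expect_equal(nrow(g), 39)
  expect_equal(g$chrom[39], "X")
  expect_true(all(g$length > 0))
  # CanFam2-like scale: largest ~122 Mb, smallest autosome ~24 Mb, ~2.4 Gb
  expect_equal(g$length[1], 122e6, tolerance = 0.01)
  expect_equal(g$length[38], 24e6, tolerance = 0.01)
  expect_equal(sum(g$length), 2.4e9, tolerance = 0.05)
  g2 <- sim_genome(n_autosomes = 2, length_scale = 1e6)
  expect_equal(attr(g2, "autosomal_bp"), 2e6)
  expect_error(sim_genome(n_autosomes = 2, length_scale = -1), "positive")
  expect_identical(sim_genome("toy"), sim_genome("toy"))
})

test_that("probe grids have the expected density and determinism", {
  g <- tibble::tibble(chrom = c("1", "X"), length = c(130e3, 5e3))
  pr <- sim_probes(g, 13e3)
  expect_equal(sum(pr$chrom == "1"), 10)      # floor(130/13)
  expect_equal(sum(pr$chrom == "X"), 1)       # shorter than spacing
  n_full <- nrow(sim_probes(sim_genome("canine"), 13e3))
  expect_gt(n_full, 170e3)                    # ~180k-feature array scale
  expect_lt(n_full, 190e3)
  expect_identical(sim_probes(sim_genome("toy")), sim_probes(sim_genome("toy")))
})

test_that("signal generator plants exact shifts and obeys its noise model", {
  pr <- sim_probes(sim_genome("toy"))
  cna <- tibble::tibble(chrom = "1", start = 0, end = 1.3e6, shift = 1)
  s0 <- sim_signal(pr, cna, noise_sd = 0, seed = 1)
  lr <- log2(s0$r_signal / s0$g_signal)
  inside <- s0$chrom == "1" & s0$start < 1.3e6
  expect_equal(lr[inside], rep(1, sum(inside)))
  expect_equal(lr[!inside], rep(0, sum(!inside)))
  expect_true(all(s0$r_signal > 0 & s0$g_signal > 0))
  # CLT bound on the mean planted shift under noise
  big <- tibble::tibble(chrom = "1", start = 0, end = 6.5e6, shift = 0.58)
  sn <- sim_signal(pr, big, noise_sd = 0.1, seed = 2)
  lrn <- log2(sn$r_signal / sn$g_signal)
  in_big <- sn$chrom == "1"
  n_in <- sum(in_big)
  expect_gt(n_in, 350)
  expect_lt(abs(mean(lrn[in_big]) - 0.58), 3 * 0.1 / sqrt(n_in))
  expect_identical(sim_signal(pr, cna, seed = 5), sim_signal(pr, cna, seed = 5))
  bad <- tibble::tibble(chrom = c("1", "1"), start = c(0, 5e5),
                        end = c(1e6, 2e6), shift = c(1, 1))
  expect_error(sim_signal(pr, bad), "Overlapping")
})

test_that("cohort generator respects labels, counts and carrier frequencies", {
  g <- sim_genome("toy")
  sig <- subtype_signatures(g)
  grid <- make_marker_grid(g, 2.6e5)
  co <- sim_cohort(sig, n_per_subtype = 20, grid = grid, seed = 1)
  expect_equal(nrow(co), 7 * 20)
  expect_setequal(unique(co$subtype),
                  c("AML", "T-CLL", "B-CLL", "ALL", "B-LSA", "T-LSA", "HM"))
  # degenerate draw: frequency 1, zero noise -> identical profiles
  one <- tibble::tibble(subtype = c("A", "B"), chrom = "1",
                        start = c(0, 2.6e6), end = c(2.6e6, 5.2e6),
                        shift = c(1, -1), freq = 1)
  det <- sim_cohort(one, n_per_subtype = 5, grid = grid, noise_sd = 0, seed = 2)
  a_rows <- as.matrix(det[det$subtype == "A", -(1:2)])
  expect_true(all(apply(a_rows, 2, function(v) length(unique(v)) == 1)))
  # binomial 3-sigma bound on the carrier fraction at frequency 0.5
  half <- tibble::tibble(subtype = c("A", "B"), chrom = "1", start = 0,
                         end = c(2.6e6, 1e5), shift = c(2, 1),
                         freq = c(0.5, 1))
  ch <- sim_cohort(half, n_per_subtype = 200, grid = grid, noise_sd = 0,
                   seed = 3)
  carrier <- mean(as.matrix(ch[ch$subtype == "A", "1:000000000"]) == 2)
  expect_lt(abs(carrier - 0.5), 0.11)
  expect_error(sim_cohort(half[0, ], grid = grid), "Empty")
})

test_that("fish count generator is multinomially coherent", {
  sure <- tibble::tibble(locus = "L1", copy = 2, p = 1)
  cnt <- sim_fish_counts(sure, n_cells = 50, seed = 1)
  expect_equal(cnt$n[cnt$copy == "2"], 50)
  expect_equal(sum(cnt$n), 50)
  truth <- tibble::tibble(locus = sprintf("L%03d", 1:200),
                          copy = rep(c(0, 1, 3, 5), 50), p = 0.93)
  cnts <- sim_fish_counts(truth, n_cells = 50, seed = 2)
  expect_true(all(tapply(cnts$n, cnts$locus, sum) == 50))
  modes <- vapply(split(cnts, cnts$locus),
                  function(d) modal_copy(d), integer(1))
  expect_equal(unname(modes[truth$locus]), truth$copy)
  expect_error(sim_fish_counts(tibble::tibble(locus = "L", copy = 2, p = 0)),
               "0, 1")
})

test_that("expression generator plants separable differential rows", {
  em <- sim_expression(n_genes = 500, n_diff = 40, effect_log2 = 5,
                       within_sd = 0.2, seed = 1)
  expect_identical(em, sim_expression(n_genes = 500, n_diff = 40,
                                      effect_log2 = 5, within_sd = 0.2,
                                      seed = 1))
  expect_equal(nrow(sd_filter(em, 2)), 40)
  flat <- sim_expression(n_genes = 100, n_diff = 0, within_sd = 0.1, seed = 2)
  expect_warning(kept <- sd_filter(flat, 0.5), "every row")
  expect_equal(nrow(kept), 0)
  expect_error(sim_expression(groups = c(case = 3)), ">= 2 groups")
})
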