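small_expr <- function(m, roles = NULL) {
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%d", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal"))
  attr(out, "roles") <- roles
  out
}

test_that("median centering zeroes every array and is a projection", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(10, 10, 10))
  ctr <- median_center(small_expr(m))
  expect_equal(ctr$s1, c(-1, 0, 1))
  expect_equal(ctr$s2, c(0, 0, 0))
  expect_equal(median_center(ctr), ctr)
})

test_that("the SD filter keeps exactly the high-variability rows", {
  m <- rbind(flat1 = rep(1, 4), var1 = c(0, 0, 5, 5), flat2 = rep(2, 4))
  kept <- sd_filter(small_expr(m), 2)
  expect_equal(kept$gene_id, "g2")          # SD(0,0,5,5) = 2.89
  # boundary: a row with SD exactly at the threshold is retained
  x <- c(-1, 1)
  row_sd <- sd(x)
  expect_equal(nrow(sd_filter(small_expr(rbind(x)), row_sd)), 1)
  # monotone in the threshold
  em <- sim_expression(n_genes = 300, n_diff = 30, seed = 3)
  expect_gte(nrow(sd_filter(em, 1.5)), nrow(sd_filter(em, 2)))
  expect_gte(nrow(sd_filter(em, 2)),
             nrow(suppressWarnings(sd_filter(em, 3))))
})

test_that("signed fold changes follow the log2 differences", {
  m <- cbind(case_1 = c(5, 7, 2), base_1 = c(5, 5, 5), base_2 = c(5, 5, 5))
  roles <- c(case_1 = "case", base_1 = "baseline", base_2 = "baseline")
  fc <- fold_change(small_expr(m, roles))
  expect_equal(fc$fold, c(1, 4, -8))   # d = 0, +2, -3
  hits <- fold_change_hits(fc, 5)
  expect_equal(hits$gene_id, "g3")
  expect_equal(hits$direction, "down")
  # a baseline sample against itself is fold +1 everywhere
  self <- fold_change(small_expr(m, roles), baseline = "base_1",
                      case = "base_1")
  expect_true(all(self$fold == 1))
  expect_error(fold_change(small_expr(m, NULL), baseline = character()),
               "baseline")
})

test_that("expression clustering groups replicates and planted designs", {
  set.seed(55)
  m <- cbind(matrix(rnorm(40, 0, 0.05), 10, 4),
             matrix(rnorm(20, 4, 0.05), 10, 2))
  colnames(m) <- c(paste0("ctl", 1:4), paste0("case", 1:2))
  fit <- cluster_expression(small_expr(m))
  expect_setequal(split(colnames(m), cutree(fit, 2))[[1]], paste0("ctl", 1:4))
  dup <- m[, c(1, 1, 5)]
  colnames(dup) <- c("a", "b", "c")
  expect_equal(min(cluster_expression(small_expr(dup))$height), 0)
})

test_that("comparative Ct quantification inverts planted fold changes", {
  ct_tbl <- function(case_target, case_ref = 25) {
    tibble::tibble(
      sample = rep(c("case_1", "base_1", "base_2"), each = 2),
      role = rep(c("case", "baseline", "baseline"), each = 2),
      gene = rep(c("TP53", "RPL32"), 3),
      ct = c(case_target, case_ref, 25, 25, 25, 25))
  }
  expect_equal(ddct(ct_tbl(25))$fold, 1)               # all Cts equal
  expect_equal(ddct(ct_tbl(23))$fold, 4)               # 2 cycles lower
  expect_equal(ddct(ct_tbl(25 - log2(17)))$fold, 17)   # closed-form inversion
  # plate shift: adding a constant to one sample's Cts cancels
  shifted <- ct_tbl(23)
  shifted$ct[shifted$sample == "case_1"] <-
    shifted$ct[shifted$sample == "case_1"] + 1.7
  expect_equal(ddct(shifted)$fold, 4)
  # replicates are averaged before the deltas
  reps <- dplyr::bind_rows(ct_tbl(22), ct_tbl(24))
  expect_equal(ddct(reps)$fold, 4)
  expect_error(ddct(ct_tbl(23), reference = "ACTB"), "ACTB")
})

test_that("simulated Ct tables round-trip through the comparative method", {
  ct <- sim_ct_table(seed = 9)
  out <- ddct(ct)
  truth <- sim_truth(ct)
  expect_equal(out$fold[match(truth$gene, out$gene)], truth$fold,
               tolerance = 1e-9)
  expect_equal(out$fold[out$gene == "FLT3"], 17, tolerance = 1e-9)
})
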