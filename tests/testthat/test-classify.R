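test_that("grid projection takes length-weighted means and defaults to 0", {
  grid <- tibble::tibble(marker = c("a", "b", "c"), chrom = "1",
                         start = c(0, 10, 20), end = c(10, 20, 30))
  seg <- tibble::tibble(chrom = "1", start = c(0, 5), end = c(5, 10),
                        n_probes = 5L, seg_mean = c(1, 0))
  v <- project_to_grid(seg, grid)
  expect_equal(v$value, c(0.5, 0, 0))   # half 1.0 / half 0.0; no overlap -> 0
  full <- tibble::tibble(chrom = "1", start = 0, end = 10, n_probes = 5L,
                         seg_mean = 0.7)
  expect_equal(project_to_grid(full, grid)$value[1], 0.7)
  expect_error(project_to_grid(full, grid[0, ]), "Empty")
})

test_that("projection agrees with the direct-summation oracle and is idempotent", {
  for (s in 1:5) {
    set.seed(300 + s)
    bounds <- sort(sample(1:99, 6))
    seg <- tibble::tibble(chrom = "1", start = c(0, bounds),
                          end = c(bounds, 100), n_probes = 1L,
                          seg_mean = round(rnorm(7), 2))
    grid <- tibble::tibble(marker = sprintf("m%d", 1:10), chrom = "1",
                           start = (0:9) * 10, end = (1:10) * 10)
    v <- project_to_grid(seg, grid)
    expect_equal(v$value, oracle_project(seg, grid))
    # re-projecting bin values on the same grid is the identity
    again <- project_to_grid(
      dplyr::mutate(v, n_probes = 1L, seg_mean = v$value), grid)
    expect_equal(again$value, v$value)
  }
})

test_that("cohort scaling matches the robust centering arithmetic", {
  co <- tibble::tibble(sample_id = c("s1", "s2"),
                       m1 = c(0, 1), m2 = c(0, 1), m3 = c(0, 1),
                       m4 = c(3, 5))
  sc <- scale_cohort(co)
  expect_equal(as.numeric(sc[1, -1]), c(0, 0, 0, 4))  # {0,0,0,3} -> {0,0,0,4}
  flat_row <- tibble::tibble(sample_id = "s2", m1 = 1, m2 = 1, m3 = 1, m4 = 1)
  expect_error(scale_cohort(flat_row), "s2")
  fixed <- scale_cohort(sc[1, ])
  expect_equal(as.numeric(fixed[1, -1]), c(0, 0, 0, 4))  # idempotent
  const_col <- tibble::tibble(sample_id = c("a", "b"), m1 = c(1, 1),
                              m2 = c(0, 2))
  expect_error(scale_cohort(const_col, mode = "marker"), "m1")
})

test_that("ward clustering merges duplicates first and ignores row order", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5), d = c(5.2, 5))
  fit <- ward_cluster(m)
  expect_equal(min(fit$height), 0)
  first <- rownames(m)[-fit$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  perm <- m[c(3, 1, 4, 2), ]
  coph1 <- as.matrix(cophenetic(fit))
  coph2 <- as.matrix(cophenetic(ward_cluster(perm)))
  expect_equal(coph2[rownames(coph1), colnames(coph1)], coph1)
  expect_error(ward_cluster(rbind(c(1, NA), c(0, 0))), "Missing")
  expect_error(ward_cluster(m[1, , drop = FALSE]), ">= 2")
})

test_that("ward linkage reproduces the brute-force agglomeration oracle", {
  for (s in 1:8) {
    set.seed(400 + s)
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 3), n, dimnames = list(paste0("r", 1:n), NULL))
    fit <- ward_cluster(m)
    expect_equal(as.matrix(cophenetic(fit))[rownames(m), rownames(m)],
                 oracle_ward_cophenetic(m), tolerance = 1e-8)
  }
})

test_that("planted two-group structure dominates the top split", {
  set.seed(77)
  m <- rbind(matrix(rnorm(15, 0, 0.1), 5),
             matrix(rnorm(15, 5, 0.1), 5))
  rownames(m) <- paste0("r", 1:10)
  fit <- ward_cluster(m)
  expect_setequal(split(rownames(m), cutree(fit, 2))[[1]], paste0("r", 1:5))
})

test_that("co-clustering vote assigns the right subtype and flags fallback", {
  co <- tibble::tibble(
    sample_id = paste0("ref", 1:6),
    subtype = rep(c("T-LSA", "HM"), each = 3),
    m1 = c(1, 1.1, 0.9, -2, -2.1, -1.9),
    m2 = c(2, 2.1, 1.9, 0, 0.1, -0.1))
  q <- tibble::tibble(sample_id = "q1", m1 = 1, m2 = 2)  # == ref1
  asg <- classify_cohort(co, q, k = 2, scale_mode = "none")
  expect_equal(asg$subtype, "T-LSA")
  expect_false(asg$fallback)
  # an outlier query lands in its own cluster -> nearest-neighbour fallback
  far <- tibble::tibble(sample_id = "q2", m1 = 50, m2 = 60)
  asg2 <- classify_cohort(co, far, k = 3, scale_mode = "none")
  expect_true(asg2$fallback)
  expect_true(asg2$subtype %in% co$subtype)
  # assignments survive sample relabeling
  co2 <- dplyr::mutate(co, sample_id = paste0("zz", 1:6))
  asg3 <- classify_cohort(co2, q, k = 2, scale_mode = "none")
  expect_equal(asg3$subtype, asg$subtype)
  expect_error(classify_cohort(co, q, k = 50, scale_mode = "none"), "leaves")
})

test_that("a signature-bearing query recovers its subtype among seven", {
  g <- sim_genome("toy")
  sig <- subtype_signatures(g)
  grid <- make_marker_grid(g, 2.6e5)
  co <- sim_cohort(sig, n_per_subtype = 10, grid = grid, seed = 5)
  q <- sim_cohort(sig, n_per_subtype = 2, grid = grid, seed = 99,
                  prefix = "Q")
  tq <- q[q$subtype == "T-LSA", ][1, ]
  asg <- classify_cohort(co, tq[, setdiff(names(tq), "subtype")])
  expect_equal(asg$subtype, "T-LSA")
})

test_that("dichotomous call tracks cluster by shared signature", {
  grid <- tibble::tibble(marker = sprintf("m%d", 1:20), chrom = "1",
                         start = (0:19) * 10, end = (1:20) * 10)
  mk_calls <- function(states) {
    segs <- tibble::tibble(chrom = "1", start = (0:19) * 10,
                           end = (1:20) * 10, n_probes = 5L,
                           seg_mean = states * 1.0)
    call_threshold(as_cgh_segments(segs), min_probes = 1)
  }
  shared <- c(rep(1, 8), rep(0, 12))
  tracks <- list(t1 = mk_calls(shared),
                 t2 = mk_calls(c(rep(1, 7), 0, rep(0, 12))),
                 hm = mk_calls(c(rep(0, 10), rep(-1, 10))))
  cc <- cluster_cell_lines(tracks, grid)
  expect_setequal(split(names(tracks), cutree(cc$fit, 2))[[1]], c("t1", "t2"))
  same <- list(a = mk_calls(shared), b = mk_calls(shared))
  expect_equal(min(cluster_cell_lines(same, grid)$fit$height), 0)
})
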