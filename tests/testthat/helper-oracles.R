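# Independent oracles used to cross-check the implementation.

# Brute-force maximal circular two-sample statistic (vectorized over arc
# starts for each arc length). Mirrors the definition, not the C++ code.
oracle_max_circ_t <- function(x, min_width = 3) {
  n <- length(x)
  if (n < 2 * min_width) return(list(i = -1L, j = -1L, stat = -1))
  S <- c(0, cumsum(x))
  tot <- S[n + 1]
  best <- -Inf; bi <- -1L; bj <- -1L
  for (l in min_width:(n - min_width)) {
    i <- 0:(n - l)
    in_sum <- S[i + l + 1] - S[i + 1]
    t <- abs(in_sum / l - (tot - in_sum) / (n - l)) / sqrt(1 / l + 1 / (n - l))
    m <- which.max(t)
    if (t[m] > best) {
      best <- t[m]; bi <- i[m]; bj <- i[m] + l
    }
  }
  list(i = bi, j = bj, stat = best)
}

# Interior change-points induced by an arc (an arc and its complement are
# the same split of the circle, so compare cut sets, not (i, j) pairs).
arc_cuts <- function(res, n) {
  cuts <- c(res$i, res$j)
  sort(cuts[cuts > 0 & cuts < n])
}

same_split <- function(a, b, n, slack = 1) {
  ca <- arc_cuts(a, n)
  cb <- arc_cuts(b, n)
  length(ca) == length(cb) && all(abs(ca - cb) <= slack)
}

# Best single (linear) two-sample split, the classic change-point oracle.
oracle_best_linear_split <- function(x) {
  n <- length(x)
  S <- cumsum(x)
  k <- 1:(n - 1)
  t <- abs(S[k] / k - (S[n] - S[k]) / (n - k)) / sqrt(1 / k + 1 / (n - k))
  which.max(t)
}

# Exact Ward agglomeration via the Lance-Williams minimum-variance update
# on squared Euclidean distances; returns the cophenetic distance matrix in
# the ward.D2 height convention (sqrt of the variance-increase criterion).
oracle_ward_cophenetic <- function(m) {
  n <- nrow(m)
  D <- as.matrix(dist(m))^2
  diag(D) <- Inf
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    pairs <- which(D == min(D[active, active]), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    i <- pairs[1, 1]; j <- pairs[1, 2]
    h <- sqrt(D[i, j])
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    for (l in setdiff(active, c(i, j))) {
      D[i, l] <- D[l, i] <-
        ((sizes[i] + sizes[l]) * D[i, l] + (sizes[j] + sizes[l]) * D[j, l] -
           sizes[l] * D[i, j]) / (sizes[i] + sizes[j] + sizes[l])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    D[j, ] <- Inf; D[, j] <- Inf
  }
  rownames(coph) <- colnames(coph) <- rownames(m)
  coph
}

# Length-weighted projection of segments onto bins, by direct summation.
oracle_project <- function(seg, grid) {
  vapply(seq_len(nrow(grid)), function(k) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(seg))) {
      if (seg$chrom[i] != grid$chrom[k]) next
      ovl <- min(seg$end[i], grid$end[k]) - max(seg$start[i], grid$start[k])
      if (ovl > 0) {
        num <- num + ovl * seg$seg_mean[i]
        den <- den + ovl
      }
    }
    if (den > 0) num / den else 0
  }, numeric(1))
}

# Shared fabricated inputs -------------------------------------------------

toy_profile <- function(cna = NULL, noise_sd = 0.1, seed = 1) {
  pr <- sim_probes(sim_genome("toy"), 13000)
  normalize_profile(sim_signal(pr, cna, noise_sd = noise_sd, seed = seed),
                    quiet = TRUE)
}

# Segment table with known probe-level values for the robust calling rule:
# probe response alternating -1/+1 (median 0, mean abs deviation 1).
mad_rule_segments <- function(seg_means) {
  n <- length(seg_means)
  segs <- tibble::tibble(
    chrom = "1",
    start = (seq_len(n) - 1) * 1e5,
    end = seq_len(n) * 1e5,
    n_probes = 10L,
    seg_mean = seg_means
  )
  probes <- tibble::tibble(
    chrom = "1", start = (0:99) * 1e3, end = (1:100) * 1e3,
    ratio = rep(c(-1, 1), 50)
  )
  as_cgh_segments(segs, probes)
}
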