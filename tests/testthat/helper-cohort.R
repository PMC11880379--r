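# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# small cohort without fragments: fast, used by most module tests
small_cohort <- function(seed = 42L, ...) {
  key <- paste0("co_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(
      sim_config(seed = seed, cells_per_lineage = 300,
                 include_fragments = FALSE, ...))
  }
  .fixture_env[[key]]
}

# tiny cohort with fragments for QC / IO round-trips
frag_cohort <- function(seed = 7L) {
  if (is.null(.fixture_env$frag_co)) {
    .fixture_env$frag_co <- simulate_cohort(
      sim_config(seed = seed, cells_per_lineage = 60, n_genes = 120,
                 n_peaks = 300, n_lineage_daps = 30, n_planted_links = 12,
                 n_shared_cres = 3, n_pc_genes = 15, n_pc_daps = 40,
                 n_tf_per_lineage = 3, n_shared_tfs = 2,
                 include_fragments = TRUE))
  }
  .fixture_env$frag_co
}

# deterministic toy PWM with a sharp core and optional uniform flanks
toy_pwm <- function(core = c("A", "C", "G", "T", "A", "C"), flank_left = 0,
                    flank_right = 0, name = "toy", p = 1e-12) {
  bases <- c("A", "C", "G", "T")
  core_mat <- vapply(core, function(b) {
    v <- rep(0.04, 4)
    v[match(b, bases)] <- 0.88
    v
  }, numeric(4))
  rownames(core_mat) <- bases
  unif <- matrix(0.25, 4, flank_left + flank_right,
                 dimnames = list(bases, NULL))
  mat <- cbind(unif[, seq_len(flank_left), drop = FALSE], core_mat,
               unif[, seq_len(flank_right), drop = FALSE])
  regconverge:::new_pwm(mat, name, p = p)
}

# brute-force greedy iterative-overlap oracle (O(n^2))
greedy_oracle <- function(pk) {
  pk <- pk[order(-pk$score, pk$chrom, pk$start), , drop = FALSE]
  kept <- pk[0, ]
  while (nrow(pk) > 0) {
    top <- pk[1, ]
    kept <- rbind(kept, top)
    overlaps <- pk$chrom == top$chrom & pk$start < top$end & pk$end > top$start
    pk <- pk[!overlaps, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$start), ]
}

# brute-force ungapped PWM similarity oracle (independent reimplementation)
similarity_oracle <- function(ma, mb) {
  rc <- function(m) {
    out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  col_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(if (max(abs(x - y)) < 1e-12) 1 else 0)
    }
    stats::cor(x, y)
  }
  min_ov <- max(5, ceiling(0.75 * min(ncol(ma), ncol(mb))))
  best <- -Inf
  for (mb2 in list(mb, rc(mb))) {
    for (s in -(ncol(mb2) - 1):(ncol(ma) - 1)) {
      scores <- c()
      for (i in seq_len(ncol(ma))) {
        j <- i - s
        if (j >= 1 && j <= ncol(mb2)) scores <- c(scores, col_cor(ma[, i], mb2[, j]))
      }
      if (length(scores) >= min_ov) best <- max(best, mean(scores))
    }
  }
  best
}

# exhaustive DTW path enumeration on a small grid: all monotone paths with
# steps {(1,0),(0,1),(1,1)} from (1,1) to (n,m); returns min total cost
exhaustive_dtw_cost <- function(D) {
  n <- nrow(D); m <- ncol(D)
  best <- Inf
  recurse <- function(i, j, cost) {
    cost <- cost + D[i, j]
    if (cost >= best) return()
    if (i == n && j == m) {
      best <<- cost
      return()
    }
    if (i < n) recurse(i + 1, j, cost)
    if (j < m) recurse(i, j + 1, cost)
    if (i < n && j < m) recurse(i + 1, j + 1, cost)
  }
  recurse(1, 1, 0)
  best
}
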