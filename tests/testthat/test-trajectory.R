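test_that("pseudotime binning matches the hand oracle", {
  x <- matrix(c(1, 2, 3, 10,
                0, 0, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  t <- c(0, 0.25, 0.5, 1)
  b <- bin_pseudotime(x, t, n_bins = 2)
  # first bin closed on both sides: cells at 0, 0.25 and 0.5
  expect_equal(unname(b$counts), c(3, 1))
  expect_equal(unname(b$means["g1", ]), c(2, 10))
  expect_equal(unname(b$means["g2", ]), c(1 / 3, 1))
  # constant feature z-scores to zeros
  xc <- rbind(x, g3 = rep(5, 4))
  bc <- bin_pseudotime(xc, t, n_bins = 2)
  expect_equal(unname(bc$z["g3", ]), c(0, 0))
  expect_error(bin_pseudotime(x, rep(0.5, 4), 2), "one pseudotime")
})

test_that("planted module means are non-decreasing across bins", {
  co <- small_cohort()
  mods <- unlist(co$truth$module_genes)
  norm <- normalize_log(co$rna$counts)
  idx <- co$rna$cells$lineage == "L1"
  b <- bin_pseudotime(norm[mods, idx], co$rna$cells$pseudotime[idx], 6)
  profile <- colMeans(b$means)
  expect_true(all(diff(profile) > -0.1))
  expect_gt(profile[length(profile)], profile[1] + 0.5)
})

test_that("DTW cost equals exhaustive path enumeration on small grids", {
  set.seed(30)
  for (dims in list(c(4, 4), c(5, 7), c(8, 8), c(8, 3))) {
    D <- matrix(runif(prod(dims)), dims[1], dims[2])
    expect_equal(regconverge:::dtw_cost(D), exhaustive_dtw_cost(D),
                 tolerance = 1e-12)
  }
})

test_that("open-ended alignment minimises mean path cost exactly (oracle)", {
  # exhaustive oracle over all boundary start/end cuts on a small grid
  open_oracle <- function(D) {
    n <- nrow(D); m <- ncol(D)
    best <- Inf
    starts <- rbind(cbind(seq_len(n), 1), cbind(1, seq_len(m)))
    paths <- function(i, j, acc, len) {
      if ((i == n || j == m)) {
        best <<- min(best, acc / len)
      }
      if (i < n) paths(i + 1, j, acc + D[i + 1, j], len + 1)
      if (j < m) paths(i, j + 1, acc + D[i, j + 1], len + 1)
      if (i < n && j < m) paths(i + 1, j + 1, acc + D[i + 1, j + 1], len + 1)
    }
    for (s in seq_len(nrow(starts))) {
      paths(starts[s, 1], starts[s, 2], D[starts[s, 1], starts[s, 2]], 1)
    }
    best
  }
  set.seed(31)
  for (rep in 1:5) {
    D <- matrix(runif(30, 0.05, 1), 5, 6)
    got <- regconverge:::open_dtw(D)
    expect_equal(got$total / got$length, open_oracle(D), tolerance = 1e-10)
  }
})

test_that("identity alignment is the diagonal with zero matched cost", {
  centers <- seq(0, 1, length.out = 15)
  vals <- smooth_profiles(30, centers)
  rownames(vals) <- paste0("f", 1:30)
  bins <- make_bins(vals, centers)
  al <- align_trajectories(bins, bins, n_points = 20)
  expect_equal(al$path, cbind(1:20, 1:20), ignore_attr = TRUE)
  expect_equal(max(al$matched_dissimilarity), 0, tolerance = 1e-12)
  expect_length(unlist(al$unmatched), 0)
})

test_that("a known monotone warp is recovered within two indices", {
  centers <- seq(0, 1, length.out = 40)
  warp <- function(u) u^1.6
  a_vals <- smooth_profiles(25, centers)
  b_vals <- smooth_profiles(25, centers, warp = warp)
  rownames(a_vals) <- rownames(b_vals) <- paste0("f", 1:25)
  # B at position u shows A's state at warp(u): true map j -> i = warp(u_j)
  al <- align_trajectories(make_bins(a_vals, centers),
                           make_bins(b_vals, centers), n_points = 40)
  for (r in seq_len(nrow(al$path))) {
    i <- al$path[r, 1]; j <- al$path[r, 2]
    true_i <- 1 + 39 * warp((j - 1) / 39)
    expect_lt(abs(i - true_i), 2 + 1e-9)
  }
})

test_that("a divergent terminal extension is reported unmatched", {
  centers_a <- seq(0, 1, length.out = 30)
  a_vals <- smooth_profiles(10, centers_a, seed = 33)
  rownames(a_vals) <- paste0("f", 1:10)
  # B runs through A's programme in its first 30 bins, then 10 extra bins
  # of a divergent programme
  set.seed(34)
  div <- matrix(rnorm(10 * 10, sd = 2), 10, 10) +
    matrix(rep(seq(4, 8, length.out = 10), each = 10), 10, 10)
  b_vals <- cbind(a_vals, div)
  centers_b <- seq(0, 1, length.out = 40)
  al <- align_trajectories(make_bins(a_vals, centers_a),
                           make_bins(b_vals, centers_b), n_points = 40)
  expect_gt(length(al$unmatched$b_tail), 4)
  expect_length(al$unmatched$a_tail, 0)
  expect_length(al$unmatched$a_head, 0)
})

test_that("alignment is symmetric up to path transposition", {
  centers <- seq(0, 1, length.out = 25)
  a_vals <- smooth_profiles(20, centers, seed = 35)
  b_vals <- smooth_profiles(20, centers, warp = function(u) u^1.3, seed = 35)
  rownames(a_vals) <- rownames(b_vals) <- paste0("f", 1:20)
  ab <- align_trajectories(make_bins(a_vals, centers),
                           make_bins(b_vals, centers), n_points = 30)
  ba <- align_trajectories(make_bins(b_vals, centers),
                           make_bins(a_vals, centers), n_points = 30)
  expect_equal(ab$mean_cost, ba$mean_cost, tolerance = 1e-10)
  expect_equal(unname(ab$path), unname(ba$path[, 2:1]), ignore_attr = TRUE)
})

test_that("pseudotime transfer: exact profile match and uniform fallback", {
  co <- small_cohort()
  norm <- normalize_log(co$rna$counts)
  idx <- which(co$rna$cells$lineage == "L1")[1:50]
  r <- as.matrix(norm[, idx])
  t_r <- co$rna$cells$pseudotime[idx]
  # an "ATAC" cell identical to RNA cell 7
  fake <- r[, 7, drop = FALSE]
  colnames(fake) <- "atac1"
  got <- transfer_pseudotime(r, t_r, fake, k = 1)
  expect_equal(unname(got), t_r[7])
  # k = population with uniform profiles: mean pseudotime
  flat <- matrix(1, nrow(r), 1, dimnames = list(rownames(r), "atac2"))
  rflat <- matrix(rep(seq_len(nrow(r)), 50), nrow(r), 50,
                  dimnames = list(rownames(r), colnames(r)))
  got2 <- transfer_pseudotime(rflat, t_r, rflat[, 1, drop = FALSE], k = 50)
  expect_equal(unname(got2), mean(t_r))
  expect_error(transfer_pseudotime(r, t_r, fake, k = 51), "exceeds")
})

test_that("transferred pseudotime tracks the truth on paired cells", {
  co <- small_cohort()
  norm <- normalize_log(co$rna$counts)
  act <- gene_activity(co$atac$counts, co$peaks, co$genome$genes)
  anorm <- normalize_log(act)
  l <- "L1"
  ridx <- which(co$rna$cells$lineage == l)
  aidx <- which(co$atac$cells$lineage == l)
  tt <- transfer_pseudotime(norm[, ridx], co$rna$cells$pseudotime[ridx],
                            anorm[, aidx], k = 50)
  rho <- cor(tt, co$atac$cells$pseudotime[aidx], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("gene activity equals a brute-force interval sum", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      tss = c(10000L, 40000L, 80000L),
                      start = c(10000L, 30000L, 80000L),
                      end = c(20000L, 40000L, 90000L))
  peaks <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                      start = c(12000L, 8500L, 41000L, 200000L),
                      end = c(12501L, 9001L, 41501L, 200501L))
  set.seed(36)
  counts <- Matrix::Matrix(matrix(rpois(4 * 5, 3), 4, 5,
                                  dimnames = list(peaks$peak_id,
                                                  paste0("c", 1:5))),
                           sparse = TRUE)
  act <- gene_activity(counts, peaks, genes, upstream = 2000)
  # p1 in g1 body; p2 in g1 upstream window; p3 in g2 upstream (minus strand)
  expect_equal(as.numeric(act["g1", ]),
               as.numeric(counts["p1", ] + counts["p2", ]))
  expect_equal(as.numeric(act["g2", ]), as.numeric(counts["p3", ]))
  expect_equal(as.numeric(act["g3", ]), rep(0, 5))
  # upstream = 0 removes the promoter-only contribution
  act0 <- gene_activity(counts, peaks, genes, upstream = 0)
  expect_equal(as.numeric(act0["g1", ]), as.numeric(counts["p1", ]))
  expect_equal(as.numeric(act0["g2", ]), rep(0, 5))
})
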