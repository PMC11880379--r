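#' Equidistant pseudotime binning with per-bin feature means
#'
#' Bins span `[min(t), max(t)]` with equal widths (first bin closed on both
#' sides, later bins left-open), per the usual `cut(..., include.lowest)`
#' convention. Empty bins are dropped with a warning; the z-scored view
#' scales each feature across the retained bins (constant features map to
#' zeros).
#'
#' @param x features x cells normalised matrix.
#' @param pseudotime per-cell pseudotime (finite).
#' @param n_bins number of bins (>= 2).
#' @return object of class `trajectory_bins`: `edges`, `centers`, `counts`,
#'   `means` (features x retained bins), `z`.
#' @export
bin_pseudotime <- function(x, pseudotime, n_bins) {
  stopifnot(ncol(x) == length(pseudotime), n_bins >= 2)
  if (!all(is.finite(pseudotime))) stop("pseudotime must be finite")
  rng <- range(pseudotime)
  if (rng[1] == rng[2]) stop("all cells share one pseudotime value")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(pseudotime, breaks = edges, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0)) {
    warning(sum(counts == 0), " empty pseudotime bin(s) dropped")
  }
  keep <- which(counts > 0)
  dense <- as_dense(x)
  means <- vapply(keep, function(b) rowMeans(dense[, bin == b, drop = FALSE]),
                  numeric(nrow(dense)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(dense))
  dimnames(means) <- list(rownames(x), paste0("bin", keep))
  centers <- (edges[keep] + edges[keep + 1L]) / 2
  z <- t(apply(means, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(means)
  structure(list(edges = edges, centers = centers, counts = counts[keep],
                 means = means, z = z),
            class = "trajectory_bins")
}

# linear interpolation of each feature's bin-centre profile at n_points
# equidistant pseudotime positions
interpolate_bins <- function(bins, n_points, features = NULL) {
  m <- bins$means
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  at <- seq(min(bins$centers), max(bins$centers), length.out = n_points)
  out <- t(apply(m, 1, function(r) {
    stats::approx(bins$centers, r, xout = at)$y
  }))
  dimnames(out) <- list(rownames(m), NULL)
  list(values = out, positions = at)
}

# cumulative-cost DP for DTW with steps {(1,0),(0,1),(1,1)}; closed
# endpoints; returns total cost of the optimal full path
dtw_cost <- function(D) {
  n <- nrow(D); m <- ncol(D)
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- D[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1) best <- min(best, acc[i - 1, j])
      if (j > 1) best <- min(best, acc[i, j - 1])
      if (i > 1 && j > 1) best <- min(best, acc[i - 1, j - 1])
      acc[i, j] <- D[i, j] + best
    }
  }
  acc[n, m]
}

# one DP pass of the open-ended alignment for penalised costs d = D - lambda:
# free start anywhere on the first row/column, free end anywhere on the last
# row/column; minimises total penalised cost, ties broken towards longer
# paths, then towards the diagonal step
open_dtw_pass <- function(D, lambda, open_begin = TRUE, open_end = TRUE) {
  n <- nrow(D); m <- ncol(D)
  d <- D - lambda
  V <- matrix(Inf, n, m)
  L <- matrix(0L, n, m)
  P <- matrix(0L, n, m)  # 0 start, 1 diag, 2 up(i-1), 3 left(j-1)
  eps <- 1e-12
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      bv <- Inf; bl <- 0L; bp <- 0L
      # candidates in preference order (diagonal first); a later candidate
      # replaces only on a strictly smaller value, so ties keep the
      # diagonal continuation and never restart the path
      consider <- function(v, l, p) {
        if (v < bv - eps) {
          bv <<- v; bl <<- l; bp <<- p
        }
      }
      if (i > 1 && j > 1) consider(V[i - 1, j - 1], L[i - 1, j - 1], 1L)
      if (i > 1) consider(V[i - 1, j], L[i - 1, j], 2L)
      if (j > 1) consider(V[i, j - 1], L[i, j - 1], 3L)
      can_start <- (i == 1 && j == 1) ||
        (open_begin && (i == 1 || j == 1))
      if (can_start) consider(0, 0L, 0L)
      V[i, j] <- bv + d[i, j]
      L[i, j] <- bl + 1L
      P[i, j] <- bp
    }
  }
  ends <- if (open_end) {
    rbind(cbind(n, seq_len(m)), cbind(seq_len(n - 1), m))
  } else cbind(n, m)
  ev <- V[ends]
  el <- L[ends]
  best <- which(ev < min(ev) + eps)
  best <- best[which.max(el[best])]
  end <- ends[best, ]
  # trace back
  path <- matrix(NA_integer_, L[end[1], end[2]], 2)
  i <- end[1]; j <- end[2]
  for (s in seq(nrow(path), 1)) {
    path[s, ] <- c(i, j)
    p <- P[i, j]
    if (p == 0L) break
    if (p == 1L) { i <- i - 1; j <- j - 1 }
    else if (p == 2L) i <- i - 1
    else j <- j - 1
  }
  list(value = V[end[1], end[2]], path = path,
       total = sum(D[path]), length = nrow(path))
}

# exact minimisation of the mean path cost over all boundary start/end cuts
# by Dinkelbach fractional programming: iterate lambda <- total/length of
# the path minimising total - lambda * length until the optimum reaches 0
open_dtw <- function(D, open_begin = TRUE, open_end = TRUE) {
  lambda <- mean(diag(D))
  res <- NULL
  for (it in 1:50) {
    res <- open_dtw_pass(D, lambda, open_begin, open_end)
    if (res$value >= -1e-10) break
    lambda_new <- res$total / res$length
    if (abs(lambda_new - lambda) < 1e-12) break
    lambda <- lambda_new
  }
  res
}

#' Align two binned trajectories by open-ended dynamic time warping
#'
#' Each feature profile is linearly interpolated at `n_points` equidistant
#' pseudotime positions; the dissimilarity between position i of trajectory
#' A and position j of trajectory B is `1 - Spearman rho` across shared
#' features. The optimal monotone warping path (steps right/down/diagonal)
#' is found with free terminal cuts: over all boundary start/end pairs, the
#' path minimising the mean dissimilarity along the path is selected
#' (exact minimisation by Dinkelbach fractional programming). Terminal
#' indices cut off on either trajectory are reported as unmatched.
#'
#' @param bins_a,bins_b `trajectory_bins` objects.
#' @param shared_features features used for the dissimilarity (default:
#'   intersection of rownames).
#' @param n_points number of interpolated positions (default 40).
#' @param open_begin,open_end allow cutting the start/end of either
#'   trajectory (default TRUE).
#' @return list of class `alignment_result`: `D`, `path` (two-column index
#'   matrix), `matched_dissimilarity`, `mean_cost`, `unmatched` (per
#'   trajectory, head/tail index vectors), `points_a`, `points_b`.
#' @export
align_trajectories <- function(bins_a, bins_b, shared_features = NULL,
                               n_points = 40L, open_begin = TRUE,
                               open_end = TRUE) {
  if (is.null(shared_features)) {
    shared_features <- intersect(rownames(bins_a$means), rownames(bins_b$means))
  }
  if (length(shared_features) < 2) stop("need >= 2 shared features")
  ia <- interpolate_bins(bins_a, n_points, shared_features)
  ib <- interpolate_bins(bins_b, n_points, shared_features)
  const_a <- apply(ia$values, 2, function(cc) all(cc == cc[1]))
  const_b <- apply(ib$values, 2, function(cc) all(cc == cc[1]))
  if (any(const_a) || any(const_b)) {
    stop("constant interpolated profiles (undefined ranks) at positions: A[",
         paste(which(const_a), collapse = ","), "] B[",
         paste(which(const_b), collapse = ","), "]")
  }
  D <- 1 - cor(ia$values, ib$values, method = "spearman")
  res <- open_dtw(D, open_begin, open_end)
  path <- res$path
  start <- path[1, ]; end <- path[nrow(path), ]
  unmatched <- list(
    a_head = if (start[1] > 1) seq_len(start[1] - 1) else integer(0),
    b_head = if (start[2] > 1) seq_len(start[2] - 1) else integer(0),
    a_tail = if (end[1] < n_points) seq(end[1] + 1, n_points) else integer(0),
    b_tail = if (end[2] < n_points) seq(end[2] + 1, n_points) else integer(0))
  structure(list(D = D, path = path,
                 matched_dissimilarity = D[path],
                 mean_cost = res$total / res$length,
                 unmatched = unmatched,
                 points_a = ia, points_b = ib),
            class = "alignment_result")
}

#' Transfer pseudotime from RNA cells to ATAC cells by correlation kNN
#'
#' Features shared between the RNA expression matrix and the ATAC
#' gene-activity matrix are z-scored jointly across both cell sets; each
#' ATAC cell receives the similarity-weighted mean pseudotime of its `k`
#' most Spearman-correlated RNA cells (weights `(rho + 1) / 2`).
#'
#' @param rna_x features x RNA-cells matrix.
#' @param rna_pseudotime per-RNA-cell pseudotime.
#' @param atac_activity features x ATAC-cells gene-activity matrix.
#' @param k neighbourhood size (default 10).
#' @return named numeric vector of transferred pseudotimes.
#' @export
transfer_pseudotime <- function(rna_x, rna_pseudotime, atac_activity, k = 10L) {
  shared <- intersect(rownames(rna_x), rownames(atac_activity))
  if (length(shared) == 0) stop("no shared features")
  if (k > ncol(rna_x)) stop("k exceeds the RNA population")
  r <- as_dense(rna_x[shared, , drop = FALSE])
  a <- as_dense(atac_activity[shared, , drop = FALSE])
  comb <- cbind(r, a)
  mu <- rowMeans(comb)
  s <- apply(comb, 1, sd)
  s[s == 0] <- 1
  rz <- (r - mu) / s
  az <- (a - mu) / s
  rho <- suppressWarnings(cor(az, rz, method = "spearman"))  # atac x rna
  rho[is.na(rho)] <- 0  # degenerate (constant) profiles carry no signal
  out <- vapply(seq_len(nrow(rho)), function(i) {
    nb <- order(rho[i, ], decreasing = TRUE)[seq_len(k)]
    w <- (rho[i, nb] + 1) / 2
    if (sum(w) == 0) w <- rep(1, length(nb))
    sum(w * rna_pseudotime[nb]) / sum(w)
  }, numeric(1))
  setNames(out, colnames(atac_activity))
}

#' Gene activity from peak accessibility counts
#'
#' Per gene, sums the counts of all peaks overlapping the gene body or the
#' strand-aware `upstream` bp promoter region.
#'
#' @param atac_counts peaks x cells count matrix (rownames = peak ids).
#' @param peaks peak table (`peak_id`, `chrom`, `start`, `end`).
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `tss`, `start`,
#'   `end`).
#' @param upstream promoter extension upstream of the TSS (default 2000).
#' @return genes x cells sparse activity matrix (zero rows for genes with no
#'   overlapping peak).
#' @export
gene_activity <- function(atac_counts, peaks, genes, upstream = 2000L) {
  pk <- as.data.frame(peaks)
  pk <- pk[match(rownames(atac_counts), pk$peak_id), ]
  plus <- genes$strand == "+"
  reg_start <- ifelse(plus, genes$start - upstream, genes$start)
  reg_end <- ifelse(plus, genes$end, genes$end + upstream)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(reg_start + 1, 1), reg_end))
  p_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  hits <- GenomicRanges::findOverlaps(g_gr, p_gr)
  A <- sparseMatrix(i = S4Vectors::queryHits(hits),
                    j = S4Vectors::subjectHits(hits), x = 1,
                    dims = c(nrow(genes), nrow(pk)))
  act <- A %*% atac_counts
  rownames(act) <- genes$gene_id
  colnames(act) <- colnames(atac_counts)
  act
}
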