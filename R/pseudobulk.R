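#' Depth-normalise and log-transform UMI counts
#'
#' `value = ln(1 + 1e4 * count / cell_total)`.
#'
#' @param counts features x cells non-negative count matrix.
#' @param scale_factor library-size scale (default 1e4).
#' @return a sparse matrix of normalised values.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop("cells with zero total counts: ",
         paste(head(colnames(counts)[tot == 0], 5), collapse = ", "))
  }
  x <- as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
  x@x <- log1p(scale_factor * x@x / rep.int(tot, diff(x@p)))
  x
}

#' Select highly variable features by standardised variance
#'
#' Fits a local regression of log10 variance on log10 mean over features,
#' standardises each observation by the trend-predicted standard deviation
#' (clipping standardised values at `sqrt(n_cells)`), and returns features
#' whose standardised variance exceeds the median plus one (unscaled) MAD
#' over all features.
#'
#' @param x features x cells normalised matrix.
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return list with `selected` (feature ids) and `stats` (per-feature mean,
#'   variance and standardised variance).
#' @export
select_hvg <- function(x, loess_span = 0.3) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 cells")
  if (nrow(x) < 2) stop("need at least 2 features to fit a trend")
  mu <- Matrix::rowMeans(x)
  xsq <- if (is(x, "sparseMatrix")) {
    y <- x
    y@x <- y@x^2
    Matrix::rowSums(y)
  } else rowSums(x^2)
  v <- (xsq - n * mu^2) / (n - 1)
  if (all(v <= .Machine$double.eps)) {
    warning("constant matrix; no variable features")
    return(list(selected = character(0),
                stats = data.frame(mean = mu, variance = v,
                                   std_variance = rep(0, length(v)))))
  }
  ok <- v > 0 & mu > 0
  fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span,
               degree = 2, family = "gaussian")
  sd_pred <- rep(NA_real_, length(v))
  sd_pred[ok] <- sqrt(10^predict(fit))
  clip <- sqrt(n)
  std_var <- rep(0, length(v))
  dense <- as_dense(x)
  for (i in which(ok)) {
    z <- (dense[i, ] - mu[i]) / sd_pred[i]
    z <- pmin(pmax(z, -clip), clip)
    std_var[i] <- sum((z - mean(z))^2) / (n - 1)
  }
  thr <- median(std_var) + median(abs(std_var - median(std_var)))
  sel <- rownames(x)[std_var > thr]
  list(selected = sel,
       stats = data.frame(mean = mu, variance = v, std_variance = std_var,
                          row.names = rownames(x)))
}

#' Per-cell module activity score
#'
#' Mean expression of the module genes minus the mean of control genes drawn
#' from the same average-expression bins (`n_ctrl` controls per module gene,
#' sampled with replacement within the bin).
#'
#' @param x features x cells normalised matrix.
#' @param gene_set module gene ids (subset of rownames).
#' @param n_bins number of equal-frequency average-expression bins.
#' @param n_ctrl control genes sampled per module gene.
#' @param seed sampling seed.
#' @return named numeric vector of per-cell scores.
#' @export
score_module <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% rownames(x))) stop("gene_set must be a subset of features")
  avg <- Matrix::rowMeans(x)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- if (n_bins <= 1) {
    rep(1L, nrow(x))
  } else {
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }
  names(bins) <- rownames(x)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  mod_mean <- Matrix::colMeans(x[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(x[ctrl, , drop = FALSE])
  setNames(as.numeric(mod_mean - ctrl_mean), colnames(x))
}

#' Pseudobulk profiles: per-group means of normalised values
#'
#' @param x features x cells matrix.
#' @param groups per-cell group labels (length `ncol(x)`).
#' @return list with `profile` (features x groups matrix) and `groups`
#'   (group sizes).
#' @export
pseudobulk_means <- function(x, groups) {
  stopifnot(length(groups) == ncol(x))
  if (anyNA(groups)) stop("every cell must be labelled")
  f <- factor(groups)
  sizes <- table(f)
  if (any(sizes == 0)) stop("empty group")
  ind <- sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                      dims = c(length(f), nlevels(f)))
  prof <- as.matrix(x %*% ind)
  prof <- sweep(prof, 2, as.numeric(sizes), "/")
  colnames(prof) <- levels(f)
  list(profile = prof, groups = as.integer(sizes))
}

#' Spearman correlation co-clustering of pseudobulk profiles
#'
#' Computes pairwise Spearman's rank correlations between group profiles
#' restricted to a feature subset and clusters groups by average-linkage
#' agglomeration on distance 1 - rho. Optionally reports whether a
#' designated group set forms an exclusive clade of the dendrogram.
#'
#' @param profile features x groups matrix (e.g. from [pseudobulk_means()]).
#' @param feature_subset features to use (default all).
#' @param designated optional character vector of group names to test as an
#'   exclusive clade.
#' @param linkage hclust method (default "average").
#' @return list with `rho`, `hclust`, `dropped` (constant columns) and
#'   `designated_clade` (logical or NA).
#' @export
correlate_and_cluster <- function(profile, feature_subset = NULL,
                                  designated = NULL, linkage = "average") {
  if (is.list(profile) && !is.null(profile$profile)) profile <- profile$profile
  if (!is.null(feature_subset)) {
    feature_subset <- intersect(feature_subset, rownames(profile))
    profile <- profile[feature_subset, , drop = FALSE]
  }
  if (ncol(profile) < 3) stop("need at least 3 groups")
  const <- apply(profile, 2, function(col) length(unique(col)) == 1)
  dropped <- colnames(profile)[const]
  if (any(const)) {
    warning("dropping constant profile columns: ",
            paste(dropped, collapse = ", "))
    profile <- profile[, !const, drop = FALSE]
  }
  rho <- cor(profile, method = "spearman")
  hc <- hclust(stats::as.dist(1 - rho), method = linkage)
  verdict <- if (is.null(designated)) NA else is_exclusive_clade(hc, designated)
  list(rho = rho, hclust = hc, dropped = dropped,
       designated_clade = verdict)
}
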