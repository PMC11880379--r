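#' Logistic-regression marker test with latent covariates
#'
#' For each feature, group membership is regressed on the feature's
#' normalised value plus the latent covariates, and compared with a
#' covariates-only null model by a 1-df likelihood-ratio chi-square test.
#' Features are tested only if detected in at least `min_pct` of the cells
#' of either group. Natural-log fold changes follow the convention
#' `ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#'
#' @param x features x cells normalised matrix.
#' @param group_mask logical vector over cells (TRUE = in-group).
#' @param latent_covariates optional numeric matrix/data.frame of per-cell
#'   covariates (factors should be pre-expanded or passed as a data.frame).
#' @param min_pct detection-fraction gate (default 0.1).
#' @param logfc_min log fold-change threshold for `pass` (default 0.5; use
#'   0.25 for fine-grained contrasts such as differential accessibility).
#' @param alpha adjusted-p threshold for `pass`.
#' @param adjust `"bonferroni"` (default) or `"BH"`, applied over tested
#'   features only.
#' @return a `data.frame` (MarkerTable) with `log_fc`, `pct_in`, `pct_out`,
#'   `p_raw`, `p_adj`, `pass`, `tested` and `separation_flag` per feature.
#' @export
lr_markers <- function(x, group_mask, latent_covariates = NULL,
                       min_pct = 0.1, logfc_min = 0.5, alpha = 0.05,
                       adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  group_mask <- as.logical(group_mask)
  stopifnot(length(group_mask) == ncol(x))
  n_in <- sum(group_mask)
  n_out <- sum(!group_mask)
  if (n_in == 0 || n_out == 0) stop("group_mask must split cells non-trivially")

  xs <- as(Matrix(x, sparse = TRUE), "CsparseMatrix")
  pct_in <- Matrix::rowSums(xs[, group_mask, drop = FALSE] > 0) / n_in
  pct_out <- Matrix::rowSums(xs[, !group_mask, drop = FALSE] > 0) / n_out
  ex <- xs
  ex@x <- expm1(ex@x)
  mean_in <- Matrix::rowSums(ex[, group_mask, drop = FALSE]) / n_in
  mean_out <- Matrix::rowSums(ex[, !group_mask, drop = FALSE]) / n_out
  log_fc <- log((mean_in + 1) / (mean_out + 1))

  tested <- pct_in >= min_pct | pct_out >= min_pct
  y <- as.numeric(group_mask)
  lat <- NULL
  if (!is.null(latent_covariates)) {
    lat <- as.matrix(as.data.frame(latent_covariates))
    storage.mode(lat) <- "double"
    # drop constant covariates (e.g. a single stage level)
    lat <- lat[, apply(lat, 2, function(c) length(unique(c)) > 1), drop = FALSE]
  }
  X0 <- cbind(intercept = rep(1, length(y)), lat)
  fit0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  dev0 <- fit0$deviance

  dense <- as_dense(xs)
  n_feat <- nrow(dense)
  p_raw <- rep(NA_real_, n_feat)
  sep_flag <- rep(FALSE, n_feat)
  for (i in which(tested)) {
    xf <- dense[i, ]
    if (all(xf == xf[1])) next
    X1 <- cbind(X0, feature = xf)
    fit1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial(),
                                            control = list(maxit = 50)))
    beta <- fit1$coefficients[["feature"]]
    if (!fit1$converged || is.na(beta) || abs(beta) > 15 ||
        fit1$deviance < 1e-6) {
      pen <- ridge_logistic_lrt(X0, X1, y)
      p_raw[i] <- pen$p
      sep_flag[i] <- TRUE
    } else {
      stat <- max(0, dev0 - fit1$deviance)
      p_raw[i] <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  p_adj <- rep(NA_real_, n_feat)
  p_adj[tested] <- p.adjust(p_raw[tested],
                            method = ifelse(adjust == "BH", "BH", "bonferroni"))
  pass <- !is.na(p_adj) & p_adj < alpha & log_fc > logfc_min
  data.frame(feature = rownames(xs), log_fc = log_fc, pct_in = pct_in,
             pct_out = pct_out, p_raw = p_raw, p_adj = p_adj, pass = pass,
             tested = tested, separation_flag = sep_flag,
             row.names = rownames(xs), stringsAsFactors = FALSE)
}

# ridge-penalised Newton fallback for (quasi-)separated fits; LRT on the
# penalised deviances, flagged upstream
ridge_logistic_lrt <- function(X0, X1, y, lambda = 1e-2, maxit = 50) {
  dev0 <- ridge_logistic_dev(X0, y, lambda, maxit)
  dev1 <- ridge_logistic_dev(X1, y, lambda, maxit)
  list(p = pchisq(max(0, dev0 - dev1), df = 1, lower.tail = FALSE))
}

ridge_logistic_dev <- function(X, y, lambda, maxit) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X))
  pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- drop(crossprod(X, y - p)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- tryCatch(solve(H, g), error = function(e) rep(0, ncol(X)))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  -2 * sum(y * eta - log1p(exp(eta)))
}

#' Intersection of significant markers across lineages
#'
#' @param tables list of MarkerTables from [lr_markers()].
#' @return character vector of features with `pass = TRUE` in every table.
#' @export
common_markers <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) stop("need at least one table")
  if (is.data.frame(tables)) tables <- list(tables)
  sets <- lapply(tables, function(tb) tb$feature[tb$pass])
  Reduce(intersect, sets)
}
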