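pwm_matrix <- function(x) {
  if (inherits(x, "pwm")) x$mat else as.matrix(x)
}

#' Per-column information content of a PWM (bits)
#'
#' `IC_j = 2 + sum_b p_bj log2 p_bj` against a uniform background; 0 log 0
#' is taken as 0. Values lie in [0, 2].
#'
#' @param pwm a `pwm` object or a 4 x L column-stochastic matrix.
#' @return numeric vector of length L.
#' @export
ic_profile <- function(pwm) {
  m <- pwm_matrix(pwm)
  apply(m, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Trim uninformative PWM extremities
#'
#' Strips the maximal contiguous runs of terminal columns whose information
#' content is below `min_ic`, from both ends, refusing to trim below length
#' 4 (the core is symmetrically re-extended if needed).
#'
#' @param pwm a `pwm` object or 4 x L matrix.
#' @param min_ic information-content threshold in bits (default 0.25).
#' @return the trimmed object (same type as the input).
#' @export
trim_pwm <- function(pwm, min_ic = 0.25) {
  m <- pwm_matrix(pwm)
  ic <- ic_profile(m)
  informative <- which(ic >= min_ic)
  if (length(informative) == 0) stop("all columns below the IC threshold")
  lo <- min(informative)
  hi <- max(informative)
  while (hi - lo + 1 < 4) {  # never trim below length 4
    if (lo > 1) lo <- lo - 1
    if (hi - lo + 1 < 4 && hi < ncol(m)) hi <- hi + 1
    if (lo == 1 && hi == ncol(m)) break
  }
  out <- m[, lo:hi, drop = FALSE]
  if (inherits(pwm, "pwm")) {
    pwm$mat <- out
    pwm
  } else out
}

reverse_complement_pwm <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

col_correlation <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    return(if (max(abs(x - y)) < 1e-12) 1 else 0)
  }
  cor(x, y)
}

#' Ungapped PWM similarity with reverse-complement search
#'
#' Maximum, over all ungapped offsets with overlap of at least
#' `max(5, ceil(0.75 * min(La, Lb)))` columns and over `b` versus its
#' reverse complement, of the mean column-wise Pearson correlation between
#' probability columns. Columns with zero variance contribute 1 when
#' identical and 0 otherwise.
#'
#' @param a,b `pwm` objects or 4 x L matrices.
#' @return similarity score in [-1, 1].
#' @export
pwm_similarity <- function(a, b) {
  ma <- pwm_matrix(a)
  mb <- pwm_matrix(b)
  if (ncol(ma) < 4 || ncol(mb) < 4) stop("PWMs must have length >= 4")
  min_ov <- max(5, ceiling(0.75 * min(ncol(ma), ncol(mb))))
  if (min_ov > min(ncol(ma), ncol(mb))) {
    stop("no admissible offset: motifs too short for the overlap gate")
  }
  best <- -Inf
  for (mat_b in list(mb, reverse_complement_pwm(mb))) {
    la <- ncol(ma); lb <- ncol(mat_b)
    for (s in seq(-(lb - 1), la - 1)) {
      ia <- max(1, 1 + s):min(la, lb + s)
      ib <- ia - s
      if (length(ia) < min_ov) next
      sc <- mean(vapply(seq_along(ia), function(k) {
        col_correlation(ma[, ia[k]], mat_b[, ib[k]])
      }, numeric(1)))
      if (sc > best) best <- sc
    }
  }
  best
}

#' Remove redundant motifs by similarity components
#'
#' Builds a graph on motif pairs whose similarity exceeds `threshold` and,
#' per connected component, keeps the motif with the lowest discovery
#' p-value (ties broken by name).
#'
#' @param pwms named list of `pwm` objects with discovery p-values.
#' @param threshold similarity threshold, exclusive (default 0.8).
#' @param trim trim PWMs (at the default IC threshold) before scoring
#'   similarity (default TRUE).
#' @return list with `kept` (pwm list), `redundancy` (data.frame mapping
#'   each motif to its component representative) and `similarity` matrix.
#' @export
dedup_motifs <- function(pwms, threshold = 0.8, trim = TRUE) {
  stopifnot(is.list(pwms), length(pwms) >= 1)
  nms <- vapply(pwms, function(p) p$name, "")
  names(pwms) <- nms
  mats <- if (trim) lapply(pwms, function(p) trim_pwm(p)$mat) else lapply(pwms, `[[`, "mat")
  n <- length(pwms)
  sim <- diag(1, n)
  dimnames(sim) <- list(nms, nms)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        sim[i, j] <- sim[j, i] <- pwm_similarity(mats[[i]], mats[[j]])
      }
    }
  }
  # connected components of the > threshold graph (label propagation)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(sim[i, ] > threshold)
      newc <- min(comp[c(i, nb)])
      if (newc < comp[i]) { comp[i] <- newc; changed <- TRUE }
      for (k in nb) if (comp[k] > newc) { comp[k] <- newc; changed <- TRUE }
    }
    if (!changed) break
  }
  pvals <- vapply(pwms, function(p) p$p, numeric(1))
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    idx[order(pvals[idx], nms[idx])][1]
  }, integer(1))
  rep_of <- nms[keep[match(comp, sort(unique(comp)))]]
  list(kept = pwms[sort(keep)],
       redundancy = data.frame(motif = nms, representative = rep_of,
                               stringsAsFactors = FALSE),
       similarity = sim)
}

#' Motif occurrence matrix from ground truth or toy sequences
#'
#' With `truth` (a named list mapping motif names to peak-id sets) the hit
#' sets are passed through. With `sequences` (named character vector, one
#' per peak), a hit is called when the maximum log-odds score of the PWM
#' (probabilities with pseudocount 0.01, uniform 0-order background) over
#' all positions and both strands reaches `score_frac` of the motif's
#' maximum attainable score.
#'
#' @param pwms named list of `pwm` objects.
#' @param peak_ids character vector of peak ids (row order of the result).
#' @param truth optional named list motif -> peak ids.
#' @param sequences optional named character vector of peak sequences.
#' @param score_frac fraction of the maximum score required (default 0.8).
#' @return sparse logical peaks x motifs matrix.
#' @export
scan_motifs <- function(pwms, peak_ids, truth = NULL, sequences = NULL,
                        score_frac = 0.8) {
  nms <- vapply(pwms, function(p) p$name, "")
  if (!is.null(truth)) {
    hits <- Matrix(FALSE, length(peak_ids), length(pwms),
                   dimnames = list(peak_ids, nms), sparse = TRUE)
    for (m in seq_along(pwms)) {
      hits[intersect(truth[[nms[m]]], peak_ids), m] <- TRUE
    }
    return(as(hits, "CsparseMatrix"))
  }
  if (is.null(sequences)) stop("either truth or sequences must be supplied")
  stopifnot(all(peak_ids %in% names(sequences)))
  bases <- c("A", "C", "G", "T")
  hit_mat <- sapply(pwms, function(p) {
    m <- (p$mat + 0.01) / (1 + 0.04)
    lo <- log(m / 0.25)
    max_score <- sum(apply(lo, 2, max))
    vapply(peak_ids, function(pid) {
      sq <- strsplit(toupper(sequences[[pid]]), "")[[1]]
      L <- ncol(lo)
      if (length(sq) < L) stop("sequence shorter than motif: ", pid)
      idx <- match(sq, bases)
      best <- -Inf
      for (strand_lo in list(lo, log(reverse_complement_pwm(m) / 0.25))) {
        for (s in 1:(length(sq) - L + 1)) {
          win <- idx[s:(s + L - 1)]
          if (anyNA(win)) next  # N bases never score
          sc <- sum(strand_lo[cbind(win, seq_len(L))])
          if (sc > best) best <- sc
        }
      }
      is.finite(best) && best >= score_frac * max_score
    }, logical(1))
  })
  hit_mat <- matrix(hit_mat, nrow = length(peak_ids),
                    dimnames = list(peak_ids, nms))
  as(Matrix(hit_mat, sparse = TRUE), "CsparseMatrix")
}

#' Bias-corrected per-cell motif deviation z-scores
#'
#' For motif m and cell c, the expected count is
#' `depth_c * sum(totals over the motif's peaks) / sum(all peak totals)`;
#' the raw deviation is `(observed - expected) / expected`. For each motif,
#' `n_background` matched peak sets of the same size are drawn by replacing
#' every member peak with one of its `k_neighbors` nearest neighbours in
#' z-scored (GC content, log mean accessibility) space; the z-score is the
#' raw deviation standardised by the background mean and SD.
#'
#' @param counts peaks x cells accessibility counts.
#' @param hits peaks x motifs logical/binary matrix.
#' @param gc per-peak GC content.
#' @param n_background number of background peak sets (default 50).
#' @param k_neighbors neighbourhood size for background matching
#'   (default 50).
#' @param seed sampling seed.
#' @return list of class `deviation_matrix`: `z` (motifs x cells), `raw`,
#'   `background_mean`, `background_sd`, `flagged` (motifs with undefined
#'   z).
#' @export
motif_deviations <- function(counts, hits, gc, n_background = 50L,
                             k_neighbors = 50L, seed = 1L) {
  stopifnot(nrow(counts) == nrow(hits), length(gc) == nrow(counts))
  H <- as(Matrix(hits != 0, sparse = TRUE), "CsparseMatrix") * 1
  motif_sizes <- Matrix::colSums(H)
  if (any(motif_sizes == 0)) {
    stop("motif(s) with zero peaks: ",
         paste(colnames(H)[motif_sizes == 0], collapse = ", "))
  }
  tot_p <- Matrix::rowSums(counts)
  depth <- Matrix::colSums(counts)
  Tt <- sum(tot_p)
  obs <- as.matrix(Matrix::t(H) %*% counts)
  frac <- as.numeric(Matrix::t(H) %*% tot_p) / Tt
  expd <- outer(frac, as.numeric(depth))
  raw <- (obs - expd) / expd

  # background matching space
  feat <- cbind(scale(gc), scale(log1p(tot_p)))
  feat[is.nan(feat)] <- 0
  dmat <- as.matrix(stats::dist(feat))
  diag(dmat) <- Inf
  k <- min(k_neighbors, nrow(dmat) - 1L)
  knn <- t(apply(dmat, 1, function(r) order(r)[seq_len(k)]))

  trip <- Matrix::summary(H)
  peak_of <- trip$i
  motif_of <- trip$j
  n_motifs <- ncol(H)
  bg_raw <- array(NA_real_, c(n_motifs, ncol(counts), n_background))
  with_seed(seed, {
    for (b in seq_len(n_background)) {
      pick <- knn[cbind(peak_of, sample.int(k, length(peak_of), replace = TRUE))]
      W <- sparseMatrix(i = pick, j = motif_of, x = 1,
                        dims = dim(H))
      obs_b <- as.matrix(Matrix::t(W) %*% counts)
      frac_b <- as.numeric(Matrix::t(W) %*% tot_p) / Tt
      expd_b <- outer(frac_b, as.numeric(depth))
      bg_raw[, , b] <- (obs_b - expd_b) / expd_b
    }
  })
  bg_mean <- apply(bg_raw, c(1, 2), mean)
  bg_sd <- apply(bg_raw, c(1, 2), sd)
  z <- (raw - bg_mean) / bg_sd
  flagged <- rowSums(!is.finite(z)) > 0
  z[!is.finite(z)] <- NA_real_
  dimnames(z) <- dimnames(raw) <- list(colnames(H), colnames(counts))
  structure(list(z = z, raw = raw, background_mean = bg_mean,
                 background_sd = bg_sd,
                 flagged = colnames(H)[flagged],
                 n_background = n_background),
            class = "deviation_matrix")
}

#' Annotate de novo motifs with candidate transcription factors
#'
#' Candidates are reference motifs with similarity at least `sim_min` whose
#' TF is present in the expression matrix and detected in at least
#' `expr_min_frac` of cells. `n` aggregates of `k` cells each are drawn
#' uniformly with replacement (cells are assumed paired/aligned between the
#' deviation and expression matrices); candidates are ranked by the
#' Spearman correlation between aggregate mean motif deviation and
#' aggregate mean TF expression, ties broken by similarity then name.
#'
#' @param denovo named list of de novo `pwm` objects.
#' @param reference named list of reference `pwm` objects with `tf` set.
#' @param rna_x features x cells expression matrix.
#' @param deviations `deviation_matrix` (cells aligned with `rna_x`
#'   columns).
#' @param k,n cells per aggregate and number of aggregates (defaults 50 and
#'   400).
#' @param k_small,n_small values used when `small = TRUE` (defaults 20 and
#'   200).
#' @param small use the small-cluster aggregate sizes.
#' @param sim_min candidate similarity gate (default 0.6).
#' @param expr_min_frac minimum detection fraction for a candidate TF
#'   (default 0.05).
#' @param seed aggregate sampling seed.
#' @return list with `table` (all candidates with ranks; `selected` marks
#'   the best per motif) and `unannotated` (named reasons).
#' @export
annotate_motifs <- function(denovo, reference, rna_x, deviations,
                            k = 50L, n = 400L, k_small = 20L, n_small = 200L,
                            small = FALSE, sim_min = 0.6,
                            expr_min_frac = 0.05, seed = 1L) {
  if (small) { k <- k_small; n <- n_small }
  z <- deviations$z
  n_cells <- ncol(z)
  stopifnot(ncol(rna_x) == n_cells)
  ref_tf <- vapply(reference, function(p) p$tf, "")
  has_expr <- ref_tf %in% rownames(rna_x)
  detect_frac <- setNames(rep(0, length(reference)), names(reference))
  detect_frac[has_expr] <- Matrix::rowSums(rna_x[ref_tf[has_expr], , drop = FALSE] > 0)[seq_len(sum(has_expr))] / n_cells
  agg <- with_seed(seed, {
    matrix(sample.int(n_cells, k * n, replace = TRUE), nrow = k)
  })
  agg_ind <- sparseMatrix(i = as.integer(agg), j = rep(seq_len(n), each = k),
                          x = 1 / k, dims = c(n_cells, n))
  expr_agg <- as.matrix(rna_x %*% agg_ind)  # features x n

  rows <- list()
  unannotated <- character(0)
  for (dm in names(denovo)) {
    sims <- vapply(reference, function(r) pwm_similarity(denovo[[dm]], r),
                   numeric(1))
    cand <- names(reference)[sims >= sim_min & has_expr &
                               detect_frac >= expr_min_frac]
    if (length(cand) == 0) {
      unannotated[dm] <- "no candidate passed the similarity/expression gates"
      next
    }
    zi <- z[dm, ]
    zi[is.na(zi)] <- 0
    dev_agg <- as.numeric(zi %*% agg_ind)
    rho <- vapply(cand, function(cm) {
      suppressWarnings(cor(dev_agg, expr_agg[ref_tf[cm], ], method = "spearman"))
    }, numeric(1))
    rho[is.na(rho)] <- -Inf
    ord <- order(-rho, -sims[cand], cand)
    rows[[dm]] <- data.frame(
      motif = dm, candidate = cand[ord], tf = ref_tf[cand][ord],
      similarity = sims[cand][ord],
      expr_fraction = detect_frac[cand][ord],
      rho = rho[ord], rank = seq_along(ord),
      selected = seq_along(ord) == 1, stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame()
  list(table = table, unannotated = unannotated, k = k, n = n)
}

#' Compare motif similarity between mesenchymal and non-mesenchymal contexts
#'
#' For every transcription factor with motifs discovered in multiple
#' contexts, all cross-lineage same-TF motif pairs are scored with the
#' trimmed similarity; pairs are grouped by whether both motifs come from
#' mesenchymal populations or both from non-mesenchymal populations, and
#' the two groups are compared by a two-sided Mann-Whitney test.
#'
#' @param pwms named list of `pwm` objects with `context$lineage` and
#'   `context$mesenchymal` set.
#' @param tf_of named character vector mapping motif names to source TF ids.
#' @param trim trim PWMs before scoring (default TRUE).
#' @return list with `mesenchymal`, `non_mesenchymal` (similarity vectors),
#'   medians, `location_shift` (mesenchymal median minus non-mesenchymal
#'   median) and the rank-sum p-value (NA when degenerate).
#' @export
context_similarity_groups <- function(pwms, tf_of, trim = TRUE) {
  nms <- vapply(pwms, function(p) p$name, "")
  names(pwms) <- nms
  mats <- if (trim) lapply(pwms, function(p) trim_pwm(p)$mat) else
    lapply(pwms, `[[`, "mat")
  mes <- numeric(0)
  non <- numeric(0)
  for (tf in unique(tf_of)) {
    group <- nms[tf_of[nms] == tf]
    if (length(group) < 2) next
    prs <- utils::combn(group, 2, simplify = FALSE)
    for (pp in prs) {
      c1 <- pwms[[pp[1]]]$context
      c2 <- pwms[[pp[2]]]$context
      if (identical(c1$lineage, c2$lineage)) next
      s <- pwm_similarity(mats[[pp[1]]], mats[[pp[2]]])
      if (isTRUE(c1$mesenchymal) && isTRUE(c2$mesenchymal)) {
        mes <- c(mes, s)
      } else if (identical(c1$mesenchymal, FALSE) && identical(c2$mesenchymal, FALSE)) {
        non <- c(non, s)
      }
    }
  }
  if (length(mes) == 0 || length(non) == 0) stop("a context group is empty")
  p <- if (length(unique(c(mes, non))) > 1) {
    suppressWarnings(wilcox.test(mes, non, alternative = "two.sided"))$p.value
  } else NA_real_
  list(mesenchymal = mes, non_mesenchymal = non,
       median_mesenchymal = median(mes), median_non_mesenchymal = median(non),
       location_shift = median(mes) - median(non), rank_sum_p = p)
}
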