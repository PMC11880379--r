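#' Build cell aggregates for link analysis
#'
#' Draws `n_aggregates` groups of exactly `cells_per` cells. In `random`
#' mode each aggregate samples cells uniformly (without replacement within
#' an aggregate when the population allows it). In `knn` mode each
#' aggregate is seeded at a random cell and takes its `cells_per - 1`
#' nearest neighbours in the supplied embedding.
#'
#' @param cell_ids character vector of cells.
#' @param n_aggregates number of aggregates (default 500).
#' @param cells_per cells per aggregate (default 100).
#' @param seed sampling seed.
#' @param mode `"random"` or `"knn"`.
#' @param embedding cells x dims matrix (rownames = cell ids), required for
#'   knn mode.
#' @param max_overlap if below 1, aggregates sharing more than this
#'   fraction of members with an already-kept aggregate are dropped
#'   (redundancy filter; the returned matrix then has fewer columns).
#' @return cells_per x n_aggregates character matrix of member ids.
#' @export
aggregate_cells <- function(cell_ids, n_aggregates = 500L, cells_per = 100L,
                            seed = 1L, mode = c("random", "knn"),
                            embedding = NULL, max_overlap = 1) {
  mode <- match.arg(mode)
  n_pop <- length(cell_ids)
  if (n_pop == 0) stop("empty population")
  with_seed(seed, {
    if (mode == "random") {
      memb <- vapply(seq_len(n_aggregates), function(a) {
        sample(cell_ids, cells_per, replace = cells_per > n_pop)
      }, character(cells_per))
    } else {
      if (is.null(embedding)) stop("knn mode requires an embedding")
      if (cells_per > n_pop) stop("cells_per exceeds the population in knn mode")
      emb <- embedding[cell_ids, , drop = FALSE]
      dmat <- as.matrix(stats::dist(emb))
      seeds <- sample.int(n_pop, n_aggregates, replace = TRUE)
      memb <- vapply(seeds, function(s) {
        cell_ids[order(dmat[s, ])[seq_len(cells_per)]]
      }, character(cells_per))
    }
    memb <- matrix(memb, nrow = cells_per,
                   dimnames = list(NULL, paste0("agg", seq_len(n_aggregates))))
    if (max_overlap < 1) {
      kept <- 1L
      for (a in seq_len(ncol(memb))[-1]) {
        ov <- vapply(kept, function(kk) {
          length(intersect(memb[, a], memb[, kk])) / cells_per
        }, numeric(1))
        if (all(ov <= max_overlap)) kept <- c(kept, a)
      }
      memb <- memb[, kept, drop = FALSE]
    }
    memb
  })
}

aggregate_means <- function(x, membership) {
  idx <- matrix(match(membership, colnames(x)), nrow = nrow(membership))
  if (anyNA(idx)) stop("aggregate members missing from the matrix")
  ind <- sparseMatrix(i = as.integer(idx),
                      j = rep(seq_len(ncol(idx)), each = nrow(idx)),
                      x = 1 / nrow(idx), dims = c(ncol(x), ncol(idx)))
  out <- as.matrix(x %*% ind)
  colnames(out) <- colnames(membership)
  out
}

#' Peak-to-gene links from correlated aggregate profiles
#'
#' Candidate pairs are peaks whose centre lies within `window` bp of a
#' gene's TSS. For each candidate, the Pearson correlation between
#' aggregate mean accessibility and aggregate mean (pseudo)expression is
#' computed, with a t-distribution p-value (df = n_aggregates - 2) and
#' Benjamini-Hochberg adjustment over all tested pairs. Links with
#' `r >= r_min` and `fdr < fdr_max` are retained.
#'
#' @param atac_agg peaks x aggregates mean accessibility matrix.
#' @param expr_agg genes x aggregates mean expression matrix (same
#'   aggregate membership).
#' @param peaks peak table (`peak_id`, `chrom`, `start`, `end`).
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @param window TSS window in bp (default 250000).
#' @param r_min correlation cutoff (default 0.45).
#' @param fdr_max FDR cutoff (default 1e-4).
#' @param lineage label stored on the output rows.
#' @param keep_all return all tested pairs, not only the retained links.
#' @return a LinkTable `data.frame`: `peak_id`, `gene_id`, `r`, `p_raw`,
#'   `fdr`, `distance`, `lineage`, `retained`; skipped zero-variance pairs
#'   are counted in `attr(, "n_skipped")`.
#' @export
peak_gene_links <- function(atac_agg, expr_agg, peaks, genes,
                            window = 250000L, r_min = 0.45, fdr_max = 1e-4,
                            lineage = NA_character_, keep_all = FALSE) {
  stopifnot(ncol(atac_agg) == ncol(expr_agg))
  n_agg <- ncol(atac_agg)
  pk <- as.data.frame(peaks)
  pk <- pk[pk$peak_id %in% rownames(atac_agg), ]
  gn <- as.data.frame(genes)
  gn <- gn[gn$gene_id %in% rownames(expr_agg), ]
  center <- (pk$start + pk$end) %/% 2
  pk_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(center + 1L, center + 1L))
  win_gr <- GenomicRanges::GRanges(gn$chrom,
                                   IRanges::IRanges(pmax(gn$tss + 1L - window, 1L),
                                                    gn$tss + 1L + window))
  hits <- GenomicRanges::findOverlaps(pk_gr, win_gr)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (length(pi) == 0) {
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      r = numeric(0), p_raw = numeric(0), fdr = numeric(0),
                      distance = integer(0), lineage = character(0),
                      retained = logical(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  a <- as_dense(atac_agg)[pk$peak_id[pi], , drop = FALSE]
  e <- as_dense(expr_agg)[gn$gene_id[gi], , drop = FALSE]
  sd_a <- apply(a, 1, sd)
  sd_e <- apply(e, 1, sd)
  ok <- sd_a > 0 & sd_e > 0
  n_skipped <- sum(!ok)
  az <- (a - rowMeans(a)) / pmax(sd_a, 1e-300)
  ez <- (e - rowMeans(e)) / pmax(sd_e, 1e-300)
  r <- rowSums(az * ez) / (n_agg - 1)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  if (n_agg >= 3) {
    tstat <- r[ok] * sqrt((n_agg - 2) / pmax(1e-300, 1 - r[ok]^2))
    p[ok] <- 2 * pt(abs(tstat), df = n_agg - 2, lower.tail = FALSE)
  } else {
    warning("fewer than 3 aggregates; correlation p-values undefined")
  }
  fdr <- rep(NA_real_, length(p))
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  out <- data.frame(peak_id = pk$peak_id[pi], gene_id = gn$gene_id[gi],
                    r = ifelse(ok, r, NA_real_), p_raw = p, fdr = fdr,
                    distance = abs(center[pi] - gn$tss[gi]),
                    lineage = lineage,
                    retained = ok & r >= r_min & !is.na(fdr) & fdr < fdr_max,
                    stringsAsFactors = FALSE)
  if (!keep_all) out <- out[out$retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cluster link activity profiles by hkmeans
#'
#' Ward hierarchical clustering of the z-scored rows is cut at `k` to
#' initialise k-means centres, followed by Lloyd k-means refinement to
#' convergence. Deterministic given the inputs.
#'
#' @param activity links x groups matrix.
#' @param k number of clusters (>= 2).
#' @param max_iter maximum k-means iterations (default 100).
#' @return list with `cluster` (assignments), `centers`, `tot_withinss` and
#'   the per-iteration objective trace.
#' @export
hkmeans_links <- function(activity, k, max_iter = 100L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(activity)) stop("k exceeds the number of links")
  z <- t(apply(activity, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  hc <- hclust(stats::dist(z), method = "ward.D2")
  init <- cutree(hc, k = k)
  centers <- vapply(seq_len(k), function(cc) colMeans(z[init == cc, , drop = FALSE]),
                    numeric(ncol(z)))
  centers <- t(centers)
  trace <- numeric(0)
  assign_prev <- init
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(z^2), rep(1, k)) - 2 * z %*% t(centers) +
      outer(rep(1, nrow(z)), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(nrow(z)), cl)])
    trace <- c(trace, obj)
    for (cc in seq_len(k)) {
      if (any(cl == cc)) centers[cc, ] <- colMeans(z[cl == cc, , drop = FALSE])
    }
    if (it > 1 && identical(cl, assign_prev)) break
    if (length(trace) > 1 &&
        abs(trace[length(trace) - 1] - obj) < 1e-6 * (1 + abs(obj))) break
    assign_prev <- cl
  }
  list(cluster = setNames(cl, rownames(activity)), centers = centers,
       tot_withinss = trace[length(trace)], objective_trace = trace)
}

#' Cross-lineage overlap counts of link CREs and target genes
#'
#' Venn-style counts of distal link cis-regulatory elements and of target
#' genes: shared by all lineages, by exactly two, or lineage-specific.
#'
#' @param linktables named list (per lineage) of LinkTables.
#' @param distal_only restrict CRE counting to non-promoter peaks when a
#'   `category` column is present (default TRUE).
#' @return list with `cre_counts` and `gene_counts` (named vectors:
#'   `shared_all`, `shared_two`, `specific`), plus the per-class id sets.
#' @export
link_overlap_counts <- function(linktables, distal_only = TRUE) {
  stopifnot(is.list(linktables), length(linktables) >= 2)
  n_lin <- length(linktables)
  get_set <- function(tb, col) {
    tb <- as.data.frame(tb)
    if (distal_only && "category" %in% names(tb) && col == "peak_id") {
      tb <- tb[tb$category != "promoter", , drop = FALSE]
    }
    unique(tb[[col]])
  }
  count_overlap <- function(col) {
    sets <- lapply(linktables, get_set, col = col)
    all_ids <- unique(unlist(sets))
    n_in <- vapply(all_ids, function(id) {
      sum(vapply(sets, function(s) id %in% s, logical(1)))
    }, integer(1))
    list(counts = c(shared_all = sum(n_in == n_lin),
                    shared_two = sum(n_in >= 2 & n_in < n_lin),
                    specific = sum(n_in == 1)),
         ids = split(all_ids, ifelse(n_in == n_lin, "shared_all",
                                     ifelse(n_in >= 2, "shared_two", "specific"))))
  }
  cre <- count_overlap("peak_id")
  gene <- count_overlap("gene_id")
  list(cre_counts = cre$counts, gene_counts = gene$counts,
       cre_ids = cre$ids, gene_ids = gene$ids)
}

#' Mean conservation score over intervals
#'
#' Arithmetic mean of the per-base track score over each interval; bases
#' not covered by the track score 0 and are flagged. Optional grouping
#' returns per-group score distributions.
#'
#' @param track data.frame bedGraph-style track (`chrom`, `start`, `end`,
#'   `score`; 0-based half-open).
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`), one
#'   row per element.
#' @param groups optional per-interval group labels.
#' @return data.frame per interval: `mean_score`, `covered_fraction`; with
#'   `groups`, an attached `group_summary` attribute (per-group mean and
#'   median).
#' @export
mean_conservation <- function(track, intervals, groups = NULL) {
  iv <- as.data.frame(intervals)
  if (any(iv$end <= iv$start)) stop("empty or invalid interval(s)")
  tr_gr <- GenomicRanges::GRanges(track$chrom,
                                  IRanges::IRanges(track$start + 1L, track$end))
  iv_gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(iv_gr, tr_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(iv_gr[qi], tr_gr[si])
  w <- IRanges::width(ov)
  widths <- iv$end - iv$start
  sum_score <- rep(0, nrow(iv))
  sum_cov <- rep(0, nrow(iv))
  if (length(qi)) {
    tap <- tapply(w * track$score[si], qi, sum)
    sum_score[as.integer(names(tap))] <- tap
    tap2 <- tapply(w, qi, sum)
    sum_cov[as.integer(names(tap2))] <- tap2
  }
  out <- data.frame(mean_score = sum_score / widths,
                    covered_fraction = sum_cov / widths)
  if (!is.null(rownames(iv))) rownames(out) <- rownames(iv)
  out$uncovered_flag <- out$covered_fraction < 1
  if (!is.null(groups)) {
    gs <- aggregate(out$mean_score, list(group = groups),
                    function(v) c(mean = mean(v), median = median(v), n = length(v)))
    attr(out, "group_summary") <- data.frame(group = gs$group,
                                             mean = gs$x[, "mean"],
                                             median = gs$x[, "median"],
                                             n = gs$x[, "n"])
  }
  out
}
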