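#' Summit-centred fixed-width peak finalisation with iterative overlap removal
#'
#' Each summit is extended to a window of `width` bp centred on it
#' (`[summit - (width-1)/2, summit + (width-1)/2 + 1)`, 0-based half-open).
#' Windows spilling past chromosome bounds are dropped. Overlaps are then
#' resolved iteratively: repeatedly keep the highest-score peak and discard
#' every peak overlapping it, breaking score ties by (chrom, start).
#'
#' @param summits data.frame with `chrom`, `summit` (0-based position) and
#'   `score` (-log10 significance); extra columns are carried through.
#' @param width odd peak width (default 501).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data.frame of disjoint fixed-width peaks (`chrom`, `start`,
#'   `end`, `summit`, `score`, ...).
#' @export
finalize_peaks <- function(summits, width = 501L, chrom_sizes) {
  if (width %% 2 == 0) stop("width must be odd (integer centre required)")
  half <- (width - 1L) %/% 2L
  pk <- as.data.frame(summits)
  stopifnot(all(c("chrom", "summit", "score") %in% names(pk)))
  pk$start <- as.integer(pk$summit - half)
  pk$end <- as.integer(pk$summit + half + 1L)
  within <- pk$start >= 0 & pk$end <= chrom_sizes[pk$chrom]
  pk <- pk[!is.na(within) & within, , drop = FALSE]
  iterative_overlap(pk)
}

# greedy score-ranked overlap resolution; equivalent to repeatedly taking
# the most significant peak and discarding everything that touches it
iterative_overlap <- function(pk) {
  if (nrow(pk) == 0) return(pk)
  ord <- order(-pk$score, pk$chrom, pk$start)
  pk <- pk[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  state <- integer(nrow(pk))  # 0 undecided, 1 kept, -1 discarded
  adj <- split(s, factor(q, levels = seq_len(nrow(pk))))
  for (i in seq_len(nrow(pk))) {
    if (state[i] != 0) next
    state[i] <- 1L
    nb <- adj[[i]]
    state[nb[state[nb] == 0L]] <- -1L
  }
  out <- pk[state == 1L, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Merge per-lineage peak sets into a consensus set
#'
#' Union of the finalized sets followed by the same iterative-overlap logic;
#' each consensus peak records which origins contributed a peak overlapping
#' it.
#'
#' @param peaksets named list of finalized peak data.frames.
#' @return consensus peak data.frame with an `origins` column
#'   (comma-separated contributing origin names).
#' @export
merge_origins <- function(peaksets) {
  stopifnot(is.list(peaksets), length(peaksets) >= 1)
  if (is.null(names(peaksets))) names(peaksets) <- paste0("set", seq_along(peaksets))
  all_pk <- do.call(rbind, lapply(names(peaksets), function(nm) {
    df <- as.data.frame(peaksets[[nm]])
    df$.origin <- nm
    df[, c("chrom", "start", "end", "summit", "score", ".origin")]
  }))
  cons <- iterative_overlap(all_pk)
  cons_gr <- GenomicRanges::GRanges(cons$chrom,
                                    IRanges::IRanges(cons$start + 1L, cons$end))
  all_gr <- GenomicRanges::GRanges(all_pk$chrom,
                                   IRanges::IRanges(all_pk$start + 1L, all_pk$end))
  hits <- GenomicRanges::findOverlaps(cons_gr, all_gr)
  contrib <- tapply(all_pk$.origin[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(o) paste(sort(unique(o)), collapse = ","))
  cons$origins <- NA_character_
  cons$origins[as.integer(names(contrib))] <- as.character(contrib)
  cons$.origin <- NULL
  cons
}

#' Assign genomic categories to peaks
#'
#' Precedence promoter > intronic > intergenic: a peak is a promoter if it
#' overlaps the strand-aware window `[TSS + promoter_window[1],
#' TSS + promoter_window[2]]`; otherwise intronic if it overlaps a gene
#' body; otherwise intergenic. With `four_way = TRUE` the gene-body category
#' is split no further here (exonic structure is not modelled); the flag is
#' accepted for interface compatibility.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame with `chrom`, `strand`, `tss`, `start`, `end`.
#' @param promoter_window upstream/downstream extent around the TSS in
#'   transcription direction (default c(-2000, 100)).
#' @return the peak data.frame with a `category` column.
#' @export
classify_peaks <- function(peaks, genes, promoter_window = c(-2000L, 100L)) {
  pk <- as.data.frame(peaks)
  pk_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$tss + promoter_window[1],
                       genes$tss - promoter_window[2])
  prom_end <- ifelse(plus, genes$tss + promoter_window[2],
                     genes$tss - promoter_window[1])
  prom_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(pmax(prom_start + 1, 1), prom_end + 1))
  body_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  is_prom <- IRanges::overlapsAny(pk_gr, prom_gr)
  in_body <- IRanges::overlapsAny(pk_gr, body_gr)
  pk$category <- ifelse(is_prom, "promoter",
                        ifelse(in_body, "intronic", "intergenic"))
  pk
}

#' Category enrichment of differential peaks against a consensus set
#'
#' Fold change of each category's fraction among differential peaks relative
#' to the consensus peak set, with a two-sided binomial test of the
#' differential count against the consensus fraction.
#'
#' @param dap_peaks categorized differential peak data.frame.
#' @param consensus_peaks categorized consensus peak data.frame.
#' @return data.frame per category: counts, fractions, `fold`, `p`.
#' @export
category_enrichment <- function(dap_peaks, consensus_peaks) {
  cats <- c("promoter", "intronic", "intergenic")
  n_dap <- nrow(dap_peaks)
  n_cons <- nrow(consensus_peaks)
  out <- lapply(cats, function(cc) {
    k <- sum(dap_peaks$category == cc)
    m <- sum(consensus_peaks$category == cc)
    frac_cons <- m / n_cons
    if (m == 0) {
      return(data.frame(category = cc, n_dap = k, n_consensus = m,
                        frac_dap = k / n_dap, frac_consensus = 0,
                        fold = NA_real_, p = NA_real_, undefined = TRUE))
    }
    p <- binom.test(k, n_dap, frac_cons, alternative = "two.sided")$p.value
    data.frame(category = cc, n_dap = k, n_consensus = m,
               frac_dap = k / n_dap, frac_consensus = frac_cons,
               fold = (k / n_dap) / frac_cons, p = p, undefined = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-lineage similarity of promoter-proximal versus distal peaks
#'
#' For every lineage pair, computes Spearman's rho of pseudobulk
#' accessibility across promoter-proximal differential peaks, and across
#' `n_resamples` equal-size random samples of distal (intronic/intergenic)
#' differential peaks. Returns both coefficient distributions and a
#' two-sided rank-sum comparison.
#'
#' @param accessibility peaks x lineages pseudobulk accessibility matrix.
#' @param categories per-peak category (aligned with rows).
#' @param n_resamples number of distal resamples per lineage pair
#'   (default 80).
#' @param seed sampling seed.
#' @return list with `promoter_rho`, `distal_rho`, medians, the rank-sum
#'   test and a `replacement_flag`.
#' @export
promoter_distal_similarity <- function(accessibility, categories,
                                       n_resamples = 80L, seed = 1L) {
  stopifnot(nrow(accessibility) == length(categories))
  if (ncol(accessibility) < 2) stop("need at least 2 lineages")
  prom_idx <- which(categories == "promoter")
  dist_idx <- which(categories %in% c("intronic", "intergenic"))
  if (length(prom_idx) == 0 || length(dist_idx) == 0) {
    stop("both promoter and distal categories must be non-empty")
  }
  replace_flag <- length(dist_idx) < length(prom_idx)
  if (replace_flag) {
    warning("fewer distal than promoter peaks; sampling with replacement")
  }
  pairs <- utils::combn(colnames(accessibility), 2, simplify = FALSE)
  prom_rho <- vapply(pairs, function(pp) {
    cor(accessibility[prom_idx, pp[1]], accessibility[prom_idx, pp[2]],
        method = "spearman")
  }, numeric(1))
  names(prom_rho) <- vapply(pairs, paste, "", collapse = "~")
  distal <- with_seed(seed, {
    res <- lapply(seq_len(n_resamples), function(r) {
      idx <- sample(dist_idx, length(prom_idx), replace = replace_flag)
      vapply(pairs, function(pp) {
        cor(accessibility[idx, pp[1]], accessibility[idx, pp[2]],
            method = "spearman")
      }, numeric(1))
    })
    do.call(rbind, res)
  })
  colnames(distal) <- names(prom_rho)
  test <- if (length(unique(c(prom_rho, as.numeric(distal)))) > 1) {
    suppressWarnings(wilcox.test(prom_rho, as.numeric(distal),
                                 alternative = "two.sided"))
  } else NULL
  list(promoter_rho = prom_rho, distal_rho = distal,
       median_promoter = median(prom_rho),
       median_distal = median(as.numeric(distal)),
       rank_sum_p = if (is.null(test)) NA_real_ else test$p.value,
       replacement_flag = replace_flag)
}
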