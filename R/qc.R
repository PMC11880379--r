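#' Per-cell RNA quality metrics
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param mito_gene_ids character vector of mitochondrial gene ids (subset of
#'   rownames).
#' @return data.frame with `total_umi`, `genes_detected`, `mito_fraction`,
#'   `genes_per_umi` per cell.
#' @export
rna_qc_metrics <- function(counts, mito_gene_ids = character(0)) {
  if (ncol(counts) == 0) stop("matrix has zero cells")
  if (!all(mito_gene_ids %in% rownames(counts))) {
    stop("mito_gene_ids must be a subset of the feature names")
  }
  total <- Matrix::colSums(counts)
  if (all(total == 0)) stop("all-zero count matrix")
  detected <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_gene_ids)) {
    Matrix::colSums(counts[mito_gene_ids, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, ncol(counts))
  data.frame(cell_id = colnames(counts), total_umi = total,
             genes_detected = detected, mito_fraction = mito,
             genes_per_umi = detected / pmax(total, 1),
             row.names = colnames(counts), stringsAsFactors = FALSE)
}

#' Filter RNA cells by total counts, mitochondrial fraction and gene ratio
#'
#' Three rules, each with its own flag:
#' \describe{
#'   \item{umi}{remove cells with total UMI > 4 x mean or < 0.2 x median of
#'     the sample.}
#'   \item{mito}{remove cells whose mitochondrial fraction exceeds both
#'     median + 3 x MAD (unscaled) and 0.1 — unless the cell's total UMI
#'     exceeds the sample median.}
#'   \item{ratio}{remove cells whose genes-detected-to-UMI ratio is below
#'     0.15 — unless the cell detects at least 2/3 of the sample maximum of
#'     genes.}
#' }
#' Sample-level statistics (mean, median, MAD, max) are computed once on the
#' input population and reported, so that re-filtering a kept subset with the
#' frozen statistics is a no-op.
#'
#' @param counts genes x cells count matrix.
#' @param mito_gene_ids mitochondrial gene ids.
#' @param ratio_min minimum genes-per-UMI ratio (default 0.15).
#' @param ratio_exception one of `"high_detected"` (default: spare cells with
#'   >= 2/3 of the max genes detected) or `"low_detected"` (the literal
#'   alternative reading: spare cells with < 2/3 of the max).
#' @return list with `kept` (cell ids), `metrics`, `flags` (logical
#'   data.frame, TRUE = rule fired), and `stats` (the frozen sample
#'   statistics).
#' @export
qc_filter_rna <- function(counts, mito_gene_ids = character(0),
                          ratio_min = 0.15,
                          ratio_exception = c("high_detected", "low_detected"),
                          stats = NULL) {
  ratio_exception <- match.arg(ratio_exception)
  m <- rna_qc_metrics(counts, mito_gene_ids)
  if (is.null(stats)) {
    stats <- list(umi_mean = mean(m$total_umi),
                  umi_median = median(m$total_umi),
                  mito_median = median(m$mito_fraction),
                  mito_mad = median(abs(m$mito_fraction - median(m$mito_fraction))),
                  genes_max = max(m$genes_detected))
  }
  umi_high <- m$total_umi > 4 * stats$umi_mean
  umi_low <- m$total_umi < 0.2 * stats$umi_median
  mito_hit <- m$mito_fraction > (stats$mito_median + 3 * stats$mito_mad) &
    m$mito_fraction > 0.1 & !(m$total_umi > stats$umi_median)
  ratio_low <- m$genes_per_umi < ratio_min
  spared <- if (ratio_exception == "high_detected") {
    m$genes_detected >= (2 / 3) * stats$genes_max
  } else {
    m$genes_detected < (2 / 3) * stats$genes_max
  }
  ratio_hit <- ratio_low & !spared
  flags <- data.frame(umi_high = umi_high, umi_low = umi_low,
                      mito = mito_hit, ratio = ratio_hit,
                      row.names = rownames(m))
  kept <- rownames(m)[!(umi_high | umi_low | mito_hit | ratio_hit)]
  list(kept = kept, metrics = m, flags = flags, stats = stats,
       ratio_exception = ratio_exception)
}

#' ATAC per-barcode quality metrics from a fragments table
#'
#' @param fragments data.frame/data.table with columns `chrom`, `start`,
#'   `end`, `barcode` (0-based half-open intervals).
#' @param peaks peak table with `chrom`, `start`, `end`.
#' @param genes gene table with `chrom`, `tss` (used for TSS enrichment).
#' @param tss_core half-width of the TSS core window (default 50 bp).
#' @param flank_range distance range of the background flank windows
#'   (default 1901-2000 bp on both sides).
#' @return data.frame per barcode: `n_fragments`, `fragments_in_peaks`,
#'   `frip`, `nucleosome_signal`, `tss_enrichment`, `zero_flag`.
#' @export
compute_atac_metrics <- function(fragments, peaks, genes,
                                 tss_core = 50L, flank_range = c(1901L, 2000L)) {
  frag <- as.data.frame(fragments)
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(frag)))
  bc <- sort(unique(frag$barcode))
  fr_gr <- GenomicRanges::GRanges(frag$chrom,
                                  IRanges::IRanges(frag$start + 1L, frag$end))
  pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$start + 1L, peaks$end))
  in_peak <- IRanges::overlapsAny(fr_gr, pk_gr)
  n_tot <- tapply(rep(1L, nrow(frag)), factor(frag$barcode, levels = bc), sum,
                  default = 0L)
  n_in <- tapply(as.integer(in_peak), factor(frag$barcode, levels = bc), sum,
                 default = 0L)

  len <- frag$end - frag$start
  mono <- len >= 147 & len <= 294
  nfr <- len < 147
  f <- factor(frag$barcode, levels = bc)
  n_mono <- tapply(as.integer(mono), f, sum, default = 0L)
  n_nfr <- tapply(as.integer(nfr), f, sum, default = 0L)
  nuc_sig <- n_mono / pmax(1, n_nfr)

  # insertion sites = both fragment ends
  ins_pos <- c(frag$start, frag$end - 1L)
  ins_chr <- c(frag$chrom, frag$chrom)
  ins_bc <- c(frag$barcode, frag$barcode)
  ins_gr <- GenomicRanges::GRanges(ins_chr, IRanges::IRanges(ins_pos + 1L, ins_pos + 1L))
  core_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$tss + 1L - tss_core,
                                                     genes$tss + 1L + tss_core))
  fl_lo <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tss + 1L - flank_range[2],
                                                   genes$tss + 1L - flank_range[1]))
  fl_hi <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tss + 1L + flank_range[1],
                                                   genes$tss + 1L + flank_range[2]))
  in_core <- IRanges::overlapsAny(ins_gr, core_gr)
  in_flank <- IRanges::overlapsAny(ins_gr, c(fl_lo, fl_hi))
  fi <- factor(ins_bc, levels = bc)
  n_core <- tapply(as.integer(in_core), fi, sum, default = 0L)
  n_flank <- tapply(as.integer(in_flank), fi, sum, default = 0L)
  core_width <- 2 * tss_core + 1
  flank_width <- 2 * (flank_range[2] - flank_range[1] + 1)
  tss_enr <- (n_core / core_width + 0.1) / (n_flank / flank_width + 0.1)

  out <- data.frame(barcode = bc, n_fragments = as.integer(n_tot),
                    fragments_in_peaks = as.integer(n_in),
                    frip = ifelse(n_tot > 0, n_in / n_tot, 0),
                    nucleosome_signal = as.numeric(nuc_sig),
                    tss_enrichment = as.numeric(tss_enr),
                    zero_flag = n_tot == 0,
                    row.names = bc, stringsAsFactors = FALSE)
  out$nucleosome_signal[out$zero_flag] <- 0
  out$tss_enrichment[out$zero_flag] <- 0
  out
}

#' Threshold filter for ATAC barcodes
#'
#' Keeps barcodes with fragments-in-peaks in a closed range, FRiP strictly
#' above `frip_min`, nucleosome signal strictly below `nucleosome_max` and
#' TSS enrichment strictly above `tss_min`.
#'
#' @param metrics data.frame from [compute_atac_metrics()] (or any table
#'   with the same columns).
#' @param fragments_range closed range of fragments-in-peaks (default
#'   1000-100000).
#' @param frip_min minimum FRiP, exclusive (default 0.15).
#' @param nucleosome_max maximum nucleosome signal, exclusive (default 4).
#' @param tss_min minimum TSS enrichment, exclusive (default 2).
#' @return character vector of kept barcodes.
#' @export
qc_filter_atac <- function(metrics, fragments_range = c(1000, 100000),
                           frip_min = 0.15, nucleosome_max = 4, tss_min = 2) {
  keep <- metrics$fragments_in_peaks >= fragments_range[1] &
    metrics$fragments_in_peaks <= fragments_range[2] &
    metrics$frip > frip_min &
    metrics$nucleosome_signal < nucleosome_max &
    metrics$tss_enrichment > tss_min
  metrics$barcode[keep]
}
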