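# independent rule-by-rule oracle used against qc_filter_rna
rna_rule_oracle <- function(m) {
  umi_mean <- mean(m$total_umi)
  umi_med <- median(m$total_umi)
  mito_med <- median(m$mito_fraction)
  mito_mad <- median(abs(m$mito_fraction - mito_med))
  gmax <- max(m$genes_detected)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    bad <- FALSE
    if (m$total_umi[i] > 4 * umi_mean) bad <- TRUE
    if (m$total_umi[i] < 0.2 * umi_med) bad <- TRUE
    if (m$mito_fraction[i] > mito_med + 3 * mito_mad &&
        m$mito_fraction[i] > 0.1 && !(m$total_umi[i] > umi_med)) bad <- TRUE
    if (m$genes_detected[i] / m$total_umi[i] < 0.15 &&
        !(m$genes_detected[i] >= 2 / 3 * gmax)) bad <- TRUE
    keep[i] <- !bad
  }
  keep
}

# build a count matrix whose per-cell metrics match a target table
counts_from_metrics <- function(total, detected, mito,
                                n_genes = max(detected) + 2) {
  n <- length(total)
  mat <- matrix(0L, n_genes, n,
                dimnames = list(c(sprintf("G%02d", seq_len(n_genes - 1)), "MT-1"),
                                sprintf("cell%03d", seq_len(n))))
  for (i in seq_len(n)) {
    mito_umi <- round(mito[i] * total[i])
    rest <- total[i] - mito_umi
    k <- max(1, detected[i] - (mito_umi > 0))
    base <- rest %/% k
    extra <- rest - base * k
    mat[seq_len(k), i] <- base
    mat[1, i] <- mat[1, i] + extra
    mat["MT-1", i] <- mito_umi
  }
  mat
}


make_bins <- function(values, centers) {
  structure(list(edges = NULL, centers = centers,
                 counts = rep(1L, length(centers)), means = values,
                 z = values), class = "trajectory_bins")
}

smooth_profiles <- function(n_feat, centers, warp = identity, seed = 32) {
  set.seed(seed)
  t(vapply(seq_len(n_feat), function(i) {
    a <- runif(1, 0.5, 2); b <- runif(1, -3, 3); ph <- runif(1, 0, pi)
    a * sin(2 * pi * warp(centers) + ph) + b * warp(centers)
  }, numeric(length(centers))))
}

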