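test_that("information content closed forms", {
  m <- matrix(c(1, 0, 0, 0,
                0.25, 0.25, 0.25, 0.25,
                0.5, 0.5, 0, 0), 4, 3,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  ic <- ic_profile(m)
  expect_equal(ic, c(2, 0, 1))
})

test_that("trimming removes exactly the uniform flanks and is idempotent", {
  p <- toy_pwm(flank_left = 2, flank_right = 3)
  trimmed <- trim_pwm(p)
  expect_equal(ncol(trimmed$mat), 6)
  expect_equal(trimmed$mat, toy_pwm()$mat)
  # idempotent; identity when nothing is below threshold
  expect_equal(trim_pwm(trimmed)$mat, trimmed$mat)
  expect_equal(trim_pwm(toy_pwm())$mat, toy_pwm()$mat)
  # refuses to go below length 4
  short <- toy_pwm(core = c("A", "C"), flank_left = 2, flank_right = 2)
  expect_gte(ncol(trim_pwm(short)$mat), 4)
  # all-uniform matrix is an error
  unif <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(trim_pwm(unif), "below the IC threshold")
})

test_that("similarity: self = 1, reverse complement = 1, symmetry", {
  p <- toy_pwm(core = c("A", "C", "G", "G", "T", "A", "C"))
  expect_equal(pwm_similarity(p, p), 1)
  rc <- regconverge:::new_pwm(
    regconverge:::reverse_complement_pwm(p$mat), "rc")
  expect_equal(pwm_similarity(p, rc), 1)
  q <- toy_pwm(core = c("T", "T", "G", "A", "C", "C"))
  expect_equal(pwm_similarity(p, q), pwm_similarity(q, p))
  expect_error(pwm_similarity(p$mat[, 1:3], q), "length >= 4")
})

test_that("similarity equals the brute-force offset oracle on random pairs", {
  set.seed(40)
  rand_mat <- function(len) {
    m <- matrix(rgamma(4 * len, 0.7), 4, len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    sweep(m, 2, colSums(m), "/")
  }
  for (rep in 1:100) {
    la <- sample(6:22, 1)
    lb <- sample(6:22, 1)
    a <- rand_mat(la)
    b <- rand_mat(lb)
    expect_equal(pwm_similarity(a, b), similarity_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("dedup keeps lowest-p representative per similarity component", {
  base <- toy_pwm(core = c("A", "C", "G", "T", "A", "C", "G", "T"))
  near <- base
  near$mat[, 1] <- c(0.8, 0.08, 0.08, 0.04)
  far <- toy_pwm(core = c("T", "G", "A", "A", "C", "T", "G", "G"))
  pwms <- list(
    regconverge:::new_pwm(base$mat, "m1", p = 1e-20),
    regconverge:::new_pwm(near$mat, "m2", p = 1e-15),
    regconverge:::new_pwm(base$mat, "m3", p = 1e-12),
    regconverge:::new_pwm(far$mat, "m4", p = 1e-5))
  res <- dedup_motifs(pwms, threshold = 0.8)
  expect_setequal(names(res$kept), c("m1", "m4"))
  expect_equal(res$redundancy$representative[res$redundancy$motif == "m3"], "m1")

  # random graphs <= 20 nodes against a brute-force component oracle
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    mats <- lapply(seq_len(n), function(i) {
      toy_pwm(core = sample(c("A", "C", "G", "T"), 8, replace = TRUE),
              name = paste0("x", i))$mat
    })
    pw <- lapply(seq_len(n), function(i) {
      regconverge:::new_pwm(mats[[i]], sprintf("x%02d", i),
                            p = 10^-sample(5:30, 1))
    })
    res <- dedup_motifs(pw, threshold = 0.8, trim = FALSE)
    # oracle: BFS components on the similarity graph
    sim <- res$similarity
    adj <- sim > 0.8
    diag(adj) <- FALSE
    comp <- rep(NA_integer_, n)
    cid <- 0
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    pvals <- vapply(pw, `[[`, 1, "p")
    nms <- vapply(pw, `[[`, "", "name")
    want <- sort(vapply(split(seq_len(n), comp), function(ix) {
      nms[ix[order(pvals[ix], nms[ix])][1]]
    }, ""))
    expect_identical(sort(names(res$kept)), unname(want))
  }
})

test_that("sequence scanning: consensus hits, flat background does not", {
  p <- toy_pwm(core = c("A", "C", "G", "T", "A", "C", "G", "T"))
  seqs <- c(pk1 = "TTTTTACGTACGTTTTTT",   # contains the consensus
            pk2 = "GGGGGGGGGGGGGGGGGG",   # no match
            pk3 = "TTTTTTACGTACGT")       # consensus at the end
  hits <- scan_motifs(list(p), names(seqs), sequences = seqs)
  expect_true(hits["pk1", "toy"])
  expect_false(hits["pk2", "toy"])
  expect_true(hits["pk3", "toy"])
  # reverse-complement of the consensus also hits
  seqs_rc <- c(pk = "GGGGACGTACGTGGGG", pkrc = "CCCCACGTACGTCCCC")
  hits_rc <- scan_motifs(list(p), names(seqs_rc), sequences = seqs_rc)
  expect_true(all(as.matrix(hits_rc)))
  expect_error(scan_motifs(list(p), "pk1", sequences = c(pk1 = "ACGT")),
               "shorter")
  # truth mode passes hit sets through
  ht <- scan_motifs(list(p), c("a", "b", "c"), truth = list(toy = c("a", "c")))
  expect_equal(as.logical(ht[, "toy"]), c(TRUE, FALSE, TRUE))

  # brute-force position-by-position oracle on toy sequences
  set.seed(42)
  lo <- log(((p$mat + 0.01) / 1.04) / 0.25)
  rc_lo <- log((regconverge:::reverse_complement_pwm((p$mat + 0.01) / 1.04)) / 0.25)
  max_score <- sum(apply(lo, 2, max))
  oracle_hit <- function(sq) {
    ch <- strsplit(sq, "")[[1]]
    idx <- match(ch, c("A", "C", "G", "T"))
    best <- -Inf
    for (mat in list(lo, rc_lo)) {
      for (s in 1:(length(idx) - ncol(mat) + 1)) {
        win <- idx[s:(s + ncol(mat) - 1)]
        if (anyNA(win)) next
        best <- max(best, sum(mat[cbind(win, seq_len(ncol(mat)))]))
      }
    }
    best >= 0.8 * max_score
  }
  seqs20 <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, "")
  names(seqs20) <- paste0("s", 1:20)
  got <- as.logical(scan_motifs(list(p), names(seqs20), sequences = seqs20))
  expect_identical(got, unname(vapply(seqs20, oracle_hit, TRUE)))
})

test_that("deviation z-scores are calibrated under random hit assignment", {
  set.seed(43)
  n_peaks <- 400
  n_cells <- 500
  counts <- Matrix::Matrix(
    matrix(rpois(n_peaks * n_cells,
                 rep(exp(rnorm(n_peaks, 0, 0.5)), n_cells)),
           n_peaks, n_cells,
           dimnames = list(sprintf("p%03d", 1:n_peaks),
                           sprintf("c%03d", 1:n_cells))), sparse = TRUE)
  gc <- runif(n_peaks, 0.3, 0.7)
  hits <- Matrix::Matrix(matrix(runif(n_peaks * 12) < 0.15, n_peaks, 12,
                                dimnames = list(rownames(counts),
                                                sprintf("m%02d", 1:12))),
                         sparse = TRUE)
  dev <- motif_deviations(counts, hits, gc, seed = 1)
  zm <- rowMeans(dev$z, na.rm = TRUE)
  zs <- apply(dev$z, 1, sd, na.rm = TRUE)
  expect_true(all(abs(zm) < 0.1))
  expect_true(all(zs > 0.8 & zs < 1.2))
})

test_that("deviations: trivial identity and planted lineage signal", {
  # single motif covering the single peak: observed equals expected
  counts1 <- Matrix::Matrix(matrix(3, 1, 4,
                                   dimnames = list("p1", paste0("c", 1:4))),
                            sparse = TRUE)
  hits1 <- Matrix::Matrix(matrix(TRUE, 1, 1,
                                 dimnames = list("p1", "m1")), sparse = TRUE)
  dev1 <- motif_deviations(counts1, hits1, gc = 0.5, seed = 1)
  expect_equal(unname(dev1$raw[1, ]), rep(0, 4))

  co <- small_cohort()
  hits <- scan_motifs(co$pwms$denovo, rownames(co$atac$counts),
                      truth = co$truth$motif_truth)
  lin_motifs <- paste0("DN_", co$truth$lineage_tfs$L1)
  dev <- motif_deviations(co$atac$counts, hits[, lin_motifs], co$peaks$gc,
                          seed = 2)
  meta <- co$atac$cells
  z_ec_own <- rowMeans(dev$z[, meta$lineage == "L1" & meta$cluster == "EC"])
  z_pc_own <- rowMeans(dev$z[, meta$lineage == "L1" & meta$cluster == "PC"])
  z_ec_other <- rowMeans(dev$z[, meta$lineage != "L1" & meta$cluster == "EC"])
  expect_true(all(z_ec_own > z_pc_own))
  expect_true(all(z_ec_own > z_ec_other))
})

test_that("motif annotation ranks the planted source TF first", {
  co <- small_cohort()
  hits <- scan_motifs(co$pwms$denovo, rownames(co$atac$counts),
                      truth = co$truth$motif_truth)
  keep <- Matrix::colSums(hits) > 0
  dev <- motif_deviations(co$atac$counts, hits[, keep], co$peaks$gc, seed = 3)
  # paired cells: align expression columns with the ATAC cells
  rna_of <- co$truth$paired_cells[colnames(co$atac$counts)]
  norm <- normalize_log(co$rna$counts)[, rna_of]
  nm10 <- intersect(rownames(dev$z), names(co$pwms$denovo))[1:10]
  ann <- annotate_motifs(co$pwms$denovo[nm10], co$pwms$reference, norm, dev,
                         seed = 4)
  tab <- ann$table[ann$table$selected, ]
  # each de novo motif DN_<TF>... should resolve to its source TF
  src <- sub("^DN_(STF_[0-9]+|TF_L[0-9]+_[0-9]+).*$", "\\1", tab$motif)
  expect_gt(mean(tab$tf == src), 0.8)
  # a TF never expressed is excluded from candidacy
  ref2 <- co$pwms$reference
  ref2[[1]]$tf <- "NOT_A_GENE"
  ann2 <- annotate_motifs(co$pwms$denovo[1], ref2[1], norm, dev, seed = 4)
  expect_true(nrow(ann2$table) == 0)
  expect_length(ann2$unannotated, 1)
})

test_that("mesenchymal motif variants are less similar than exact copies", {
  co <- small_cohort()
  dn <- co$pwms$denovo
  tf_of <- setNames(sub("^DN_(S?TF_[^_]*(_[0-9]+)?).*$", "\\1", names(dn)),
                    names(dn))
  res <- context_similarity_groups(dn, tf_of)
  expect_lt(res$median_mesenchymal, res$median_non_mesenchymal)
  expect_equal(res$median_non_mesenchymal, 1, tolerance = 1e-6)
  expect_lt(res$location_shift, 0)
  # swapping the group labels flips the location shift
  dn_sw <- lapply(dn, function(p) {
    p$context$mesenchymal <- !isTRUE(p$context$mesenchymal)
    p
  })
  res_sw <- context_similarity_groups(dn_sw, tf_of)
  expect_equal(res_sw$location_shift, -res$location_shift, tolerance = 1e-9)
})
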