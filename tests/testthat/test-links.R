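test_that("aggregate construction: shape, determinism, overlap filter", {
  cells <- sprintf("c%03d", 1:120)
  m <- aggregate_cells(cells, n_aggregates = 50, cells_per = 30, seed = 1)
  expect_equal(dim(m), c(30, 50))
  expect_true(all(m %in% cells))
  expect_identical(m, aggregate_cells(cells, 50, 30, seed = 1))
  # within-aggregate sampling without replacement when possible
  expect_true(all(apply(m, 2, function(col) !anyDuplicated(col))))
  # population smaller than an aggregate: whole population with replacement
  m2 <- aggregate_cells(cells[1:20], 5, 30, seed = 2)
  expect_equal(dim(m2), c(30, 5))
  # knn mode pools nearest cells in the embedding
  emb <- matrix(seq_along(cells), ncol = 1, dimnames = list(cells, "d1"))
  m3 <- aggregate_cells(cells, 10, 9, seed = 3, mode = "knn", embedding = emb)
  spans <- apply(m3, 2, function(col) diff(range(match(col, cells))))
  expect_true(all(spans <= 9))
  expect_error(aggregate_cells(cells[1:5], 3, 10, mode = "knn",
                               embedding = emb[1:5, , drop = FALSE]),
               "exceeds")
  # redundancy filter reduces the aggregate count
  m4 <- aggregate_cells(cells, 50, 30, seed = 4, mode = "knn",
                        embedding = emb, max_overlap = 0.5)
  expect_lt(ncol(m4), 50)
})

test_that("link correlation equals the two-pass Pearson formula", {
  set.seed(50)
  n_agg <- 40
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                      start = c(1000L, 5000L), end = c(1501L, 5501L))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000L)
  atac <- matrix(rnorm(2 * n_agg), 2, n_agg,
                 dimnames = list(peaks$peak_id, NULL))
  expr <- matrix(rnorm(n_agg), 1, n_agg, dimnames = list("g1", NULL))
  lt <- peak_gene_links(atac, expr, peaks, genes, window = 10000,
                        r_min = -1, fdr_max = 1.01, keep_all = TRUE)
  for (i in 1:2) {
    x <- atac[i, ]; y <- expr[1, ]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(lt$r[lt$peak_id == peaks$peak_id[i]], r_oracle,
                 tolerance = 1e-12)
  }
  expect_equal(lt$distance, abs((peaks$start + peaks$end) %/% 2 - genes$tss))
})

test_that("window gate: peaks beyond the window are never tested", {
  peaks <- data.frame(peak_id = c("near", "far"), chrom = "chr1",
                      start = c(1000L, 400000L), end = c(1501L, 400501L))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000L)
  atac <- matrix(rnorm(2 * 30), 2, 30, dimnames = list(peaks$peak_id, NULL))
  expr <- matrix(rnorm(30), 1, 30, dimnames = list("g1", NULL))
  lt <- peak_gene_links(atac, expr, peaks, genes, window = 250000,
                        keep_all = TRUE)
  expect_identical(unique(lt$peak_id), "near")
})

test_that("retention is monotone in the thresholds", {
  set.seed(51)
  n <- 60
  peaks <- data.frame(peak_id = sprintf("p%02d", 1:20), chrom = "chr1",
                      start = seq(1000L, by = 2000L, length.out = 20))
  peaks$end <- peaks$start + 501L
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 20000L)
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", NULL))
  atac <- matrix(rep(expr, each = 20) + rnorm(20 * n, sd = seq(0.2, 3, length.out = 20)),
                 20, n, dimnames = list(peaks$peak_id, NULL))
  n_loose <- nrow(peak_gene_links(atac, expr, peaks, genes, r_min = 0.3,
                                  fdr_max = 0.01))
  n_mid <- nrow(peak_gene_links(atac, expr, peaks, genes, r_min = 0.5,
                                fdr_max = 0.01))
  n_tight <- nrow(peak_gene_links(atac, expr, peaks, genes, r_min = 0.5,
                                  fdr_max = 1e-6))
  expect_true(n_loose >= n_mid && n_mid >= n_tight)
})

test_that("planted links are recovered and the permuted null is empty", {
  co <- small_cohort()
  meta <- co$atac$cells
  norm <- normalize_log(co$rna$counts)
  anorm <- normalize_log(co$atac$counts)
  truth_pairs <- paste(co$truth$planted_links$peak_id,
                       co$truth$planted_links$gene_id)
  found <- NULL
  null_found <- 0L
  tested <- 0L
  for (l in co$genome$lineages) {
    ac <- rownames(meta)[meta$lineage == l]
    emb <- matrix(meta[ac, "pseudotime"], ncol = 1, dimnames = list(ac, "t"))
    memb <- aggregate_cells(ac, 500, 100, seed = 7, mode = "knn",
                            embedding = emb, max_overlap = 0.8)
    aagg <- regconverge:::aggregate_means(anorm, memb)
    rmemb <- matrix(co$truth$paired_cells[memb], nrow = nrow(memb),
                    dimnames = dimnames(memb))
    eagg <- regconverge:::aggregate_means(norm, rmemb)
    lt <- peak_gene_links(aagg, eagg, co$peaks, co$genome$genes, lineage = l)
    found <- rbind(found, lt)
    # permuted aggregate pairing destroys every link
    set.seed(60 + match(l, co$genome$lineages))
    lt0 <- peak_gene_links(aagg, eagg[, sample(ncol(eagg))], co$peaks,
                           co$genome$genes, lineage = l, keep_all = TRUE)
    null_found <- null_found + sum(lt0$retained)
    tested <- tested + sum(!is.na(lt0$p_raw))
  }
  found_pairs <- unique(paste(found$peak_id, found$gene_id))
  recall <- mean(truth_pairs %in% found_pairs)
  precision <- mean(found_pairs %in% truth_pairs)
  expect_gt(recall, 0.7)   # small cohort; the acceptance suite tests 0.8
  expect_gt(precision, 0.8)
  expect_lte(null_found, max(1, 1e-4 * tested + 3 * sqrt(1e-4 * tested)))
})

test_that("hkmeans recovers planted blocks and handles edge cases", {
  set.seed(52)
  block1 <- matrix(rnorm(20 * 8, mean = rep(c(3, -3), each = 4)), 20, 8,
                   byrow = TRUE)
  block2 <- matrix(rnorm(15 * 8, mean = rep(c(-3, 3), each = 4)), 15, 8,
                   byrow = TRUE)
  m <- rbind(block1, block2)
  rownames(m) <- sprintf("l%02d", seq_len(nrow(m)))
  res <- hkmeans_links(m, k = 2)
  cl <- res$cluster
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:35])), 1)
  expect_false(cl[1] == cl[21])
  # objective never increases
  expect_true(all(diff(res$objective_trace) <= 1e-8))
  # duplicated rows land together; k = n gives singletons
  m2 <- m[c(1, 1, 21, 21), ]
  rownames(m2) <- paste0("r", 1:4)
  res2 <- hkmeans_links(m2, k = 2)
  expect_equal(res2$cluster[["r1"]], res2$cluster[["r2"]])
  res3 <- hkmeans_links(m[1:5, ], k = 5)
  expect_equal(sort(unname(res3$cluster)), 1:5)
  expect_error(hkmeans_links(m, k = 100), "exceeds")
  expect_error(hkmeans_links(m, k = 1), ">= 2")
})

test_that("overlap counts: identical, disjoint and planted asymmetry", {
  t1 <- data.frame(peak_id = c("p1", "p2"), gene_id = c("g1", "g2"),
                   category = "intergenic")
  t2 <- data.frame(peak_id = c("p1", "p2"), gene_id = c("g1", "g2"),
                   category = "intergenic")
  ov <- link_overlap_counts(list(a = t1, b = t2))
  expect_equal(unname(ov$cre_counts["shared_all"]), 2)
  expect_equal(unname(ov$gene_counts["shared_all"]), 2)
  t3 <- data.frame(peak_id = c("p3", "p4"), gene_id = c("g3", "g4"),
                   category = "intergenic")
  ov2 <- link_overlap_counts(list(a = t1, b = t3))
  expect_equal(unname(ov2$cre_counts["shared_all"]), 0)
  expect_equal(unname(ov2$cre_counts["specific"]), 4)
  # shared target genes through lineage-specific CREs
  mk <- function(pks) data.frame(peak_id = pks, gene_id = c("g1", "g2"),
                                 category = "intergenic")
  ov3 <- link_overlap_counts(list(a = mk(c("a1", "a2")),
                                  b = mk(c("b1", "b2")),
                                  c = mk(c("c1", "c2"))))
  expect_equal(unname(ov3$gene_counts["shared_all"]), 2)
  expect_equal(unname(ov3$cre_counts["shared_all"]), 0)
  expect_equal(unname(ov3$cre_counts["specific"]), 6)
  # promoter CREs are excluded when distal_only is set
  t4 <- data.frame(peak_id = c("p1", "pp"), gene_id = c("g1", "g9"),
                   category = c("intergenic", "promoter"))
  ov4 <- link_overlap_counts(list(a = t4, b = t1))
  expect_false("pp" %in% unlist(ov4$cre_ids))
})

test_that("mean conservation equals hand averages and respects coverage", {
  track <- data.frame(chrom = "chr1",
                      start = c(0L, 10L, 20L),
                      end = c(10L, 20L, 30L),
                      score = c(0.2, 0.6, 1.0))
  iv <- data.frame(chrom = "chr1", start = c(5L, 0L, 25L, 40L),
                   end = c(15L, 30L, 35L, 50L))
  res <- mean_conservation(track, iv)
  expect_equal(res$mean_score[1], (5 * 0.2 + 5 * 0.6) / 10)
  expect_equal(res$mean_score[2], mean(c(0.2, 0.6, 1.0)))
  # partial coverage: missing bases score 0 and are flagged
  expect_equal(res$mean_score[3], 5 * 1.0 / 10)
  expect_true(res$uncovered_flag[3])
  expect_equal(res$mean_score[4], 0)
  # constant track gives the constant everywhere covered
  tr2 <- data.frame(chrom = "chr1", start = 0L, end = 100L, score = 0.42)
  res2 <- mean_conservation(tr2, iv[1:2, ])
  expect_equal(res2$mean_score, c(0.42, 0.42))
  expect_error(mean_conservation(track,
                                 data.frame(chrom = "chr1", start = 5L,
                                            end = 5L)), "interval")
})

test_that("planted conservation ordering: shared elements exceed specific", {
  co <- small_cohort()
  shared_ids <- co$peaks$peak_id[co$peaks$role == "shared_cre"]
  spec_ids <- unlist(co$truth$lineage_daps)
  iv <- co$peaks[c(shared_ids, spec_ids), c("chrom", "start", "end")]
  groups <- c(rep("shared", length(shared_ids)),
              rep("specific", length(spec_ids)))
  res <- mean_conservation(co$conservation, iv, groups)
  gs <- attr(res, "group_summary")
  expect_gt(gs$mean[gs$group == "shared"], gs$mean[gs$group == "specific"] + 0.2)
})
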