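#' Pipeline configuration
#'
#' Collects stage toggles, thresholds (defaulting to the values used
#' throughout the package) and the seed for a full synthetic-cohort run.
#' Unknown keys are rejected.
#'
#' @param seed integer master seed.
#' @param sim a [sim_config()] (defaults to `sim_config(seed)`).
#' @param stages character vector of stages to run, in pipeline order.
#' @param rna_logfc_min,atac_logfc_min marker log-fold-change thresholds
#'   (broad 0.5, fine 0.25).
#' @param alpha adjusted-p threshold.
#' @param min_pct detection gate for marker tests.
#' @param atac_qc list of ATAC QC thresholds (fragments range, FRiP,
#'   nucleosome signal, TSS enrichment).
#' @param n_bins pseudotime bins per lineage.
#' @param n_align_points interpolated points for trajectory alignment.
#' @param link_window,link_r_min,link_fdr_max peak-to-gene link settings.
#' @param n_aggregates,cells_per_aggregate link aggregate geometry.
#' @param aggregate_max_overlap redundancy filter for link aggregates
#'   (fraction of shared members above which an aggregate is dropped).
#' @param deviation_cells_per_lineage cells per lineage subsampled for
#'   motif deviation scoring.
#' @param transfer_k RNA neighbours used when transferring pseudotime to
#'   ATAC cells.
#' @param outdir optional directory for the JSON report.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            stages = c("sim", "qc", "pseudobulk",
                                       "differential", "peaks", "trajectory",
                                       "motifs", "links"),
                            rna_logfc_min = 0.5, atac_logfc_min = 0.25,
                            alpha = 0.05, min_pct = 0.1,
                            atac_qc = list(fragments_range = c(1000, 100000),
                                           frip_min = 0.15, nucleosome_max = 4,
                                           tss_min = 2),
                            n_bins = 20L, n_align_points = 40L,
                            link_window = 250000L, link_r_min = 0.45,
                            link_fdr_max = 1e-4,
                            n_aggregates = 500L, cells_per_aggregate = 100L,
                            aggregate_max_overlap = 0.8,
                            deviation_cells_per_lineage = 500L,
                            transfer_k = 50L,
                            outdir = NULL) {
  if (is.null(sim)) sim <- sim_config(seed)
  known <- c("sim", "qc", "pseudobulk", "differential", "peaks", "trajectory",
             "motifs", "links")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(list(seed = as.integer(seed), sim = sim, stages = stages,
                 rna_logfc_min = rna_logfc_min,
                 atac_logfc_min = atac_logfc_min, alpha = alpha,
                 min_pct = min_pct, atac_qc = atac_qc,
                 n_bins = as.integer(n_bins),
                 n_align_points = as.integer(n_align_points),
                 link_window = as.integer(link_window),
                 link_r_min = link_r_min, link_fdr_max = link_fdr_max,
                 n_aggregates = as.integer(n_aggregates),
                 cells_per_aggregate = as.integer(cells_per_aggregate),
                 aggregate_max_overlap = aggregate_max_overlap,
                 deviation_cells_per_lineage = as.integer(deviation_cells_per_lineage),
                 transfer_k = as.integer(transfer_k),
                 outdir = outdir),
            class = "pipeline_config")
}

require_stage <- function(state, what, needed_by) {
  if (is.null(state[[what]])) {
    stop("stage '", needed_by, "' requires '", what,
         "' which was not run or produced no output")
  }
  state[[what]]
}

#' Run the full regulatory-convergence pipeline on a synthetic cohort
#'
#' Chains simulation, QC, pseudobulk co-clustering, marker testing, peak
#' categorisation and promoter/distal similarity, pseudotime trajectory
#' alignment and transfer, motif deviation scoring and annotation, and
#' peak-to-gene link analysis with conservation summaries. Produces a
#' machine-readable report with every stage's headline outputs.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (skips the `sim` stage draw).
#' @return list with `report` (JSON-serialisable) and `state`
#'   (intermediate objects).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = list(seed = config$seed, stages = config$stages))
  state <- list()
  run <- function(stage) stage %in% config$stages

  # ---- sim ----
  if (run("sim")) {
    if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
    state$cohort <- cohort
    report$sim <- list(n_rna_cells = ncol(cohort$rna$counts),
                       n_genes = nrow(cohort$rna$counts),
                       n_atac_cells = ncol(cohort$atac$counts),
                       n_peaks = nrow(cohort$atac$counts),
                       lineages = cohort$genome$lineages,
                       module_sizes = lengths(cohort$truth$module_genes))
  } else if (!is.null(cohort)) {
    state$cohort <- cohort
  }
  co <- require_stage(state, "cohort", "qc")
  lineages <- co$genome$lineages
  truth <- co$truth

  # ---- qc ----
  if (run("qc")) {
    rqc <- qc_filter_rna(co$rna$counts, truth$mito_genes)
    atac_kept <- colnames(co$atac$counts)
    atac_metrics <- NULL
    if (!is.null(co$fragments)) {
      atac_metrics <- compute_atac_metrics(co$fragments, co$peaks,
                                           co$genome$genes)
      atac_kept <- qc_filter_atac(atac_metrics,
                                  fragments_range = config$atac_qc$fragments_range,
                                  frip_min = config$atac_qc$frip_min,
                                  nucleosome_max = config$atac_qc$nucleosome_max,
                                  tss_min = config$atac_qc$tss_min)
    }
    state$qc <- list(rna_kept = rqc$kept, atac_kept = atac_kept,
                     rna_flags = rqc$flags, atac_metrics = atac_metrics)
    report$qc <- list(rna_kept = length(rqc$kept),
                      rna_removed = ncol(co$rna$counts) - length(rqc$kept),
                      atac_kept = length(atac_kept),
                      atac_metrics_computed = !is.null(atac_metrics))
  } else {
    state$qc <- list(rna_kept = colnames(co$rna$counts),
                     atac_kept = colnames(co$atac$counts))
  }
  rna_cells <- state$qc$rna_kept
  rna_meta <- co$rna$cells[rna_cells, ]
  norm <- normalize_log(co$rna$counts[, rna_cells, drop = FALSE])
  state$norm <- norm

  # ---- differential (markers feed the pseudobulk verdicts) ----
  if (run("differential")) {
    marker_tables <- list()
    for (l in lineages) {
      idx <- rna_meta$lineage == l
      x <- norm[, idx, drop = FALSE]
      mask <- rna_meta$cluster[idx] == "EC"
      lat <- data.frame(log_depth = log(Matrix::colSums(co$rna$counts[, rna_cells[idx]])),
                        stage2 = as.numeric(rna_meta$stage[idx] == "S2"),
                        stage3 = as.numeric(rna_meta$stage[idx] == "S3"))
      marker_tables[[l]] <- lr_markers(x, mask, lat, min_pct = config$min_pct,
                                       logfc_min = config$rna_logfc_min,
                                       alpha = config$alpha)
    }
    shared <- common_markers(marker_tables)
    state$markers <- marker_tables
    state$shared_markers <- shared
    report$differential <- list(
      n_de_per_lineage = vapply(marker_tables, function(tb) sum(tb$pass), 0L),
      n_shared_markers = length(shared),
      module_recovery = if (length(unlist(truth$module_genes))) {
        length(intersect(shared, unlist(truth$module_genes))) /
          length(unlist(truth$module_genes))
      } else NA)
  }

  # ---- pseudobulk co-clustering ----
  if (run("pseudobulk")) {
    mk <- require_stage(state, "markers", "pseudobulk")
    group <- paste(rna_meta$lineage, rna_meta$cluster, sep = "_")
    pb <- pseudobulk_means(norm, group)
    de_union <- unique(unlist(lapply(mk, function(tb) tb$feature[tb$pass])))
    ec_groups <- paste(lineages, "EC", sep = "_")
    cc_de <- correlate_and_cluster(pb$profile, de_union, designated = ec_groups)
    tf_feats <- unlist(truth$lineage_tfs)
    cc_tf <- NULL
    lineage_clades <- NA
    if (length(tf_feats) >= 2) {
      cc_tf <- correlate_and_cluster(pb$profile, tf_feats)
      lineage_clades <- all(vapply(lineages, function(l) {
        is_exclusive_clade(cc_tf$hclust,
                           grep(paste0("^", l, "_"), colnames(pb$profile),
                                value = TRUE))
      }, logical(1)))
    }
    score <- score_module(norm, unlist(truth$module_genes) %||% rownames(norm)[1:5],
                          seed = config$seed)
    state$pseudobulk <- list(profile = pb, cc_de = cc_de, cc_tf = cc_tf,
                             module_score = score)
    report$pseudobulk <- list(
      n_groups = ncol(pb$profile),
      ec_exclusive_clade_de = cc_de$designated_clade,
      lineage_clades_tf = lineage_clades,
      module_score_ec_minus_pc = mean(score[rna_meta$cluster == "EC"]) -
        mean(score[rna_meta$cluster == "PC"]))
  }

  # ---- peaks ----
  atac_cells <- state$qc$atac_kept
  atac_meta <- co$atac$cells[atac_cells, ]
  anorm <- normalize_log(co$atac$counts[, atac_cells, drop = FALSE])
  if (run("peaks")) {
    pk_cat <- classify_peaks(co$peaks, co$genome$genes)
    dap_tables <- list()
    for (l in lineages) {
      idx <- atac_meta$lineage == l
      x <- anorm[, idx, drop = FALSE]
      mask <- atac_meta$cluster[idx] == "EC"
      lat <- data.frame(log_frag = log(Matrix::colSums(co$atac$counts[, atac_cells[idx]])),
                        stage2 = as.numeric(atac_meta$stage[idx] == "S2"),
                        stage3 = as.numeric(atac_meta$stage[idx] == "S3"))
      dap_tables[[l]] <- lr_markers(x, mask, lat, min_pct = config$min_pct,
                                    logfc_min = config$atac_logfc_min,
                                    alpha = config$alpha)
    }
    dap_ids <- unique(unlist(lapply(dap_tables, function(tb) tb$feature[tb$pass])))
    dap_cat <- pk_cat[pk_cat$peak_id %in% dap_ids, ]
    enr <- category_enrichment(dap_cat, pk_cat)
    # EC pseudobulk accessibility per lineage over the DAPs
    ec_prof <- vapply(lineages, function(l) {
      sel <- atac_meta$lineage == l & atac_meta$cluster == "EC"
      Matrix::rowMeans(anorm[dap_ids, sel, drop = FALSE])
    }, numeric(length(dap_ids)))
    pd <- promoter_distal_similarity(ec_prof,
                                     pk_cat$category[match(dap_ids, pk_cat$peak_id)],
                                     seed = config$seed)
    state$peaks <- list(categorized = pk_cat, dap_tables = dap_tables,
                        dap_ids = dap_ids, enrichment = enr, prom_distal = pd)
    report$peaks <- list(
      n_daps = length(dap_ids),
      category_fold = setNames(enr$fold, enr$category),
      promoter_rho_median = pd$median_promoter,
      distal_rho_median = pd$median_distal,
      promoter_exceeds_distal = pd$median_promoter > pd$median_distal)
  }

  # ---- trajectory ----
  if (run("trajectory")) {
    feats <- unique(c(unlist(truth$module_genes), unlist(truth$lineage_tfs),
                      truth$shared_tfs))
    if (!length(feats)) feats <- rownames(norm)
    bins <- lapply(setNames(lineages, lineages), function(l) {
      idx <- rna_meta$lineage == l
      bin_pseudotime(norm[feats, idx, drop = FALSE], rna_meta$pseudotime[idx],
                     config$n_bins)
    })
    aligns <- list()
    prs <- utils::combn(lineages, 2, simplify = FALSE)
    mod_feats <- intersect(unlist(truth$module_genes), feats)
    if (length(mod_feats) < 2) mod_feats <- feats
    for (pp in prs) {
      aligns[[paste(pp, collapse = "~")]] <-
        align_trajectories(bins[[pp[1]]], bins[[pp[2]]], mod_feats,
                           n_points = config$n_align_points)
    }
    activity <- gene_activity(co$atac$counts[, atac_cells, drop = FALSE],
                              co$peaks, co$genome$genes)
    transferred <- unlist(lapply(lineages, function(l) {
      ridx <- which(rna_meta$lineage == l)
      aidx <- which(atac_meta$lineage == l)
      transfer_pseudotime(norm[, ridx, drop = FALSE],
                          rna_meta$pseudotime[ridx],
                          normalize_log(activity[, aidx, drop = FALSE]),
                          k = min(config$transfer_k, length(ridx)))
    }))
    truth_t <- co$atac$cells[names(transferred), "pseudotime"]
    state$trajectory <- list(bins = bins, alignments = aligns,
                             activity = activity, transferred = transferred)
    report$trajectory <- list(
      mean_alignment_cost = vapply(aligns, function(a) a$mean_cost, 0),
      transfer_spearman = suppressWarnings(
        cor(transferred, truth_t, method = "spearman")))
  }

  # ---- motifs ----
  if (run("motifs")) {
    hit <- scan_motifs(c(co$pwms$denovo), rownames(co$atac$counts),
                       truth = truth$motif_truth)
    keep_m <- Matrix::colSums(hit) > 0
    hit <- hit[, keep_m, drop = FALSE]
    sub <- with_seed(config$seed, {
      unlist(lapply(lineages, function(l) {
        idx <- which(atac_meta$lineage == l)
        sample(idx, min(config$deviation_cells_per_lineage, length(idx)))
      }))
    })
    dev <- motif_deviations(co$atac$counts[, atac_cells[sub], drop = FALSE],
                            hit, co$peaks$gc, seed = config$seed)
    # pair deviations with expression through the cell pairing
    ann <- NULL
    if (!is.null(truth$paired_cells)) {
      paired_rna <- truth$paired_cells[atac_cells[sub]]
      ok <- paired_rna %in% colnames(norm)
      dev_paired <- dev
      dev_paired$z <- dev$z[, ok, drop = FALSE]
      ann <- annotate_motifs(co$pwms$denovo[colnames(hit)], co$pwms$reference,
                             norm[, paired_rna[ok], drop = FALSE], dev_paired,
                             seed = config$seed)
    }
    tf_of <- setNames(sub("^DN_(S?TF_[^_]*(_[0-9]+)?).*$", "\\1",
                          names(co$pwms$denovo)), names(co$pwms$denovo))
    ctx <- tryCatch(context_similarity_groups(co$pwms$denovo, tf_of),
                    error = function(e) NULL)
    state$motifs <- list(hits = hit, deviations = dev, annotation = ann,
                         context = ctx, cells = atac_cells[sub])
    sel <- if (!is.null(ann) && nrow(ann$table)) {
      tab <- ann$table[ann$table$selected, ]
      mean(tab$tf == sub("^DN_", "", tab$motif) |
             mapply(grepl, paste0("^DN_", tab$tf), tab$motif))
    } else NA
    report$motifs <- list(
      n_motifs = ncol(hit),
      deviation_z_sd = stats::median(apply(dev$z, 1, sd, na.rm = TRUE)),
      annotation_top1_accuracy = sel,
      mesenchymal_median_similarity = if (!is.null(ctx)) ctx$median_mesenchymal else NA,
      non_mesenchymal_median_similarity = if (!is.null(ctx)) ctx$median_non_mesenchymal else NA)
  }

  # ---- links ----
  if (run("links")) {
    if (is.null(truth$paired_cells)) {
      stop("stage 'links' requires paired cells (or a transferred pseudoexpression)")
    }
    pk_cat <- if (!is.null(state$peaks)) state$peaks$categorized else
      classify_peaks(co$peaks, co$genome$genes)
    linktabs <- list()
    for (l in lineages) {
      acells <- atac_cells[atac_meta$lineage == l]
      acells <- acells[truth$paired_cells[acells] %in% colnames(norm)]
      # kNN aggregates along pseudotime: each aggregate pools
      # developmentally similar cells, so aggregate means span the
      # trajectory instead of averaging it away
      emb <- matrix(co$atac$cells[acells, "pseudotime"], ncol = 1,
                    dimnames = list(acells, "t"))
      memb <- aggregate_cells(acells, config$n_aggregates,
                              config$cells_per_aggregate,
                              seed = child_seed(config$seed, match(l, lineages)),
                              mode = "knn", embedding = emb,
                              max_overlap = config$aggregate_max_overlap)
      atac_agg <- aggregate_means(anorm, memb)
      rmemb <- matrix(truth$paired_cells[memb], nrow = nrow(memb),
                      dimnames = dimnames(memb))
      expr_agg <- aggregate_means(norm, rmemb)
      lt <- peak_gene_links(atac_agg, expr_agg, co$peaks, co$genome$genes,
                            window = config$link_window,
                            r_min = config$link_r_min,
                            fdr_max = config$link_fdr_max, lineage = l)
      lt$category <- pk_cat$category[match(lt$peak_id, pk_cat$peak_id)]
      linktabs[[l]] <- lt
    }
    ov <- link_overlap_counts(linktabs)
    all_links <- do.call(rbind, linktabs)
    cons_groups <- c(shared_all = "shared_all", shared_two = "shared_two",
                     specific = "specific")
    cre_ids <- unlist(lapply(names(ov$cre_ids), function(g) {
      setNames(rep(g, length(ov$cre_ids[[g]])), ov$cre_ids[[g]])
    }))
    cons <- NULL
    if (length(cre_ids)) {
      iv <- co$peaks[names(cre_ids), c("chrom", "start", "end")]
      cons <- mean_conservation(co$conservation, iv, groups = unname(cre_ids))
    }
    truth_pairs <- paste(truth$planted_links$peak_id, truth$planted_links$gene_id)
    found_pairs <- unique(paste(all_links$peak_id, all_links$gene_id))
    recall <- if (length(truth_pairs)) {
      mean(truth_pairs %in% found_pairs)
    } else NA
    precision <- if (length(found_pairs)) {
      mean(found_pairs %in% truth_pairs)
    } else NA
    gs <- if (!is.null(cons)) attr(cons, "group_summary") else NULL
    state$links <- list(tables = linktabs, overlap = ov, conservation = cons)
    report$links <- list(
      n_links = nrow(all_links),
      recall = recall, precision = precision,
      cre_counts = as.list(ov$cre_counts),
      gene_counts = as.list(ov$gene_counts),
      conservation_by_group = if (!is.null(gs)) {
        setNames(as.list(gs$mean), gs$group)
      } else NULL)
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  list(report = report, state = state)
}
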