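#' Configuration for the synthetic three-lineage cohort generator
#'
#' Builds the parameter set that defines a simulated multi-omic cohort: three
#' embryonic lineages (neural crest, somite, lateral plate mesoderm by
#' default) whose mesenchymal cells converge onto a shared chondrogenic
#' expression module along pseudotime, preceded by lineage-specific
#' transcription-factor waves, with matching chromatin structure (shared
#' promoter-proximal peaks, lineage-specific distal peaks, planted
#' peak-to-gene links, motif occurrences and a conservation track).
#'
#' @param seed integer seed; every stochastic draw in the generator derives
#'   from it.
#' @param n_lineages number of lineages (default 3).
#' @param cells_per_lineage cells simulated per lineage and modality.
#' @param n_genes total number of genes (module genes, TFs, mitochondrial and
#'   baseline genes included).
#' @param n_module_genes sizes of the two shared chondrogenic co-expression
#'   modules (default 17 and 41).
#' @param n_tf_per_lineage lineage-restricted transcription factors per
#'   lineage.
#' @param n_shared_tfs TFs active in the chondrogenic programme of all
#'   lineages (their binding motifs are discovered independently per lineage).
#' @param n_peaks total accessible peaks.
#' @param frac_promoter fraction of peaks that are promoter-proximal.
#' @param n_lineage_daps differentially accessible distal peaks planted per
#'   lineage.
#' @param n_planted_links lineage-specific distal cis-regulatory elements
#'   linked to module genes (split across lineages).
#' @param n_shared_cres distal elements linked to module genes and active in
#'   all lineages.
#' @param nb_dispersion negative-binomial size parameter for RNA counts.
#' @param depth_lognormal_params `c(mu, sigma)` of the per-cell log-normal
#'   depth factor.
#' @param tf_bump_center pseudotime at which lineage TF expression peaks;
#'   must precede `chondro_midpoint`.
#' @param chondro_midpoint pseudotime midpoint of the shared module's
#'   sigmoidal rise.
#' @param effect_size_logfc amplitude (natural-log scale) of planted effects;
#'   per-feature amplitudes are drawn as `effect_size_logfc * U(0.6, 1.4)`.
#' @param motif_lengths integer range of simulated motif core lengths.
#' @param conservation_levels `c(shared_mean, specific_mean, noise_sd)` of
#'   the per-base conservation score track.
#' @param paired generate ATAC cells paired one-to-one with RNA cells.
#' @param include_fragments also materialise a fragments table (needed for
#'   ATAC QC metrics; skip for RNA-only analyses).
#' @param atac_depth multiplier on per-cell ATAC fragment rates (overall
#'   sequencing depth of the ATAC modality).
#' @param n_mito_genes mitochondrial genes (for RNA QC).
#' @param n_pc_genes highly expressed progenitor-state genes whose
#'   expression declines along pseudotime in every lineage (keeps library
#'   composition roughly balanced as the chondrogenic programme rises).
#' @param n_pc_daps accessible progenitor-state distal peaks closing along
#'   pseudotime in every lineage (the chromatin counterpart of
#'   `n_pc_genes`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_lineages = 3L,
                       cells_per_lineage = 1500L,
                       n_genes = 500L,
                       n_module_genes = c(17L, 41L),
                       n_tf_per_lineage = 8L,
                       n_shared_tfs = 6L,
                       n_peaks = 1200L,
                       frac_promoter = 0.3,
                       n_lineage_daps = 120L,
                       n_planted_links = 60L,
                       n_shared_cres = 9L,
                       nb_dispersion = 2,
                       depth_lognormal_params = c(0, 0.35),
                       tf_bump_center = 0.35,
                       chondro_midpoint = 0.65,
                       effect_size_logfc = 2.5,
                       motif_lengths = c(8L, 22L),
                       conservation_levels = c(shared_mean = 0.65,
                                               specific_mean = 0.25,
                                               noise_sd = 0.08),
                       paired = TRUE,
                       include_fragments = TRUE,
                       atac_depth = 3,
                       n_mito_genes = 8L,
                       n_pc_genes = 45L,
                       n_pc_daps = 150L) {
  cfg <- list(seed = as.integer(seed), n_lineages = as.integer(n_lineages),
              cells_per_lineage = as.integer(cells_per_lineage),
              n_genes = as.integer(n_genes),
              n_module_genes = as.integer(n_module_genes),
              n_tf_per_lineage = as.integer(n_tf_per_lineage),
              n_shared_tfs = as.integer(n_shared_tfs),
              n_peaks = as.integer(n_peaks), frac_promoter = frac_promoter,
              n_lineage_daps = as.integer(n_lineage_daps),
              n_planted_links = as.integer(n_planted_links),
              n_shared_cres = as.integer(n_shared_cres),
              nb_dispersion = nb_dispersion,
              depth_lognormal_params = depth_lognormal_params,
              tf_bump_center = tf_bump_center,
              chondro_midpoint = chondro_midpoint,
              effect_size_logfc = effect_size_logfc,
              motif_lengths = as.integer(motif_lengths),
              conservation_levels = conservation_levels,
              paired = isTRUE(paired),
              include_fragments = isTRUE(include_fragments),
              atac_depth = atac_depth,
              n_mito_genes = as.integer(n_mito_genes),
              n_pc_genes = as.integer(n_pc_genes),
              n_pc_daps = as.integer(n_pc_daps))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$tf_bump_center >= cfg$chondro_midpoint) {
    stop("tf_bump_center must precede chondro_midpoint")
  }
  if (cfg$frac_promoter <= 0 || cfg$frac_promoter >= 1) {
    stop("frac_promoter must lie strictly between 0 and 1")
  }
  counts <- c(cfg$n_lineages, cfg$cells_per_lineage, cfg$n_genes,
              cfg$n_module_genes, cfg$n_peaks, cfg$n_lineage_daps)
  if (any(counts <= 0)) stop("all counts must be positive")
  n_special <- sum(cfg$n_module_genes) + cfg$n_lineages * cfg$n_tf_per_lineage +
    cfg$n_shared_tfs + cfg$n_mito_genes + cfg$n_pc_genes
  if (cfg$n_genes <= n_special) {
    stop("n_genes too small for the requested module/TF/mito/PC genes")
  }
  invisible(cfg)
}

# ---- genome layout -------------------------------------------------------
# One shared chromosome carries module genes, their promoters and linked
# distal elements; one chromosome per lineage carries that lineage's TF genes
# and its block of lineage-specific distal peaks. Genes sit in 600-kb "slots"
# so that peak-to-gene candidate windows of neighbouring genes never overlap.
SLOT <- 600000L
TSS_OFFSET <- 300000L
GENE_BODY <- 10000L

sim_genome <- function(cfg) {
  lineages <- paste0("L", seq_len(cfg$n_lineages))
  n_module <- sum(cfg$n_module_genes)
  module_ids <- c(sprintf("MODA_%02d", seq_len(cfg$n_module_genes[1])),
                  sprintf("MODB_%02d", seq_len(cfg$n_module_genes[2])))
  tf_ids <- unlist(lapply(lineages, function(l) {
    sprintf("TF_%s_%d", l, seq_len(cfg$n_tf_per_lineage))
  }))
  stf_ids <- sprintf("STF_%d", seq_len(cfg$n_shared_tfs))
  mito_ids <- sprintf("MT-G%d", seq_len(cfg$n_mito_genes))
  n_base <- cfg$n_genes - n_module - length(tf_ids) - length(stf_ids) -
    length(mito_ids)
  base_ids <- sprintf("G%04d", seq_len(n_base))

  # distribute baseline genes: ~half shared chromosome, rest across lineages
  n_base_shared <- ceiling(n_base / 2)
  base_chrom <- c(rep("chrS", n_base_shared),
                  rep(paste0("chr", lineages),
                      length.out = n_base - n_base_shared))
  gene_tab <- data.frame(
    gene_id = c(module_ids, stf_ids, mito_ids, base_ids, tf_ids),
    type = c(rep(c("module_a", "module_b"), cfg$n_module_genes),
             rep("shared_tf", length(stf_ids)),
             rep("mito", length(mito_ids)),
             rep("baseline", n_base),
             rep("tf", length(tf_ids))),
    lineage = c(rep(NA_character_, n_module + length(stf_ids) +
                      length(mito_ids) + n_base),
                rep(lineages, each = cfg$n_tf_per_lineage)),
    stringsAsFactors = FALSE)
  gene_tab$chrom <- NA_character_
  shared_rows <- gene_tab$type %in% c("module_a", "module_b", "shared_tf",
                                      "mito")
  gene_tab$chrom[shared_rows] <- "chrS"
  gene_tab$chrom[gene_tab$type == "baseline"] <- base_chrom
  gene_tab$chrom[gene_tab$type == "tf"] <- paste0("chr", gene_tab$lineage[gene_tab$type == "tf"])
  # progenitor-state genes: highly expressed, declining along pseudotime
  pc_idx <- head(which(gene_tab$type == "baseline" & gene_tab$chrom == "chrS"),
                 cfg$n_pc_genes)
  gene_tab$type[pc_idx] <- "pc"

  # assign slot indices per chromosome, leaving spare slots for
  # gene-free background peaks
  gene_tab$slot <- NA_integer_
  chrom_levels <- c("chrS", paste0("chr", lineages))
  spare <- 300L
  chrom_sizes <- integer(0)
  for (ch in chrom_levels) {
    idx <- which(gene_tab$chrom == ch)
    gene_tab$slot[idx] <- seq_along(idx)
    chrom_sizes[ch] <- (length(idx) + spare + 1L) * SLOT
  }
  gene_tab$tss <- (gene_tab$slot - 1L) * SLOT + TSS_OFFSET
  gene_tab$strand <- rep(c("+", "-"), length.out = nrow(gene_tab))
  gene_tab$start <- ifelse(gene_tab$strand == "+", gene_tab$tss,
                           gene_tab$tss - GENE_BODY)
  gene_tab$end <- ifelse(gene_tab$strand == "+", gene_tab$tss + GENE_BODY,
                         gene_tab$tss)
  rownames(gene_tab) <- gene_tab$gene_id
  list(genes = gene_tab, chrom_sizes = chrom_sizes, lineages = lineages,
       spare_slots = spare)
}

# ---- peak layout ---------------------------------------------------------
sim_peaks <- function(cfg, genome) {
  genes <- genome$genes
  lineages <- genome$lineages
  width <- 501L
  half <- 250L

  module_rows <- genes[genes$type %in% c("module_a", "module_b"), ]
  prom_n <- round(cfg$frac_promoter * cfg$n_peaks)
  # promoters: all module genes, shared TFs, lineage TFs, mito, then baseline
  prom_order <- c(rownames(module_rows),
                  rownames(genes[genes$type == "shared_tf", ]),
                  rownames(genes[genes$type == "tf", ]),
                  rownames(genes[genes$type == "pc", ]),
                  rownames(genes[genes$type == "mito", ]),
                  rownames(genes[genes$type == "baseline", ]))
  prom_genes <- head(prom_order, prom_n)

  mk <- function(chrom, summit, role, origin, gene = NA_character_) {
    data.frame(chrom = chrom, summit = as.integer(summit), role = role,
               origin = origin, gene = gene, stringsAsFactors = FALSE)
  }
  pk <- list()
  g <- genes[prom_genes, ]
  pk$prom <- mk(g$chrom, g$tss, "promoter", "shared", g$gene_id)

  # lineage-specific distal DAP blocks: half intronic in baseline genes on
  # the lineage chromosome, half intergenic in gene-free positions
  for (l in lineages) {
    ch <- paste0("chr", l)
    host <- genes[genes$chrom == ch & genes$type == "baseline", ]
    n_intronic <- min(floor(cfg$n_lineage_daps / 2), nrow(host))
    hosts <- host[rep(seq_len(nrow(host)), length.out = n_intronic), ]
    intronic_summit <- ifelse(hosts$strand == "+", hosts$tss + 5000L,
                              hosts$tss - 5000L)
    n_intergenic <- cfg$n_lineage_daps - n_intronic
    max_slot <- max(genes$slot[genes$chrom == ch]) + genome$spare_slots
    free_slots <- seq(max(genes$slot[genes$chrom == ch]) + 1L,
                      length.out = n_intergenic)
    free_slots <- ((free_slots - 1L) %% max_slot) + 1L
    inter_summit <- (free_slots - 1L) * SLOT + 20000L
    pk[[paste0("dap_", l)]] <- rbind(
      mk(ch, intronic_summit, "dap", l),
      mk(ch, inter_summit, "dap", l))
  }

  # shared distal CREs near module genes (active in all lineages)
  mod_ids <- rownames(module_rows)
  sc_genes <- module_rows[rep(seq_len(nrow(module_rows)),
                              length.out = cfg$n_shared_cres), ]
  pk$shared_cre <- mk(sc_genes$chrom, sc_genes$tss + 60000L, "shared_cre",
                      "shared", sc_genes$gene_id)

  # lineage-specific link CREs near module genes
  per_lin <- ceiling(cfg$n_planted_links / length(lineages))
  for (i in seq_along(lineages)) {
    l <- lineages[i]
    n_l <- min(per_lin, cfg$n_planted_links - per_lin * (i - 1L))
    if (n_l <= 0) next
    lg <- module_rows[rep(seq_len(nrow(module_rows)), length.out = n_l), ]
    pk[[paste0("cre_", l)]] <- mk(lg$chrom, lg$tss - 40000L - i * 15000L,
                                  "link_cre", l, lg$gene_id)
  }

  # progenitor-state distal peaks, closing along pseudotime in all lineages
  if (cfg$n_pc_daps > 0) {
    per_chr <- ceiling(cfg$n_pc_daps / length(genome$chrom_sizes))
    pcd <- list()
    for (ch in names(genome$chrom_sizes)) {
      first_free <- max(genes$slot[genes$chrom == ch]) + 1L
      slots <- seq(first_free + 150L, length.out = per_chr)
      pcd[[ch]] <- mk(ch, (slots - 1L) * SLOT + 40000L, "pc_dap", "shared")
    }
    pk$pc_dap <- head(do.call(rbind, pcd), cfg$n_pc_daps)
  }

  used <- sum(vapply(pk, nrow, 1L))
  n_bg <- cfg$n_peaks - used
  if (n_bg < 0) stop("n_peaks too small for the planted peak classes")
  # background peaks: half in gene bodies (intronic), half in gene-free
  # slots, spread across chromosomes, so the consensus set has a realistic
  # category mix
  n_bg_intronic <- n_bg %/% 2
  host <- genes[genes$type == "baseline" & genes$chrom == "chrS", ]
  if (nrow(host) == 0) stop("no baseline host genes for intronic peaks")
  hosts <- host[rep(seq_len(nrow(host)), length.out = n_bg_intronic), ]
  body_off <- 3000L + 1500L * (seq_len(n_bg_intronic) %/% nrow(host))
  pk$bg_intronic <- mk(hosts$chrom,
                       ifelse(hosts$strand == "+", hosts$tss + body_off,
                              hosts$tss - body_off),
                       "background", "shared")
  bg <- list()
  per_chr <- ceiling((n_bg - n_bg_intronic) / length(genome$chrom_sizes))
  for (ch in names(genome$chrom_sizes)) {
    first_free <- max(genes$slot[genes$chrom == ch]) + 1L
    slots <- seq(first_free + 60L, length.out = per_chr)
    bg[[ch]] <- mk(ch, (slots - 1L) * SLOT + 30000L, "background", "shared")
  }
  pk$bg <- head(do.call(rbind, bg), n_bg - n_bg_intronic)

  peaks <- do.call(rbind, pk)
  peaks$start <- peaks$summit - half
  peaks$end <- peaks$summit + half + 1L
  peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  peaks$score <- round(runif(nrow(peaks), 2, 300), 3)
  peaks$gc <- 0.3 + 0.4 * rbeta(nrow(peaks), 5, 5)
  rownames(peaks) <- peaks$peak_id
  peaks[, c("peak_id", "chrom", "start", "end", "summit", "score", "origin",
            "role", "gene", "gc")]
}

# ---- PWM helpers ---------------------------------------------------------
rand_pwm_core <- function(len) {
  mat <- vapply(seq_len(len), function(j) {
    p <- rep(0.05, 4)
    p[sample.int(4, 1)] <- 0.85
    p / sum(p)
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  mat
}

uniform_cols <- function(n) {
  if (n == 0) return(matrix(numeric(0), 4, 0, dimnames = list(c("A", "C", "G", "T"), NULL)))
  jitter <- matrix(runif(4 * n, 0.22, 0.28), 4, n)
  m <- sweep(jitter, 2, colSums(jitter), "/")
  rownames(m) <- c("A", "C", "G", "T")
  m
}

new_pwm <- function(mat, name, p = NA_real_, cluster = NA_character_,
                    lineage = NA_character_, mesenchymal = NA, tf = NA_character_) {
  structure(list(mat = mat, name = name, p = p,
                 context = list(cluster = cluster, lineage = lineage,
                                mesenchymal = mesenchymal),
                 tf = tf),
            class = "pwm")
}

sim_pwms <- function(cfg, genome, peaks, truth_env) {
  lineages <- genome$lineages
  genes <- genome$genes
  tf_genes <- rownames(genes)[genes$type == "tf"]
  stf_genes <- rownames(genes)[genes$type == "shared_tf"]
  core_len <- pmin(pmax(cfg$motif_lengths[1],
                        sample(seq(cfg$motif_lengths[1],
                                   min(14L, cfg$motif_lengths[2])),
                               length(tf_genes) + length(stf_genes),
                               replace = TRUE)),
                   cfg$motif_lengths[2])
  all_tfs <- c(tf_genes, stf_genes)
  cores <- lapply(seq_along(all_tfs), function(i) rand_pwm_core(core_len[i]))
  names(cores) <- all_tfs

  reference <- lapply(all_tfs, function(tf) {
    new_pwm(cores[[tf]], paste0("REF_", tf), tf = tf)
  })
  names(reference) <- vapply(reference, `[[`, "", "name")

  denovo <- list()
  motif_truth <- list()
  # lineage TFs: one de-novo-like motif, discovered in that lineage's
  # mesenchyme; hits planted in that lineage's distal DAPs and link CREs
  for (tf in tf_genes) {
    l <- genes[tf, "lineage"]
    mat <- cbind(uniform_cols(sample(0:2, 1)), cores[[tf]],
                 uniform_cols(sample(0:2, 1)))
    nm <- paste0("DN_", tf)
    denovo[[nm]] <- new_pwm(mat, nm, p = 10^-runif(1, 12, 40), cluster = "EC",
                            lineage = l, mesenchymal = TRUE, tf = NA_character_)
    cand <- peaks$peak_id[peaks$origin == l &
                            peaks$role %in% c("dap", "link_cre")]
    hit <- cand[runif(length(cand)) < 0.6]
    bgp <- peaks$peak_id[!(peaks$peak_id %in% cand)]
    hit <- c(hit, bgp[runif(length(bgp)) < 0.02])
    motif_truth[[nm]] <- hit
  }
  # convergent TFs: discovered in the mesenchyme of every lineage with
  # lineage-specific heterodimeric 5' extensions, and in one non-mesenchymal
  # population per lineage as an exact copy of the core
  for (tf in stf_genes) {
    shared_cand <- peaks$peak_id[peaks$role %in% c("shared_cre", "promoter") &
                                   !is.na(peaks$gene) &
                                   peaks$gene %in% rownames(genes)[genes$type %in% c("module_a", "module_b")]]
    for (l in lineages) {
      ext <- rand_pwm_core(sample(3:5, 1))
      mat <- cbind(uniform_cols(1), ext, cores[[tf]], uniform_cols(1))
      nm <- paste0("DN_", tf, "_", l, "_mes")
      denovo[[nm]] <- new_pwm(mat, nm, p = 10^-runif(1, 12, 40),
                              cluster = "EC", lineage = l, mesenchymal = TRUE,
                              tf = NA_character_)
      motif_truth[[nm]] <- shared_cand[runif(length(shared_cand)) < 0.6]
      nm2 <- paste0("DN_", tf, "_", l, "_non")
      mat2 <- cbind(uniform_cols(1), cores[[tf]], uniform_cols(1))
      denovo[[nm2]] <- new_pwm(mat2, nm2, p = 10^-runif(1, 12, 40),
                               cluster = "skin", lineage = l,
                               mesenchymal = FALSE, tf = NA_character_)
      motif_truth[[nm2]] <- shared_cand[runif(length(shared_cand)) < 0.6]
    }
  }
  truth_env$motif_truth <- motif_truth
  list(denovo = denovo, reference = reference)
}

#' Simulate a three-lineage synthetic multi-omic cohort
#'
#' Draws RNA counts (negative binomial) and ATAC counts (Poisson) for
#' `n_lineages x cells_per_lineage` cells with planted structure: a shared
#' chondrogenic gene module rising sigmoidally along pseudotime in every
#' lineage, lineage-restricted TF waves peaking earlier, shared
#' promoter-proximal peaks versus lineage-specific distal peaks, planted
#' peak-to-gene links, motif occurrence sets and a conservation track that is
#' elevated on shared elements. All draws derive from `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `synthetic_cohort` with elements `rna`, `atac`
#'   (sparse counts with `cells` metadata data frames), `fragments`
#'   (data.table or NULL), `genome`, `peaks`, `pwms`, `conservation` and
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    genome <- sim_genome(cfg)
    peaks <- sim_peaks(cfg, genome)
    genes <- genome$genes
    lineages <- genome$lineages
    n_cells <- cfg$n_lineages * cfg$cells_per_lineage

    # ---- cells ----
    lineage <- rep(lineages, each = cfg$cells_per_lineage)
    t_true <- runif(n_cells)
    # stages are collection batches whose developmental states overlap:
    # later stages are enriched for, but not defined by, later pseudotimes
    stage <- ifelse(runif(n_cells) < 0.3 + 0.4 * t_true, "S2", "S1")
    cluster <- ifelse(t_true >= 0.75, "EC", ifelse(t_true <= 0.25, "PC", "other"))
    depth_rna <- exp(rnorm(n_cells, cfg$depth_lognormal_params[1],
                           cfg$depth_lognormal_params[2]))
    depth_atac <- exp(rnorm(n_cells, cfg$depth_lognormal_params[1],
                            cfg$depth_lognormal_params[2]))
    rna_ids <- sprintf("RNA_%s_%04d", lineage, sequence(rep(cfg$cells_per_lineage, cfg$n_lineages)))
    atac_ids <- sub("^RNA", "ATAC", rna_ids)

    rna_cells <- data.frame(cell_id = rna_ids, lineage = lineage,
                            stage = stage, cluster = cluster,
                            pseudotime = t_true, row.names = rna_ids,
                            stringsAsFactors = FALSE)
    atac_cells <- data.frame(cell_id = atac_ids, lineage = lineage,
                             stage = stage, cluster = cluster,
                             pseudotime = t_true, row.names = atac_ids,
                             stringsAsFactors = FALSE)

    # ---- RNA counts ----
    amp_u <- runif(nrow(genes), 0.6, 1.4)
    amp <- cfg$effect_size_logfc * amp_u
    # planted-up genes rest at low expression; progenitor genes are highly
    # expressed and decline, roughly balancing library composition along t
    base_log <- rnorm(nrow(genes), log(0.8), 1.0)
    up_types <- c("module_a", "module_b", "shared_tf", "tf")
    base_log[genes$type %in% up_types] <- rnorm(sum(genes$type %in% up_types),
                                                log(0.1), 0.5)
    base_log[genes$type == "pc"] <- rnorm(sum(genes$type == "pc"), log(2), 0.5)
    base_log[genes$type == "mito"] <- log(3)
    sig <- sigmoid_rise(t_true, cfg$chondro_midpoint)
    bump <- gauss_bump(t_true, cfg$tf_bump_center)
    eff <- matrix(0, nrow(genes), n_cells,
                  dimnames = list(rownames(genes), rna_ids))
    shared_up <- genes$type %in% c("module_a", "module_b", "shared_tf")
    eff[shared_up, ] <- outer(amp[shared_up], sig)
    pc_rows <- genes$type == "pc"
    eff[pc_rows, ] <- outer(-amp[pc_rows], sig)
    for (l in lineages) {
      tf_rows <- which(genes$type == "tf" & genes$lineage == l)
      own <- lineage == l
      eff[tf_rows, own] <- outer(amp[tf_rows],
                                 0.33 + gauss_bump(t_true[own], cfg$tf_bump_center))
    }
    mu <- exp(sweep(eff, 1, base_log, "+"))
    mu <- sweep(mu, 2, depth_rna, "*")
    rna_counts <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu),
                         nrow(mu), ncol(mu), dimnames = dimnames(mu))
    rna <- as(Matrix(rna_counts, sparse = TRUE), "CsparseMatrix")

    # ---- ATAC counts ----
    acc_amp <- cfg$effect_size_logfc * runif(nrow(peaks), 0.6, 1.4)
    base_acc <- rnorm(nrow(peaks), log(0.8), 0.6)
    shared_open <- peaks$role == "shared_cre" |
      (peaks$role == "promoter" & !is.na(peaks$gene) &
         genes[peaks$gene, "type"] %in% c("module_a", "module_b", "shared_tf"))
    tf_prom <- peaks$role == "promoter" & !is.na(peaks$gene) &
      genes[peaks$gene, "type"] == "tf"
    # peaks that open along t rest nearly closed; progenitor-state peaks
    # rest open and close, balancing per-cell accessible mass
    opening <- shared_open | tf_prom | peaks$role %in% c("dap", "link_cre")
    base_acc[opening] <- rnorm(sum(opening), log(0.12), 0.5)
    closing <- peaks$role == "pc_dap" |
      (peaks$role == "promoter" & !is.na(peaks$gene) &
         genes[peaks$gene, "type"] == "pc")
    base_acc[peaks$role == "pc_dap"] <- rnorm(sum(peaks$role == "pc_dap"),
                                              log(1.6), 0.4)
    aeff <- matrix(0, nrow(peaks), n_cells,
                   dimnames = list(peaks$peak_id, atac_ids))
    aeff[shared_open, ] <- outer(acc_amp[shared_open], sig)
    aeff[closing, ] <- outer(-acc_amp[closing], sig)
    for (l in lineages) {
      own <- lineage == l
      lin_rows <- which(peaks$origin == l & peaks$role %in% c("dap", "link_cre"))
      aeff[lin_rows, own] <- outer(acc_amp[lin_rows], sigmoid_rise(t_true[own], cfg$chondro_midpoint))
      tp <- which(tf_prom & genes[peaks$gene, "lineage"] == l)
      if (length(tp)) {
        aeff[tp, own] <- outer(0.5 * acc_amp[tp],
                               gauss_bump(t_true[own], cfg$tf_bump_center))
      }
    }
    arate <- exp(sweep(aeff, 1, base_acc, "+"))
    arate <- sweep(arate, 2, cfg$atac_depth * depth_atac, "*")
    atac_counts <- matrix(rpois(length(arate), arate), nrow(arate), ncol(arate),
                          dimnames = dimnames(arate))
    atac <- as(Matrix(atac_counts, sparse = TRUE), "CsparseMatrix")

    # ---- fragments ----
    fragments <- NULL
    if (cfg$include_fragments) {
      fragments <- sim_fragments(atac, peaks, genome)
    }

    # ---- conservation track ----
    conservation <- sim_conservation(cfg, peaks)

    # ---- truth + pwms ----
    truth_env <- new.env()
    pwms <- sim_pwms(cfg, genome, peaks, truth_env)
    module_genes <- list(
      A = rownames(genes)[genes$type == "module_a"],
      B = rownames(genes)[genes$type == "module_b"])
    lineage_tfs <- lapply(setNames(lineages, lineages), function(l) {
      rownames(genes)[genes$type == "tf" & genes$lineage == l]
    })
    lineage_daps <- lapply(setNames(lineages, lineages), function(l) {
      peaks$peak_id[peaks$origin == l & peaks$role == "dap"]
    })
    # every co-driven peak-gene pair within the candidate window is ground
    # truth: distal CREs plus the promoters of module, shared-TF and
    # lineage-TF genes (whose accessibility tracks their gene's expression)
    linked <- peaks[peaks$role %in% c("link_cre", "shared_cre") |
                      (peaks$role == "promoter" & !is.na(peaks$gene) &
                         genes[peaks$gene, "type"] %in%
                           c("module_a", "module_b", "shared_tf", "tf", "pc")), ]
    planted_links <- data.frame(peak_id = linked$peak_id, gene_id = linked$gene,
                                lineage = ifelse(linked$origin == "shared", "all",
                                                 linked$origin),
                                role = linked$role, stringsAsFactors = FALSE)
    truth <- list(module_genes = module_genes,
                  lineage_tfs = lineage_tfs,
                  shared_tfs = rownames(genes)[genes$type == "shared_tf"],
                  mito_genes = rownames(genes)[genes$type == "mito"],
                  lineage_daps = lineage_daps,
                  planted_links = planted_links,
                  true_pseudotime = setNames(t_true, rna_ids),
                  cell_labels = rna_cells[, c("lineage", "stage", "cluster")],
                  motif_truth = truth_env$motif_truth,
                  paired_cells = if (cfg$paired) setNames(rna_ids, atac_ids) else NULL,
                  null = FALSE)

    structure(list(rna = list(counts = rna, cells = rna_cells),
                   atac = list(counts = atac, cells = atac_cells),
                   fragments = fragments,
                   genome = list(genes = genes[, c("gene_id", "chrom", "strand",
                                                   "tss", "start", "end", "type",
                                                   "lineage")],
                                 chrom_sizes = genome$chrom_sizes,
                                 lineages = lineages),
                   peaks = peaks,
                   pwms = pwms,
                   conservation = conservation,
                   truth = truth,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

# expand ATAC peak counts into a fragments table with a bimodal
# (nucleosome-free / mono-nucleosome) length mixture, plus off-peak
# background fragments (~20% of in-peak totals)
sim_fragments <- function(atac, peaks, genome) {
  trip <- Matrix::summary(atac)
  n_frag <- sum(trip$x)
  pk_i <- rep.int(trip$i, trip$x)
  cell_j <- rep.int(trip$j, trip$x)
  lens <- frag_lengths(n_frag)
  width <- peaks$end[1] - peaks$start[1]
  offset <- floor(runif(n_frag) * pmax(1, width - lens))
  start <- peaks$start[pk_i] + offset
  frag <- data.table::data.table(
    chrom = peaks$chrom[pk_i], start = start, end = start + lens,
    barcode = colnames(atac)[cell_j], count = 1L)

  # background fragments scattered over the genome
  cell_tot <- Matrix::colSums(atac)
  n_bg <- rpois(length(cell_tot), 0.25 * cell_tot)
  tot_bg <- sum(n_bg)
  if (tot_bg > 0) {
    sizes <- genome$chrom_sizes
    ch <- sample(names(sizes), tot_bg, replace = TRUE,
                 prob = sizes / sum(sizes))
    lens_bg <- frag_lengths(tot_bg)
    start_bg <- floor(runif(tot_bg) * (sizes[ch] - lens_bg - 1))
    bg <- data.table::data.table(
      chrom = ch, start = as.integer(start_bg),
      end = as.integer(start_bg + lens_bg),
      barcode = rep.int(colnames(atac), n_bg), count = 1L)
    frag <- rbind(frag, bg)
  }
  data.table::setorder(frag, chrom, start)
  frag[]
}

frag_lengths <- function(n) {
  nf <- runif(n) < 0.65
  len <- integer(n)
  len[nf] <- pmin(pmax(round(rnorm(sum(nf), 90, 20)), 50L), 140L)
  len[!nf] <- pmin(pmax(round(rnorm(sum(!nf), 210, 25)), 160L), 280L)
  len
}

# piecewise-constant (10-bp block) conservation track over the peak set;
# shared elements drawn around shared_mean, everything else around
# specific_mean
sim_conservation <- function(cfg, peaks) {
  lv <- cfg$conservation_levels
  shared <- peaks$role %in% c("shared_cre") |
    (peaks$role == "promoter" & !is.na(peaks$gene) & grepl("^MOD", peaks$gene))
  block <- 10L
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    edges <- seq(peaks$start[i], peaks$end[i], by = block)
    if (edges[length(edges)] < peaks$end[i]) edges <- c(edges, peaks$end[i])
    n_b <- length(edges) - 1L
    m <- if (shared[i]) lv[["shared_mean"]] else lv[["specific_mean"]]
    sc <- pmin(pmax(rnorm(n_b, m, lv[["noise_sd"]]), 0.001), 0.999)
    out[[i]] <- data.frame(chrom = peaks$chrom[i], start = edges[-length(edges)],
                           end = edges[-1L], score = round(sc, 4))
  }
  do.call(rbind, out)
}

#' Remove all planted structure from a cohort
#'
#' Returns a cohort with identical count marginals whose cell labels
#' (pseudotime, stage, cluster) have been permuted within lineage x
#' depth-tertile strata, breaking every association between labels and
#' counts. Used as a type-I-error harness for the marker tests.
#'
#' @param cohort a `synthetic_cohort`.
#' @param seed permutation seed (defaults to the cohort's seed + 1).
#' @return a `synthetic_cohort` whose `truth` records no planted effects.
#' @export
null_cohort <- function(cohort, seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cells <- cohort$rna$cells
  depth <- Matrix::colSums(cohort$rna$counts)
  with_seed(seed, {
    perm <- seq_len(nrow(cells))
    for (l in unique(cells$lineage)) {
      idx <- which(cells$lineage == l)
      tert <- cut(rank(depth[idx], ties.method = "first"), 3, labels = FALSE)
      for (k in 1:3) {
        s <- idx[tert == k]
        perm[s] <- s[sample.int(length(s))]
      }
    }
    lab_cols <- c("stage", "cluster", "pseudotime")
    cells[, lab_cols] <- cells[perm, lab_cols]
    out <- cohort
    out$rna$cells <- cells
    if (!is.null(cohort$truth$paired_cells)) {
      rna_of_atac <- cohort$truth$paired_cells
      out$atac$cells[, lab_cols] <- cells[rna_of_atac, lab_cols]
    }
    out$truth$module_genes <- list(A = character(0), B = character(0))
    out$truth$lineage_tfs <- lapply(out$truth$lineage_tfs, function(x) character(0))
    out$truth$lineage_daps <- lapply(out$truth$lineage_daps, function(x) character(0))
    out$truth$planted_links <- out$truth$planted_links[0, ]
    out$truth$true_pseudotime <- setNames(cells$pseudotime, rownames(cells))
    out$truth$cell_labels <- cells[, c("lineage", "stage", "cluster")]
    out$truth$null <- TRUE
    out
  })
}
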