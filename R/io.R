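#' Write a cohort as a bundle of standard-format fixture files
#'
#' Emits Matrix Market count matrices with barcode/feature TSVs, a BED6+3
#' peak file, a fragments TSV, JASPAR-style PFM files (plus a metadata
#' TSV), a bedGraph conservation track, the gene table, cell metadata, the
#' ground truth as JSON and the generator configuration as YAML. The bundle
#' round-trips losslessly through [read_bundle()] on all count matrices.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_modality <- function(mod, name) {
    d <- file.path(directory, name)
    dir.create(d, showWarnings = FALSE)
    Matrix::writeMM(mod$counts, file.path(d, "matrix.mtx"))
    writeLines(colnames(mod$counts), file.path(d, "barcodes.tsv"))
    writeLines(rownames(mod$counts), file.path(d, "features.tsv"))
    write.table(mod$cells, file.path(d, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_modality(cohort$rna, "rna")
  write_modality(cohort$atac, "atac")

  pk <- cohort$peaks
  bed <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                    name = pk$peak_id, score = round(pk$score * 10),
                    strand = ".", summit_offset = pk$summit - pk$start,
                    origin = pk$origin, role = pk$role)
  write.table(bed, file.path(directory, "peaks.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(pk[, c("peak_id", "score", "gene", "gc")],
              file.path(directory, "peaks_attrs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(cohort$fragments)) {
    data.table::fwrite(cohort$fragments, file.path(directory, "fragments.tsv"),
                       sep = "\t", col.names = FALSE)
  }
  write_pfm(cohort$pwms$denovo, file.path(directory, "pwms_denovo.pfm"))
  write_pfm(cohort$pwms$reference, file.path(directory, "pwms_reference.pfm"))
  meta <- do.call(rbind, lapply(c(cohort$pwms$denovo, cohort$pwms$reference),
                                function(p) {
    data.frame(name = p$name, p = p$p, cluster = p$context$cluster %||% NA,
               lineage = p$context$lineage %||% NA,
               mesenchymal = p$context$mesenchymal %||% NA,
               tf = p$tf %||% NA,
               set = if (p$name %in% names(cohort$pwms$denovo)) "denovo" else "reference",
               stringsAsFactors = FALSE)
  }))
  write.table(meta, file.path(directory, "pwms_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  write.table(cohort$conservation, file.path(directory, "conservation.bedGraph"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cohort$genome$genes, file.path(directory, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(cohort$genome$chrom_sizes),
                         size = as.integer(cohort$genome$chrom_sizes)),
              file.path(directory, "chrom_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_pseudotime <- as.list(truth$true_pseudotime)
  truth$paired_cells <- as.list(truth$paired_cells)
  truth$cell_labels <- cbind(cell_id = rownames(cohort$truth$cell_labels),
                             cohort$truth$cell_labels)
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(unclass(cohort$config), file.path(directory, "config.yaml"))
  invisible(directory)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# JASPAR-style PFM writer: probabilities scaled to counts of 1e6
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    counts <- round(p$mat * 1e6)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b, paste(counts[b, ], collapse = " ")), con)
    }
  }
}

#' Read JASPAR-style PFM files into column-normalised PWMs
#'
#' @param path PFM file path.
#' @param meta optional metadata data.frame (from a bundle's
#'   `pwms_meta.tsv`).
#' @return named list of `pwm` objects with columns summing to 1.
#' @export
read_pfm <- function(path, meta = NULL) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  out <- list()
  for (s in starts) {
    name <- sub("^>\\s*", "", lines[s])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    vals <- lapply(rows, function(r) {
      body <- gsub("^[ACGT]\\s*\\[\\s*|\\s*\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(body), "\\s+")[[1]])
    })
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    m <- sweep(m, 2, colSums(m), "/")
    info <- if (!is.null(meta)) meta[meta$name == name, , drop = FALSE] else NULL
    out[[name]] <- new_pwm(m, name,
                           p = if (!is.null(info) && nrow(info)) info$p else NA_real_,
                           cluster = if (!is.null(info) && nrow(info)) info$cluster else NA_character_,
                           lineage = if (!is.null(info) && nrow(info)) info$lineage else NA_character_,
                           mesenchymal = if (!is.null(info) && nrow(info)) info$mesenchymal else NA,
                           tf = if (!is.null(info) && nrow(info)) info$tf else NA_character_)
  }
  out
}

#' Read a fixture bundle back into a cohort-shaped dataset
#'
#' Validates intervals (0-based half-open, start < end, within chromosome
#' bounds) and matrix dimensions; malformed BED records are reported with
#' their line numbers.
#'
#' @param directory a directory written by [write_fixtures()].
#' @return a list shaped like a `synthetic_cohort`.
#' @export
read_bundle <- function(directory) {
  read_modality <- function(name) {
    d <- file.path(directory, name)
    counts <- as(Matrix::readMM(file.path(d, "matrix.mtx")), "CsparseMatrix")
    barcodes <- readLines(file.path(d, "barcodes.tsv"))
    features <- readLines(file.path(d, "features.tsv"))
    if (length(barcodes) != ncol(counts) || length(features) != nrow(counts)) {
      stop("dimension mismatch in ", d)
    }
    dimnames(counts) <- list(features, barcodes)
    cells <- read.table(file.path(d, "cells.tsv"), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    rownames(cells) <- cells$cell_id
    list(counts = counts, cells = cells)
  }
  rna <- read_modality("rna")
  atac <- read_modality("atac")

  chrom_sizes_df <- read.table(file.path(directory, "chrom_sizes.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  chrom_sizes <- setNames(chrom_sizes_df$size, chrom_sizes_df$chrom)
  bed <- read.table(file.path(directory, "peaks.bed"), sep = "\t",
                    stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score10", "strand",
                  "summit_offset", "origin", "role")
  bad <- which(bed$start >= bed$end | bed$start < 0 |
                 bed$end > chrom_sizes[bed$chrom])
  if (length(bad)) {
    stop("malformed BED record(s) at line(s): ", paste(bad, collapse = ", "))
  }
  attrs <- read.table(file.path(directory, "peaks_attrs.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = bed$name, chrom = bed$chrom, start = bed$start,
                      end = bed$end, summit = bed$start + bed$summit_offset,
                      score = attrs$score[match(bed$name, attrs$peak_id)],
                      origin = bed$origin, role = bed$role,
                      gene = attrs$gene[match(bed$name, attrs$peak_id)],
                      gc = attrs$gc[match(bed$name, attrs$peak_id)],
                      stringsAsFactors = FALSE)
  rownames(peaks) <- peaks$peak_id

  frag_path <- file.path(directory, "fragments.tsv")
  fragments <- if (file.exists(frag_path)) {
    fr <- data.table::fread(frag_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "barcode",
                                          "count"))
    fr
  } else NULL

  meta <- read.table(file.path(directory, "pwms_meta.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  pwms <- list(denovo = read_pfm(file.path(directory, "pwms_denovo.pfm"), meta),
               reference = read_pfm(file.path(directory, "pwms_reference.pfm"), meta))

  conservation <- read.table(file.path(directory, "conservation.bedGraph"),
                             sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "score"))
  genes <- read.table(file.path(directory, "genes.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  truth$true_pseudotime <- unlist(truth$true_pseudotime)
  if (!is.null(truth$paired_cells)) truth$paired_cells <- unlist(truth$paired_cells)
  cl <- truth$cell_labels
  truth$cell_labels <- data.frame(cl[, c("lineage", "stage", "cluster")],
                                  row.names = cl$cell_id)
  config <- yaml::read_yaml(file.path(directory, "config.yaml"))
  structure(list(rna = rna, atac = atac, fragments = fragments,
                 genome = list(genes = genes, chrom_sizes = chrom_sizes,
                               lineages = sort(unique(genes$lineage[!is.na(genes$lineage)]))),
                 peaks = peaks, pwms = pwms, conservation = conservation,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}
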