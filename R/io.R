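#' Write a cohort to disk as plain-text fixtures
#'
#' Emits the standard file layout consumed by the readers: one tracking TSV
#' per mouse, the UMI matrix in MatrixMarket coordinate format with
#' `genes.tsv` / `barcodes.tsv`, a bridge TSV, mouse metadata, the
#' ground-truth tables and the generator configuration as YAML.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character()
  for (mid in cohort$meta$mouse_id) {
    files <- c(files, tsv(cohort$tracking[cohort$tracking$mouse_id == mid, ],
                          sprintf("tracking_%s.tsv", mid)))
  }
  files <- c(files, tsv(cohort$meta, "mouse_meta.tsv"))
  mtx <- file.path(out_dir, "matrix.mtx")
  Matrix::writeMM(cohort$counts, mtx)
  files <- c(files, mtx)
  writeLines(cohort$genes, file.path(out_dir, "genes.tsv"))
  writeLines(cohort$cell_barcodes, file.path(out_dir, "barcodes.tsv"))
  files <- c(files, file.path(out_dir, c("genes.tsv", "barcodes.tsv")))
  files <- c(files, tsv(cohort$bridges, "bridges.tsv"))
  files <- c(files, tsv(cohort$truth$cells, "ground_truth_cells.tsv"))
  files <- c(files, tsv(cohort$truth$genes, "ground_truth_genes.tsv"))
  files <- c(files, tsv(cohort$truth$clones, "ground_truth_clones.tsv"))
  cfg <- cohort$config
  cfg$planted_genes <- lapply(cfg$planted_genes, unclass)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  files <- c(files, file.path(out_dir, "config.yaml"))
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the fixture files.
#' @return a `synth_cohort` object equivalent to the one written (the
#'   configuration is reconstructed from `config.yaml` when present).
#' @export
read_cohort <- function(dir) {
  tsv <- function(name, colClasses = NA) {
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = colClasses)
  }
  meta <- tsv("mouse_meta.tsv")
  tracking <- do.call(rbind, lapply(meta$mouse_id, function(mid) {
    tsv(sprintf("tracking_%s.tsv", mid))
  }))
  rownames(tracking) <- NULL
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes, barcodes)
  bridges <- tsv("bridges.tsv")
  truth <- list(
    cells = tsv("ground_truth_cells.tsv"),
    genes = tsv("ground_truth_genes.tsv",
                colClasses = c(gene = "character", pattern = "character",
                               direction = "character",
                               switch_ranks = "character",
                               effect_size = "numeric",
                               target_measure = "character")),
    clones = tsv("ground_truth_clones.tsv")
  )
  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    raw$planted_genes <- lapply(raw$planted_genes, function(p) {
      planted_gene(pattern = p$pattern, id = p$id, direction = p$direction,
                   switch_ranks = unlist(p$switch_ranks),
                   effect_size = p$effect_size,
                   target_measure = p$target_measure)
    })
    config <- structure(raw[names(formals(synth_config))],
                        class = "synth_config")
  }
  structure(list(
    tracking = tracking, meta = meta, counts = counts, genes = genes,
    cell_barcodes = barcodes, bridges = bridges, truth = truth,
    config = config
  ), class = "synth_cohort")
}

#' Write an association scan as long-format TSV
#'
#' One row per (gene, direction, threshold) with per-mouse P values, the
#' Fisher-combined P and the false-positive score, plus a per-gene summary
#' file.
#'
#' @param scan an [run_scan()] result.
#' @param out_dir output directory.
#' @return invisibly, the files written.
#' @export
write_scan <- function(scan, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character()
  if (!is.null(scan$combined_p)) {
    n_thr <- nrow(scan$thresholds)
    n_genes <- length(scan$genes)
    long <- do.call(rbind, lapply(c("high", "low"), function(dir) {
      df <- data.frame(
        gene = rep(scan$genes, each = n_thr),
        measure = scan$measure,
        direction = dir,
        threshold_rank = rep(scan$thresholds$rank, n_genes),
        threshold_value = rep(scan$thresholds$threshold_value, n_genes),
        combined_p = as.vector(scan$combined_p[[dir]]),
        fps = as.vector(scan$fps[[dir]])
      )
      for (mi in seq_along(scan$mice)) {
        df[[paste0("p_", scan$mice[mi])]] <-
          as.vector(scan$p_mouse[[dir]][, , mi])
      }
      df
    }))
    path <- file.path(out_dir, sprintf("scan_%s.tsv", scan$measure))
    utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  path <- file.path(out_dir, sprintf("scan_%s_summary.tsv", scan$measure))
  utils::write.table(scan$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, path))
}
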