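#' Validate a pipeline run configuration
#'
#' Checks a configuration (a YAML file path or a list) against the known
#' keys, applies defaults and aggregates all errors into one message.
#' Recognised keys:
#' * `input_dir` - a cohort fixture directory (mutually exclusive with
#'   `synth`);
#' * `synth` - a list of [synth_config()] arguments for an on-the-fly
#'   synthetic cohort;
#' * `measures` - nonempty subset of the five lineage-output measures;
#' * `min_group` (default 4), `n_scrambles` (default 100), `fps_cutoff`
#'   (default 0.05, in (0,1)), `seed` (default 1);
#' * `classify` - list of [classify_control()] arguments;
#' * `colocalize_window` (default 5 ranks);
#' * `out_dir` - where to write tables and the manifest.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated configuration list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("input_dir", "synth", "measures", "min_group", "n_scrambles",
             "fps_cutoff", "seed", "classify", "colocalize_window", "out_dir")
  errors <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(measures = c("hsc", "granulocyte", "b_cell", "total_blood",
                                "bias"),
                   min_group = 4, n_scrambles = 100, fps_cutoff = 0.05,
                   seed = 1, classify = list(), colocalize_window = 5,
                   out_dir = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (!length(config$measures)) {
    errors <- c(errors, "'measures' must be nonempty")
  } else {
    bad <- setdiff(config$measures, defaults$measures)
    if (length(bad)) {
      errors <- c(errors, paste0("unknown measure(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (!is.numeric(config$fps_cutoff) || config$fps_cutoff <= 0 ||
      config$fps_cutoff >= 1) {
    errors <- c(errors, "'fps_cutoff' must be in (0, 1)")
  }
  if (!is.numeric(config$min_group) || config$min_group < 0) {
    errors <- c(errors, "'min_group' must be a non-negative count")
  }
  if (!is.numeric(config$n_scrambles) || config$n_scrambles < 1) {
    errors <- c(errors, "'n_scrambles' must be a positive count")
  }
  if (!is.null(config$input_dir) && !is.null(config$synth)) {
    errors <- c(errors, "give either 'input_dir' or 'synth', not both")
  }
  if (is.null(config$input_dir) && is.null(config$synth)) {
    errors <- c(errors, "one of 'input_dir' or 'synth' is required")
  }
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir)) {
    errors <- c(errors, paste0("input_dir does not exist: ", config$input_dir))
  }
  cc <- tryCatch(do.call(classify_control, config$classify),
                 error = function(e) {
                   errors <<- c(errors, paste0("classify: ", conditionMessage(e)))
                   NULL
                 })
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  config$classify <- cc
  structure(config, class = "run_config")
}

#' Run the full association pipeline
#'
#' Orchestrates the stages end to end: load or simulate a cohort, build the
#' cell directory from the bridge records, quantify clonal lineage output,
#' QC and normalize the expression matrix, run the thresholded association
#' scan for each requested measure, classify the significant genes'
#' association curves and colocalize their peaks and transitions.  All
#' tabular artifacts (and a JSON manifest sufficient to reproduce the run)
#' are written to `out_dir` when given.
#'
#' @param config a [validate_config()]-accepted configuration (list, path or
#'   `run_config`).
#' @return object of class `assoc_report`: list with `cohort`, `directory`,
#'   `outputs`, `qc`, per-measure `scans`, `patterns` and `clusters`, and
#'   the run `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf(...))

  if (!is.null(config$synth)) {
    synth_args <- config$synth
    if (is.null(synth_args$seed)) synth_args$seed <- config$seed
    cohort <- generate_cohort(do.call(synth_config, synth_args))
  } else {
    cohort <- read_cohort(config$input_dir)
  }
  log_stage("cohort: %d cells, %d genes, %d mice",
            length(cohort$cell_barcodes), length(cohort$genes),
            nrow(cohort$meta))

  directory <- build_directory(cohort$bridges,
                               known_tracking = unique(cohort$tracking$tracking_barcode),
                               known_cells = cohort$cell_barcodes)
  log_stage("directory: %d cells mapped, %d multi-mapped discarded",
            nrow(directory$map), length(unique(directory$discarded$cell_barcode)))

  outputs <- clone_output(cohort$tracking, cohort$meta)
  log_stage("clonal output: %d/%d clones pass the global filter",
            sum(outputs$passed_global_filter), nrow(outputs))

  qc <- qc_expression(cohort$counts)
  log_stage("expression QC: %d/%d cells, %d/%d genes retained",
            sum(qc$cell_mask), length(qc$cell_mask),
            sum(qc$gene_mask), length(qc$gene_mask))

  scans <- list()
  patterns <- list()
  clusters <- list()
  for (i in seq_along(config$measures)) {
    ms <- config$measures[i]
    scan <- run_scan(qc, directory, outputs, measure = ms,
                     min_group = config$min_group,
                     n_scrambles = config$n_scrambles,
                     seed = config$seed + i,
                     fps_cutoff = config$fps_cutoff)
    log_stage("scan '%s': %d valid thresholds, %d significant genes",
              ms, nrow(scan$thresholds), sum(scan$summary$significant))
    scans[[ms]] <- scan
    if (nrow(scan$thresholds)) {
      patterns[[ms]] <- classify_patterns(scan, control = config$classify)
      clusters[[ms]] <- colocalize(patterns[[ms]], config$colocalize_window)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cloneAssoc")),
    r_version = R.version.string,
    seed = config$seed,
    measures = config$measures,
    params = config[c("min_group", "n_scrambles", "fps_cutoff",
                      "colocalize_window")],
    classify = unclass(config$classify),
    timing_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  report <- structure(list(
    cohort = cohort, directory = directory, outputs = outputs, qc = qc,
    scans = scans, patterns = patterns, clusters = clusters,
    manifest = manifest, config = config
  ), class = "assoc_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ms in names(scans)) write_scan(scans[[ms]], config$out_dir)
    for (ms in names(patterns)) {
      utils::write.table(patterns[[ms]],
                         file.path(config$out_dir, sprintf("patterns_%s.tsv", ms)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(clusters[[ms]]$peak_clusters,
                         file.path(config$out_dir, sprintf("peak_clusters_%s.tsv", ms)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.assoc_report <- function(x, ...) {
  cat("Association pipeline report\n")
  for (ms in names(x$scans)) {
    s <- x$scans[[ms]]
    cat(sprintf("  %-12s %3d thresholds, %3d significant genes",
                ms, nrow(s$thresholds), sum(s$summary$significant)))
    if (!is.null(x$patterns[[ms]]) && nrow(x$patterns[[ms]])) {
      tab <- table(x$patterns[[ms]]$class)
      cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")",
          sep = "")
    }
    cat("\n")
  }
  invisible(x)
}
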