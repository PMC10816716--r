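#' Build the cell-barcode to tracking-barcode directory
#'
#' Molecular-bridge reads pair a droplet cellular barcode with a transcribed
#' clonal tracking barcode.  This builds the validated directory used to
#' assign each single-cell transcriptome to its clone:
#' records whose barcodes are not on the known lists are dropped, pairs with
#' read support below `min_support` are dropped, and any cellular barcode
#' still linked to two or more distinct tracking barcodes is discarded (such
#' cells may come from multiple viral integrations or droplet doublets).  One
#' tracking barcode may legitimately own many cellular barcodes, because a
#' clone can contain several HSCs.
#'
#' @param records data.frame with columns `cell_barcode`, `tracking_barcode`,
#'   `read_support` (>= 1) and optionally `mouse_id`.
#' @param known_tracking character vector of valid tracking barcodes.
#' @param known_cells character vector of valid cellular barcodes.
#' @param min_support minimum summed read support for a (cell, tracking) pair
#'   (default 1, i.e. no support filter).
#' @return object of class `cell_directory`: list with `map` (data.frame
#'   `cell_barcode`, `tracking_barcode`, and `mouse_id` if supplied),
#'   `discarded` (multi-mapped cells with their candidate barcodes) and
#'   `min_support`.
#' @export
build_directory <- function(records, known_tracking, known_cells,
                            min_support = 1) {
  if (!length(known_tracking) || !length(known_cells)) {
    stop("known barcode lists must be nonempty")
  }
  empty <- function() {
    structure(list(
      map = data.frame(cell_barcode = character(), tracking_barcode = character(),
                       stringsAsFactors = FALSE),
      discarded = data.frame(cell_barcode = character(), tracking_barcode = character(),
                             stringsAsFactors = FALSE),
      min_support = min_support
    ), class = "cell_directory")
  }
  if (!nrow(records)) {
    warning("no bridge records; returning empty directory")
    return(empty())
  }
  if (any(records$read_support < 1)) stop("read_support must be >= 1")
  rec <- records[records$cell_barcode %in% known_cells &
                   records$tracking_barcode %in% known_tracking, , drop = FALSE]
  if (!nrow(rec)) {
    warning("no bridge records overlap the known barcode lists")
    return(empty())
  }
  has_mouse <- "mouse_id" %in% names(rec)
  key <- paste(rec$cell_barcode, rec$tracking_barcode, sep = "\r")
  support <- tapply(rec$read_support, key, sum)
  first <- rec[!duplicated(key), , drop = FALSE]
  first$read_support <- as.numeric(support[paste(first$cell_barcode,
                                                 first$tracking_barcode, sep = "\r")])
  first <- first[first$read_support >= min_support, , drop = FALSE]
  # multi-map discard happens after the support filter
  n_tbc <- tapply(first$tracking_barcode, first$cell_barcode,
                  function(z) length(unique(z)))
  multi <- names(n_tbc)[n_tbc >= 2]
  discarded <- first[first$cell_barcode %in% multi, , drop = FALSE]
  kept <- first[!(first$cell_barcode %in% multi), , drop = FALSE]
  cols <- c("cell_barcode", "tracking_barcode", if (has_mouse) "mouse_id")
  map <- kept[order(kept$cell_barcode), cols, drop = FALSE]
  rownames(map) <- NULL
  stopifnot(!anyDuplicated(map$cell_barcode))
  structure(list(
    map = map,
    discarded = discarded[, c(cols, "read_support"), drop = FALSE],
    min_support = min_support
  ), class = "cell_directory")
}

#' Summary statistics of a cell directory
#'
#' @param directory a [build_directory()] result.
#' @param all_cells character vector of all cellular barcodes considered.
#' @param all_tracking character vector of all known tracking barcodes.
#' @return data.frame with one row: number and fraction of cells mapped,
#'   fraction of bridge-linked cells that were multi-mapped, and number of
#'   clones (tracking barcodes) with at least one mapped cell.
#' @export
directory_stats <- function(directory, all_cells, all_tracking) {
  n_cells <- length(all_cells)
  n_mapped <- nrow(directory$map)
  n_multi <- length(unique(directory$discarded$cell_barcode))
  n_linked <- n_mapped + n_multi
  data.frame(
    n_cells = n_cells,
    n_mapped = n_mapped,
    mapped_fraction = if (n_cells) n_mapped / n_cells else 0,
    n_multimapped = n_multi,
    multimap_fraction = if (n_linked) n_multi / n_linked else 0,
    n_clones_mapped = length(unique(directory$map$tracking_barcode)),
    n_clones_known = length(all_tracking)
  )
}

#' @export
print.cell_directory <- function(x, ...) {
  cat("Cell-barcode to tracking-barcode directory\n")
  cat(sprintf("  %d cells mapped to %d clones; %d multi-mapped cells discarded\n",
              nrow(x$map), length(unique(x$map$tracking_barcode)),
              length(unique(x$discarded$cell_barcode))))
  invisible(x)
}
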