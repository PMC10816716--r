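#' Clonal abundance in the blood (%WBC)
#'
#' Converts barcode read counts from one sorted blood population of one mouse
#' into clonal abundances expressed as percent of all white blood cells
#' (%WBC).  The read fraction of a barcode is scaled by the population's share
#' of white blood cells, the donor chimerism and the GFP+ (barcoded) fraction
#' among donor cells, so that abundances are comparable between mice:
#'
#' \deqn{\%WBC = (pop\ \%WBC) \times (donor\ frac) \times (GFP\ frac) \times
#'   reads / total\ reads}
#'
#' @param reads named numeric vector of read counts per tracking barcode
#'   (zeros allowed, total must be positive).
#' @param pop_pct_wbc percent of white blood cells made up by this population
#'   (0-100).
#' @param donor_pct donor chimerism percent (0-100).
#' @param gfp_pct GFP+ percent among donor cells (0-100).
#' @return named numeric vector of clonal abundances in %WBC; sums to
#'   `pop_pct_wbc * donor_pct/100 * gfp_pct/100`.
#' @seealso [clonal_abundance_hsc()], [lineage_bias()]
#' @export
clonal_abundance_blood <- function(reads, pop_pct_wbc, donor_pct, gfp_pct) {
  .check_pct(pop_pct_wbc, "pop_pct_wbc")
  .check_pct(donor_pct, "donor_pct")
  .check_pct(gfp_pct, "gfp_pct")
  if (any(reads < 0)) stop("read counts must be non-negative")
  total <- sum(reads)
  if (total <= 0) {
    stop("total reads are zero for this population; clonal abundance is undefined")
  }
  pop_pct_wbc * (donor_pct / 100) * (gfp_pct / 100) * reads / total
}

#' Clonal abundance of HSCs (% barcoded HSCs)
#'
#' A clone's share of all barcoded HSCs recovered from the bone marrow,
#' in percent: `100 * reads / total reads`.  Sums to 100 per mouse.
#'
#' @inheritParams clonal_abundance_blood
#' @return named numeric vector summing to 100.
#' @export
clonal_abundance_hsc <- function(reads) {
  if (any(reads < 0)) stop("read counts must be non-negative")
  total <- sum(reads)
  if (total <= 0) stop("total HSC reads are zero; clonal abundance is undefined")
  100 * reads / total
}

#' Lineage bias of a clone
#'
#' Dimensionless bias between B cell (lymphoid) and granulocyte (myeloid)
#' output, in \[-1, 1\].  Clonal abundances are first normalized by the
#' population totals so the statistic compares a clone's relative standing in
#' each lineage.  Boundary cases are fixed: a clone detected only in B cells
#' scores exactly 1 and a clone detected only in granulocytes exactly -1.  The
#' continuous branch is
#'
#' \deqn{bias = \frac{\arctan\left(\frac{b/b_{tot}}{g/g_{tot}}\right) - \pi/4}{\pi/4}}
#'
#' which is 0 for a balanced clone and approaches the boundary values in the
#' single-lineage limits.  A clone absent from both lineages has undefined
#' bias (`NA`).
#'
#' @param gr_abund,b_abund clonal abundance in granulocytes / B cells (%WBC);
#'   vectors are recycled together.
#' @param gr_total_pct_wbc,b_total_pct_wbc total population abundances (%WBC),
#'   must be positive.
#' @return numeric vector in \[-1, 1\], `NA` where undefined.
#' @export
lineage_bias <- function(gr_abund, b_abund, gr_total_pct_wbc, b_total_pct_wbc) {
  if (any(gr_total_pct_wbc <= 0) || any(b_total_pct_wbc <= 0)) {
    stop("population totals must be positive")
  }
  if (any(gr_abund < 0, na.rm = TRUE) || any(b_abund < 0, na.rm = TRUE)) {
    stop("clonal abundances must be non-negative")
  }
  n <- max(length(gr_abund), length(b_abund))
  gr <- rep_len(gr_abund, n)
  b <- rep_len(b_abund, n)
  out <- rep_len(NA_real_, n)
  out[gr == 0 & b > 0] <- 1
  out[gr > 0 & b == 0] <- -1
  both <- which(gr > 0 & b > 0)
  if (length(both)) {
    ratio <- (b[both] / rep_len(b_total_pct_wbc, n)[both]) /
      (gr[both] / rep_len(gr_total_pct_wbc, n)[both])
    out[both] <- (atan(ratio) - pi / 4) / (pi / 4)
  }
  out
}

#' Per-clone lineage-output table
#'
#' Builds the five lineage-output measures for every (mouse, tracking barcode)
#' pair from tracking read counts and mouse metadata, and applies the
#' abundance filters:
#' * `hsc` - clonal abundance among barcoded HSCs (% barcoded HSCs);
#' * `granulocyte`, `b_cell` - clonal abundance in blood (%WBC);
#' * `total_blood` - granulocyte + B cell abundance (%WBC);
#' * `bias` - lineage bias, see [lineage_bias()].
#'
#' Barcodes absent from a population are assigned zero reads there.  A
#' `differentiation_ratio` column (total blood abundance / HSC abundance) is
#' carried as an optional derived quantity; it is not one of the five scan
#' measures.
#'
#' @param tracking data.frame with columns `mouse_id`, `tracking_barcode`,
#'   `population` (one of `"hsc"`, `"granulocyte"`, `"b_cell"`) and `reads`.
#' @param meta data.frame with one row per mouse: `mouse_id`, `donor_pct`,
#'   `gfp_pct`, `gr_pct_wbc`, `b_pct_wbc`.
#' @param global_min_pct_wbc clones whose blood contribution (granulocyte + B)
#'   is lower than this are excluded from all analyses (default 0.001 %WBC;
#'   the bound itself passes).
#' @param bias_min_frac_of_max clones below this fraction of the per-mouse
#'   most abundant clone in both lineages are excluded from the bias analysis
#'   only (default 0.01; the bound itself passes).
#' @return an object of class `clone_output`: a data.frame with one row per
#'   (mouse, barcode), the five measures, `differentiation_ratio` and logical
#'   flags `passed_global_filter`, `passed_bias_filter`.
#' @export
clone_output <- function(tracking, meta,
                         global_min_pct_wbc = 0.001,
                         bias_min_frac_of_max = 0.01) {
  need <- c("mouse_id", "tracking_barcode", "population", "reads")
  if (!all(need %in% names(tracking))) {
    stop("tracking table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tracking$population), c("hsc", "granulocyte", "b_cell"))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))

  pieces <- lapply(split(tracking, tracking$mouse_id), function(tr) {
    mid <- tr$mouse_id[1]
    m <- meta[meta$mouse_id == mid, , drop = FALSE]
    if (nrow(m) != 1) stop("metadata missing for mouse ", mid)
    barcodes <- sort(unique(tr$tracking_barcode))
    reads_of <- function(pop) {
      r <- tr[tr$population == pop, ]
      out <- stats::setNames(numeric(length(barcodes)), barcodes)
      if (nrow(r)) out[r$tracking_barcode] <- out[r$tracking_barcode] + r$reads
      out
    }
    gr_reads <- reads_of("granulocyte")
    b_reads <- reads_of("b_cell")
    hsc_reads <- reads_of("hsc")
    gr_tot <- m$gr_pct_wbc * m$donor_pct / 100 * m$gfp_pct / 100
    b_tot <- m$b_pct_wbc * m$donor_pct / 100 * m$gfp_pct / 100
    gr <- if (sum(gr_reads) > 0) {
      clonal_abundance_blood(gr_reads, m$gr_pct_wbc, m$donor_pct, m$gfp_pct)
    } else stats::setNames(numeric(length(barcodes)), barcodes)
    b <- if (sum(b_reads) > 0) {
      clonal_abundance_blood(b_reads, m$b_pct_wbc, m$donor_pct, m$gfp_pct)
    } else stats::setNames(numeric(length(barcodes)), barcodes)
    hsc <- if (sum(hsc_reads) > 0) {
      clonal_abundance_hsc(hsc_reads)
    } else stats::setNames(rep(NA_real_, length(barcodes)), barcodes)
    data.frame(
      mouse_id = mid,
      tracking_barcode = barcodes,
      hsc = unname(hsc),
      granulocyte = unname(gr),
      b_cell = unname(b),
      total_blood = unname(gr + b),
      bias = lineage_bias(unname(gr), unname(b), gr_tot, b_tot),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  tab$differentiation_ratio <- ifelse(
    is.na(tab$hsc) | tab$hsc == 0, NA_real_, tab$total_blood / tab$hsc
  )
  tab <- apply_clone_filters(tab, global_min_pct_wbc, bias_min_frac_of_max)
  class(tab) <- c("clone_output", "data.frame")
  attr(tab, "global_min_pct_wbc") <- global_min_pct_wbc
  attr(tab, "bias_min_frac_of_max") <- bias_min_frac_of_max
  tab
}

#' Apply the clone abundance filters
#'
#' Sets `passed_global_filter` (blood contribution at least
#' `global_min_pct_wbc` %WBC; "lower than" is excluded, so equality passes)
#' and `passed_bias_filter` (clone reaches at least `bias_min_frac_of_max` of
#' the per-mouse maximum clone abundance in at least one lineage).  A clone
#' failing the global filter always fails the bias filter too.
#'
#' @param table data.frame with at least `mouse_id`, `granulocyte`, `b_cell`
#'   and `total_blood` columns.
#' @inheritParams clone_output
#' @return `table` with the two logical flag columns set.
#' @export
apply_clone_filters <- function(table,
                                global_min_pct_wbc = 0.001,
                                bias_min_frac_of_max = 0.01) {
  table$passed_global_filter <- table$total_blood >= global_min_pct_wbc
  bias_ok <- logical(nrow(table))
  for (mid in unique(table$mouse_id)) {
    i <- table$mouse_id == mid
    max_gr <- max(table$granulocyte[i])
    max_b <- max(table$b_cell[i])
    # kept if prominent in either lineage; "less than" is strict
    bias_ok[i] <- (max_gr > 0 & table$granulocyte[i] >= bias_min_frac_of_max * max_gr) |
      (max_b > 0 & table$b_cell[i] >= bias_min_frac_of_max * max_b)
  }
  table$passed_bias_filter <- bias_ok & table$passed_global_filter
  table
}

#' Long-format measure table for retained clones
#'
#' One row per (mouse, clone, measure) for clones passing the global filter;
#' the `bias` measure additionally requires the bias filter and a defined
#' bias value.  This is the input joined to cells for the association scan.
#'
#' @param x a [clone_output()] table.
#' @param measures subset of
#'   `c("hsc", "granulocyte", "b_cell", "total_blood", "bias")`.
#' @return data.frame with columns `mouse_id`, `tracking_barcode`, `measure`,
#'   `value`.
#' @export
derive_measures <- function(x, measures = c("hsc", "granulocyte", "b_cell",
                                            "total_blood", "bias")) {
  measures <- match.arg(measures, several.ok = TRUE)
  keep <- x[x$passed_global_filter, , drop = FALSE]
  out <- lapply(measures, function(ms) {
    k <- keep
    if (ms == "bias") k <- k[k$passed_bias_filter & !is.na(k$bias), , drop = FALSE]
    if (ms == "hsc") k <- k[!is.na(k$hsc), , drop = FALSE]
    data.frame(
      mouse_id = k$mouse_id,
      tracking_barcode = k$tracking_barcode,
      measure = ms,
      value = k[[ms]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.check_pct <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 100)) {
    stop(what, " must be a percent in [0, 100]")
  }
  invisible(x)
}

#' @export
print.clone_output <- function(x, ...) {
  cat("Clone lineage-output table\n")
  cat(sprintf("  %d clones across %d mice\n",
              nrow(x), length(unique(x$mouse_id))))
  cat(sprintf("  %d pass the %g %%WBC global filter, %d the bias filter\n",
              sum(x$passed_global_filter), attr(x, "global_min_pct_wbc"),
              sum(x$passed_bias_filter)))
  invisible(x)
}

#' @export
summary.clone_output <- function(object, ...) {
  df <- as.data.frame(object)
  out <- do.call(rbind, lapply(split(df, df$mouse_id), function(d) {
    data.frame(
      mouse_id = d$mouse_id[1],
      n_clones = nrow(d),
      n_pass_global = sum(d$passed_global_filter),
      n_pass_bias = sum(d$passed_bias_filter),
      hsc_sum = sum(d$hsc, na.rm = TRUE),
      blood_sum = sum(d$total_blood)
    )
  }))
  rownames(out) <- NULL
  out
}
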