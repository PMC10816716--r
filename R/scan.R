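#' Enumerate valid lineage-output thresholds
#'
#' Candidate thresholds are the distinct clone-level output values observed
#' among mapped cells, pooled over mice.  A threshold `t` puts cells with
#' output value `<= t` in the "low" group and `> t` in the "high" group.  A
#' threshold is valid iff both groups contain more than `min_group` cells in
#' every mouse (strictly more, so `min_group = 4` requires at least 5 cells
#' per group per mouse).
#'
#' @param cells data.frame with one row per mapped cell: `cell_barcode`,
#'   `mouse_id`, `tracking_barcode`, `value` (the clone's output for the
#'   chosen measure).
#' @param min_group minimum group size bound (strict; default 4).
#' @return object of class `threshold_set`: data.frame of valid thresholds
#'   with columns `threshold_value`, `rank` (index among all pooled candidate
#'   values, ascending) and `rank_frac` (`rank / n_candidates`), plus
#'   attributes `n_candidates` and `min_group`.  Zero rows (with a warning)
#'   when no threshold is valid.
#' @export
enumerate_thresholds <- function(cells, min_group = 4) {
  stopifnot(all(c("mouse_id", "tracking_barcode", "value") %in% names(cells)))
  clone_vals <- unique(cells[, c("mouse_id", "tracking_barcode", "value")])
  cand <- sort(unique(clone_vals$value))
  n_cand <- length(cand)
  valid <- rep(TRUE, n_cand)
  for (vm in split(cells$value, cells$mouse_id)) {
    n_low <- findInterval(cand, sort(vm))
    n_high <- length(vm) - n_low
    valid <- valid & n_low > min_group & n_high > min_group
  }
  out <- data.frame(
    threshold_value = cand[valid],
    rank = seq_len(n_cand)[valid],
    rank_frac = seq_len(n_cand)[valid] / n_cand
  )
  if (!nrow(out)) warning("no valid thresholds for this measure")
  structure(out, class = c("threshold_set", "data.frame"),
            n_candidates = n_cand, min_group = min_group)
}

#' One-sided directional Mann-Whitney P values
#'
#' Compares expression of one gene between the high- and low-output cell
#' groups in one mouse and returns both one-sided P values: `p_high` is the
#' probability-style P that expression is higher in the high group, `p_low`
#' the opposite direction.  The production path is the tie-corrected normal
#' approximation with continuity correction; for small tie-free groups the
#' exact Mann-Whitney tail is used instead (`exact = "auto"`), matching
#' standard rank-sum practice.
#'
#' @param high,low numeric expression vectors of the two groups (nonempty).
#' @param exact `"auto"` (exact when tie-free and both groups <= 50),
#'   `"always"` (error if ties present) or `"never"`.
#' @return named numeric vector `c(p_high = , p_low = )`.
#' @export
directional_pvalues <- function(high, low, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  n1 <- length(high)
  n2 <- length(low)
  if (!n1 || !n2) stop("both groups must be nonempty")
  v <- c(high, low)
  r <- rank(v)
  ties <- any(duplicated(v))
  u_high <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- switch(exact,
    always = if (ties) stop("exact P values require tie-free data") else TRUE,
    never = FALSE,
    auto = !ties && n1 <= 50 && n2 <= 50
  )
  if (use_exact) {
    p_high <- stats::pwilcox(u_high - 1, n1, n2, lower.tail = FALSE)
    p_low <- stats::pwilcox(n1 * n2 - u_high - 1, n1, n2, lower.tail = FALSE)
    return(c(p_high = p_high, p_low = p_low))
  }
  N <- n1 + n2
  tab <- table(v)
  tiesum <- sum(tab^3 - tab)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tiesum / (N * (N - 1)))
  if (sigma2 <= 0) return(c(p_high = 1, p_low = 1))
  mu <- n1 * n2 / 2
  s <- sqrt(sigma2)
  c(
    p_high = stats::pnorm((u_high - mu - 0.5) / s, lower.tail = FALSE),
    p_low = stats::pnorm((n1 * n2 - u_high - mu - 0.5) / s, lower.tail = FALSE)
  )
}

#' Fisher's combined probability
#'
#' Combines independent one-sided P values (one per replicate mouse) for the
#' same gene and direction: `X = -2 sum(log p)` is referred to the upper tail
#' of a chi-square distribution with `2k` degrees of freedom.  P values are
#' floored at `floor` before taking logs.
#'
#' @param p numeric vector of P values in (0, 1].
#' @param floor lower floor applied before the log (default 1e-300).
#' @return the combined P value.
#' @export
fisher_combine <- function(p, floor = 1e-300) {
  if (!length(p)) stop("no P values to combine")
  if (any(p > 1)) stop("P values must be <= 1")
  if (any(p <= 0)) {
    warning("non-positive P values floored at ", floor)
  }
  p <- pmax(p, floor)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Scramble-control cohorts
#'
#' Generates mock cohorts by randomly remapping clonal tracking data to gene
#' expression data: within each mouse, every cell is independently assigned a
#' tracking barcode drawn uniformly with replacement from that mouse's
#' observed tracking barcodes.  Cell counts per mouse are preserved; the
#' number of cells per clone is free to change, as in the real mapping noise
#' this controls for.
#'
#' @param cells data.frame with `cell_barcode`, `mouse_id` (and any other
#'   columns); one row per mapped cell.
#' @param barcodes_by_mouse named list (by mouse) of the observed tracking
#'   barcodes eligible for reassignment.
#' @param n_sets number of scramble sets (default 100).
#' @param seed RNG seed.
#' @return object of class `scramble_set`: character matrix, cells x sets, of
#'   reassigned tracking barcodes (rows follow `cells`).
#' @export
make_scrambles <- function(cells, barcodes_by_mouse, n_sets = 100, seed = 1) {
  stopifnot(n_sets >= 1)
  n <- nrow(cells)
  out <- matrix(NA_character_, nrow = n, ncol = n_sets)
  rng <- .with_seed(seed, {
    for (mid in unique(cells$mouse_id)) {
      i <- which(cells$mouse_id == mid)
      pool <- barcodes_by_mouse[[as.character(mid)]]
      if (!length(pool)) stop("no observed tracking barcodes for mouse ", mid)
      for (s in seq_len(n_sets)) {
        out[i, s] <- pool[sample.int(length(pool), length(i), replace = TRUE)]
      }
    }
    out
  })
  structure(rng, class = c("scramble_set", class(rng)), seed = seed)
}

#' False-positive scores from scramble controls
#'
#' At each (direction, threshold), let `N_exp(g)` be the number of genes in
#' the experimental table with combined P less than or equal to gene g's, and
#' `N_ctrl(g, s)` the analogous count within scramble set s at gene g's
#' experimental P.  The false-positive score is
#' `FPS(g) = median_s N_ctrl(g, s) / N_exp(g)`; values below 0.05 are
#' conventionally called significant.
#'
#' @param p_exp thresholds x genes matrix of experimental combined P values
#'   for one direction.
#' @param p_ctrl list over scramble sets of matrices shaped like `p_exp`.
#' @return matrix shaped like `p_exp` of false-positive scores.
#' @export
false_positive_scores <- function(p_exp, p_ctrl) {
  stopifnot(length(p_ctrl) >= 1)
  for (pc in p_ctrl) stopifnot(identical(dim(pc), dim(p_exp)))
  fps <- p_exp
  n_sets <- length(p_ctrl)
  for (t in seq_len(nrow(p_exp))) {
    pe <- p_exp[t, ]
    n_exp <- rank(pe, ties.method = "max")
    n_ctrl <- matrix(0L, nrow = n_sets, ncol = length(pe))
    for (s in seq_len(n_sets)) {
      n_ctrl[s, ] <- findInterval(pe, sort(p_ctrl[[s]][t, ]))
    }
    fps[t, ] <- apply(n_ctrl, 2, stats::median) / n_exp
  }
  fps
}

#' Thresholded association scan of expression against clonal output
#'
#' The full iterative differential-expression scan for one lineage-output
#' measure: at every valid threshold, cells of each mouse are split into
#' high- and low-output groups and each gene is tested with the one-sided
#' Mann-Whitney test in both directions; P values of the same direction are
#' Fisher-combined across mice, and scramble-control cohorts supply a
#' false-positive score for every (gene, direction, threshold).  A gene is
#' called significant when any of its false-positive scores falls below
#' `fps_cutoff`.
#'
#' @param qc an [qc_expression()] result.
#' @param directory a [build_directory()] result whose `map` carries
#'   `mouse_id`.
#' @param outputs a [clone_output()] table.
#' @param measure one of `"hsc"`, `"granulocyte"`, `"b_cell"`,
#'   `"total_blood"`, `"bias"`.
#' @param min_group valid-threshold group bound (strict; default 4).
#' @param n_scrambles number of scramble-control sets (default 100).
#' @param seed RNG seed for the scrambles.
#' @param fps_cutoff significance cutoff on the false-positive score
#'   (default 0.05).
#' @return object of class `assoc_scan`: list with `measure`, `thresholds`
#'   (the [enumerate_thresholds()] table), `genes`, `mice`, `cells` (the
#'   cell-to-clone join used), `p_mouse` (per-direction list of
#'   thresholds x genes x mice arrays), `combined_p` and `fps`
#'   (per-direction lists of thresholds x genes matrices), `summary` (per
#'   gene: minimum FPS, its direction/threshold, significance) and the scan
#'   parameters.  The median-split (50% rank) threshold is reported in
#'   `median_split_rank`.
#' @export
run_scan <- function(qc, directory, outputs, measure = "granulocyte",
                     min_group = 4, n_scrambles = 100, seed = 1,
                     fps_cutoff = 0.05) {
  cells <- .join_cells(qc, directory, outputs, measure)
  thresholds <- enumerate_thresholds(cells, min_group)
  genes <- rownames(qc$logcounts)
  empty_summary <- function() data.frame(
    gene = genes, min_fps = NA_real_, direction = NA_character_,
    threshold_value = NA_real_, threshold_rank = NA_integer_,
    combined_p = NA_real_, significant = FALSE
  )
  if (!nrow(thresholds)) {
    warning("empty threshold set; returning empty scan result")
    return(structure(list(
      measure = measure, thresholds = thresholds, genes = genes,
      mice = unique(cells$mouse_id), cells = cells,
      p_mouse = NULL, combined_p = NULL, fps = NULL,
      summary = empty_summary(), median_split_rank = NA_integer_,
      params = list(min_group = min_group, n_scrambles = n_scrambles,
                    seed = seed, fps_cutoff = fps_cutoff)
    ), class = "assoc_scan"))
  }

  mice <- sort(unique(cells$mouse_id))
  # per-mouse expression ranks are shared by all thresholds and all scrambles
  pre <- lapply(mice, function(mid) {
    idx <- which(cells$mouse_id == mid)
    X <- t(qc$logcounts[, cells$cell_barcode[idx], drop = FALSE])  # cells x genes
    Rk <- apply(X, 2, rank)
    tiesum <- apply(X, 2, function(v) {
      tb <- table(v)
      sum(tb^3 - tb)
    })
    list(idx = idx, ranks = Rk, tiesum = tiesum, N = length(idx))
  })
  names(pre) <- mice

  clone_value <- .clone_value_lookup(outputs, measure)
  exp_p <- .scan_pvalues(pre, cells$value, thresholds$threshold_value)

  # scramble cohorts reuse the expression ranks; only group labels change
  pool <- lapply(split(cells$tracking_barcode, cells$mouse_id), unique)
  scrambles <- make_scrambles(cells, pool, n_sets = n_scrambles, seed = seed)
  ctrl_high <- vector("list", n_scrambles)
  ctrl_low <- vector("list", n_scrambles)
  for (s in seq_len(n_scrambles)) {
    v <- clone_value[paste(cells$mouse_id, scrambles[, s], sep = "\r")]
    ps <- .scan_pvalues(pre, v, thresholds$threshold_value)
    ctrl_high[[s]] <- ps$combined$high
    ctrl_low[[s]] <- ps$combined$low
  }
  fps <- list(
    high = false_positive_scores(exp_p$combined$high, ctrl_high),
    low = false_positive_scores(exp_p$combined$low, ctrl_low)
  )

  summ <- empty_summary()
  for (g in seq_along(genes)) {
    cand <- rbind(
      data.frame(direction = "high", t = seq_len(nrow(thresholds)),
                 fps = fps$high[, g], p = exp_p$combined$high[, g]),
      data.frame(direction = "low", t = seq_len(nrow(thresholds)),
                 fps = fps$low[, g], p = exp_p$combined$low[, g])
    )
    best <- cand[order(cand$fps, cand$p), ][1, ]
    summ$min_fps[g] <- best$fps
    summ$direction[g] <- best$direction
    summ$threshold_value[g] <- thresholds$threshold_value[best$t]
    summ$threshold_rank[g] <- thresholds$rank[best$t]
    summ$combined_p[g] <- best$p
    summ$significant[g] <- best$fps < fps_cutoff
  }

  structure(list(
    measure = measure, thresholds = thresholds, genes = genes, mice = mice,
    cells = cells, p_mouse = exp_p$per_mouse, combined_p = exp_p$combined,
    fps = fps, summary = summ,
    median_split_rank = thresholds$rank[which.min(abs(thresholds$rank_frac - 0.5))],
    params = list(min_group = min_group, n_scrambles = n_scrambles,
                  seed = seed, fps_cutoff = fps_cutoff)
  ), class = "assoc_scan")
}

#' Association curve of one gene
#'
#' The gene's `-log10(combined P)` values across the valid thresholds, in
#' rank coordinates, for the requested direction (by default the gene's
#' dominant direction, i.e. the one attaining its minimum false-positive
#' score).  This is the curve the pattern classifier consumes.
#'
#' @param scan an [run_scan()] result.
#' @param gene gene id.
#' @param direction `"high"`, `"low"` or `NULL` (dominant).
#' @return object of class `assoc_curve`: data.frame with `rank`,
#'   `rank_frac`, `threshold_value`, `neg_log10_p`, `fps`; attributes `gene`,
#'   `measure`, `direction`.
#' @export
association_curve <- function(scan, gene, direction = NULL) {
  g <- match(gene, scan$genes)
  if (is.na(g)) stop("gene not in scan: ", gene)
  if (is.null(scan$combined_p)) stop("scan has no thresholds")
  if (is.null(direction)) {
    direction <- scan$summary$direction[match(gene, scan$summary$gene)]
  }
  direction <- match.arg(direction, c("high", "low"))
  p <- scan$combined_p[[direction]][, g]
  out <- data.frame(
    rank = scan$thresholds$rank,
    rank_frac = scan$thresholds$rank_frac,
    threshold_value = scan$thresholds$threshold_value,
    neg_log10_p = -log10(pmax(p, 1e-300)),
    fps = scan$fps[[direction]][, g]
  )
  structure(out, class = c("assoc_curve", "data.frame"),
            gene = gene, measure = scan$measure, direction = direction)
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("Association scan: measure '%s'\n", x$measure))
  cat(sprintf("  %d genes, %d mice, %d valid thresholds, %d scramble sets\n",
              length(x$genes), length(x$mice), nrow(x$thresholds),
              x$params$n_scrambles))
  cat(sprintf("  %d genes significant (min FPS < %g)\n",
              sum(x$summary$significant), x$params$fps_cutoff))
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, ...) {
  s <- object$summary
  s[order(s$min_fps, s$combined_p), ]
}

#' @export
plot.assoc_curve <- function(x, ...) {
  plot(x$rank, x$neg_log10_p, pch = 16, col = "grey40",
       xlab = "lineage output rank (threshold)",
       ylab = expression(-log[10] ~ "combined P"),
       main = sprintf("%s (%s, %s)", attr(x, "gene"), attr(x, "measure"),
                      attr(x, "direction")), ...)
  invisible(x)
}

# ---- internals --------------------------------------------------------------

# join retained cells to their clone's output value for one measure
.join_cells <- function(qc, directory, outputs, measure) {
  map <- directory$map
  if (!"mouse_id" %in% names(map)) {
    stop("directory map must carry mouse_id for the scan")
  }
  keep <- map$cell_barcode %in% colnames(qc$logcounts)
  map <- map[keep, , drop = FALSE]
  clone_value <- .clone_value_lookup(outputs, measure)
  v <- clone_value[paste(map$mouse_id, map$tracking_barcode, sep = "\r")]
  out <- data.frame(
    cell_barcode = map$cell_barcode,
    mouse_id = map$mouse_id,
    tracking_barcode = map$tracking_barcode,
    value = unname(v),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$value), , drop = FALSE]
  if (!nrow(out)) stop("no mapped cells carry a value for measure ", measure)
  rownames(out) <- NULL
  out
}

.clone_value_lookup <- function(outputs, measure) {
  mv <- derive_measures(outputs, measure)
  stats::setNames(mv$value, paste(mv$mouse_id, mv$tracking_barcode, sep = "\r"))
}

# vectorised scan over all thresholds/genes/mice given per-cell output values
.scan_pvalues <- function(pre, values, thr) {
  n_thr <- length(thr)
  n_genes <- ncol(pre[[1]]$ranks)
  log_high <- matrix(0, n_thr, n_genes)
  log_low <- matrix(0, n_thr, n_genes)
  per_mouse <- list(
    high = array(NA_real_, c(n_thr, n_genes, length(pre))),
    low = array(NA_real_, c(n_thr, n_genes, length(pre)))
  )
  for (mi in seq_along(pre)) {
    pm <- pre[[mi]]
    v <- values[pm$idx]
    H <- outer(thr, v, function(t, x) as.numeric(x > t))  # thresholds x cells
    n1 <- rowSums(H)
    n2 <- pm$N - n1
    RS <- H %*% pm$ranks
    U1 <- RS - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- outer(n1 * n2 / 12, (pm$N + 1) - pm$tiesum / (pm$N * (pm$N - 1)))
    s <- sqrt(pmax(sigma2, 0))
    ok <- s > 0
    p_high <- matrix(1, n_thr, n_genes)
    p_low <- matrix(1, n_thr, n_genes)
    z_high <- (U1 - mu - 0.5) / ifelse(ok, s, 1)
    z_low <- ((n1 * n2 - U1) - mu - 0.5) / ifelse(ok, s, 1)
    p_high[ok] <- stats::pnorm(z_high[ok], lower.tail = FALSE)
    p_low[ok] <- stats::pnorm(z_low[ok], lower.tail = FALSE)
    per_mouse$high[, , mi] <- p_high
    per_mouse$low[, , mi] <- p_low
    log_high <- log_high + log(pmax(p_high, 1e-300))
    log_low <- log_low + log(pmax(p_low, 1e-300))
  }
  df <- 2 * length(pre)
  list(
    per_mouse = per_mouse,
    combined = list(
      high = stats::pchisq(-2 * log_high, df, lower.tail = FALSE),
      low = stats::pchisq(-2 * log_low, df, lower.tail = FALSE)
    )
  )
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
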