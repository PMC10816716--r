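#' Specification of a planted association gene
#'
#' Describes how a synthetic gene's expression depends on the output rank of
#' the clone a cell belongs to, mirroring the four association patterns:
#' * `constant`: a monotone log-mean shift across the full rank range
#'   (linear dose-response);
#' * `discrete`: the linear dose-response applies only below the single
#'   breakpoint rank (mean-centred there, so no association leaks across the
#'   breakpoint); expression is flat above it;
#' * `unimodal`: an on/off toggle - cells of clones above the switch rank are
#'   drawn from the high expression state;
#' * `multimodal`: the state toggles at each of several switch ranks.  Note
#'   that only up-switches produce peaks in the same test direction, so a
#'   gene whose dominant-direction curve shows two peaks needs three
#'   alternating switches (the default); with two switches the second peak
#'   appears in the opposite direction.
#'
#' Default effect sizes (log2 mean shift) differ by pattern to emulate the
#' magnitudes such genes reach in practice: a constant dose-response spreads
#' a moderate effect over the whole range, while toggle-type genes show a
#' strong two-state contrast.
#'
#' @param pattern one of `"constant"`, `"discrete"`, `"unimodal"`,
#'   `"multimodal"`.
#' @param id gene id; `NULL` assigns one when the cohort is generated.
#' @param direction `"positive"` (expression rises with output) or
#'   `"negative"`.
#' @param switch_ranks output-rank fractions in (0,1), strictly increasing:
#'   empty for constant, exactly one for discrete/unimodal, two or more for
#'   multimodal.
#' @param effect_size log2 mean expression shift; pattern-specific default.
#' @param target_measure which lineage-output measure drives the gene.
#' @return list of class `planted_gene`.
#' @export
planted_gene <- function(pattern = c("constant", "discrete", "unimodal",
                                     "multimodal"),
                         id = NULL,
                         direction = c("positive", "negative"),
                         switch_ranks = NULL,
                         effect_size = NULL,
                         target_measure = "granulocyte") {
  pattern <- match.arg(pattern)
  direction <- match.arg(direction)
  target_measure <- match.arg(target_measure,
                              c("hsc", "granulocyte", "b_cell", "total_blood",
                                "bias"))
  if (is.null(switch_ranks)) {
    switch_ranks <- switch(pattern,
      constant = numeric(),
      discrete = 0.5,
      unimodal = 0.5,
      multimodal = c(0.25, 0.5, 0.75)
    )
  }
  n_sw <- length(switch_ranks)
  ok <- switch(pattern,
    constant = n_sw == 0,
    discrete = n_sw == 1,
    unimodal = n_sw == 1,
    multimodal = n_sw >= 2
  )
  if (!ok) stop("planted_gene: switch_ranks has wrong length for pattern ", pattern)
  if (n_sw && (any(switch_ranks <= 0) || any(switch_ranks >= 1) ||
               any(diff(switch_ranks) <= 0))) {
    stop("planted_gene: switch_ranks must be strictly increasing in (0, 1)")
  }
  if (is.null(effect_size)) {
    effect_size <- switch(pattern, constant = 0.6, discrete = 1.5,
                          unimodal = 2, multimodal = 2)
  }
  if (!is.finite(effect_size)) stop("planted_gene: effect_size must be finite")
  structure(list(id = id, pattern = pattern, direction = direction,
                 switch_ranks = switch_ranks, effect_size = effect_size,
                 target_measure = target_measure),
            class = "planted_gene")
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator.  Defaults emulate the
#' measured study conditions: four recipient mice, heavy-tailed clonal output
#' (log-normal), multi-cell clones averaging a few HSCs each (hundreds of
#' mapped cells per cohort), about 20% of bridge-linked cellular barcodes
#' mapped to multiple tracking barcodes, and donor/GFP/population metadata of
#' the same order as reported chimerism.
#'
#' @param n_mice number of mice (default 4).
#' @param clones_per_mouse barcoded clones per mouse (default 40).
#' @param cells_per_clone_law log-normal law (`meanlog`, `sdlog`) for the
#'   number of profiled HSCs per clone (rounded, floored at 1).
#' @param output_law log-normal law for true per-lineage clonal weights.
#' @param n_genes number of (non-mitochondrial) genes.
#' @param planted_genes list of [planted_gene()] specs.
#' @param baseline_expression_law log-normal law for per-gene baseline mean
#'   UMI counts plus a negative-binomial `dispersion` (size) parameter;
#'   `planted_floor` is the minimum baseline mean given to planted genes so
#'   they are detectable.
#' @param cell_size_law log-normal `sdlog` of per-cell library size factors.
#' @param mito_fraction_law beta law (`shape1`, `shape2`) for per-cell
#'   mitochondrial UMI fractions.
#' @param n_mito_genes number of mitochondrial genes (named `mt-*`).
#' @param multimap_cell_fraction fraction of bridge-linked cellular barcodes
#'   carrying two or more distinct tracking barcodes (default 0.20).
#' @param unmapped_cell_fraction fraction of cells with no bridge record.
#' @param depth sequencing depth per sorted population (reads; default 1e5).
#' @param meta mouse metadata: `donor_pct`, `gfp_pct`, `gr_pct_wbc`,
#'   `b_pct_wbc` (defaults 95, 60, 20, 40).
#' @param seed RNG seed; identical config and seed give identical cohorts.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_mice = 4,
                         clones_per_mouse = 40,
                         cells_per_clone_law = list(meanlog = 1, sdlog = 0.8),
                         output_law = list(meanlog = 0, sdlog = 1.5),
                         n_genes = 200,
                         planted_genes = list(),
                         baseline_expression_law = list(meanlog = -0.5,
                                                        sdlog = 1,
                                                        dispersion = 2,
                                                        planted_floor = 2),
                         cell_size_law = list(sdlog = 0.3),
                         mito_fraction_law = list(shape1 = 2, shape2 = 60),
                         n_mito_genes = 8,
                         multimap_cell_fraction = 0.2,
                         unmapped_cell_fraction = 0.1,
                         depth = 1e5,
                         meta = list(donor_pct = 95, gfp_pct = 60,
                                     gr_pct_wbc = 20, b_pct_wbc = 40),
                         seed = 1) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

#' Validate a synthetic cohort configuration
#'
#' @param cfg a [synth_config()] list.
#' @return `cfg`, invisibly unchanged, or an error naming the offending
#'   field.
#' @export
validate_synth_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x)) {
      stop("synth_config: '", field, "' must be a positive count")
    }
  }
  chk_frac <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1) {
      stop("synth_config: '", field, "' must be a fraction in [0, 1]")
    }
  }
  chk_count(cfg$n_mice, "n_mice")
  chk_count(cfg$clones_per_mouse, "clones_per_mouse")
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$n_mito_genes, "n_mito_genes")
  chk_count(cfg$depth, "depth")
  chk_frac(cfg$multimap_cell_fraction, "multimap_cell_fraction")
  chk_frac(cfg$unmapped_cell_fraction, "unmapped_cell_fraction")
  if (!is.numeric(cfg$cells_per_clone_law$sdlog) ||
      cfg$cells_per_clone_law$sdlog < 0) {
    stop("synth_config: 'cells_per_clone_law' needs sdlog >= 0")
  }
  if (!is.numeric(cfg$output_law$sdlog) || cfg$output_law$sdlog < 0) {
    stop("synth_config: 'output_law' needs sdlog >= 0")
  }
  if (!is.numeric(cfg$baseline_expression_law$dispersion) ||
      cfg$baseline_expression_law$dispersion <= 0) {
    stop("synth_config: 'baseline_expression_law' needs dispersion > 0")
  }
  if (any(unlist(cfg$mito_fraction_law) <= 0)) {
    stop("synth_config: 'mito_fraction_law' needs positive beta shapes")
  }
  for (p in cfg$planted_genes) {
    if (!inherits(p, "planted_gene")) {
      stop("synth_config: 'planted_genes' must be a list of planted_gene()")
    }
  }
  if (length(cfg$planted_genes) > cfg$n_genes) {
    stop("synth_config: 'planted_genes' cannot outnumber n_genes")
  }
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort with the statistical structure the downstream
#' analysis assumes: per-mouse tracking read counts for the HSC, granulocyte
#' and B cell populations (multinomial sampling of heavy-tailed true clonal
#' weights at fixed depth), a sparse UMI matrix with negative-binomial genes
#' and planted association genes driven by the clones' pooled output ranks,
#' mitochondrial genes realising a per-cell mito fraction, bridge records
#' with configurable unmapped and multi-mapped cell fractions, and the full
#' ground truth.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_cohort`: list with `tracking`, `meta`,
#'   `counts` (sparse genes x cells UMI matrix), `genes`, `cell_barcodes`,
#'   `bridges`, `truth` (`cells`, `genes`, `clones` data.frames) and
#'   `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  mice <- sprintf("M%d", seq_len(config$n_mice))
  meta <- data.frame(
    mouse_id = mice,
    donor_pct = config$meta$donor_pct,
    gfp_pct = config$meta$gfp_pct,
    gr_pct_wbc = config$meta$gr_pct_wbc,
    b_pct_wbc = config$meta$b_pct_wbc,
    stringsAsFactors = FALSE
  )

  # true clonal weights and sequenced reads per population
  clones <- do.call(rbind, lapply(mice, function(mid) {
    k <- config$clones_per_mouse
    data.frame(
      mouse_id = mid,
      tracking_barcode = sprintf("TBC_%s_%03d", mid, seq_len(k)),
      w_hsc = stats::rlnorm(k, config$output_law$meanlog, config$output_law$sdlog),
      w_gr = stats::rlnorm(k, config$output_law$meanlog, config$output_law$sdlog),
      w_b = stats::rlnorm(k, config$output_law$meanlog, config$output_law$sdlog),
      stringsAsFactors = FALSE
    )
  }))
  rownames(clones) <- NULL

  tracking <- do.call(rbind, lapply(mice, function(mid) {
    cl <- clones[clones$mouse_id == mid, ]
    pops <- list(hsc = cl$w_hsc, granulocyte = cl$w_gr, b_cell = cl$w_b)
    do.call(rbind, lapply(names(pops), function(pop) {
      reads <- as.integer(stats::rmultinom(1, config$depth,
                                           pops[[pop]] / sum(pops[[pop]])))
      data.frame(mouse_id = mid, tracking_barcode = cl$tracking_barcode,
                 population = pop, reads = reads, stringsAsFactors = FALSE)
    }))
  }))
  rownames(tracking) <- NULL

  # true measures per clone (from true weights, same formulas as the analysis)
  truth_clones <- do.call(rbind, lapply(mice, function(mid) {
    cl <- clones[clones$mouse_id == mid, ]
    m <- meta[meta$mouse_id == mid, ]
    gr <- clonal_abundance_blood(stats::setNames(cl$w_gr, cl$tracking_barcode),
                                 m$gr_pct_wbc, m$donor_pct, m$gfp_pct)
    b <- clonal_abundance_blood(stats::setNames(cl$w_b, cl$tracking_barcode),
                                m$b_pct_wbc, m$donor_pct, m$gfp_pct)
    hsc <- clonal_abundance_hsc(stats::setNames(cl$w_hsc, cl$tracking_barcode))
    gr_tot <- m$gr_pct_wbc * m$donor_pct / 100 * m$gfp_pct / 100
    b_tot <- m$b_pct_wbc * m$donor_pct / 100 * m$gfp_pct / 100
    data.frame(
      mouse_id = mid, tracking_barcode = cl$tracking_barcode,
      hsc = unname(hsc), granulocyte = unname(gr), b_cell = unname(b),
      total_blood = unname(gr + b),
      bias = lineage_bias(unname(gr), unname(b), gr_tot, b_tot),
      stringsAsFactors = FALSE
    )
  }))
  rownames(truth_clones) <- NULL
  for (ms in c("hsc", "granulocyte", "b_cell", "total_blood", "bias")) {
    v <- truth_clones[[ms]]
    truth_clones[[paste0("rank_frac_", ms)]] <- (rank(v) - 0.5) / length(v)
  }

  # cells
  n_cells_per_clone <- pmax(1L, as.integer(round(stats::rlnorm(
    nrow(clones), config$cells_per_clone_law$meanlog,
    config$cells_per_clone_law$sdlog))))
  cell_clone_idx <- rep(seq_len(nrow(clones)), n_cells_per_clone)
  n_cells <- length(cell_clone_idx)
  cell_barcodes <- sprintf("CB%05d", seq_len(n_cells))
  truth_cells <- data.frame(
    cell_barcode = cell_barcodes,
    mouse_id = clones$mouse_id[cell_clone_idx],
    tracking_barcode = clones$tracking_barcode[cell_clone_idx],
    stringsAsFactors = FALSE
  )

  # genes and planted specs
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  planted <- config$planted_genes
  auto <- 0L
  for (i in seq_along(planted)) {
    if (is.null(planted[[i]]$id)) {
      auto <- auto + 1L
      planted[[i]]$id <- gene_ids[auto]
    } else if (!planted[[i]]$id %in% gene_ids) {
      stop("planted gene id not in gene list: ", planted[[i]]$id)
    }
  }
  if (anyDuplicated(vapply(planted, `[[`, "", "id"))) {
    stop("duplicate planted gene ids")
  }
  mito_ids <- if (config$n_mito_genes)
    sprintf("mt-%d", seq_len(config$n_mito_genes)) else character()

  truth_genes <- data.frame(
    gene = gene_ids, pattern = "null", direction = NA_character_,
    switch_ranks = "", effect_size = NA_real_, target_measure = NA_character_,
    stringsAsFactors = FALSE
  )
  for (p in planted) {
    i <- match(p$id, gene_ids)
    truth_genes$pattern[i] <- p$pattern
    truth_genes$direction[i] <- p$direction
    truth_genes$switch_ranks[i] <- paste(p$switch_ranks, collapse = ",")
    truth_genes$effect_size[i] <- p$effect_size
    truth_genes$target_measure[i] <- p$target_measure
  }

  # expression
  bl <- config$baseline_expression_law
  mu_g <- stats::rlnorm(config$n_genes, bl$meanlog, bl$sdlog)
  floor_mu <- if (is.null(bl$planted_floor)) 2 else bl$planted_floor
  for (p in planted) mu_g[match(p$id, gene_ids)] <-
    pmax(mu_g[match(p$id, gene_ids)], floor_mu)
  size_f <- stats::rlnorm(n_cells, 0, config$cell_size_law$sdlog)

  shift <- matrix(0, nrow = config$n_genes, ncol = n_cells)
  for (p in planted) {
    rf <- truth_clones[[paste0("rank_frac_", p$target_measure)]]
    cell_rf <- rf[cell_clone_idx]
    s <- planted_shift(p, cell_rf)
    shift[match(p$id, gene_ids), ] <- s
  }

  counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells)
  for (g in seq_len(config$n_genes)) {
    mu <- mu_g[g] * size_f * 2^shift[g, ]
    counts[g, ] <- stats::rnbinom(n_cells, mu = mu, size = bl$dispersion)
  }

  if (length(mito_ids)) {
    mito_frac <- stats::rbeta(n_cells, config$mito_fraction_law$shape1,
                              config$mito_fraction_law$shape2)
    nonmito_tot <- colSums(counts)
    mito_tot <- as.integer(round(mito_frac / (1 - mito_frac) *
                                   pmax(nonmito_tot, 1)))
    w_mito <- rev(seq_along(mito_ids))
    mito_counts <- vapply(mito_tot, function(tot) {
      as.integer(stats::rmultinom(1, tot, w_mito))
    }, integer(length(mito_ids)))
    counts <- rbind(counts, mito_counts)
  }
  all_genes <- c(gene_ids, mito_ids)
  dimnames(counts) <- list(all_genes, cell_barcodes)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  # bridges
  mapped <- stats::runif(n_cells) >= config$unmapped_cell_fraction
  multi <- mapped & stats::runif(n_cells) < config$multimap_cell_fraction
  recs <- list()
  for (i in which(mapped)) {
    recs[[length(recs) + 1L]] <- data.frame(
      cell_barcode = cell_barcodes[i],
      tracking_barcode = truth_cells$tracking_barcode[i],
      mouse_id = truth_cells$mouse_id[i],
      read_support = 1L + stats::rpois(1, 2),
      stringsAsFactors = FALSE
    )
    if (multi[i]) {
      others <- setdiff(
        clones$tracking_barcode[clones$mouse_id == truth_cells$mouse_id[i]],
        truth_cells$tracking_barcode[i]
      )
      recs[[length(recs) + 1L]] <- data.frame(
        cell_barcode = cell_barcodes[i],
        tracking_barcode = others[sample.int(length(others), 1)],
        mouse_id = truth_cells$mouse_id[i],
        read_support = 1L + stats::rpois(1, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  bridges <- if (length(recs)) do.call(rbind, recs) else data.frame(
    cell_barcode = character(), tracking_barcode = character(),
    mouse_id = character(), read_support = integer()
  )
  rownames(bridges) <- NULL
  truth_cells$mapped <- mapped
  truth_cells$multimapped <- multi

  structure(list(
    tracking = tracking, meta = meta, counts = counts, genes = all_genes,
    cell_barcodes = cell_barcodes, bridges = bridges,
    truth = list(cells = truth_cells, genes = truth_genes,
                 clones = truth_clones),
    config = config
  ), class = "synth_cohort")
}

#' Log2 expression shift of a planted gene at given output ranks
#'
#' @param spec a [planted_gene()].
#' @param rank_frac numeric vector of pooled output-rank fractions in (0, 1).
#' @return numeric vector of log2 mean shifts.
#' @export
planted_shift <- function(spec, rank_frac) {
  e <- spec$effect_size
  s <- spec$switch_ranks
  out <- switch(spec$pattern,
    constant = e * (2 * rank_frac - 1),
    # mean-centred dose on the active side only, so no association leaks
    # across the breakpoint
    discrete = ifelse(rank_frac <= s[1], e * (2 * rank_frac / s[1] - 1), 0),
    unimodal = ifelse(rank_frac > s[1], e, 0),
    multimodal = {
      state <- rowSums(outer(rank_frac, s, ">"))
      ifelse(state %% 2 == 1, e, 0)
    }
  )
  if (spec$direction == "negative") out <- -out
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort\n")
  cat(sprintf("  %d mice, %d clones, %d cells, %d genes (%d planted)\n",
              nrow(x$meta), nrow(x$truth$clones), length(x$cell_barcodes),
              length(x$genes), sum(x$truth$genes$pattern != "null")))
  cat(sprintf("  %d bridge records (%d cells mapped, %d multi-mapped)\n",
              nrow(x$bridges), sum(x$truth$cells$mapped),
              sum(x$truth$cells$multimapped)))
  invisible(x)
}
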