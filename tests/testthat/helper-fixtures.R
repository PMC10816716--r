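# Shared fixture builders and independent oracles.

# small mouse metadata table
toy_meta <- function(mice = "M1", donor = 100, gfp = 100, gr = 20, b = 40) {
  data.frame(mouse_id = mice, donor_pct = donor, gfp_pct = gfp,
             gr_pct_wbc = gr, b_pct_wbc = b, stringsAsFactors = FALSE)
}

# tracking table from named read vectors per population
toy_tracking <- function(mouse = "M1", hsc = NULL, gr = NULL, b = NULL) {
  mk <- function(v, pop) {
    if (is.null(v)) return(NULL)
    data.frame(mouse_id = mouse, tracking_barcode = names(v), population = pop,
               reads = unname(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null),
                        list(mk(hsc, "hsc"), mk(gr, "granulocyte"), mk(b, "b_cell"))))
}

# exhaustive-permutation oracle for the one-sided Mann-Whitney tail:
# enumerate every assignment of the pooled (tie-free) values to a "high"
# group of the observed size and count assignments at least as extreme
mw_exact_oracle <- function(high, low) {
  v <- c(high, low)
  stopifnot(!anyDuplicated(v))
  n1 <- length(high)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(length(v), n1)
  u_all <- apply(picks, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  c(p_high = mean(u_all >= u_obs), p_low = mean(u_all <= u_obs))
}

# chi-square upper tail by numerical integration (independent of pchisq)
chisq_tail_oracle <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-12)$value
}

# noiseless curve grid drawn from the four association models
curve_grid <- function() {
  x <- 1:100
  gauss <- function(b, mu, sigma, c) b * exp(-(x - mu)^2 / (2 * sigma^2)) + c
  step <- function(d, e, f) ifelse(x <= f, d, e)
  curves <- list()
  add <- function(truth, y) curves[[length(curves) + 1]] <<-
    list(truth = truth, x = x, y = y)
  for (a in c(1, 3, 6)) add("constant", rep(a, length(x)))
  for (b in c(6, 10)) for (sigma in c(8, 15)) for (mu in c(30, 50, 70)) {
    add("unimodal", gauss(b, mu, sigma, 0.5))
  }
  for (jump in list(c(2, 6), c(6, 2), c(1, 5), c(7, 3))) {
    for (f in c(30, 50, 70)) add("discrete", step(jump[1], jump[2], f))
  }
  for (b2 in c(4, 6)) {
    add("multimodal", gauss(6, 30, 8, 0.5) + gauss(b2, 70, 8, 0))
  }
  curves
}

# small planted cohort shared by scan/classify tests
planted_cohort <- function(specs, seed, n_genes = 150, ...) {
  cfg <- synth_config(planted_genes = specs, n_genes = n_genes, seed = seed, ...)
  co <- generate_cohort(cfg)
  dir <- build_directory(co$bridges,
                         known_tracking = unique(co$tracking$tracking_barcode),
                         known_cells = co$cell_barcodes)
  out <- clone_output(co$tracking, co$meta)
  qc <- qc_expression(co$counts)
  list(cohort = co, directory = dir, outputs = out, qc = qc)
}
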