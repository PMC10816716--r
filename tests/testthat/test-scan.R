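test_that("threshold enumeration enforces both-group sizes in every mouse", {
  cells10 <- data.frame(cell_barcode = sprintf("c%d", 1:10), mouse_id = "M1",
                        tracking_barcode = sprintf("T%d", 1:10), value = 1:10)
  ts <- enumerate_thresholds(cells10, min_group = 4)
  # independent exhaustive check of all candidate splits: low = {v <= t}
  valid_oracle <- Filter(function(t) {
    sum(cells10$value <= t) > 4 && sum(cells10$value > t) > 4
  }, 1:10)
  expect_equal(ts$threshold_value, valid_oracle)
  expect_equal(length(valid_oracle), 1)  # only the 5/5 split survives

  cells9 <- cells10[1:9, ]
  expect_warning(ts9 <- enumerate_thresholds(cells9, 4), "no valid")
  expect_equal(nrow(ts9), 0)

  # the rule applies per mouse: a 9-cell mouse invalidates everything
  two <- rbind(cells10,
               transform(cells9, mouse_id = "M2",
                         cell_barcode = sprintf("d%d", 1:9)))
  expect_warning(ts2 <- enumerate_thresholds(two, 4), "no valid")
  expect_equal(nrow(ts2), 0)
})

test_that("directional P values match exact enumeration and handle ties", {
  p <- directional_pvalues(high = c(3, 4, 5), low = c(1, 2))
  expect_equal(unname(p["p_high"]), 0.1)  # all C(5,2) assignments enumerated
  expect_equal(unname(p["p_low"]), 1)

  tied <- directional_pvalues(high = rep(2, 4), low = rep(2, 5))
  expect_true(all(tied >= 0.5))

  set.seed(8)
  for (i in 1:20) {
    hi <- rnorm(sample(8:15, 1))
    lo <- rnorm(sample(8:15, 1))
    p <- directional_pvalues(hi, lo)
    # the two one-sided tails overlap only by the (small) point mass at the
    # observed statistic, so their minimum sits essentially at or below 1/2
    expect_lte(min(p), 0.55)
    expect_gte(sum(p), 1 - 1e-9)
  }
})

test_that("Fisher combination satisfies its identities", {
  expect_equal(fisher_combine(0.05), 0.05, tolerance = 1e-12)
  expect_equal(fisher_combine(rep(1, 4)), 1)
  # numerical-integration oracle for four P = 0.5, X = 5.545, df 8
  oracle <- chisq_tail_oracle(-2 * sum(log(rep(0.5, 4))), 8)
  expect_equal(fisher_combine(rep(0.5, 4)), oracle, tolerance = 1e-9)
  expect_warning(fl <- fisher_combine(c(0, 0.5)), "floored")
  expect_true(fl > 0)
  expect_error(fisher_combine(numeric()), "no P values")
})

test_that("decreasing any component P never increases the combined P", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(4)
    j <- sample(4, 1)
    q <- p
    q[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(q), fisher_combine(p) + 1e-12)
  }
})

test_that("scrambles preserve per-mouse cell counts and are reproducible", {
  cells <- data.frame(cell_barcode = sprintf("c%d", 1:30),
                      mouse_id = rep(c("M1", "M2"), each = 15),
                      stringsAsFactors = FALSE)
  pool <- list(M1 = sprintf("T%d", 1:5), M2 = sprintf("T%d", 6:8))
  s1 <- make_scrambles(cells, pool, n_sets = 10, seed = 4)
  s2 <- make_scrambles(cells, pool, n_sets = 10, seed = 4)
  expect_identical(unclass(s1), unclass(s2))
  expect_equal(dim(s1), c(30, 10))
  # reassignment stays within the mouse
  expect_true(all(s1[1:15, ] %in% pool$M1))
  expect_true(all(s1[16:30, ] %in% pool$M2))
  # with replacement: clone multiplicities generally differ from 1-per-clone
  expect_true(any(apply(s1, 2, function(z) max(table(z[1:15]))) > 3))
})

test_that("false positive scores hit their boundary values", {
  # one threshold, five genes; experimental P's strictly ordered
  p_exp <- matrix(c(1e-8, 1e-3, 0.01, 0.1, 0.5), nrow = 1)
  # controls where no gene reaches the top experimental P
  ctrl_far <- matrix(c(0.2, 0.3, 0.4, 0.6, 0.9), nrow = 1)
  fps <- false_positive_scores(p_exp, list(ctrl_far, ctrl_far, ctrl_far))
  expect_equal(fps[1, 1], 0)  # N_exp 1, median N_ctrl 0
  # identical control and experimental tables: N_exp = median N_ctrl
  fps_eq <- false_positive_scores(p_exp, list(p_exp, p_exp, p_exp))
  expect_true(all(fps_eq == 1))
})

test_that("reversing the output measure swaps the two directions", {
  co <- planted_cohort(list(planted_gene("constant", effect_size = 2)),
                       seed = 21, n_genes = 40)
  cells <- cloneAssoc:::.join_cells(co$qc, co$directory, co$outputs,
                                    "granulocyte")
  mice <- sort(unique(cells$mouse_id))
  pre <- lapply(mice, function(mid) {
    idx <- which(cells$mouse_id == mid)
    X <- t(co$qc$logcounts[, cells$cell_barcode[idx], drop = FALSE])
    list(idx = idx, ranks = apply(X, 2, rank),
         tiesum = apply(X, 2, function(v) {
           tb <- table(v)
           sum(tb^3 - tb)
         }), N = length(idx))
  })
  vals <- sort(unique(cells$value))
  # drop the top value: its high group is empty, which has no mirror image
  thr <- vals[-length(vals)]
  fwd <- cloneAssoc:::.scan_pvalues(pre, cells$value, thr)
  # mirrored thresholds: low group of -v at -t equals high group of v at
  # the next lower candidate, so compare against the shifted grid
  thr_rev <- rev(-vals)[-length(vals)]
  bwd <- cloneAssoc:::.scan_pvalues(pre, -cells$value, thr_rev)
  n <- length(thr)
  expect_equal(fwd$combined$high, bwd$combined$low[n:1, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(fwd$combined$low, bwd$combined$high[n:1, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("a strongly planted gene is significant and nulls typically are not", {
  co <- planted_cohort(list(planted_gene("constant", effect_size = 2,
                                         target_measure = "granulocyte")),
                       seed = 51, n_genes = 200)
  sc <- run_scan(co$qc, co$directory, co$outputs, "granulocyte",
                 n_scrambles = 20, seed = 52)
  s <- sc$summary
  expect_true(s$significant[s$gene == "g0001"])
  expect_lt(mean(s$significant[s$gene != "g0001"]), 0.25)
  # curve accessor agrees with the stored tables
  cv <- association_curve(sc, "g0001", direction = "high")
  expect_equal(nrow(cv), nrow(sc$thresholds))
  expect_equal(cv$neg_log10_p,
               -log10(pmax(sc$combined_p$high[, which(sc$genes == "g0001")],
                           1e-300)))
  # median-split threshold is reported
  expect_true(sc$median_split_rank %in% sc$thresholds$rank)
})

test_that("an empty threshold set yields an empty scan with a warning", {
  co <- planted_cohort(list(), seed = 71, n_genes = 20, clones_per_mouse = 3,
                       cells_per_clone_law = list(meanlog = 0, sdlog = 0))
  expect_warning(
    expect_warning(sc <- run_scan(co$qc, co$directory, co$outputs,
                                  "granulocyte", n_scrambles = 2, seed = 1),
                   "no valid"),
    "empty")
  expect_false(any(sc$summary$significant))
})
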