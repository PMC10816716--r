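test_that("blood clonal abundance follows the %WBC scaling", {
  # arithmetic oracle: 0.20 x 1.00 x 0.50 x 0.6 x 100 = 6 %WBC
  ab <- clonal_abundance_blood(c(B1 = 60, B2 = 40), 20, 100, 50)
  expect_equal(unname(ab["B1"]), 6)
  expect_equal(unname(ab["B2"]), 4)
  # total equals pop x donor x gfp fractions, expressed in %WBC
  expect_equal(sum(ab), 20 * 1 * 0.5)

  one <- clonal_abundance_blood(c(X = 500), 30, 80, 50)
  expect_equal(unname(one), 30 * 0.8 * 0.5)
  expect_equal(unname(clonal_abundance_blood(c(A = 10, B = 0), 20, 100, 100)["B"]), 0)
  expect_error(clonal_abundance_blood(c(A = 0), 20, 100, 100), "undefined")
  expect_error(clonal_abundance_blood(c(A = 5), 120, 100, 100), "percent")
})

test_that("HSC clonal abundance is a percentage of barcoded HSCs", {
  expect_equal(unname(clonal_abundance_hsc(c(B1 = 25, B2 = 75))), c(25, 75))
  expect_equal(unname(clonal_abundance_hsc(c(only = 7))), 100)
  k <- 8
  expect_equal(unname(clonal_abundance_hsc(stats::setNames(rep(3, k), letters[1:k]))),
               rep(100 / k, k))
  expect_error(clonal_abundance_hsc(c(a = 0, b = 0)), "zero")
})

test_that("lineage bias matches the piecewise definition", {
  expect_identical(lineage_bias(0, 0.5, 10, 20), 1)
  expect_identical(lineage_bias(0.5, 0, 10, 20), -1)
  # balanced clone: lineage-normalized ratio 1, arctan(1) = pi/4, bias 0
  expect_equal(lineage_bias(1, 2, 10, 20), 0)
  expect_true(is.na(lineage_bias(0, 0, 10, 20)))
  expect_error(lineage_bias(1, 1, 0, 20), "positive")
})

test_that("continuous bias is antisymmetric under lineage swap", {
  set.seed(42)
  gr <- runif(50, 0.01, 5)
  b <- runif(50, 0.01, 5)
  fwd <- lineage_bias(gr, b, 10, 25)
  rev <- lineage_bias(b, gr, 25, 10)
  expect_equal(fwd, -rev)
  expect_true(all(fwd >= -1 & fwd <= 1))
})

test_that("clone table: HSC sums to 100 per mouse and depth scaling cancels", {
  tr <- toy_tracking(hsc = c(T1 = 10, T2 = 30, T3 = 60),
                     gr = c(T1 = 100, T2 = 300, T3 = 600),
                     b = c(T1 = 50, T2 = 100, T3 = 850))
  tab <- clone_output(tr, toy_meta())
  expect_equal(sum(tab$hsc), 100)
  tr2 <- tr
  tr2$reads <- tr2$reads * 17
  tab2 <- clone_output(tr2, toy_meta())
  for (col in c("hsc", "granulocyte", "b_cell", "total_blood", "bias")) {
    expect_equal(tab2[[col]], tab[[col]])
  }
})

test_that("abundance filters use strict 'lower than' boundaries", {
  meta <- toy_meta()
  # barcodes tuned so T_small sits exactly at, and T_tiny below, 0.001 %WBC
  # of combined blood; max-abundance clone T_big dominates both lineages
  tab <- data.frame(
    mouse_id = "M1",
    tracking_barcode = c("T_big", "T_mid", "T_small", "T_tiny"),
    granulocyte = c(5, 0.05, 0.0005, 0.0002),
    b_cell = c(8, 0.04, 0.0005, 0.0002),
    stringsAsFactors = FALSE
  )
  tab$total_blood <- tab$granulocyte + tab$b_cell
  res <- apply_clone_filters(tab)
  expect_equal(res$passed_global_filter, c(TRUE, TRUE, TRUE, FALSE))
  # T_small: exactly 0.001 total passes ("lower than" excludes)
  expect_true(res$passed_global_filter[3])
  # bias filter: 1% of max in at least one lineage; T_mid has 1% of gr max
  expect_true(res$passed_bias_filter[2])
  expect_false(res$passed_bias_filter[3])
  # most abundant clone passes both
  expect_true(res$passed_bias_filter[1] && res$passed_global_filter[1])
  # failing global implies failing bias
  expect_true(all(res$passed_bias_filter <= res$passed_global_filter))

  # clone at 0.5% of max in BOTH lineages is excluded from bias only
  tab2 <- data.frame(
    mouse_id = "M1", tracking_barcode = c("max", "weak"),
    granulocyte = c(10, 0.05), b_cell = c(10, 0.05),
    stringsAsFactors = FALSE
  )
  tab2$total_blood <- tab2$granulocyte + tab2$b_cell
  res2 <- apply_clone_filters(tab2)
  expect_true(res2$passed_global_filter[2])
  expect_false(res2$passed_bias_filter[2])
})

test_that("derive_measures reports filtered clones only, with totals", {
  tr <- toy_tracking(hsc = c(T1 = 50, T2 = 50),
                     gr = c(T1 = 999999, T2 = 1),
                     b = c(T1 = 999999, T2 = 1))
  tab <- clone_output(tr, toy_meta())
  expect_equal(tab$total_blood, tab$granulocyte + tab$b_cell)
  mv <- derive_measures(tab)
  # T2's blood contribution is far below 0.001 %WBC: absent from all measures
  expect_false("T2" %in% mv$tracking_barcode)
  expect_true(all(c("hsc", "granulocyte", "b_cell", "total_blood", "bias") %in%
                    mv$measure))
})

test_that("measured clone output matches generative truth at high depth", {
  cfg <- synth_config(n_mice = 2, clones_per_mouse = 25, n_genes = 20,
                      depth = 1e6, seed = 77)
  co <- generate_cohort(cfg)
  tab <- clone_output(co$tracking, co$meta)
  m <- merge(as.data.frame(tab), co$truth$clones,
             by = c("mouse_id", "tracking_barcode"), suffixes = c("_obs", "_true"))
  # multinomial sampling at depth 1e6 keeps relative errors small for
  # clones that are not vanishingly rare
  big <- m$granulocyte_true > 0.01
  rel_err <- abs(m$granulocyte_obs[big] - m$granulocyte_true[big]) /
    m$granulocyte_true[big]
  expect_lt(stats::median(rel_err), 0.05)
  expect_equal(cor(m$hsc_obs, m$hsc_true), 1, tolerance = 1e-3)
})
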