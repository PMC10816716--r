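test_that("formula fits recover their generating parameters", {
  x <- 1:60
  flat <- fit_formula(x, rep(3, 60), "constant")
  expect_equal(unname(flat$params["a"]), 3)
  expect_equal(flat$residual, 0)

  y <- 4 * exp(-(x - 40)^2 / (2 * 10^2)) + 1
  g <- fit_formula(x, y, "gaussian")
  expect_equal(unname(g$params[c("b", "mu", "sigma", "c")]), c(4, 40, 10, 1),
               tolerance = 1e-6)
  expect_lt(g$residual, 1e-6)

  ys <- ifelse(x <= 30, 2, 6)
  s <- fit_formula(x, ys, "step")
  expect_equal(unname(s$params[c("d", "e", "f")]), c(2, 6, 30))
  expect_equal(s$residual, 0)
  # exhaustive breakpoint oracle: no other f does better
  sse <- sapply(x[-60], function(f) {
    sum((ys[x <= f] - mean(ys[x <= f]))^2) + sum((ys[x > f] - mean(ys[x > f]))^2)
  })
  expect_equal(x[which.min(sse)], 30)
})

test_that("minimum-degree polynomial stops at the first r2 >= 0.9", {
  x <- 1:50
  line <- fit_polynomial_min_degree(x, 2 * x + 1)
  expect_equal(line$degree, 1)
  expect_equal(line$r2, 1)
  flat <- fit_polynomial_min_degree(x, rep(2, 50))
  expect_equal(flat$degree, 1)
  expect_equal(unname(stats::coef(flat$coef_fit)[2]), 0, tolerance = 1e-10)

  y2 <- 5 * exp(-(x - 15)^2 / 50) + 4 * exp(-(x - 38)^2 / 50)
  fit <- fit_polynomial_min_degree(x, y2)
  expect_gte(fit$r2, 0.9)
  if (fit$degree > 1) {
    # minimality: one degree lower must miss the target
    prev <- stats::lm(y2 ~ poly(x, degree = fit$degree - 1))
    r2_prev <- 1 - sum(stats::residuals(prev)^2) / sum((y2 - mean(y2))^2)
    expect_lt(r2_prev, 0.9)
  }
})

test_that("noiseless curves from every model are classified perfectly", {
  for (cv in curve_grid()) {
    cl <- classify_curve(cv$x, cv$y)
    expect_equal(cl$class, cv$truth,
                 label = sprintf("noiseless %s curve", cv$truth))
  }
})

test_that("noisy curves (sd 0.5) are classified with at least 80% accuracy", {
  set.seed(2718)
  hits <- 0
  total <- 0
  for (rep in 1:2) {
    for (cv in curve_grid()) {
      cl <- classify_curve(cv$x, cv$y + rnorm(length(cv$y), sd = 0.5))
      total <- total + 1
      hits <- hits + (cl$class == cv$truth)
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("every classifiable curve receives exactly one of the four classes", {
  set.seed(99)
  for (i in 1:30) {
    x <- 1:40
    y <- abs(stats::filter(rnorm(40, sd = 2), rep(1, 5), circular = TRUE))
    cl <- classify_curve(x, as.numeric(y))
    expect_true(cl$class %in% c("constant", "discrete", "unimodal", "multimodal"))
    switch(cl$class,
      unimodal = expect_length(cl$peaks, 1),
      multimodal = expect_gte(length(cl$peaks), 2),
      discrete = expect_length(cl$transitions, 1),
      constant = expect_length(c(cl$peaks, cl$transitions), 0)
    )
  }
  short <- classify_curve(1:4, c(1, 2, 3, 4))
  expect_equal(short$class, "unclassifiable")
})

test_that("classification is invariant to monotone re-indexing of x", {
  set.seed(17)
  grid <- curve_grid()
  for (cv in grid[seq(1, length(grid), by = 4)]) {
    y <- cv$y + rnorm(length(cv$y), sd = 0.3)
    base <- classify_curve(cv$x, y)
    # strictly monotone transform, then re-rank back to even spacing
    x2 <- rank(exp(cv$x / 30) + cv$x^1.3)
    expect_equal(classify_curve(x2, y)$class, base$class)
  }
})

test_that("colocalization clusters interior peaks but never boundary peaks", {
  mk_call <- function(gene, peaks, boundary = FALSE, transitions = numeric()) {
    structure(list(gene = gene, class = "unimodal", peaks = peaks,
                   transitions = transitions, boundary_peak = boundary),
              class = "pattern_call")
  }
  calls <- list(mk_call("a", 50), mk_call("b", 51), mk_call("c", 52),
                mk_call("d", 80))
  cl <- colocalize(calls, window = 5)
  expect_equal(unname(table(cl$peak_clusters$cluster)[["1"]]), 3)
  expect_equal(max(cl$peak_clusters$cluster), 2)

  calls2 <- list(mk_call("edge", 1, boundary = TRUE), mk_call("in", 3))
  cl2 <- colocalize(calls2, window = 5)
  expect_false("edge" %in% cl2$peak_clusters$gene)
  expect_true("edge" %in% cl2$boundary_peaks$gene)

  cl0 <- colocalize(list(), window = 5)
  expect_equal(nrow(cl0$peak_clusters), 0)

  # transitions cluster independently of peaks
  calls3 <- list(mk_call("s1", numeric(), transitions = 40),
                 mk_call("s2", numeric(), transitions = 42))
  cl3 <- colocalize(calls3, window = 5)
  expect_equal(max(cl3$transition_clusters$cluster), 1)
})
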