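#' Control parameters for pattern classification
#'
#' Acceptance cutoffs for the sequential fitting cascade and the polynomial
#' peak counting.  Residuals are root-mean-square Euclidean distances between
#' the curve and the fitted line, on the -log10(P) scale.  Because the
#' curves' amplitudes span an order of magnitude (a gene's peak significance
#' scales with its effect), the Gaussian and step cutoffs are expressed
#' relative to the curve's amplitude (range of y), while the constant cutoff
#' is absolute (a flat association is flat on the -log10 P scale regardless
#' of amplitude).  The defaults were calibrated on the synthetic cohort
#' generator so that noiseless curves drawn from each model are classified
#' perfectly and noisy planted cohorts with high accuracy; all are
#' user-adjustable.
#'
#' @param tau_constant accept the constant model if its RMS residual is at
#'   most this, in -log10(P) units (default 1.2).
#' @param gauss_veto best-fit guard on the constant acceptance: a curve is
#'   not constant when the Gaussian model fits it to a near-noiseless level
#'   (RMS residual below `gauss_veto`) while improving substantially on the
#'   constant fit (default 0.25).
#' @param tau_gaussian accept the Gaussian model if its RMS residual is at
#'   most this fraction of the curve amplitude (default 0.085).
#' @param min_peak_drop Gaussian acceptance additionally requires a genuine
#'   interior peak: the fitted curve must fall by at least this fraction of
#'   its height `b` at both ends of the observed range (default 0.25).  A
#'   half-Gaussian pinned to one edge (the typical shape of a one-sided,
#'   discrete association) is thereby passed on to the step model.
#' @param tau_step accept the step model if its RMS residual is at most this
#'   fraction of the curve amplitude (default 0.14).
#' @param prominence minimum prominence of a local maximum of the fitted
#'   polynomial to count as a peak, as a fraction of the curve amplitude
#'   (default 0.05, floored at 0.1 -log10(P) units).
#' @param r2_target polynomial stopping rule: smallest degree whose r-squared
#'   reaches this (default 0.9).
#' @param max_degree cap on the polynomial degree (default 15, further capped
#'   at n - 2).
#' @param grid_n evaluation grid size for polynomial peak counting
#'   (default 512).
#' @return list of class `classify_control`.
#' @export
classify_control <- function(tau_constant = 1.2, gauss_veto = 0.25,
                             tau_gaussian = 0.085, min_peak_drop = 0.25,
                             tau_step = 0.14, prominence = 0.05,
                             r2_target = 0.9, max_degree = 15, grid_n = 512) {
  structure(list(
    tau_constant = tau_constant, gauss_veto = gauss_veto,
    tau_gaussian = tau_gaussian, min_peak_drop = min_peak_drop,
    tau_step = tau_step, prominence = prominence, r2_target = r2_target,
    max_degree = max_degree, grid_n = grid_n
  ), class = "classify_control")
}

#' Fit one association-model formula to a curve
#'
#' The three parametric models of the classification cascade:
#' * `constant`: `y = a` (least-squares mean);
#' * `gaussian`: `y = b * exp(-(x - mu)^2 / (2 sigma^2)) + c`, nonlinear
#'   least squares (Levenberg-Marquardt) with multi-start initialisation
#'   (`mu` at the argmax and at the quartiles of `x`, `sigma` at an eighth,
#'   quarter and half of the range, `b` at the range of `y`, `c` at its
#'   minimum);
#' * `step`: `y = d` for `x <= f`, `e` for `x > f`, solved exactly by
#'   exhaustive search of the breakpoint over observed `x` values with
#'   segment means.
#'
#' @param x,y numeric curve coordinates (equal length >= 5; `x` strictly
#'   increasing).
#' @param formula one of `"constant"`, `"gaussian"`, `"step"`.
#' @return list of class `formula_fit`: `formula`, `params` (named),
#'   `fitted`, `residual` (RMS Euclidean distance; `Inf` if the Gaussian fit
#'   failed to converge from every start).
#' @export
fit_formula <- function(x, y, formula = c("constant", "gaussian", "step")) {
  formula <- match.arg(formula)
  .check_curve(x, y)
  fit <- switch(formula,
    constant = {
      a <- mean(y)
      list(params = c(a = a), fitted = rep(a, length(y)))
    },
    gaussian = .fit_gaussian(x, y),
    step = .fit_step(x, y)
  )
  if (is.null(fit)) {
    return(structure(list(formula = formula, params = NULL, fitted = NULL,
                          residual = Inf, converged = FALSE),
                     class = "formula_fit"))
  }
  structure(list(
    formula = formula, params = fit$params, fitted = fit$fitted,
    residual = sqrt(mean((y - fit$fitted)^2)), converged = TRUE
  ), class = "formula_fit")
}

#' Minimum-degree polynomial fit
#'
#' Fits polynomials of ascending degree and returns the first whose
#' r-squared reaches `r2_target`; if no degree up to the cap reaches it, the
#' best fit found is returned with `reached_target = FALSE`.
#'
#' @inheritParams fit_formula
#' @param r2_target target coefficient of determination (default 0.9).
#' @param max_degree degree cap (default `min(15, n - 2)`).
#' @return list of class `formula_fit` with `formula = "polynomial"`,
#'   `degree`, `r2`, `reached_target`, `coef_fit` (the `lm` object),
#'   `fitted` and `residual`.
#' @export
fit_polynomial_min_degree <- function(x, y, r2_target = 0.9,
                                      max_degree = min(15, length(x) - 2)) {
  .check_curve(x, y)
  sst <- sum((y - mean(y))^2)
  best <- NULL
  for (d in seq_len(max(1, max_degree))) {
    fit <- stats::lm(y ~ poly(x, degree = d))
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    cand <- list(degree = d, r2 = r2, coef_fit = fit,
                 fitted = unname(stats::fitted(fit)))
    if (is.null(best) || r2 > best$r2) best <- cand
    if (r2 >= r2_target) {
      best <- cand
      break
    }
  }
  structure(list(
    formula = "polynomial", degree = best$degree, r2 = best$r2,
    reached_target = best$r2 >= r2_target, coef_fit = best$coef_fit,
    params = stats::coef(best$coef_fit), fitted = best$fitted,
    residual = sqrt(mean((y - best$fitted)^2)), converged = TRUE
  ), class = "formula_fit")
}

#' Classify an association curve
#'
#' The sequential cascade assigning one of the four association patterns to
#' a gene's -log10(combined P) curve over output rank:
#' 1. accept **constant** if the constant fit's RMS residual is within
#'    `tau_constant` and the Gaussian model does not fit the curve to a
#'    near-noiseless level while improving substantially on it (best-fit
#'    guard, see [classify_control()]);
#' 2. else accept **unimodal** if the Gaussian fit is within `tau_gaussian`
#'    of the curve amplitude, has positive height and a genuine interior
#'    peak (peak = fitted `mu`, clamped to the observed range; a peak at the
#'    boundary sets the boundary flag);
#' 3. else accept **discrete** if the step fit is within `tau_step` of the
#'    curve amplitude (transition = fitted breakpoint `f`);
#' 4. else fit the minimum-degree polynomial reaching r-squared 0.9 and count
#'    the local maxima of the fitted curve (prominence at least
#'    `prominence` of the amplitude): one peak (or none, a boundary case)
#'    gives **unimodal**, two or more **multimodal**.
#'
#' The cascade order matters because downstream formulas are strictly more
#' flexible than upstream ones.
#'
#' @param x,y the curve (`x` strictly increasing, length >= 5), or an
#'   `assoc_curve` as `x` with `y` missing.
#' @param control a [classify_control()] list.
#' @return object of class `pattern_call`: list with `class` (one of
#'   `"constant"`, `"discrete"`, `"unimodal"`, `"multimodal"`), `peaks` and
#'   `transitions` (in `x`/rank coordinates), `boundary_peak` flag, `fit`
#'   (the winning `formula_fit`), `route` (`"cascade"` or `"polynomial"`)
#'   and all candidate fits in `fits`.
#' @export
classify_curve <- function(x, y = NULL, control = classify_control()) {
  gene <- NA_character_
  if (inherits(x, "assoc_curve")) {
    gene <- attr(x, "gene")
    y <- x$neg_log10_p
    x <- x$rank
  }
  if (length(x) < 5) {
    return(structure(list(class = "unclassifiable", gene = gene,
                          peaks = numeric(), transitions = numeric(),
                          boundary_peak = FALSE, fit = NULL, fits = NULL,
                          route = NA_character_),
                     class = "pattern_call"))
  }
  .check_curve(x, y)
  amp <- diff(range(y))
  fits <- list(constant = fit_formula(x, y, "constant"),
               gaussian = fit_formula(x, y, "gaussian"),
               step = fit_formula(x, y, "step"))
  rc <- fits$constant$residual
  rg <- fits$gaussian$residual
  call <- NULL
  # a Gaussian fitting to near-noise level while much better than the flat
  # fit reveals real structure, however small the flat residual
  gauss_wins <- is.finite(rg) && rg < control$gauss_veto && rg < 0.5 * rc
  if (rc <= control$tau_constant && !gauss_wins) {
    call <- list(class = "constant", peaks = numeric(), transitions = numeric(),
                 boundary_peak = FALSE, fit = fits$constant, route = "cascade")
  }
  if (is.null(call) && is.finite(rg) && amp > 0 &&
      rg <= control$tau_gaussian * amp &&
      fits$step$residual > control$tau_step * amp) {
    # the step veto mirrors the constant stage's gaussian veto: a curve that
    # a two-plateau step already explains at this level is not unimodal
    prm <- fits$gaussian$params
    drop_frac <- 1 - exp(-(c(min(x), max(x)) - prm["mu"])^2 /
                           (2 * prm["sigma"]^2))
    if (prm["b"] > 0 && all(drop_frac >= control$min_peak_drop)) {
      peak <- min(max(unname(prm["mu"]), min(x)), max(x))
      call <- list(class = "unimodal", peaks = peak, transitions = numeric(),
                   boundary_peak = peak <= min(x) || peak >= max(x),
                   fit = fits$gaussian, route = "cascade")
    }
  }
  if (is.null(call) && amp > 0 && fits$step$residual <= control$tau_step * amp) {
    call <- list(class = "discrete", peaks = numeric(),
                 transitions = unname(fits$step$params["f"]),
                 boundary_peak = FALSE, fit = fits$step, route = "cascade")
  }
  if (is.null(call)) {
    fits$polynomial <- fit_polynomial_min_degree(x, y, control$r2_target,
                                                 min(control$max_degree,
                                                     length(x) - 2))
    pk <- .poly_peaks(fits$polynomial$coef_fit, x, control$grid_n,
                      max(0.1, control$prominence * amp))
    if (!length(pk$peaks)) {
      # monotone fit: the peak sits at (or beyond) the range boundary
      gx <- seq(min(x), max(x), length.out = control$grid_n)
      gy <- stats::predict(fits$polynomial$coef_fit,
                           newdata = data.frame(x = gx))
      pk <- list(peaks = gx[which.max(gy)], boundary = TRUE)
    }
    cls <- if (length(pk$peaks) >= 2) "multimodal" else "unimodal"
    call <- list(class = cls, peaks = pk$peaks, transitions = numeric(),
                 boundary_peak = pk$boundary, fit = fits$polynomial,
                 route = "polynomial")
  }
  structure(c(call, list(fits = fits, gene = gene)), class = "pattern_call")
}

#' Classify all significant genes of a scan
#'
#' @param scan an [run_scan()] result.
#' @param genes genes to classify (default: the scan's significant genes).
#' @param control a [classify_control()] list.
#' @return data.frame with one row per gene: `gene`, `direction`, `class`,
#'   `peaks`, `transitions` (comma-separated rank positions), `peak_frac`
#'   (first peak as a fraction of the candidate rank range), `boundary_peak`,
#'   `residual`, `route`.  The individual `pattern_call` objects are attached
#'   as the `calls` attribute.
#' @export
classify_patterns <- function(scan, genes = NULL, control = classify_control()) {
  if (is.null(genes)) genes <- scan$summary$gene[scan$summary$significant]
  calls <- lapply(genes, function(g) classify_curve(association_curve(scan, g),
                                                    control = control))
  names(calls) <- genes
  n_cand <- attr(scan$thresholds, "n_candidates")
  out <- data.frame(
    gene = genes,
    direction = scan$summary$direction[match(genes, scan$summary$gene)],
    class = vapply(calls, `[[`, "", "class"),
    peaks = vapply(calls, function(cl) paste(round(cl$peaks, 2), collapse = ","), ""),
    transitions = vapply(calls, function(cl) paste(round(cl$transitions, 2), collapse = ","), ""),
    peak_frac = vapply(calls, function(cl) {
      if (length(cl$peaks)) cl$peaks[1] / n_cand else NA_real_
    }, 0),
    boundary_peak = vapply(calls, `[[`, TRUE, "boundary_peak"),
    residual = vapply(calls, function(cl) {
      if (is.null(cl$fit)) NA_real_ else cl$fit$residual
    }, 0),
    route = vapply(calls, `[[`, "", "route"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}

#' Colocalize peaks and transitions across genes
#'
#' Single-linkage grouping of peak positions (and, separately, transition
#' positions) that lie within `window` ranks of each other.  Boundary-flagged
#' peaks cannot be located by the data (their real peak may fall outside the
#' recorded output range), so they are reported separately and never merged
#' into interior clusters.
#'
#' @param calls a [classify_patterns()] data.frame (or list of
#'   `pattern_call`s with a `gene` field).
#' @param window maximum rank gap joining two positions into one cluster.
#' @return list with `peak_clusters` and `transition_clusters` (data.frames
#'   `gene`, `position`, `cluster`) and `boundary_peaks` (data.frame `gene`,
#'   `position`).
#' @export
colocalize <- function(calls, window) {
  if (is.data.frame(calls)) calls <- attr(calls, "calls")
  if (!length(calls)) {
    empty <- data.frame(gene = character(), position = numeric(),
                        cluster = integer())
    return(list(peak_clusters = empty, transition_clusters = empty,
                boundary_peaks = empty[, 1:2]))
  }
  gather <- function(field, drop_boundary) {
    do.call(rbind, lapply(calls, function(cl) {
      pos <- cl[[field]]
      if (drop_boundary && isTRUE(cl$boundary_peak)) pos <- numeric()
      if (!length(pos)) return(NULL)
      data.frame(gene = cl$gene, position = pos, stringsAsFactors = FALSE)
    }))
  }
  cluster1d <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(gene = character(), position = numeric(),
                        cluster = integer()))
    }
    df <- df[order(df$position), , drop = FALSE]
    gaps <- diff(df$position)
    df$cluster <- cumsum(c(1L, as.integer(gaps > window)))
    rownames(df) <- NULL
    df
  }
  boundary <- do.call(rbind, lapply(calls, function(cl) {
    if (isTRUE(cl$boundary_peak) && length(cl$peaks)) {
      data.frame(gene = cl$gene, position = cl$peaks, stringsAsFactors = FALSE)
    } else NULL
  }))
  if (is.null(boundary)) {
    boundary <- data.frame(gene = character(), position = numeric())
  }
  list(
    peak_clusters = cluster1d(gather("peaks", drop_boundary = TRUE)),
    transition_clusters = cluster1d(gather("transitions", drop_boundary = FALSE)),
    boundary_peaks = boundary
  )
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("Association pattern: %s", x$class))
  if (!is.na(x$gene)) cat(sprintf(" (gene %s)", x$gene))
  cat("\n")
  if (length(x$peaks)) {
    cat("  peaks at rank(s):", paste(round(x$peaks, 2), collapse = ", "),
        if (x$boundary_peak) "[boundary]" else "", "\n")
  }
  if (length(x$transitions)) {
    cat("  transition at rank:", paste(round(x$transitions, 2), collapse = ", "), "\n")
  }
  if (!is.null(x$fit)) {
    cat(sprintf("  winning fit: %s, RMS residual %.4g\n",
                x$fit$formula, x$fit$residual))
  }
  invisible(x)
}

#' @export
plot.pattern_call <- function(x, curve = NULL, ...) {
  if (is.null(x$fit)) stop("nothing to plot for an unclassifiable call")
  if (!is.null(curve)) {
    plot(curve$rank, curve$neg_log10_p, pch = 16, col = "grey50",
         xlab = "output rank", ylab = expression(-log[10] ~ "combined P"), ...)
    lines(curve$rank, x$fit$fitted, col = "firebrick", lwd = 2)
    if (length(x$peaks)) {
      points(x$peaks, rep(max(curve$neg_log10_p), length(x$peaks)),
             pch = 25, bg = "red")
    }
  } else {
    plot(x$fit$fitted, type = "l", col = "firebrick", lwd = 2,
         xlab = "index", ylab = "fitted", ...)
  }
  invisible(x)
}

# ---- internals --------------------------------------------------------------

.check_curve <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("curve must have at least 5 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("curve must be finite")
  invisible(NULL)
}

.fit_gaussian <- function(x, y) {
  rng_x <- diff(range(x))
  starts <- expand.grid(
    mu = unique(c(x[which.max(y)], stats::quantile(x, c(0.25, 0.75)))),
    sigma = rng_x * c(1 / 8, 1 / 4, 1 / 2)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b * exp(-(x - mu)^2 / (2 * sigma^2)) + c,
        start = list(b = max(y) - min(y), mu = starts$mu[i],
                     sigma = starts$sigma[i], c = min(y)),
        lower = c(b = -Inf, mu = min(x) - rng_x, sigma = rng_x * 1e-3,
                  c = -Inf),
        upper = c(b = Inf, mu = max(x) + rng_x, sigma = rng_x * 10, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, params = stats::coef(fit),
                   fitted = unname(stats::fitted(fit)))
    }
  }
  best
}

.fit_step <- function(x, y) {
  n <- length(x)
  csum <- cumsum(y)
  csum2 <- cumsum(y^2)
  best <- NULL
  for (i in seq_len(n - 1)) {  # breakpoint f = x[i]; left = 1..i, right = i+1..n
    d <- csum[i] / i
    e <- (csum[n] - csum[i]) / (n - i)
    sse <- (csum2[i] - i * d^2) + (csum2[n] - csum2[i] - (n - i) * e^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(sse = sse, i = i, d = d, e = e)
    }
  }
  fitted <- c(rep(best$d, best$i), rep(best$e, n - best$i))
  list(params = c(d = best$d, e = best$e, f = x[best$i]), fitted = fitted)
}

# local maxima of the fitted polynomial on a dense grid, with prominence;
# maxima at the range ends are kept only at 3x the prominence bar, since the
# polynomial's edge behaviour is its least constrained part
.poly_peaks <- function(fit, x, grid_n, prominence) {
  gx <- seq(min(x), max(x), length.out = grid_n)
  gy <- unname(stats::predict(fit, newdata = data.frame(x = gx)))
  n <- length(gy)
  is_max <- c(gy[1] > gy[2],
              gy[2:(n - 1)] > gy[1:(n - 2)] & gy[2:(n - 1)] >= gy[3:n],
              gy[n] > gy[n - 1])
  idx <- which(is_max)
  if (!length(idx)) {
    return(list(peaks = numeric(), boundary = FALSE))
  }
  keep <- vapply(idx, function(i) {
    # prominence: drop from the peak to the highest of the two bounding
    # minima (to the nearest higher ground, or to the end of the range); a
    # range end with no points beyond it does not bound the prominence
    lo_l <- if (i == 1) {
      -Inf
    } else if (any(gy[seq_len(i - 1)] > gy[i])) {
      j <- max(which(gy[seq_len(i - 1)] > gy[i]))
      min(gy[j:(i - 1)])
    } else {
      min(gy[seq_len(i - 1)])
    }
    lo_r <- if (i == n) {
      -Inf
    } else if (any(gy[seq(i + 1, n)] > gy[i])) {
      j <- i + min(which(gy[seq(i + 1, n)] > gy[i]))
      min(gy[(i + 1):j])
    } else {
      min(gy[seq(i + 1, n)])
    }
    bound <- max(lo_l, lo_r)
    if (!is.finite(bound)) bound <- min(gy)
    bar <- if (i == 1 || i == n) 3 * prominence else prominence
    gy[i] - bound >= bar
  }, TRUE)
  idx <- idx[keep]
  peaks <- gx[idx]
  boundary <- any(idx == 1 | idx == n)
  list(peaks = peaks, boundary = boundary)
}
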