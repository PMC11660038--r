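# CMC estimation from concentration-response titration series by
# continuity-constrained two-segment least squares with a breakpoint
# grid search plus golden-section refinement.

TITRATION_TECHNIQUES <- c("surface_tension", "conductivity",
                          "fluor_intensity_ratio", "fluor_wavelength_shift",
                          "uvvis_peak_wavelength")

# Conventional abscissa per technique: surface tension and fluorescence
# series are analysed against log10(c); conductivity and UV/vis peak
# position against linear concentration.
default_transform <- function(technique) {
  switch(technique,
         surface_tension = "log10",
         conductivity = "linear",
         fluor_intensity_ratio = "log10",
         fluor_wavelength_shift = "log10",
         uvvis_peak_wavelength = "linear",
         stop("unknown technique: ", technique))
}

apply_transform <- function(conc, transform) {
  switch(transform,
         linear = conc,
         log10 = log10(conc),
         ln = log(conc),
         stop("unknown abscissa transform: ", transform))
}

invert_transform <- function(x, transform) {
  switch(transform,
         linear = x,
         log10 = 10^x,
         ln = exp(x))
}

#' Construct a titration series
#'
#' A concentration-response curve from one CMC-determination technique.
#' Points are sorted by concentration; concentrations must be strictly
#' positive and, after sorting, strictly increasing (no duplicates).
#'
#' @param conc Concentrations (wt% or mol L^-1), strictly positive.
#' @param response Measured response (surface tension in mN m^-1,
#'   conductivity in mS cm^-1, fluorescence intensity ratio, wavelength
#'   shift or peak position in nm).
#' @param technique One of `"surface_tension"`, `"conductivity"`,
#'   `"fluor_intensity_ratio"`, `"fluor_wavelength_shift"`,
#'   `"uvvis_peak_wavelength"`.
#' @param conc_unit `"wt_percent"` or `"mol_per_L"`.
#' @param temperature Bath temperature in K.
#' @return A `titration_series` object (data frame with metadata
#'   attributes).
#' @export
titration_series <- function(conc, response,
                             technique = "surface_tension",
                             conc_unit = "wt_percent",
                             temperature = 293) {
  technique <- match.arg(technique, TITRATION_TECHNIQUES)
  conc_unit <- match.arg(conc_unit, c("wt_percent", "mol_per_L"))
  if (length(conc) != length(response)) {
    stop("conc and response must have equal length")
  }
  if (length(conc) < 5) stop("at least 5 points required for any fit")
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be finite and strictly positive")
  }
  if (any(!is.finite(response))) stop("responses must be finite")
  ord <- order(conc)
  conc <- conc[ord]; response <- response[ord]
  if (any(diff(conc) <= 0)) {
    stop("duplicate concentrations are not allowed")
  }
  structure(data.frame(conc = conc, response = response),
            technique = technique, conc_unit = conc_unit,
            temperature = temperature,
            class = c("titration_series", "data.frame"))
}

# Continuous two-segment model on transformed abscissa x with kink at c:
#   y = a + b1*(x - c)           for x <= c
#   y = a + b2*(x - c)           for x >  c
# Linear in (a, b1, b2) for fixed c; solved by least squares.
two_segment_rss <- function(x, y, c0, constrain_post_slope_zero = FALSE) {
  d <- x - c0
  X <- if (constrain_post_slope_zero) {
    cbind(1, pmin(d, 0))
  } else {
    cbind(1, pmin(d, 0), pmax(d, 0))
  }
  fit <- stats::.lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(rss = rss, coef = fit$coefficients)
}

#' Fit a continuous two-segment (breakpoint) model to a titration series
#'
#' Estimates the CMC as the abscissa of the kink in a continuous
#' two-phase linear model fitted by least squares. The breakpoint is
#' searched on a coarse grid at the observed abscissae (keeping at least
#' 3 points on each side) and then refined by golden-section search
#' between the bracketing grid points. A one-segment (single line) model
#' is compared against the two-segment model by an F-test; the breakpoint
#' is reported as `detected = FALSE` when the one-segment fit is not
#' rejected at `alpha`.
#'
#' @param series A [titration_series()].
#' @param abscissa_transform `"linear"`, `"log10"`, `"ln"`, or `NULL` to
#'   use the technique's convention (log10 for surface tension and
#'   fluorescence, linear for conductivity and UV/vis).
#' @param constrain_post_slope_zero If `TRUE` the post-breakpoint segment
#'   is horizontal (the surface-tension plateau convention).
#' @param alpha Significance level of the one- vs two-segment F-test.
#' @return List of class `breakpoint_estimate` with `cmc` (concentration
#'   units of the input), `cmc_transformed`, `slopes` (pre, post, per
#'   transformed-abscissa unit), `intercepts`, `abscissa_transform`,
#'   `rss`, `rss_one_segment`, `f_pvalue`, `detected`, and `ci95`
#'   (`NA` until [bootstrap_breakpoint_ci()] is run).
#' @examples
#' s <- titration_series(seq(0.1, 1, length.out = 11),
#'                       c(seq(60, 40, length.out = 6),
#'                         rep(40, 5)),
#'                       technique = "surface_tension")
#' fit_two_segment(s, abscissa_transform = "linear")$cmc
#' @export
fit_two_segment <- function(series, abscissa_transform = NULL,
                            constrain_post_slope_zero = FALSE,
                            alpha = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 5) stop("at least 5 points required")
  if (any(!is.finite(series$response))) stop("responses must be finite")
  if (is.null(abscissa_transform)) {
    abscissa_transform <- default_transform(attr(series, "technique"))
  }
  abscissa_transform <- match.arg(abscissa_transform,
                                  c("linear", "log10", "ln"))
  x <- apply_transform(series$conc, abscissa_transform)
  y <- series$response
  n <- length(x)

  # coarse grid: interior abscissae with >= 3 points per side
  grid <- x[seq(3, n - 2)]
  grid <- grid[grid > x[3] - .Machine$double.eps & grid < x[n - 2] + .Machine$double.eps]
  if (length(grid) < 1) stop("too few points to place a breakpoint with 3 per side")
  rss_grid <- vapply(grid, function(c0) {
    two_segment_rss(x, y, c0, constrain_post_slope_zero)$rss
  }, numeric(1))
  i_best <- which.min(rss_grid)

  # golden-section refinement between the neighbours of the best grid point
  lo <- grid[max(i_best - 1, 1)]
  hi <- grid[min(i_best + 1, length(grid))]
  c_hat <- if (hi > lo) {
    stats::optimize(function(c0) {
      two_segment_rss(x, y, c0, constrain_post_slope_zero)$rss
    }, interval = c(lo, hi), tol = .Machine$double.eps^0.5)$minimum
  } else {
    grid[i_best]
  }
  # keep the better of refined and grid optimum (optimize can miss a
  # boundary minimum by its tolerance)
  if (two_segment_rss(x, y, grid[i_best], constrain_post_slope_zero)$rss <
      two_segment_rss(x, y, c_hat, constrain_post_slope_zero)$rss) {
    c_hat <- grid[i_best]
  }

  best <- two_segment_rss(x, y, c_hat, constrain_post_slope_zero)
  a <- best$coef[1]
  b1 <- best$coef[2]
  b2 <- if (constrain_post_slope_zero) 0 else best$coef[3]

  # one-segment null model
  fit1 <- stats::.lm.fit(cbind(1, x), y)
  rss1 <- sum(fit1$residuals^2)
  p2 <- if (constrain_post_slope_zero) 3 else 4  # a, b1, (b2), c
  df2 <- n - p2
  rss2 <- best$rss
  eps <- .Machine$double.eps * max(sum(y^2), 1)
  if (df2 <= 0) {
    pval <- NA_real_
    detected <- FALSE
  } else if (rss2 <= eps) {
    # exact two-segment fit: detected unless the single line is also exact
    pval <- if (rss1 <= eps) 1 else 0
    detected <- rss1 > eps
  } else {
    fstat <- ((rss1 - rss2) / (p2 - 2)) / (rss2 / df2)
    pval <- stats::pf(fstat, p2 - 2, df2, lower.tail = FALSE)
    detected <- is.finite(pval) && pval < alpha
  }

  cmc <- invert_transform(c_hat, abscissa_transform)
  structure(list(
    cmc = unname(cmc),
    cmc_transformed = unname(c_hat),
    ci95 = c(NA_real_, NA_real_),
    slopes = c(pre = unname(b1), post = unname(b2)),
    intercepts = c(pre = unname(a - b1 * c_hat),
                   post = unname(a - b2 * c_hat)),
    value_at_cmc = unname(a),
    abscissa_transform = abscissa_transform,
    constrain_post_slope_zero = constrain_post_slope_zero,
    rss = unname(rss2),
    rss_one_segment = unname(rss1),
    f_pvalue = unname(pval),
    detected = detected,
    n = n,
    technique = attr(series, "technique"),
    conc_unit = attr(series, "conc_unit")
  ), class = "breakpoint_estimate")
}

#' @export
print.breakpoint_estimate <- function(x, ...) {
  cat(sprintf("Two-segment breakpoint fit (%s, %s abscissa)\n",
              x$technique, x$abscissa_transform))
  if (x$detected) {
    cat(sprintf("  CMC: %.4g %s\n", x$cmc,
                if (x$conc_unit == "wt_percent") "wt%" else "mol/L"))
  } else {
    cat("  no breakpoint detected (one-segment model not rejected)\n")
  }
  if (all(is.finite(x$ci95))) {
    cat(sprintf("  95%% CI: [%.4g, %.4g]\n", x$ci95[1], x$ci95[2]))
  }
  cat(sprintf("  slopes (pre, post): %.4g, %.4g per %s-unit\n",
              x$slopes[1], x$slopes[2], x$abscissa_transform))
  cat(sprintf("  RSS: %.4g (one segment: %.4g, F-test p = %.3g)\n",
              x$rss, x$rss_one_segment, x$f_pvalue))
  invisible(x)
}

#' Predict from a breakpoint fit on the original concentration axis
#'
#' @param object A `breakpoint_estimate`.
#' @param conc Concentrations at which to evaluate the fitted two-segment
#'   model.
#' @param ... Unused.
#' @return Fitted responses.
#' @export
predict.breakpoint_estimate <- function(object, conc, ...) {
  x <- apply_transform(conc, object$abscissa_transform)
  d <- x - object$cmc_transformed
  object$value_at_cmc +
    ifelse(d <= 0, object$slopes[["pre"]] * d, object$slopes[["post"]] * d)
}

#' Residual-resampling bootstrap confidence interval for the CMC
#'
#' Refits the two-segment model to `fitted + resampled residuals` and
#' reports the percentile 2.5/97.5 interval of the breakpoint estimate.
#' Residuals are variance-inflated by `sqrt(n/(n - p))` before
#' resampling (`p` = number of fitted parameters) to undo the downward
#' bias of least-squares residuals, which otherwise narrows the interval
#' noticeably at titration-sized n. Deterministic for a fixed `seed`
#' (the caller's RNG state is left untouched).
#'
#' @inheritParams fit_two_segment
#' @param n_boot Number of bootstrap replicates (default 1000; a warning
#'   is raised below 100).
#' @param seed Integer seed (required).
#' @return The `breakpoint_estimate` from the full-data fit with `ci95`
#'   filled in and a `boot_cmc` vector of replicate breakpoints attached.
#' @export
bootstrap_breakpoint_ci <- function(series, n_boot = 1000, seed,
                                    abscissa_transform = NULL,
                                    constrain_post_slope_zero = FALSE,
                                    alpha = 0.05) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (n_boot < 100) warning("n_boot < 100: percentile interval will be noisy")
  est <- fit_two_segment(series, abscissa_transform,
                         constrain_post_slope_zero, alpha)
  x <- apply_transform(series$conc, est$abscissa_transform)
  fitted <- predict(est, series$conc)
  n_par <- if (constrain_post_slope_zero) 3 else 4
  infl <- sqrt(length(fitted) / max(length(fitted) - n_par, 1))
  resid <- (series$response - fitted) * infl

  boot_cmc <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      y_star <- fitted + sample(resid, length(resid), replace = TRUE)
      s_star <- series
      s_star$response <- y_star
      tryCatch(
        fit_two_segment(s_star, est$abscissa_transform,
                        constrain_post_slope_zero, alpha)$cmc,
        error = function(e) NA_real_
      )
    }, numeric(1))
  })

  fail_frac <- mean(!is.finite(boot_cmc))
  if (fail_frac > 0.2) {
    stop(sprintf("breakpoint fit failed in %.0f%% of bootstrap replicates",
                 100 * fail_frac))
  }
  ci <- unname(stats::quantile(boot_cmc, c(0.025, 0.975), na.rm = TRUE))
  est$ci95 <- ci
  est$boot_cmc <- boot_cmc
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Cross-technique CMC consensus summary
#'
#' Collects per-technique breakpoint estimates and flags pairs whose CMC
#' values differ by more than `max_ratio` (default 10x) — the pattern seen
#' when a fluorescent probe reports a binding transition well below the
#' colligative CMC.
#'
#' @param estimates List of `breakpoint_estimate` objects (or a single
#'   one).
#' @param max_ratio Largest acceptable pairwise ratio between detected
#'   CMCs.
#' @return List of class `cmc_consensus` with a `table` data frame
#'   (technique, cmc, detected, ci), the `agreement` flag, the worst
#'   pairwise `ratio`, and the discordant pair if any.
#' @export
consensus_cmc <- function(estimates, max_ratio = 10) {
  if (inherits(estimates, "breakpoint_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0) stop("at least one estimate required")
  stopifnot(all(vapply(estimates, inherits, logical(1), "breakpoint_estimate")))
  tab <- data.frame(
    technique = vapply(estimates, `[[`, character(1), "technique"),
    cmc = vapply(estimates, `[[`, numeric(1), "cmc"),
    detected = vapply(estimates, `[[`, logical(1), "detected"),
    ci_lo = vapply(estimates, function(e) e$ci95[1], numeric(1)),
    ci_hi = vapply(estimates, function(e) e$ci95[2], numeric(1))
  )
  det <- tab$cmc[tab$detected]
  if (length(det) == 0) stop("no detected breakpoint among the estimates")
  ratio <- max(det) / min(det)
  structure(list(
    table = tab,
    agreement = ratio <= max_ratio,
    ratio = ratio,
    discordant = if (ratio > max_ratio) {
      c(min(det), max(det))
    } else NULL
  ), class = "cmc_consensus")
}

#' @export
print.cmc_consensus <- function(x, ...) {
  cat("Cross-technique CMC summary\n")
  print(x$table, row.names = FALSE)
  if (x$agreement) {
    cat(sprintf("  techniques agree (max pairwise ratio %.2g)\n", x$ratio))
  } else {
    cat(sprintf("  DISCREPANCY: CMCs %.3g vs %.3g differ by %.3gx\n",
                x$discordant[1], x$discordant[2], x$ratio))
  }
  invisible(x)
}
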