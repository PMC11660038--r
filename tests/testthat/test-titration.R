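# Two-segment breakpoint estimation of the CMC

test_that("noiseless piecewise-linear input is recovered exactly, on- and off-grid", {
  # kink planted at a data abscissa: exact hit, zero residual
  s <- make_vshape(cmc = 0.55, conc = seq(0.1, 1, by = 0.05))
  fit <- fit_two_segment(s, abscissa_transform = "linear")
  expect_true(fit$detected)
  expect_equal(fit$cmc, 0.55, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-18)
  expect_equal(unname(fit$slopes), c(-30, 2), tolerance = 1e-9)

  # property loop: random kinks between grid points; breakpoint error
  # bounded by the golden-section tolerance, far below the grid spacing
  set.seed(42)
  conc <- seq(0.1, 1, length.out = 15)
  for (i in 1:20) {
    cmc <- runif(1, conc[4], conc[12])
    pre <- runif(1, -50, -5); post <- runif(1, -1, 5)
    s <- make_vshape(cmc = cmc, pre = pre, post = post, conc = conc)
    fit <- fit_two_segment(s, abscissa_transform = "linear")
    expect_lt(abs(fit$cmc - cmc), diff(conc)[1])
    expect_lt(fit$rss, 1e-10)
    # continuity of the two segments at the kink
    at_kink <- predict(fit, fit$cmc)
    gap <- abs((fit$intercepts[["pre"]] + fit$slopes[["pre"]] * fit$cmc_transformed) -
                 (fit$intercepts[["post"]] + fit$slopes[["post"]] * fit$cmc_transformed))
    expect_lt(gap, 1e-9 * diff(range(s$response)))
    expect_true(fit$detected)
  }
})

test_that("collinear data yield no detected breakpoint", {
  conc <- seq(0.1, 1, length.out = 12)
  s <- titration_series(conc, 5 - 3 * conc, technique = "conductivity")
  fit <- fit_two_segment(s, abscissa_transform = "linear")
  expect_false(fit$detected)
})

test_that("breakpoint location is invariant to affine response rescaling", {
  g <- gen_titration(cmc = 0.4, noise_sigma = 0.6, n = 18, seed = 11)
  f1 <- fit_two_segment(g$series)
  s2 <- g$series
  s2$response <- 3.7 * s2$response - 120
  f2 <- fit_two_segment(s2)
  expect_equal(f1$cmc, f2$cmc, tolerance = 1e-6)
  expect_equal(f1$rss * 3.7^2, f2$rss, tolerance = 1e-6)
})

test_that("plateau-constrained fit holds the post segment horizontal", {
  g <- gen_titration(technique = "surface_tension", cmc = 0.54,
                     noise_sigma = 0.5, n = 15, seed = 1)
  fit <- fit_two_segment(g$series, constrain_post_slope_zero = TRUE)
  expect_identical(unname(fit$slopes[["post"]]), 0)
  expect_true(fit$detected)
  expect_lt(abs(fit$cmc - 0.54), 0.2)
})

test_that("generator-planted CMC is covered by the bootstrap interval", {
  g <- gen_titration(technique = "surface_tension", cmc = 0.54,
                     noise_sigma = 0.5, n = 15, seed = 1)
  est <- bootstrap_breakpoint_ci(g$series, n_boot = 400, seed = 3,
                                 constrain_post_slope_zero = TRUE)
  expect_true(est$ci95[1] <= 0.54 && 0.54 <= est$ci95[2])
})

test_that("bootstrap is deterministic under seed and degenerate on noiseless data", {
  g <- gen_titration(cmc = 0.3, noise_sigma = 0.4, n = 14, seed = 5)
  a <- bootstrap_breakpoint_ci(g$series, n_boot = 200, seed = 9)
  b <- bootstrap_breakpoint_ci(g$series, n_boot = 200, seed = 9)
  expect_identical(a$ci95, b$ci95)
  expect_identical(a$boot_cmc, b$boot_cmc)

  s <- make_vshape(cmc = 0.55, conc = seq(0.1, 1, by = 0.05))
  noiseless <- bootstrap_breakpoint_ci(s, n_boot = 150, seed = 2,
                                       abscissa_transform = "linear")
  expect_lt(diff(noiseless$ci95), 1e-9)
  expect_equal(mean(noiseless$ci95), 0.55, tolerance = 1e-9)
})

test_that("average bootstrap CI width does not shrink as noise grows", {
  width_at <- function(sigma) {
    mean(vapply(1:6, function(sd) {
      g <- gen_titration(cmc = 0.5, noise_sigma = sigma, n = 16, seed = sd)
      diff(bootstrap_breakpoint_ci(g$series, n_boot = 150, seed = sd + 100)$ci95)
    }, numeric(1)))
  }
  w <- c(width_at(0.05), width_at(0.5), width_at(2))
  expect_true(all(diff(w) > -1e-9))
})

test_that("consensus flags order-of-magnitude CMC discrepancies", {
  mk <- function(cmc, tech) {
    e <- fit_two_segment(make_vshape(cmc = 0.5), abscissa_transform = "linear")
    e$cmc <- cmc; e$technique <- tech; e$detected <- TRUE
    e
  }
  ok <- consensus_cmc(list(mk(0.54, "surface_tension"),
                           mk(0.45, "conductivity"),
                           mk(0.3, "uvvis_peak_wavelength")))
  expect_true(ok$agreement)

  bad <- consensus_cmc(list(mk(0.0016, "fluor_intensity_ratio"),
                            mk(0.54, "surface_tension")))
  expect_false(bad$agreement)
  expect_equal(bad$ratio, 0.54 / 0.0016, tolerance = 1e-12)

  single <- consensus_cmc(mk(0.3, "conductivity"))
  expect_true(single$agreement)
  expect_identical(nrow(single$table), 1L)
})

test_that("input validation rejects short, non-finite and malformed series", {
  expect_error(titration_series(1:4, 1:4), "5 points")
  expect_error(titration_series(c(1, 2, 3, 4, 4), 1:5), "duplicate")
  expect_error(titration_series(c(-1, 2, 3, 4, 5), 1:5), "positive")
  expect_error(titration_series(1:5, c(1, 2, NA, 4, 5)), "finite")
  expect_error(bootstrap_breakpoint_ci(make_vshape(), n_boot = 200),
               "seed")
  expect_warning(
    bootstrap_breakpoint_ci(make_vshape(), n_boot = 50, seed = 1,
                            abscissa_transform = "linear"),
    "noisy")
})
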