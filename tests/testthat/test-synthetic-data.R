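# Generators: seed contract, planted truth, dual-implementation oracle

test_that("titration generator honours the seed contract", {
  g1 <- gen_titration(cmc = 0.5, noise_sigma = 0.5, n = 12, seed = 1)
  g1b <- gen_titration(cmc = 0.5, noise_sigma = 0.5, n = 12, seed = 1)
  g2 <- gen_titration(cmc = 0.5, noise_sigma = 0.5, n = 12, seed = 2)
  expect_identical(g1$series$response, g1b$series$response)
  expect_false(identical(g1$series$response, g2$series$response))
  # truth sidecars identical apart from the seed itself
  t1 <- g1$truth; t2 <- g2$truth
  t1$seed <- t2$seed <- NULL
  expect_identical(t1, t2)
})

test_that("noiseless titration output is exactly piecewise linear", {
  g <- gen_titration(technique = "conductivity", cmc = 0.7,
                     pre_slope = 12, post_slope = 5, noise_sigma = 0,
                     n = 15, conc_range = c(0.1, 2), seed = 1)
  fit <- fit_two_segment(g$series)
  expect_lt(abs(fit$cmc - 0.7), 1e-6)
  expect_lt(fit$rss, 1e-16)
})

test_that("wavelength-shift series saturate after the CMC", {
  g <- gen_titration(technique = "fluor_wavelength_shift", cmc = 0.3,
                     pre_slope = -15, post_slope = -15, noise_sigma = 0,
                     n = 12, conc_range = c(0.02, 1), seed = 4)
  expect_identical(g$truth$post_slope, 0)
  post <- g$series$response[g$series$conc > 0.3]
  expect_lt(diff(range(post)), 1e-9)
})

test_that("generator rejects invalid specifications", {
  expect_error(gen_titration(cmc = 5, conc_range = c(0.1, 2), seed = 1),
               "inside")
  expect_error(gen_titration(cmc = 0.5, n = 5, seed = 1), ">= 8")
  expect_error(gen_titration(cmc = 0.5), "seed")
  expect_error(gen_sasa(seed = 1, dt = 0), "dt")
  expect_error(gen_saxs(micelle_model_params(), noise_frac = -1), "non-negative")
  expect_error(gen_saxs(micelle_model_params(), noise_frac = 0.02), "seed")
})

test_that("dual SAXS implementations agree to 1e-8 on noiseless curves", {
  cases <- list(
    micelle_model_params(r_core = 14, r_outer = 30, scale_mic = 2e-6,
                         background = 1e-3),
    micelle_model_params(r_core = 16, r_outer = 30, poly_sigma = 2.5,
                         phi_hs = 0.15, r_hs = 32, scale_mic = 1e-6),
    micelle_model_params(r_core = 14, r_outer = 28, f_mono = 0.03,
                         rg_coil = 12, nu = 0.6, scale_mic = 2e-6,
                         phi_hs = 0.08, background = 5e-4)
  )
  for (p in cases) {
    g <- gen_saxs(p, noise_frac = 0)
    im <- model_intensity(g$curve$q, p)
    expect_lt(max(abs(im - g$curve$intensity) / g$curve$intensity), 1e-8)
  }
})

test_that("SAXS generator noise statistics match the declared model", {
  p <- micelle_model_params(r_core = 14, r_outer = 30, scale_mic = 2e-6,
                            background = 1e-3)
  g <- gen_saxs(p, noise_frac = 0.02, seed = 7)
  base <- gen_saxs(p, noise_frac = 0)$curve$intensity
  z <- (g$curve$intensity - base) / (0.02 * base)
  expect_lt(abs(mean(z)), 0.3)           # standard normal residuals
  expect_lt(abs(sd(z) - 1), 0.3)
  expect_equal(g$curve$sigma, 0.02 * base, tolerance = 1e-12)
})

test_that("planted hard-sphere interactions suppress the low-q intensity", {
  p <- micelle_model_params(r_core = 14, r_outer = 30, phi_hs = 0.15,
                            r_hs = 30, scale_mic = 2e-6)
  g <- gen_saxs(p, noise_frac = 0)
  s_qmin <- hard_sphere_structure_factor(min(g$curve$q), 30, 0.15)
  expect_lt(s_qmin, 1)
  no_sq <- p; no_sq$phi_hs <- 0
  g0 <- gen_saxs(no_sq, noise_frac = 0)
  expect_lt(g0$curve$q[1], 0.006)
  expect_lt(g$curve$intensity[1], g0$curve$intensity[1])
})

test_that("SASA generator plants its plateau ratio and relaxes to S_inf", {
  g <- gen_sasa(S0 = 700, S_inf = 500, tau = 0.2, noise_frac = 0,
                t_max = 4, dt = 0.002, seed = 1)
  expect_equal(g$truth$ap, 1.4, tolerance = 1e-12)
  expect_equal(tail(g$trace$value, 1), 500, tolerance = 1e-6)
  g1 <- gen_sasa(seed = 3); g2 <- gen_sasa(seed = 3)
  expect_identical(g1$trace$value, g2$trace$value)
})
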