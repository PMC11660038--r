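# SAXS micelle model: form factors, structure factor, fitting

test_that("core-shell intensity matches a real-space Fourier oracle", {
  # F(q) = 4 pi int (rho(r) - rho_solv) r^2 sinc(qr) dr, by quadrature
  ri <- 14; ro <- 30; rc <- 0.30; rs <- 0.36; rsol <- 0.333
  oracle <- function(q) {
    f <- function(r, rho) (rho - rsol) * r^2 *
      ifelse(q * r < 1e-12, 1, sin(q * r) / (q * r))
    amp <- 4 * pi * (stats::integrate(f, 0, ri, rho = rc,
                                      rel.tol = 1e-12)$value +
                       stats::integrate(f, ri, ro, rho = rs,
                                        rel.tol = 1e-12)$value)
    amp^2
  }
  q_grid <- c(1e-4, 0.005, 0.02, 0.05, 0.1, 0.2)
  got <- core_shell_sphere_intensity(q_grid, ri, ro, rc, rs, rsol)
  want <- vapply(q_grid, oracle, numeric(1))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("core-shell limits: contrast match, degenerate shell, q -> 0", {
  q <- seq(0.005, 0.4, length.out = 30)
  expect_equal(core_shell_sphere_intensity(q, 10, 25, 0.4, 0.4, 0.4),
               rep(0, length(q)), tolerance = 1e-20)
  # r_core = r_outer: homogeneous sphere of the core contrast
  v <- 4 / 3 * pi * 20^3
  expect_equal(core_shell_sphere_intensity(0, 20, 20, 0.4, 0.9, 0.3),
               (v * (0.4 - 0.3))^2, tolerance = 1e-10)
  # q -> 0 limit of the two-shell amplitude
  vi <- 4 / 3 * pi * 14^3; vo <- 4 / 3 * pi * 30^3
  expect_equal(core_shell_sphere_intensity(0, 14, 30, 0.30, 0.36, 0.333),
               (vo * (0.36 - 0.333) + vi * (0.30 - 0.36))^2,
               tolerance = 1e-12)
  expect_error(core_shell_sphere_intensity(0.1, 30, 14, 0.3, 0.36, 0.33),
               "exceed")
})

test_that("vanishing core reduces to a homogeneous sphere of shell contrast", {
  q <- seq(0.005, 0.3, length.out = 40)
  near <- core_shell_sphere_intensity(q, 1e-5, 25, 0.9, 0.36, 0.333)
  homog <- core_shell_sphere_intensity(q, 25, 25, 0.36, 0.36, 0.333)
  expect_equal(near, homog, tolerance = 1e-8)
})

test_that("generalized coil normalizes and reduces to Debye at nu = 1/2", {
  expect_identical(generalized_gaussian_coil(0, 20, 0.5), 1)
  # Debye closed form at x = (q Rg)^2 = 1
  expect_equal(generalized_gaussian_coil(1 / 20, 20, 0.5),
               2 * (exp(-1) + 1 - 1) / 1, tolerance = 1e-10)
  q <- seq(0.001, 0.5, length.out = 60)
  x <- (q * 18)^2
  debye <- 2 * (exp(-x) + x - 1) / x^2
  expect_equal(generalized_gaussian_coil(q, 18, 0.5), debye,
               tolerance = 1e-6)
  # excluded-volume coil (nu > 1/2) has a shallower high-q power law
  # (q^(-1/nu) vs the Debye q^(-2)), so it sits above at high q
  expect_gt(generalized_gaussian_coil(0.5, 18, 0.6),
            generalized_gaussian_coil(0.5, 18, 0.5))
  expect_error(generalized_gaussian_coil(0.1, 18, 0.2), "nu")
})

test_that("Percus-Yevick structure factor has the exact compressibility limit", {
  for (phi in c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.49)) {
    expect_equal(hard_sphere_structure_factor(0, 25, phi),
                 (1 - phi)^4 / (1 + 2 * phi)^2, tolerance = 1e-10)
  }
  q <- seq(0.005, 0.48, length.out = 50)
  expect_identical(hard_sphere_structure_factor(q, 25, 0), rep(1, 50))
  # large-q limit and positivity
  expect_lt(abs(hard_sphere_structure_factor(50 / 25, 25, 0.3) - 1), 0.01)
  expect_true(all(hard_sphere_structure_factor(q, 25, 0.45) > 0))
  expect_error(hard_sphere_structure_factor(q, 25, 0.64), "0.64")
})

test_that("model intensity reduces to its components and is non-negative", {
  p <- micelle_model_params(r_core = 14, r_outer = 30, poly_sigma = 0,
                            phi_hs = 0, f_mono = 0, scale_mic = 3e-6,
                            background = 2e-3)
  q <- seq(0.005, 0.48, length.out = 80)
  expect_equal(model_intensity(q, p),
               3e-6 * core_shell_sphere_intensity(q, 14, 30, 0.30, 0.36,
                                                  0.333) + 2e-3,
               tolerance = 1e-14)
  full <- micelle_model_params(r_core = 15, r_outer = 30, poly_sigma = 2,
                               phi_hs = 0.15, f_mono = 0.02,
                               scale_mic = 1e-6, background = 1e-3)
  iq <- model_intensity(q, full)
  expect_true(all(iq > 0))
  # forward limit: scale*<F(0)^2>*S(0) + f_mono + background
  i_small <- model_intensity(1e-8, full)
  s0 <- (1 - 0.15)^4 / (1 + 2 * 0.15)^2
  expect_equal(i_small,
               forward_intensity(full) * s0 + 0.02 + 1e-3,
               tolerance = 1e-6)
})

test_that("forward intensity scales quadratically with contrast", {
  p <- micelle_model_params(rho_core = 0.30, rho_shell = 0.36,
                            rho_solv = 0.333, scale_mic = 1)
  half <- micelle_model_params(
    rho_core = 0.333 + (0.30 - 0.333) / 2,
    rho_shell = 0.333 + (0.36 - 0.333) / 2,
    rho_solv = 0.333, scale_mic = 1)
  expect_equal(forward_intensity(half), forward_intensity(p) / 4,
               tolerance = 1e-10)
  p0 <- micelle_model_params(scale_mic = 0)
  expect_identical(forward_intensity(p0), 0)
  # numerical-limit consistency against the full model
  full <- micelle_model_params(r_core = 15, r_outer = 30, poly_sigma = 2,
                               phi_hs = 0, f_mono = 0.02,
                               scale_mic = 1e-6, background = 1e-3)
  expect_equal(forward_intensity(full),
               model_intensity(1e-6, full) - 1e-3 - 0.02,
               tolerance = 1e-6)
})

test_that("fit recovers a noiseless curve started at truth", {
  truth <- micelle_model_params(r_core = 14, r_outer = 30, phi_hs = 0.1,
                                scale_mic = 2e-6, background = 1e-3)
  g <- gen_saxs(truth, noise_frac = 0)
  fit <- fit_saxs(g$curve, truth,
                  fixed = c("rho_core", "rho_shell", "rho_solv",
                            "poly_sigma", "f_mono", "rg_coil", "nu"))
  expect_true(fit$converged)
  expect_lt(fit$chisq_red, 1e-10)
  expect_equal(fit$params$r_core, 14, tolerance = 1e-4)
})

test_that("fit recovers planted geometry from perturbed starts at 2% noise", {
  truth <- micelle_model_params(r_core = 14, r_outer = 30, phi_hs = 0.1,
                                r_hs = 30, scale_mic = 2e-6,
                                background = 1e-3)
  g <- gen_saxs(truth, noise_frac = 0.02, seed = 3)
  init <- truth
  for (nm in c("r_core", "r_outer", "scale_mic", "phi_hs", "r_hs")) {
    init[[nm]] <- truth[[nm]] * 1.2
  }
  fit <- fit_saxs(g$curve, init,
                  fixed = c("rho_core", "rho_shell", "rho_solv",
                            "poly_sigma", "f_mono", "rg_coil", "nu"),
                  multi_start = 4, start_seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$r_core - 14) / 14, 0.05)
  expect_lt(abs(fit$params$r_outer - 30) / 30, 0.05)
  expect_true(!is.null(fit$stderr) && all(is.finite(fit$stderr)))
})

test_that("fit residuals are statistically consistent with injected noise", {
  truth <- micelle_model_params(r_core = 14, r_outer = 30, phi_hs = 0.1,
                                scale_mic = 2e-6, background = 1e-3)
  chi2 <- vapply(1:6, function(sd) {
    g <- gen_saxs(truth, noise_frac = 0.02, seed = sd)
    fit_saxs(g$curve, truth,
             fixed = c("rho_core", "rho_shell", "rho_solv", "poly_sigma",
                       "f_mono", "rg_coil", "nu"))$chisq_red
  }, numeric(1))
  expect_gt(mean(chi2), 0.7)
  expect_lt(mean(chi2), 1.3)
})

test_that("dropping a real monomer term degrades the fit", {
  truth <- micelle_model_params(r_core = 14, r_outer = 30, f_mono = 0.05,
                                rg_coil = 15, nu = 0.5, scale_mic = 2e-6,
                                background = 1e-3)
  g <- gen_saxs(truth, noise_frac = 0.02, seed = 8)
  fixed_common <- c("rho_core", "rho_shell", "rho_solv", "poly_sigma",
                    "rg_coil", "nu", "r_hs", "phi_hs")
  full <- fit_saxs(g$curve, truth, fixed = fixed_common)
  nocoil_init <- truth; nocoil_init$f_mono <- 0
  nocoil <- fit_saxs(g$curve, nocoil_init,
                     fixed = c(fixed_common, "f_mono"))
  expect_gt(nocoil$chisq_red, full$chisq_red)
})

test_that("fit input validation", {
  truth <- micelle_model_params()
  g <- gen_saxs(truth, noise_frac = 0)
  short <- saxs_curve(g$curve$q[1:5], g$curve$intensity[1:5],
                      g$curve$sigma[1:5])
  expect_error(fit_saxs(short, truth), "fewer data points")
  expect_error(fit_saxs(g$curve, truth, fixed = "bogus"), "unknown fixed")
  expect_error(micelle_model_params(r_core = 30, r_outer = 14), "r_core")
  expect_error(micelle_model_params(poly_sigma = 10, r_core = 14), "poly_sigma")
  expect_error(micelle_model_params(phi_hs = 0.7), "phi_hs")
})
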