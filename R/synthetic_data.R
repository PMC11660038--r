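# Seeded synthetic-data generators with planted ground truth. Each
# generator returns (data, truth) so recovery tests consume only what a
# real experiment would provide plus a sidecar of the planted parameters.
#
# The SAXS generator deliberately re-derives the full intensity model by
# direct transcription of the formulas (Simpson-rule polydispersity,
# separately coded form factor, coil and Percus-Yevick terms) and shares
# no helpers with the model code in saxs_model.R: it is the package's
# dual-implementation correctness oracle.

#' Generate a synthetic titration series with a planted CMC
#'
#' Builds a continuous two-segment response on the technique's
#' conventional abscissa transform with the kink planted at `cmc`, and
#' adds i.i.d. Gaussian noise (additive: titration instruments are
#' resolution-limited, not signal-proportional). For
#' `fluor_wavelength_shift` the post-CMC branch saturates to a plateau
#' (post slope forced to zero), mimicking probe-saturation behaviour.
#'
#' @param technique Titration technique (see [titration_series()]).
#' @param cmc Planted breakpoint concentration (within `conc_range`).
#' @param pre_slope,post_slope Segment slopes per transformed-abscissa
#'   unit.
#' @param response_at_cmc Response value at the kink.
#' @param noise_sigma Additive Gaussian noise s.d. (response units).
#' @param n Number of points (>= 8).
#' @param conc_range `(min, max)` concentration range.
#' @param seed Integer seed (required).
#' @param conc_unit Concentration unit flag.
#' @return List with `series` (a [titration_series()]) and `truth` (the
#'   planted parameters, including the abscissa transform used).
#' @export
gen_titration <- function(technique = "surface_tension", cmc = 0.5,
                          pre_slope = -20, post_slope = 0,
                          response_at_cmc = 40,
                          noise_sigma = 0.5, n = 15,
                          conc_range = c(0.05, 2), seed,
                          conc_unit = "wt_percent") {
  if (missing(seed)) stop("an explicit integer seed is required")
  technique <- match.arg(technique, TITRATION_TECHNIQUES)
  if (n < 8) stop("n must be >= 8")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (cmc <= conc_range[1] || cmc >= conc_range[2]) {
    stop("cmc must lie strictly inside conc_range")
  }
  transform <- default_transform(technique)
  if (technique == "fluor_wavelength_shift") post_slope <- 0
  # geometric spacing for log-abscissa techniques, linear otherwise
  conc <- if (transform == "linear") {
    seq(conc_range[1], conc_range[2], length.out = n)
  } else {
    exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n))
  }
  x <- apply_transform(conc, transform)
  xk <- apply_transform(cmc, transform)
  d <- x - xk
  y0 <- response_at_cmc + ifelse(d <= 0, pre_slope * d, post_slope * d)
  y <- local_seed(seed, y0 + stats::rnorm(n, 0, noise_sigma))
  list(
    series = titration_series(conc, y, technique, conc_unit),
    truth = list(technique = technique, cmc = cmc,
                 pre_slope = pre_slope, post_slope = post_slope,
                 response_at_cmc = response_at_cmc,
                 noise_sigma = noise_sigma, n = n,
                 conc_range = conc_range,
                 abscissa_transform = transform, seed = seed)
  )
}

# ---- independent SAXS intensity transcription (generator-only) -------

# f(x) = 3 (sin x - x cos x)/x^3 via spherical Bessel j1: f(x) = 3 j1(x)/x
gen_sphere_ff <- function(x) {
  ifelse(abs(x) < 1e-6, 1, 3 * (sin(x) / x^2 - cos(x) / x) / x)
}

gen_coreshell_amp <- function(q, ri, ro, rc, rs, rsol) {
  (4 * pi / 3) * (ro^3 * (rs - rsol) * gen_sphere_ff(q * ro) +
                    ri^3 * (rc - rs) * gen_sphere_ff(q * ri))
}

# S(q) = 1/(1 - n c_hat(q)) with the Percus-Yevick direct correlation
# function of hard spheres (Wertheim) Fourier-transformed numerically
# (Simpson rule on r in [0, sigma_hs]); independent of the closed-form
# expression used by the model code.
gen_py_sq <- function(q, rhs, phi) {
  if (phi == 0) return(rep(1, length(q)))
  lam1 <- (1 + 2 * phi)^2 / (1 - phi)^4
  lam2 <- -(1 + phi / 2)^2 / (1 - phi)^4
  m <- 2000  # Simpson panels
  x <- seq(0, 1, length.out = m + 1)
  w <- c(1, rep(c(4, 2), length.out = m - 1), 1) / (3 * m)
  cx <- -(lam1 + 6 * phi * lam2 * x + (phi * lam1 / 2) * x^3)
  A <- 2 * q * rhs  # q times the hard-sphere diameter
  vapply(A, function(a) {
    sinc <- if (a == 0) rep(1, length(x)) else {
      ifelse(x == 0, 1, sin(a * x) / (a * x))
    }
    cq <- 24 * phi * sum(w * cx * x^2 * sinc)
    1 / (1 - cq)
  }, numeric(1))
}

gen_debye_generalized <- function(q, rg, nu) {
  u <- q^2 * rg^2 * (2 * nu + 1) * (2 * nu + 2) / 6
  vapply(u, function(uu) {
    if (uu < 1e-10) return(1)
    o2 <- 1 / (2 * nu); o1 <- 1 / nu
    ig <- function(a, z) stats::pgamma(z, a) * gamma(a)
    ig(o2, uu) / (nu * uu^o2) - ig(o1, uu) / (nu * uu^o1)
  }, numeric(1))
}

gen_saxs_noiseless <- function(q, p) {
  shell <- p$r_outer - p$r_core
  ff2 <- if (p$poly_sigma > 0) {
    # Simpson rule over +/- 3 sigma of the core-radius Gaussian
    m <- 400  # panels (even)
    r <- seq(max(p$r_core - 3 * p$poly_sigma, 1e-6),
             p$r_core + 3 * p$poly_sigma, length.out = m + 1)
    wsimp <- c(1, rep(c(4, 2), length.out = m - 1), 1)
    wg <- wsimp * exp(-(r - p$r_core)^2 / (2 * p$poly_sigma^2))
    wg <- wg / sum(wg)
    acc <- 0
    for (k in seq_along(r)) {
      acc <- acc + wg[k] *
        gen_coreshell_amp(q, r[k], r[k] + shell,
                          p$rho_core, p$rho_shell, p$rho_solv)^2
    }
    acc
  } else {
    gen_coreshell_amp(q, p$r_core, p$r_outer,
                      p$rho_core, p$rho_shell, p$rho_solv)^2
  }
  p$scale_mic * ff2 * gen_py_sq(q, p$r_hs, p$phi_hs) +
    (if (p$f_mono > 0) {
      p$f_mono * gen_debye_generalized(q, p$rg_coil, p$nu)
    } else 0) +
    p$background
}

#' Generate a synthetic absolute-scale SAXS curve
#'
#' Computes the noiseless micelle intensity with an independent
#' transcription of the core-shell / coil / Percus-Yevick model (no code
#' shared with [model_intensity()]) and applies multiplicative Gaussian
#' noise `I*(1 + noise_frac*eps)`; the emitted `sigma` column is
#' `noise_frac * I_noiseless`.
#'
#' @param params A [micelle_model_params()] (the planted truth).
#' @param q_grid Scattering vector grid in A^-1; default 120
#'   log-spaced points over the 0.005-0.48 A^-1 window typical of
#'   bioSAXS beamlines.
#' @param noise_frac Fractional noise level (>= 0).
#' @param seed Integer seed (required when `noise_frac > 0`).
#' @return List with `curve` (a [saxs_curve()]) and `truth` (planted
#'   parameters plus the generator settings).
#' @export
gen_saxs <- function(params, q_grid = NULL, noise_frac = 0.02, seed = NULL) {
  validate_micelle_params(params)
  if (noise_frac < 0) stop("noise_frac must be non-negative")
  if (noise_frac > 0 && is.null(seed)) {
    stop("an explicit integer seed is required when noise_frac > 0")
  }
  if (is.null(q_grid)) {
    q_grid <- exp(seq(log(0.005), log(0.48), length.out = 120))
  }
  i0 <- gen_saxs_noiseless(q_grid, params)
  if (noise_frac > 0) {
    eps <- local_seed(seed, stats::rnorm(length(q_grid)))
    intensity <- i0 * (1 + noise_frac * eps)
    sigma <- noise_frac * abs(i0)
  } else {
    intensity <- i0
    sigma <- pmax(0.01 * abs(i0), 1e-12)
  }
  list(
    curve = saxs_curve(q_grid, intensity, sigma),
    truth = list(params = params, noise_frac = noise_frac, seed = seed,
                 noiseless = i0)
  )
}

#' Generate a synthetic SASA equilibration trace
#'
#' Exponential relaxation \eqn{S(t) = S_\infty + (S_0-S_\infty)e^{-t/\tau}}
#' with multiplicative Gaussian noise, emulating the equilibration of the
#' solvent-accessible surface area of an aggregate during an MD run. The
#' planted aggregation propensity is `S0/S_inf`.
#'
#' @param S0 Initial plateau value (nm^2), positive.
#' @param S_inf Final plateau value (nm^2), positive.
#' @param tau Relaxation time in ns, positive.
#' @param noise_frac Fractional Gaussian noise level.
#' @param t_max Trace length in ns.
#' @param dt Sampling interval in ns (positive).
#' @param seed Integer seed (required).
#' @return List with `trace` (a [time_series_trace()]) and `truth`.
#' @export
gen_sasa <- function(S0 = 700, S_inf = 500, tau = 0.5,
                     noise_frac = 0.01, t_max = 4, dt = 0.002, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (dt <= 0) stop("dt must be positive")
  if (S0 <= 0 || S_inf <= 0 || tau <= 0) {
    stop("S0, S_inf and tau must be positive")
  }
  if (noise_frac < 0) stop("noise_frac must be non-negative")
  t <- seq(0, t_max, by = dt)
  s <- S_inf + (S0 - S_inf) * exp(-t / tau)
  v <- if (noise_frac > 0) {
    local_seed(seed, s * (1 + noise_frac * stats::rnorm(length(t))))
  } else s
  v <- pmax(v, 0)
  list(
    trace = time_series_trace(t, v, "sasa"),
    truth = list(S0 = S0, S_inf = S_inf, tau = tau, ap = S0 / S_inf,
                 noise_frac = noise_frac, t_max = t_max, dt = dt,
                 seed = seed)
  )
}
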