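# Absolute-intensity SAXS model for lipopeptide micelles:
#   I(q) = scale_mic * <|F_coreshell|^2>_poly * S_PY(q)
#          + f_mono * P_coil(q) + background
# with Gaussian polydispersity on the core radius (fixed shell thickness),
# a Percus-Yevick hard-sphere structure factor and a generalized
# Gaussian-coil monomer term.

# spherical form-factor amplitude f(x) = 3 (sin x - x cos x) / x^3, f(0)=1
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Core-shell sphere form-factor intensity
#'
#' Per-particle scattered intensity \eqn{|F(q)|^2} of a spherical
#' core-shell particle,
#' \deqn{F(q) = V_o(\rho_{shell}-\rho_{solv})\,f(qR_o)
#'            + V_i(\rho_{core}-\rho_{shell})\,f(qR_i),}
#' with \eqn{f(x) = 3(\sin x - x\cos x)/x^3} and \eqn{V = (4/3)\pi R^3}.
#' Densities may be relative (contrast) values; the overall scale is
#' carried by `scale_mic` in [model_intensity()].
#'
#' @param q Scattering vector magnitudes in A^-1 (non-negative).
#' @param r_core Core radius \eqn{R_i} in A.
#' @param r_outer Outer radius \eqn{R_o} in A (> `r_core`).
#' @param rho_core,rho_shell,rho_solv Electron densities (e A^-3 or any
#'   consistent relative unit).
#' @return \eqn{|F(q)|^2} at each `q` (units: density^2 A^6).
#' @examples
#' core_shell_sphere_intensity(0.01, 14, 30, 0.30, 0.36, 0.333)
#' @export
core_shell_sphere_intensity <- function(q, r_core, r_outer,
                                        rho_core, rho_shell, rho_solv) {
  if (!is.finite(r_core) || !is.finite(r_outer) || r_core <= 0) {
    stop("radii must be positive and finite")
  }
  if (r_core > r_outer) stop("core radius must not exceed outer radius")
  v_i <- 4 / 3 * pi * r_core^3
  v_o <- 4 / 3 * pi * r_outer^3
  amp <- v_o * (rho_shell - rho_solv) * sphere_amplitude(q * r_outer) +
    v_i * (rho_core - rho_shell) * sphere_amplitude(q * r_core)
  amp^2
}

#' Generalized Gaussian coil form factor
#'
#' Normalized form factor of an excluded-volume (generalized Gaussian)
#' polymer coil with Flory exponent \eqn{\nu},
#' \deqn{P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma\!\left(\frac{1}{2\nu},U\right)
#'  - \frac{1}{\nu U^{1/\nu}}\gamma\!\left(\frac{1}{\nu},U\right),\quad
#'  U = \frac{(2\nu+1)(2\nu+2)}{6} q^2 R_g^2,}
#' where \eqn{\gamma} is the lower incomplete gamma function. At
#' \eqn{\nu = 1/2} this reduces to the Debye function
#' \eqn{2(e^{-x}+x-1)/x^2} with \eqn{x = q^2 R_g^2}. P(0) = 1.
#'
#' @param q Scattering vector magnitudes in A^-1.
#' @param rg Radius of gyration in A.
#' @param nu Flory exponent in [0.3, 1].
#' @return Normalized form factor values in (0, 1].
#' @examples
#' generalized_gaussian_coil(1 / 20, 20, 0.5)  # Debye at qRg = 1: 0.7358
#' @export
generalized_gaussian_coil <- function(q, rg, nu = 0.5) {
  if (!is.finite(rg) || rg <= 0) stop("rg must be positive")
  if (!is.finite(nu) || nu < 0.3 || nu > 1.0) {
    stop("Flory exponent nu must lie in [0.3, 1.0]")
  }
  u <- (2 * nu + 1) * (2 * nu + 2) / 6 * (q * rg)^2
  p <- numeric(length(u))
  small <- u < 1e-10
  p[small] <- 1
  us <- u[!small]
  if (length(us)) {
    a1 <- 1 / (2 * nu)
    a2 <- 1 / nu
    # lower incomplete gamma(a, u) = pgamma(u, a) * gamma(a)
    g1 <- stats::pgamma(us, a1) * gamma(a1)
    g2 <- stats::pgamma(us, a2) * gamma(a2)
    p[!small] <- g1 / (nu * us^a1) - g2 / (nu * us^a2)
  }
  p
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic solution of the Ornstein-Zernike equation with the
#' Percus-Yevick closure for monodisperse hard spheres of radius `r_hs`
#' at volume fraction `phi`. \eqn{S(q) \to 1} as \eqn{q \to \infty} and
#' \eqn{S(0) = (1-\phi)^4/(1+2\phi)^2} (the compressibility limit).
#'
#' @param q Scattering vector magnitudes in A^-1.
#' @param r_hs Hard-sphere interaction radius in A.
#' @param phi Hard-sphere volume fraction in [0, 0.64).
#' @return \eqn{S(q)} at each `q`.
#' @examples
#' hard_sphere_structure_factor(0, 20, 0.1)  # 0.4556
#' @export
hard_sphere_structure_factor <- function(q, r_hs, phi) {
  if (!is.finite(phi) || phi < 0) stop("phi must be non-negative")
  if (phi >= 0.64) stop("phi >= 0.64: beyond random close packing, unphysical")
  if (phi == 0) return(rep(1, length(q)))
  if (!is.finite(r_hs) || r_hs <= 0) stop("r_hs must be positive")
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  a <- 2 * q * r_hs
  gg <- numeric(length(a))
  small <- a < 1e-3
  # series limit: 24 phi G(A)/A -> 24 phi (alpha/3 + beta/4 + gamma/6)
  gg24_over_a <- numeric(length(a))
  gg24_over_a[small] <- 24 * phi * (al / 3 + be / 4 + ga / 6)
  as <- a[!small]
  if (length(as)) {
    sa <- sin(as); ca <- cos(as)
    g <- al * (sa - as * ca) / as^2 +
      be * (2 * as * sa + (2 - as^2) * ca - 2) / as^3 +
      ga * (-as^4 * ca +
              4 * ((3 * as^2 - 6) * ca + (as^3 - 6 * as) * sa + 6)) / as^5
    gg24_over_a[!small] <- 24 * phi * g / as
  }
  1 / (1 + gg24_over_a)
}

#' Micelle SAXS model parameters
#'
#' Parameter bundle for [model_intensity()]: core-shell geometry and
#' contrasts, Gaussian polydispersity of the core radius, coil monomer
#' term, hard-sphere structure factor and flat background.
#'
#' @param r_core Core radius \eqn{R_i} in A.
#' @param r_outer Outer radius \eqn{R_o} in A.
#' @param rho_core,rho_shell,rho_solv Electron densities (relative units).
#' @param poly_sigma Gaussian width of the core-radius distribution in A
#'   (shell thickness held fixed); must be < `r_core`/3.
#' @param scale_mic Micelle-term prefactor carrying the cm^-1 absolute
#'   scale.
#' @param f_mono Coil (monomer) term forward intensity in cm^-1.
#' @param rg_coil Monomer coil radius of gyration in A.
#' @param nu Flory exponent of the coil, in [0.3, 1].
#' @param r_hs Hard-sphere radius in A.
#' @param phi_hs Hard-sphere volume fraction in [0, 0.64).
#' @param background Flat background in cm^-1.
#' @return List of class `micelle_model_params`.
#' @export
micelle_model_params <- function(r_core = 14, r_outer = 30,
                                 rho_core = 0.30, rho_shell = 0.36,
                                 rho_solv = 0.333,
                                 poly_sigma = 0, scale_mic = 1,
                                 f_mono = 0, rg_coil = 15, nu = 0.5,
                                 r_hs = 30, phi_hs = 0,
                                 background = 0) {
  p <- list(r_core = r_core, r_outer = r_outer, rho_core = rho_core,
            rho_shell = rho_shell, rho_solv = rho_solv,
            poly_sigma = poly_sigma, scale_mic = scale_mic,
            f_mono = f_mono, rg_coil = rg_coil, nu = nu,
            r_hs = r_hs, phi_hs = phi_hs, background = background)
  validate_micelle_params(p)
  structure(p, class = "micelle_model_params")
}

validate_micelle_params <- function(p) {
  with(p, {
    if (!(r_core > 0 && r_core < r_outer)) {
      stop("require 0 < r_core < r_outer")
    }
    if (poly_sigma < 0 || poly_sigma >= r_core / 3) {
      stop("poly_sigma must lie in [0, r_core/3)")
    }
    if (phi_hs < 0 || phi_hs >= 0.64) stop("phi_hs must lie in [0, 0.64)")
    if (nu < 0.3 || nu > 1.0) stop("nu must lie in [0.3, 1.0]")
    if (scale_mic < 0 || f_mono < 0 || background < 0) {
      stop("prefactors and background must be non-negative")
    }
  })
  invisible(TRUE)
}

# Gaussian polydispersity average of the core-shell intensity over the
# core radius (shell thickness R_o - R_i fixed), +/- 3 sigma, Gauss-
# Legendre quadrature with n_nodes nodes, normalized by the truncated
# Gaussian weight.
polydisperse_core_shell <- function(q, p, n_nodes = 41) {
  if (p$poly_sigma == 0) {
    return(core_shell_sphere_intensity(q, p$r_core, p$r_outer,
                                       p$rho_core, p$rho_shell, p$rho_solv))
  }
  shell_t <- p$r_outer - p$r_core
  lo <- max(p$r_core - 3 * p$poly_sigma, 1e-6)
  hi <- p$r_core + 3 * p$poly_sigma
  gl <- pracma::gaussLegendre(n_nodes, lo, hi)
  w <- gl$w * stats::dnorm(gl$x, p$r_core, p$poly_sigma)
  w <- w / sum(w)
  acc <- numeric(length(q))
  for (k in seq_along(gl$x)) {
    acc <- acc + w[k] * core_shell_sphere_intensity(
      q, gl$x[k], gl$x[k] + shell_t,
      p$rho_core, p$rho_shell, p$rho_solv)
  }
  acc
}

#' Full micelle SAXS intensity model
#'
#' \deqn{I(q) = s_{mic}\,\langle|F_{cs}(q)|^2\rangle_{poly}\,S_{PY}(q)
#'              + f_{mono} P_{coil}(q) + b,}
#' where the polydispersity average is a Gaussian over the core radius
#' (fixed shell thickness, +/- 3 sigma, Gauss-Legendre quadrature) and
#' the structure factor multiplies the averaged micelle term
#' (monodisperse approximation). `f_mono = 0` recovers the micelle-only
#' model.
#'
#' @param q Scattering vector magnitudes in A^-1.
#' @param params A [micelle_model_params()].
#' @param n_nodes Quadrature nodes for the polydispersity average
#'   (>= 21).
#' @return Model intensity in cm^-1 at each `q`.
#' @export
model_intensity <- function(q, params, n_nodes = 41) {
  validate_micelle_params(params)
  if (n_nodes < 21) stop("n_nodes must be >= 21")
  ff <- polydisperse_core_shell(q, params, n_nodes)
  sq <- hard_sphere_structure_factor(q, params$r_hs, params$phi_hs)
  coil <- if (params$f_mono > 0) {
    params$f_mono * generalized_gaussian_coil(q, params$rg_coil, params$nu)
  } else 0
  params$scale_mic * ff * sq + coil + params$background
}

#' Forward (q = 0) intensity of the micelle term
#'
#' Zero-angle limit of the micelle term of [model_intensity()],
#' \eqn{s_{mic}\langle F(0)^2\rangle_{poly}}, excluding the coil term and
#' background. By default the structure factor is also excluded
#' (dilute-limit extrapolation, the convention when I(0) feeds the
#' absolute-intensity molar-mass determination); set
#' `apply_structure_factor = TRUE` to multiply by \eqn{S(0)}.
#'
#' @param params A [micelle_model_params()].
#' @param apply_structure_factor Multiply by the Percus-Yevick
#'   \eqn{S(0)}?
#' @param n_nodes Polydispersity quadrature nodes.
#' @return I(0) in cm^-1.
#' @export
forward_intensity <- function(params, apply_structure_factor = FALSE,
                              n_nodes = 41) {
  validate_micelle_params(params)
  i0 <- params$scale_mic * polydisperse_core_shell(0, params, n_nodes)
  if (apply_structure_factor && params$phi_hs > 0) {
    i0 <- i0 * (1 - params$phi_hs)^4 / (1 + 2 * params$phi_hs)^2
  }
  unname(i0)
}

#' Construct a SAXS curve
#'
#' @param q Scattering vector in A^-1, strictly positive and strictly
#'   increasing.
#' @param intensity Absolute intensity in cm^-1.
#' @param sigma 1-sigma uncertainties in cm^-1 (positive). When `NULL`,
#'   synthesized as 2% of the intensity with a floor at 2% of the median
#'   intensity.
#' @return A `saxs_curve` data frame (columns `q`, `intensity`, `sigma`).
#' @export
saxs_curve <- function(q, intensity, sigma = NULL) {
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (is.null(sigma)) {
    sigma <- pmax(0.02 * abs(intensity), 0.02 * stats::median(abs(intensity)))
  }
  if (length(sigma) != length(q)) stop("sigma length differs from q")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be finite and positive")
  }
  structure(data.frame(q = q, intensity = intensity, sigma = sigma),
            class = c("saxs_curve", "data.frame"))
}

# parameters that may float in fit_saxs, in canonical order
SAXS_PAR_NAMES <- c("r_core", "r_outer", "rho_core", "rho_shell", "rho_solv",
                    "poly_sigma", "scale_mic", "f_mono", "rg_coil", "nu",
                    "r_hs", "phi_hs", "background")

default_saxs_bounds <- function() {
  list(
    lower = c(r_core = 2, r_outer = 4, rho_core = 0, rho_shell = 0,
              rho_solv = 0, poly_sigma = 0, scale_mic = 0, f_mono = 0,
              rg_coil = 2, nu = 0.3, r_hs = 2, phi_hs = 0, background = 0),
    upper = c(r_core = 200, r_outer = 400, rho_core = 1, rho_shell = 1,
              rho_solv = 1, poly_sigma = 50, scale_mic = Inf, f_mono = Inf,
              rg_coil = 500, nu = 1.0, r_hs = 500, phi_hs = 0.6,
              background = Inf)
  )
}

#' Fit the micelle SAXS model by weighted least squares
#'
#' Minimizes \eqn{\sum_i [(I_i - I_{model}(q_i))/\sigma_i]^2} with
#' Levenberg-Marquardt (box-bounded, via \pkg{minpack.lm}). Any subset of
#' parameters can be held fixed by name. Deterministic given `init`; an
#' optional multi-start mode jitters the initial values to guard against
#' local minima.
#'
#' @param curve A [saxs_curve()].
#' @param init A [micelle_model_params()] with the starting values.
#' @param fixed Character vector of parameter names to hold at their
#'   `init` values (e.g. `c("rho_solv", "nu")`).
#' @param lower,upper Named numeric vectors overriding the default box
#'   bounds for any parameter.
#' @param n_nodes Polydispersity quadrature nodes.
#' @param multi_start Number of additional jittered starts (0 = single
#'   deterministic start). Jitter is +/-20% uniform, seeded by
#'   `start_seed`.
#' @param start_seed Seed for the multi-start jitter.
#' @return List of class `saxs_fit` with `params` (fitted
#'   `micelle_model_params`), `free` (names of floated parameters),
#'   `chisq`, `chisq_red`, `dof`, `converged`, `message`, `stderr` (named
#'   parameter standard errors) and `covariance`.
#' @export
fit_saxs <- function(curve, init, fixed = character(),
                     lower = NULL, upper = NULL, n_nodes = 41,
                     multi_start = 0, start_seed = 1) {
  stopifnot(inherits(curve, "saxs_curve"))
  validate_micelle_params(init)
  bad <- setdiff(fixed, SAXS_PAR_NAMES)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  free <- setdiff(SAXS_PAR_NAMES, fixed)
  if (nrow(curve) <= length(free)) {
    stop("fewer data points than free parameters")
  }
  bounds <- default_saxs_bounds()
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper

  p0 <- unlist(init[SAXS_PAR_NAMES])
  resid_fn <- function(theta) {
    p <- as.list(replace(p0, free, theta))
    class(p) <- "micelle_model_params"
    im <- tryCatch(model_intensity(curve$q, p, n_nodes),
                   error = function(e) rep(NA_real_, nrow(curve)))
    r <- (curve$intensity - im) / curve$sigma
    r[!is.finite(r)] <- 1e6
    r
  }

  run_one <- function(theta0) {
    theta0 <- pmin(pmax(theta0, bounds$lower[free]), bounds$upper[free])
    minpack.lm::nls.lm(
      par = theta0, fn = resid_fn,
      lower = bounds$lower[free], upper = bounds$upper[free],
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))
  }

  starts <- list(p0[free])
  if (multi_start > 0) {
    jit <- local_seed(start_seed, {
      lapply(seq_len(multi_start), function(i) {
        p0[free] * stats::runif(length(free), 0.8, 1.2)
      })
    })
    starts <- c(starts, jit)
  }
  fits <- lapply(starts, function(s) tryCatch(run_one(s), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all optimisation starts failed")
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(dev)]]

  theta <- best$par
  p_fit <- as.list(replace(p0, free, theta))
  class(p_fit) <- "micelle_model_params"
  chisq <- sum(resid_fn(theta)^2)
  dof <- nrow(curve) - length(free)
  converged <- best$info %in% 1:4
  cov <- se <- NULL
  jtj <- try(best$hessian, silent = TRUE)
  if (!inherits(jtj, "try-error") && !is.null(jtj)) {
    covt <- try(solve(jtj) * chisq / dof, silent = TRUE)
    if (!inherits(covt, "try-error")) {
      cov <- covt
      se <- sqrt(pmax(diag(cov), 0))
      names(se) <- free
    }
  }
  structure(list(
    params = p_fit, free = free, fixed = fixed,
    chisq = chisq, chisq_red = chisq / dof, dof = dof,
    converged = converged, message = best$message,
    stderr = se, covariance = cov, n_starts = length(starts)
  ), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat("Micelle SAXS model fit\n")
  cat(sprintf("  converged: %s (%s)\n", x$converged, trimws(x$message)))
  cat(sprintf("  chi^2 = %.4g, reduced chi^2 = %.4g (dof = %d)\n",
              x$chisq, x$chisq_red, x$dof))
  for (nm in x$free) {
    se <- if (!is.null(x$stderr) && is.finite(x$stderr[nm])) {
      sprintf(" +/- %.3g", x$stderr[nm])
    } else ""
    cat(sprintf("  %-11s %.5g%s\n", nm, x$params[[nm]], se))
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  }
  invisible(x)
}
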