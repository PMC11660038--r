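# Gibbs adsorption-isotherm analysis of the pre-CMC surface-tension slope:
# surface excess, area per molecule at the air-water interface, and a
# surface-derived micelle association number.

#' Surface excess from the pre-CMC surface-tension slope
#'
#' Applies the Gibbs adsorption equation for a nonionic (or effectively
#' unscreened) surfactant, \eqn{\Gamma = -\frac{1}{nRT}\,d\gamma/d\ln c}.
#'
#' The slope must be expressed per unit natural log of concentration
#' (N m^-1 per ln-unit). A slope measured against \eqn{\log_{10} c} is
#' converted internally when `log_base = 10` (division by \eqn{\ln 10}).
#'
#' @param slope Pre-CMC slope \eqn{d\gamma/d\log c} in N m^-1 per log-unit
#'   of concentration. Negative for a surface-active solute.
#' @param temperature Absolute temperature in K. Default 293 K (20 C).
#' @param log_base Base of the logarithm the slope refers to: `exp(1)`
#'   (default, natural log) or `10`.
#' @param gibbs_n Gibbs prefactor (number of species adsorbing per
#'   molecule); 1 for the nonionic convention used here.
#' @return Surface excess \eqn{\Gamma} in mol m^-2, with attribute
#'   `surface_active` set to `FALSE` (and a warning raised) when the slope
#'   is non-negative.
#' @examples
#' surface_excess(-10.8e-3, temperature = 293)  # ~4.43e-6 mol m^-2
#' @export
surface_excess <- function(slope, temperature = 293, log_base = exp(1),
                           gibbs_n = 1) {
  if (!is.finite(slope)) stop("slope must be finite")
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (K)")
  }
  slope_ln <- slope / log(log_base)
  gamma <- -slope_ln / (gibbs_n * .const$R * temperature)
  surface_active <- slope_ln < 0
  if (!surface_active && slope_ln > 0) {
    warning("positive gamma-vs-ln(c) slope: solute appears surface-inactive; ",
            "returned surface excess is negative")
  }
  structure(gamma, surface_active = surface_active)
}

#' Area per molecule at the air-water interface
#'
#' \eqn{A = 1/(N_A \Gamma)}, reported in square Angstroms
#' (\eqn{10^{20}} A^2 per m^2).
#'
#' @param gamma Surface excess in mol m^-2 (positive).
#' @return Area per molecule in A^2.
#' @examples
#' area_per_molecule(4.42e-6)  # ~37.6 A^2
#' @export
area_per_molecule <- function(gamma) {
  gamma <- as.numeric(gamma)
  if (!is.finite(gamma) || gamma <= 0) {
    stop("surface excess must be positive; got ", format(gamma))
  }
  1e20 / (.const$N_A * gamma)
}

#' Surface-derived micelle association number
#'
#' Divides the surface area of a spherical micelle core,
#' \eqn{a_{mic} = 4\pi R^2}, by the interfacial area per molecule and
#' rounds to the nearest integer.
#'
#' @param radius Micelle core radius in A.
#' @param area Area per molecule in A^2.
#' @return Integer association number \eqn{p \ge 1}.
#' @examples
#' surface_association_number(14, 37.5)  # 66
#' @export
surface_association_number <- function(radius, area) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  p <- as.integer(round(4 * pi * radius^2 / area))
  max(p, 1L)
}

#' Full Gibbs surface analysis
#'
#' Convenience composite: slope -> surface excess -> area per molecule
#' (-> association number when a micelle core radius is given).
#'
#' @inheritParams surface_excess
#' @param radius Optional micelle core radius in A for the surface-derived
#'   association number.
#' @return A list of class `gibbs_analysis` with elements `slope`,
#'   `temperature`, `surface_excess` (mol m^-2), `area_per_molecule` (A^2),
#'   and, when `radius` is supplied, `a_mic` (A^2) and `p_surface`.
#' @examples
#' gibbs_analysis(-13.9e-3, radius = 14)
#' @export
gibbs_analysis <- function(slope, temperature = 293, log_base = exp(1),
                           gibbs_n = 1, radius = NULL) {
  gamma <- surface_excess(slope, temperature, log_base, gibbs_n)
  out <- list(
    slope = slope,
    temperature = temperature,
    surface_excess = as.numeric(gamma),
    area_per_molecule = area_per_molecule(gamma)
  )
  if (!is.null(radius)) {
    out$radius <- radius
    out$a_mic <- 4 * pi * radius^2
    out$p_surface <- surface_association_number(radius, out$area_per_molecule)
  }
  class(out) <- "gibbs_analysis"
  out
}

#' @export
print.gibbs_analysis <- function(x, ...) {
  cat("Gibbs adsorption analysis\n")
  cat(sprintf("  slope d(gamma)/d(ln c): %.4g N m^-1\n", x$slope))
  cat(sprintf("  T: %.1f K\n", x$temperature))
  cat(sprintf("  surface excess: %.3e mol m^-2\n", x$surface_excess))
  cat(sprintf("  area per molecule: %.1f A^2\n", x$area_per_molecule))
  if (!is.null(x$p_surface)) {
    cat(sprintf("  micelle core a_mic (R = %.1f A): %.0f A^2\n",
                x$radius, x$a_mic))
    cat(sprintf("  surface association number p: %d\n", x$p_surface))
  }
  invisible(x)
}
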