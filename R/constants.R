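# Physical constants used throughout. CODATA values except where a specific
# printed precision is conventional in scattering work (r0).

#' Physical constants
#'
#' Named list of the physical constants used by the package:
#' \describe{
#'   \item{R}{molar gas constant, 8.314 J mol^-1 K^-1}
#'   \item{N_A}{Avogadro constant, 6.02214076e23 mol^-1}
#'   \item{r0_cm}{classical electron radius (Thomson scattering length),
#'     0.28179e-12 cm per electron}
#'   \item{rho_water}{electron density of water, 0.333 e A^-3}
#' }
#' @return Named list of constants.
#' @export
micellr_constants <- function() {
  list(
    R = 8.314,              # J mol^-1 K^-1
    N_A = 6.02214076e23,    # mol^-1
    r0_cm = 0.28179e-12,    # cm e^-1
    rho_water = 0.333       # e A^-3
  )
}

.const <- micellr_constants()
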