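# Desk-scale worked example: the complete surface-chemistry and
# forward-scattering chain from printed instrument constants, with no
# curve fitting. Used by the README and the reproduction script.

#' Desk-scale micellization analysis from summary constants
#'
#' Runs the full deterministic analysis chain for one lipopeptide from
#' quantities normally read off instrument output: the pre-CMC
#' surface-tension slope, the micelle core radius, the absolute forward
#' scattering and the monomer molar mass. Returns every intermediate so
#' the arithmetic is auditable.
#'
#' @param slope Pre-CMC d(gamma)/d(ln c) in N m^-1.
#' @param temperature Temperature in K.
#' @param radius Micelle core radius in A.
#' @param i0 Absolute forward scattering in cm^-1 (optional).
#' @param conc_wt Concentration in wt% for the forward-scattering block.
#' @param m_mol Monomer molar mass in g mol^-1.
#' @param n_carbons Tail carbons excluding terminal CH3.
#' @param v_p Partial specific volume in cm^3 g^-1.
#' @return List with the Gibbs block (`surface_excess`,
#'   `area_per_molecule`, `a_mic`, `p_surface`) and, when `i0` is given,
#'   the forward-scattering block (`v_l`, `rho_l`, `delta_rho`, `m_mic`,
#'   `p_forward`).
#' @examples
#' micelle_summary_analysis(slope = -13.9e-3, radius = 14, i0 = 0.11,
#'                          conc_wt = 1, m_mol = 1376.7)
#' @export
micelle_summary_analysis <- function(slope, temperature = 293, radius = 14,
                                     i0 = NULL, conc_wt = 1, m_mol = NULL,
                                     n_carbons = 15, v_p = 1.15) {
  gb <- gibbs_analysis(slope, temperature = temperature, radius = radius)
  out <- list(
    slope = slope,
    temperature = temperature,
    surface_excess = gb$surface_excess,
    area_per_molecule = gb$area_per_molecule,
    a_mic = gb$a_mic,
    p_surface = gb$p_surface
  )
  if (!is.null(i0)) {
    if (is.null(m_mol)) stop("m_mol is required with i0")
    contrast <- contrast_model(n_carbons = n_carbons, v_p = v_p)
    fs <- forward_scatter_analysis(i0, wt_percent_to_g_cm3(conc_wt),
                                   m_mol, contrast)
    out$v_l <- contrast$v_l
    out$rho_l <- contrast$rho_l
    out$delta_rho <- contrast$delta_rho
    out$i0 <- i0
    out$m_mic <- fs$m_mic
    out$p_forward <- fs$p
  }
  out
}
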