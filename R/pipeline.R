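# End-to-end report assembly: per-technique CMC table, Gibbs block,
# SAXS fit block, forward-scattering association-number block and
# aggregation-propensity block, from a flat configuration list or YAML.

#' Run the full micellization analysis pipeline
#'
#' Executes every analysis stage for which the configuration provides
#' inputs and assembles a report; stages with missing inputs are marked
#' absent, and a stage failure is recorded per-stage without aborting the
#' remaining stages.
#'
#' The configuration is a flat named list (or a YAML file path) with
#' explicit units everywhere:
#' \describe{
#'   \item{molecule, m_mol, n_carbons, temperature}{molecule name, monomer
#'     molar mass (g mol^-1), tail carbons excluding CH3, bath T (K).}
#'   \item{titration}{named list technique -> CSV path (or
#'     `titration_series` object).}
#'   \item{gibbs_slope}{pre-CMC d(gamma)/d(ln c) in N m^-1 (when absent,
#'     taken from the surface-tension fit's pre-segment after ln
#'     conversion).}
#'   \item{mic_radius}{micelle core radius in A for the surface
#'     association number.}
#'   \item{saxs_file / saxs_curve, saxs_init, saxs_fixed}{SAXS input and
#'     fit setup.}
#'   \item{i0, conc_wt}{forward intensity (cm^-1) and concentration
#'     (wt%) for the absolute-intensity block; `i0` defaults to the SAXS
#'     fit's [forward_intensity()].}
#'   \item{trace_file / trace}{MD observable trace for the AP block.}
#'   \item{n_boot, seed}{bootstrap settings for the CMC CIs.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param seed Integer seed for all stochastic stages (bootstrap);
#'   overrides `config$seed`.
#' @return List of class `micellr_report` with one element per stage
#'   (`cmc`, `gibbs`, `saxs`, `forward`, `ap`), each either a result, the
#'   string `"absent"`, or an error record `list(error = <message>)`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- if (!is.null(seed)) seed else config$seed %||% 1L
  n_boot <- config$n_boot %||% 1000L
  report <- list(molecule = config$molecule %||% "unnamed",
                 seed = seed)

  stage <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }

  # --- CMC block -----------------------------------------------------
  report$cmc <- if (is.null(config$titration)) "absent" else stage({
    ests <- lapply(names(config$titration), function(tech) {
      src <- config$titration[[tech]]
      s <- if (inherits(src, "titration_series")) src else {
        read_titration_csv(src, technique = tech,
                           temperature = config$temperature %||% 293)
      }
      bootstrap_breakpoint_ci(
        s, n_boot = n_boot, seed = seed,
        constrain_post_slope_zero = identical(tech, "surface_tension"))
    })
    names(ests) <- names(config$titration)
    list(estimates = ests, consensus = consensus_cmc(ests))
  })

  # --- Gibbs block ---------------------------------------------------
  slope <- config$gibbs_slope
  if (is.null(slope) && is.list(report$cmc) && is.null(report$cmc$error) &&
      "surface_tension" %in% names(report$cmc$estimates)) {
    est <- report$cmc$estimates$surface_tension
    # pre-segment slope in mN/m per log-unit -> N/m per ln-unit
    s <- est$slopes[["pre"]] * 1e-3
    if (est$abscissa_transform == "log10") s <- s / log(10)
    slope <- s
  }
  report$gibbs <- if (is.null(slope)) "absent" else stage({
    gibbs_analysis(slope,
                   temperature = config$temperature %||% 293,
                   radius = config$mic_radius)
  })

  # --- SAXS block ----------------------------------------------------
  report$saxs <- if (is.null(config$saxs_file) && is.null(config$saxs_curve)) {
    "absent"
  } else stage({
    curve <- config$saxs_curve %||% read_saxs_dat(config$saxs_file)
    init <- config$saxs_init %||% micelle_model_params()
    fixed <- config$saxs_fixed %||% c("rho_solv", "nu", "rg_coil", "f_mono")
    fit_saxs(curve, init, fixed = fixed)
  })

  # --- forward-scattering block --------------------------------------
  i0 <- config$i0
  if (is.null(i0) && is.list(report$saxs) && is.null(report$saxs$error)) {
    i0 <- forward_intensity(report$saxs$params)
  }
  report$forward <- if (is.null(i0) || is.null(config$m_mol) ||
                        is.null(config$conc_wt)) {
    "absent"
  } else stage({
    contrast <- contrast_model(n_carbons = config$n_carbons %||% 15,
                               v_p = config$v_p %||% 1.15)
    forward_scatter_analysis(i0, wt_percent_to_g_cm3(config$conc_wt),
                             config$m_mol, contrast)
  })

  # --- AP block ------------------------------------------------------
  report$ap <- if (is.null(config$trace_file) && is.null(config$trace)) {
    "absent"
  } else stage({
    trace <- config$trace %||% read_xvg(config$trace_file)
    aggregation_propensity(trace,
                           init_window = config$ap_init_window,
                           final_window = config$ap_final_window)
  })

  class(report) <- "micellr_report"
  report
}

#' Convert wt% concentration to g cm^-3
#'
#' Assumes a dilute aqueous solution of density 1.00 g cm^-3, the
#' convention for sub-percent surfactant solutions (1 wt% = 0.01 g
#' cm^-3).
#'
#' @param wt Concentration in weight percent.
#' @param solution_density Solution density in g cm^-3.
#' @return Mass concentration in g cm^-3.
#' @export
wt_percent_to_g_cm3 <- function(wt, solution_density = 1.00) {
  wt / 100 * solution_density
}

#' Convert wt% to molar concentration
#'
#' @param wt Concentration in weight percent.
#' @param m_mol Molar mass in g mol^-1.
#' @param solution_density Solution density in g cm^-3.
#' @return Concentration in mol L^-1.
#' @export
wt_percent_to_mol_L <- function(wt, m_mol, solution_density = 1.00) {
  wt_percent_to_g_cm3(wt, solution_density) * 1000 / m_mol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.micellr_report <- function(x, ...) {
  cat(sprintf("micellr analysis report: %s (seed %d)\n",
              x$molecule, x$seed))
  block <- function(name, obj) {
    cat("\n==", name, "==\n")
    if (identical(obj, "absent")) {
      cat("  (no input provided)\n")
    } else if (is.list(obj) && !is.null(obj$error)) {
      cat("  stage FAILED:", obj$error, "\n")
    } else if (name == "CMC") {
      print(obj$consensus)
    } else {
      print(obj)
    }
  }
  block("CMC", x$cmc)
  block("Gibbs surface analysis", x$gibbs)
  block("SAXS model fit", x$saxs)
  block("Forward-scattering association number", x$forward)
  block("Aggregation propensity", x$ap)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `micellr_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) x else if (is.list(x)) lapply(unclass(x), strip)
    else unclass(x)
  }
  clean <- strip(unclass(report))
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
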