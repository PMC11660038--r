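# Reduction of MD observable traces (SASA, R_g, RMSD) to the
# aggregation-propensity statistic and an equilibration plateau check.

#' Construct an MD observable time trace
#'
#' @param t Times in ns, strictly increasing.
#' @param value Observable values (SASA in nm^2, R_g or RMSD in nm),
#'   finite and non-negative.
#' @param observable One of `"sasa"`, `"rg"`, `"rmsd"`.
#' @return A `time_series_trace` data frame with metadata attributes.
#' @export
time_series_trace <- function(t, value, observable = c("sasa", "rg", "rmsd")) {
  observable <- match.arg(observable)
  if (length(t) != length(value)) stop("t and value lengths differ")
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("t must be finite and strictly increasing")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("values must be finite and non-negative")
  }
  structure(data.frame(t = t, value = value),
            observable = observable,
            class = c("time_series_trace", "data.frame"))
}

window_idx <- function(trace, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be an increasing (start, end) pair in ns")
  }
  if (window[1] < min(trace$t) - 1e-12 || window[2] > max(trace$t) + 1e-12) {
    stop("window extends beyond the trace time span")
  }
  which(trace$t >= window[1] & trace$t <= window[2])
}

#' Aggregation propensity from an observable trace
#'
#' AP is the ratio of the window-averaged initial value of the observable
#' to its window-averaged final value; AP > 1 indicates compaction
#' (surface burial) over the trajectory. For SASA this is the standard
#' aggregation-propensity statistic. The uncertainty combines the two
#' window standard errors in quadrature on the ratio.
#'
#' @param trace A [time_series_trace()].
#' @param init_window `(start, end)` in ns for the initial average;
#'   default the first 2% of the trace span.
#' @param final_window `(start, end)` in ns for the final average;
#'   default the last 25% of the span. Must not overlap `init_window`.
#' @return List of class `ap_result` with `ap`, `ap_se`, `init_mean`,
#'   `final_mean`, `init_window`, `final_window`, `plateau_ok` (plateau
#'   check on the final window at the default tolerance).
#' @export
aggregation_propensity <- function(trace, init_window = NULL,
                                   final_window = NULL) {
  stopifnot(inherits(trace, "time_series_trace"))
  if (attr(trace, "observable") != "sasa") {
    warning("aggregation propensity is conventionally computed on SASA; ",
            "trace observable is '", attr(trace, "observable"), "'")
  }
  span <- range(trace$t)
  if (is.null(init_window)) {
    init_window <- c(span[1], span[1] + 0.02 * diff(span))
  }
  if (is.null(final_window)) {
    final_window <- c(span[2] - 0.25 * diff(span), span[2])
  }
  if (init_window[2] > final_window[1]) {
    stop("initial and final windows overlap")
  }
  ii <- window_idx(trace, init_window)
  fi <- window_idx(trace, final_window)
  if (length(ii) < 5) stop("initial window contains fewer than 5 samples")
  if (length(fi) < 5) stop("final window contains fewer than 5 samples")
  mi <- mean(trace$value[ii]); mf <- mean(trace$value[fi])
  if (mf <= 0) stop("final-window mean must be positive")
  sei <- stats::sd(trace$value[ii]) / sqrt(length(ii))
  sef <- stats::sd(trace$value[fi]) / sqrt(length(fi))
  ap <- mi / mf
  ap_se <- ap * sqrt((sei / mi)^2 + (sef / mf)^2)
  structure(list(
    ap = ap, ap_se = ap_se,
    init_mean = mi, final_mean = mf,
    init_window = init_window, final_window = final_window,
    n_init = length(ii), n_final = length(fi),
    plateau_ok = plateau_check(trace, final_window)
  ), class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("Aggregation propensity: %.3f +/- %.3f\n", x$ap, x$ap_se))
  cat(sprintf("  initial mean %.4g over [%.3g, %.3g] ns (n = %d)\n",
              x$init_mean, x$init_window[1], x$init_window[2], x$n_init))
  cat(sprintf("  final mean   %.4g over [%.3g, %.3g] ns (n = %d)\n",
              x$final_mean, x$final_window[1], x$final_window[2], x$n_final))
  cat(sprintf("  final-window plateau: %s\n",
              if (x$plateau_ok) "reached" else "NOT reached"))
  invisible(x)
}

#' Plateau (equilibration) check on a trace window
#'
#' `TRUE` when the least-squares slope of the observable over the window,
#' normalized by the window mean, is below `slope_tol` (fractional change
#' per ns). Used to judge whether a simulation observable has
#' equilibrated.
#'
#' @param trace A [time_series_trace()].
#' @param window `(start, end)` in ns.
#' @param slope_tol Tolerance on |slope|/mean in 1/ns (default 0.01,
#'   i.e. 1% per ns).
#' @return Logical.
#' @export
plateau_check <- function(trace, window, slope_tol = 0.01) {
  stopifnot(inherits(trace, "time_series_trace"))
  idx <- window_idx(trace, window)
  if (length(idx) < 5) stop("window contains fewer than 5 samples")
  tt <- trace$t[idx]; vv <- trace$value[idx]
  m <- mean(vv)
  if (m <= 0) return(FALSE)
  slope <- stats::coef(stats::lm.fit(cbind(1, tt), vv))[2]
  abs(slope) / m < slope_tol
}
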