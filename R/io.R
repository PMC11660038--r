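# Plain-text readers and writers for the three input dialects:
# titration CSV (conc,response), 3-column SAXS .dat (q, I, sigma), and
# xvg-style 2-column MD traces; plus JSON truth sidecars.

#' Read a titration series from CSV
#'
#' Expects two columns `conc,response` with a header line; `#` comment
#' lines are skipped. Technique and units are supplied by the caller,
#' never sniffed from the file.
#'
#' @param path CSV file path.
#' @param technique,conc_unit,temperature Passed to [titration_series()].
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, technique = "surface_tension",
                               conc_unit = "wt_percent", temperature = 293) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("conc", "response") %in% names(df))) {
    stop("expected header columns 'conc,response' in ", path)
  }
  titration_series(df$conc, df$response, technique, conc_unit, temperature)
}

#' Write a titration series to CSV
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# technique: %s, conc_unit: %s",
                     attr(series, "technique"), attr(series, "conc_unit")),
             con)
  writeLines("conc,response", con)
  writeLines(sprintf("%.10g,%.10g", series$conc, series$response), con)
  invisible(path)
}

#' Read a SAXS curve from column text
#'
#' Accepts whitespace- or comma-separated 3-column text (q, I, sigma) or
#' 2-column (q, I) with sigma synthesized as 2% of I (floored at 2% of
#' the median intensity); `#` comment lines are skipped. This covers the
#' common beamline `.dat` reductions.
#'
#' @param path File path.
#' @return A [saxs_curve()].
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- gsub(",", " ", lines)
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !(ncol %in% c(2, 3))) {
    stop("expected uniform 2- or 3-column data in ", path)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric data in ", path)
  saxs_curve(m[, 1], m[, 2], if (ncol == 3) m[, 3] else NULL)
}

#' Write a SAXS curve as 3-column text
#'
#' @param curve A [saxs_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q[A^-1]  I[cm^-1]  sigma[cm^-1]", con)
  writeLines(sprintf("%.10g %.10g %.10g", curve$q, curve$intensity,
                     curve$sigma), con)
  invisible(path)
}

#' Read an xvg-style MD observable trace
#'
#' Two-column time/value text skipping lines that start with `@` or `#`
#' (the de facto MD analysis output dialect). Units are declared by the
#' caller, not parsed from headers.
#'
#' @param path File path.
#' @param observable Observable type (see [time_series_trace()]).
#' @param time_unit Unit of the time column; `"ns"` (default) or `"ps"`
#'   (converted to ns).
#' @return A [time_series_trace()].
#' @export
read_xvg <- function(path, observable = "sasa", time_unit = c("ns", "ps")) {
  time_unit <- match.arg(time_unit)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*([@#]|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 2)) stop("expected >= 2 columns in ", path)
  t <- as.numeric(vapply(fields, `[`, character(1), 1))
  v <- as.numeric(vapply(fields, `[`, character(1), 2))
  if (anyNA(t) || anyNA(v)) stop("non-numeric data in ", path)
  if (time_unit == "ps") t <- t / 1000
  time_series_trace(t, v, observable)
}

#' Write a trace in xvg style
#'
#' @param trace A [time_series_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(trace, path) {
  stopifnot(inherits(trace, "time_series_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("@ observable %s", attr(trace, "observable")),
               "@ xaxis label \"Time (ns)\""), con)
  writeLines(sprintf("%.10g %.10g", trace$t, trace$value), con)
  invisible(path)
}

#' Write a generator truth sidecar as JSON
#'
#' @param truth Truth list from a generator.
#' @param path Output path (conventionally `<data>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  truth <- strip(truth)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a generator truth sidecar
#'
#' @param path JSON sidecar path.
#' @return Truth list.
#' @export
read_truth_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
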