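## Physical constants used throughout (SI).
.Rgas <- 8.314      # J / (mol K)
.kB   <- 1.381e-23  # J / K
.h    <- 6.626e-34  # J s

#' Construct a thermogram
#'
#' A thermogram is one thermogravimetric record at a fixed nominal heating
#' rate: sample mass versus time and temperature. Temperatures are stored in
#' kelvin and time in minutes, so the heating rate is in K/min throughout.
#'
#' @param time_min numeric, strictly increasing, minutes.
#' @param temperature_K numeric, kelvin.
#' @param mass_mg numeric, positive, milligrams.
#' @param heating_rate_nominal nominal heating rate in K/min, or `NA`.
#' @param label free-text label carried through to results.
#' @param check validate invariants (monotone time, positive mass, net mass
#'   loss, heating-rate agreement) before returning.
#' @return an object of class `thermogram` (a data frame with attributes
#'   `heating_rate_nominal` and `label`).
#' @export
thermogram <- function(time_min, temperature_K, mass_mg,
                       heating_rate_nominal = NA_real_, label = "",
                       check = TRUE) {
  x <- data.frame(time_min = as.numeric(time_min),
                  temperature_K = as.numeric(temperature_K),
                  mass_mg = as.numeric(mass_mg))
  if (check) {
    if (nrow(x) < 3L)
      stop("a thermogram needs at least 3 samples, got ", nrow(x))
    bad <- which(diff(x$time_min) <= 0)
    if (length(bad))
      stop("time must be strictly increasing; violation at row ", bad[1] + 1L)
    bad <- which(x$mass_mg <= 0)
    if (length(bad))
      stop("mass must be positive; non-positive mass at row ", bad[1])
    if (x$mass_mg[nrow(x)] > x$mass_mg[1])
      stop("final mass exceeds initial mass; not a decomposition record")
    if (is.finite(heating_rate_nominal)) {
      beta_hat <- stats::coef(stats::lm(temperature_K ~ time_min, data = x))[2]
      if (abs(beta_hat - heating_rate_nominal) > 0.05 * heating_rate_nominal)
        warning(sprintf(
          "fitted heating rate %.3f K/min deviates >5%% from nominal %.3f",
          beta_hat, heating_rate_nominal))
    }
  }
  attr(x, "heating_rate_nominal") <- heating_rate_nominal
  attr(x, "label") <- label
  class(x) <- c("thermogram", "data.frame")
  x
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram '%s': %d samples, %.1f-%.1f K, %.3f-%.3f mg, beta = %s K/min\n",
              attr(x, "label"), nrow(x),
              min(x$temperature_K), max(x$temperature_K),
              max(x$mass_mg), min(x$mass_mg),
              format(attr(x, "heating_rate_nominal"))))
  invisible(x)
}

#' Fitted heating rate of a thermogram
#'
#' Ordinary least-squares slope of temperature versus time over the record,
#' in K/min.
#'
#' @param tg a [thermogram()].
#' @return heating rate estimate, K/min.
#' @export
heating_rate <- function(tg) {
  unname(stats::coef(stats::lm(temperature_K ~ time_min, data = tg))[2])
}

.detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))))
  if (all(counts == 0))
    stop("could not auto-detect delimiter (tried comma, tab, semicolon); ",
         "pass `delimiter` explicitly")
  names(counts)[which.max(counts)]
}

#' Read a thermogravimetric record from delimited text
#'
#' Expects a header line and columns `time`, `temperature`, `mass`
#' (any additional columns are ignored). Temperatures may be recorded in
#' Celsius or kelvin; they are converted to kelvin on read, so the two
#' dialects of the same physical record produce identical thermograms.
#'
#' @param path file path.
#' @param unit temperature unit in the file: `"kelvin"` or `"celsius"`.
#' @param delimiter field delimiter; `NULL` auto-detects among
#'   comma / tab / semicolon.
#' @param heating_rate_nominal nominal heating rate, K/min (optional).
#' @param label record label; defaults to the file name.
#' @return a [thermogram()].
#' @export
read_thermogram <- function(path, unit = c("kelvin", "celsius"),
                            delimiter = NULL, heating_rate_nominal = NA_real_,
                            label = basename(path)) {
  unit <- match.arg(unit)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("time", "temperature", "mass")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) < 3L)
    stop("need at least 3 data rows, got ", nrow(raw))
  tempK <- if (unit == "celsius") raw$temperature + 273.15 else raw$temperature
  thermogram(raw$time, tempK, raw$mass,
             heating_rate_nominal = heating_rate_nominal, label = label)
}

#' Write a result table as delimited text
#'
#' Writes any homogeneous result table (activation-energy profiles, peak
#' summaries, thermodynamic tables, ...) with a header line. Numbers are
#' serialized at 17 significant digits so a read-back reproduces the doubles
#' bit-identically.
#'
#' @param rows a non-empty data frame.
#' @param path output file path.
#' @param delimiter field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, delimiter = ",") {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty results table")
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path file path.
#' @param delimiter field delimiter (default comma).
#' @return a data frame.
#' @export
read_results_table <- function(path, delimiter = ",") {
  utils::read.table(path, header = TRUE, sep = delimiter,
                    stringsAsFactors = FALSE)
}
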