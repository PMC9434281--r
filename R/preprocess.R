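#' Default pyrolysis zone bounds (kelvin)
#'
#' Drying/moisture loss up to 400 K, active devolatilization 400-740 K,
#' passive char zone above 760 K. These are the conventional stage bounds
#' for microalgal biomass pyrolysis.
#' @return named numeric vector with `drying_high`, `active_low`,
#'   `active_high`, `passive_low`.
#' @export
default_zones <- function() {
  c(drying_high = 400, active_low = 400, active_high = 740, passive_low = 760)
}

.zone_table <- function(T_range, zones = default_zones()) {
  z <- data.frame(
    zone = c("drying", "active", "passive"),
    T_start = c(T_range[1], zones[["active_low"]], zones[["passive_low"]]),
    T_end = c(zones[["drying_high"]], zones[["active_high"]], T_range[2]))
  z[z$T_start < z$T_end & z$T_start <= T_range[2] & z$T_end >= T_range[1], ]
}

## Central finite-difference gradient on a possibly non-uniform grid.
.fd_gradient <- function(y, x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

.new_conversion_profile <- function(temperature, alpha, dalpha_dT, beta,
                                    w0, wf, zones, smoothed = FALSE) {
  structure(list(temperature = temperature,
                 alpha = alpha,
                 dalpha_dT = dalpha_dT,
                 dalpha_dt = beta * dalpha_dT,
                 heating_rate = beta,
                 w0 = w0, wf = wf,
                 zones = zones,
                 smoothed = smoothed),
            class = "conversion_profile")
}

#' Convert a thermogram to a conversion profile
#'
#' Computes the degree of conversion `alpha = (w0 - w) / (w0 - wf)` over an
#' analysis window, where `w0` and `wf` are the sample masses at the window
#' bounds, together with the conversion rates `dalpha/dT` (central finite
#' differences) and `dalpha/dt = beta * dalpha/dT`. For kinetic analysis the
#' window normally spans the active pyrolysis zone only, so the moisture
#' stage does not contaminate the devolatilization kinetics; for a
#' full-record TG plot pass `window = NULL`.
#'
#' @param tg a [thermogram()].
#' @param window numeric length-2, analysis window in kelvin, or `NULL` for
#'   the full record.
#' @param zones zone bounds as in [default_zones()].
#' @return an object of class `conversion_profile`: list with elements
#'   `temperature`, `alpha`, `dalpha_dT` (1/K), `dalpha_dt` (1/min),
#'   `heating_rate` (K/min), `w0`, `wf` (mg), `zones`, `smoothed`.
#' @export
compute_conversion <- function(tg, window = NULL, zones = default_zones()) {
  stopifnot(inherits(tg, "thermogram"))
  Tspan <- range(tg$temperature_K)
  if (is.null(window)) window <- Tspan
  if (window[1] < Tspan[1] - 1e-9 || window[2] > Tspan[2] + 1e-9)
    stop(sprintf("window [%g, %g] K outside record span [%g, %g] K",
                 window[1], window[2], Tspan[1], Tspan[2]))
  keep <- tg$temperature_K >= window[1] & tg$temperature_K <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 samples inside the window")
  temperature <- tg$temperature_K[keep]
  mass <- tg$mass_mg[keep]
  time <- tg$time_min[keep]
  w0 <- mass[1]
  wf <- mass[length(mass)]
  if (w0 <= wf)
    stop("no mass loss inside the window (w0 <= wf); cannot define conversion")
  alpha <- (w0 - mass) / (w0 - wf)
  ## clip only floating-point overshoot, never real excursions
  alpha[alpha < 0 & alpha > -1e-9] <- 0
  alpha[alpha > 1 & alpha < 1 + 1e-9] <- 1
  beta <- unname(stats::coef(stats::lm(temperature ~ time))[2])
  dadT <- .fd_gradient(alpha, temperature)
  .new_conversion_profile(temperature, alpha, dadT, beta, w0, wf,
                          .zone_table(range(temperature), zones))
}

#' @export
print.conversion_profile <- function(x, ...) {
  cat(sprintf(
    "Conversion profile: %d points, %.1f-%.1f K, beta = %.3g K/min%s\n",
    length(x$temperature), min(x$temperature), max(x$temperature),
    x$heating_rate, if (isTRUE(x$smoothed)) ", smoothed DTG" else ""))
  invisible(x)
}

#' @export
plot.conversion_profile <- function(x, which = c("alpha", "dtg"), ...) {
  which <- match.arg(which)
  if (which == "alpha")
    plot(x$temperature, x$alpha, type = "l", xlab = "Temperature [K]",
         ylab = expression(alpha), ...)
  else
    plot(x$temperature, x$dalpha_dt, type = "l", xlab = "Temperature [K]",
         ylab = expression(d * alpha / d * t ~ "[1/min]"), ...)
  invisible(x)
}

#' @export
as.data.frame.conversion_profile <- function(x, ...) {
  data.frame(temperature_K = x$temperature, alpha = x$alpha,
             dalpha_dT = x$dalpha_dT, dalpha_dt = x$dalpha_dt,
             heating_rate = x$heating_rate)
}

#' Savitzky-Golay smoothing of the conversion derivative
#'
#' Replaces `dalpha/dT` by the derivative of a local polynomial fitted to
#' `alpha(T)` in a moving window (Savitzky-Golay style, but on the actual,
#' possibly non-uniform, temperature abscissa). Near the record ends the
#' window shrinks symmetrically rather than extrapolating. `alpha` itself is
#' left untouched; `dalpha/dt` is refreshed as `beta * dalpha/dT` so the
#' rate-consistency invariant survives smoothing.
#'
#' @param profile a `conversion_profile`.
#' @param window_points odd number of points in the moving window
#'   (default 21).
#' @param poly_order local polynomial order (default 3); must be smaller
#'   than `window_points`.
#' @return the profile with smoothed derivatives (`smoothed = TRUE`).
#' @export
smooth_derivative <- function(profile, window_points = 21L, poly_order = 3L) {
  stopifnot(inherits(profile, "conversion_profile"))
  n <- length(profile$temperature)
  if (window_points %% 2L == 0L)
    stop("window_points must be odd, got ", window_points)
  if (window_points <= poly_order)
    stop("window_points must exceed poly_order")
  if (window_points >= n)
    stop("window_points (", window_points, ") must be smaller than the ",
         "number of samples (", n, ")")
  half <- (window_points - 1L) %/% 2L
  Tv <- profile$temperature
  av <- profile$alpha
  d <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)              # shrink at the ends
    h <- max(h, ceiling(poly_order / 2))       # keep the fit determined
    idx <- max(1L, i - h):min(n, i + h)
    tt <- Tv[idx] - Tv[i]
    p <- min(poly_order, length(idx) - 1L)
    X <- outer(tt, 0:p, `^`)
    cf <- stats::lm.fit(X, av[idx])$coefficients
    d[i] <- cf[2]
  }
  profile$dalpha_dT <- d
  profile$dalpha_dt <- profile$heating_rate * d
  profile$smoothed <- TRUE
  profile
}

#' DTG peak detection inside the active pyrolysis zone
#'
#' Finds the global maximum of `dalpha/dt` inside the active zone (the main
#' devolatilization peak) plus any local maxima exceeding `rel_height` of
#' the main peak's height (multiple overlapping pseudo-component peaks are
#' characteristic of multi-component biomass).
#'
#' @param profile a `conversion_profile` (smooth the derivative first for
#'   noisy records).
#' @param zones zone bounds as in [default_zones()].
#' @param rel_height relative height threshold for secondary peaks
#'   (default 0.2).
#' @return a data frame of class `peak_summary` with columns `T_p` (K),
#'   `rate_at_peak` (1/min), `heating_rate` (K/min), `zone`, `is_main`.
#' @export
detect_peaks <- function(profile, zones = default_zones(), rel_height = 0.2) {
  stopifnot(inherits(profile, "conversion_profile"))
  act <- profile$temperature >= zones[["active_low"]] &
    profile$temperature <= zones[["active_high"]]
  if (!any(act))
    stop("no samples inside the active zone [",
         zones[["active_low"]], ", ", zones[["active_high"]], "] K")
  Ta <- profile$temperature[act]
  r <- profile$dalpha_dt[act]
  i_main <- which.max(r)
  ## strict local maxima on the discrete grid
  loc <- which(diff(sign(diff(r))) == -2) + 1L
  loc <- union(loc, i_main)
  loc <- loc[r[loc] >= rel_height * r[i_main]]
  loc <- loc[order(-r[loc])]
  out <- data.frame(T_p = Ta[loc],
                    rate_at_peak = r[loc],
                    heating_rate = profile$heating_rate,
                    zone = "active",
                    is_main = loc == i_main)
  class(out) <- c("peak_summary", "data.frame")
  out
}

#' Isoconversional table: temperatures and rates at fixed conversions
#'
#' For each heating rate, interpolates the temperature `T_alpha` at which
#' each grid conversion is reached (monotone linear interpolation of `T`
#' as a function of `alpha`) and the conversion rate `dalpha/dt` at that
#' point. This is the common input of all isoconversional estimators.
#'
#' @param profiles list of `conversion_profile`s at distinct heating rates
#'   (at least 2).
#' @param alpha_grid conversions in (0,1); default 0.1-0.8 step 0.05.
#' @return a data frame of class `iso_table` with columns `alpha`, `beta`
#'   (K/min), `T` (K), `rate` (1/min).
#' @export
temperatures_at_conversion <- function(profiles,
                                       alpha_grid = seq(0.1, 0.8, by = 0.05)) {
  if (inherits(profiles, "conversion_profile")) profiles <- list(profiles)
  if (length(profiles) < 2L)
    stop("isoconversional analysis needs at least 2 heating rates, got ",
         length(profiles))
  if (any(alpha_grid <= 0 | alpha_grid >= 1))
    stop("alpha_grid values must lie strictly inside (0, 1)")
  rows <- lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    a <- p$alpha
    if (min(a) > min(alpha_grid) || max(a) < max(alpha_grid))
      stop(sprintf(
        "profile %d (beta = %g K/min) spans alpha [%.4g, %.4g]; cannot cover grid [%g, %g]",
        k, p$heating_rate, min(a), max(a), min(alpha_grid), max(alpha_grid)))
    Tg <- stats::approx(a, p$temperature, xout = alpha_grid,
                        ties = "ordered")$y
    rg <- stats::approx(a, p$dalpha_dt, xout = alpha_grid,
                        ties = "ordered")$y
    data.frame(alpha = alpha_grid, beta = p$heating_rate, T = Tg, rate = rg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("iso_table", "data.frame")
  out
}
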