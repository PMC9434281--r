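#' Combined kinetic analysis (truncated Sestak-Berggren fit)
#'
#' Fits the linearized combined-kinetics equation
#' `ln(dalpha/dt) - ln[(1-alpha)^n alpha^m] = ln(cA) - Ea / (R T)`
#' to one conversion profile: for each candidate exponent pair `(n, m)` the
#' left-hand side is regressed on `1/T`, the pair maximizing R-squared on a
#' coarse grid is refined by bounded local optimization, and the activation
#' energy and `ln(cA)` come from the slope and intercept at the optimum.
#' Standard errors are taken from the covariance of the joint linear model
#' `ln(rate) ~ 1/T + ln(1-alpha) + ln(alpha)` at the optimum.
#'
#' @param profile a `conversion_profile`.
#' @param alpha_range conversions retained for the fit (default
#'   `[0.05, 0.95]`).
#' @param n_bounds,m_bounds search bounds for the exponents (defaults
#'   `[0, 4]` and `[-1, 1]`).
#' @param grid_step coarse-grid step for the `(n, m)` scan (default 0.05).
#' @param r2_floor below this best R-squared the result is flagged
#'   `adequate = FALSE` (default 0.5).
#' @return an object of class `combined_fit` with elements `Ea`
#'   (kJ/mol), `ln_cA` (rate in 1/min), `n`, `m`, their standard errors,
#'   `R2`, `heating_rate`, `n_obs`, `adequate`, `residuals`.
#' @export
combined_kinetics_fit <- function(profile, alpha_range = c(0.05, 0.95),
                                  n_bounds = c(0, 4), m_bounds = c(-1, 1),
                                  grid_step = 0.05, r2_floor = 0.5) {
  stopifnot(inherits(profile, "conversion_profile"))
  keep <- profile$alpha >= alpha_range[1] & profile$alpha <= alpha_range[2] &
    profile$dalpha_dt > 0
  if (sum(keep) < 5L)
    stop("fewer than 5 usable points with positive rate in alpha range [",
         alpha_range[1], ", ", alpha_range[2], "]")
  a <- profile$alpha[keep]
  x <- 1 / profile$temperature[keep]
  lr <- log(profile$dalpha_dt[keep])
  l1 <- log(1 - a)
  l2 <- log(a)
  r2_of <- function(nm) {
    y <- lr - nm[1] * l1 - nm[2] * l2
    r <- suppressWarnings(stats::cor(x, y))
    if (!is.finite(r)) 0 else r^2
  }
  ngrid <- seq(n_bounds[1], n_bounds[2], by = grid_step)
  mgrid <- seq(m_bounds[1], m_bounds[2], by = grid_step)
  best <- c(NA, NA); best_r2 <- -Inf
  for (m in mgrid) {
    r2s <- vapply(ngrid, function(n) r2_of(c(n, m)), 0)
    i <- which.max(r2s)
    if (r2s[i] > best_r2) { best_r2 <- r2s[i]; best <- c(ngrid[i], m) }
  }
  opt <- stats::optim(best, function(nm) -r2_of(nm), method = "L-BFGS-B",
                      lower = c(n_bounds[1], m_bounds[1]),
                      upper = c(n_bounds[2], m_bounds[2]))
  nm <- opt$par
  ## joint linear model at the optimum for coefficients and uncertainties
  fit <- stats::lm(lr ~ x + l1 + l2)
  ## exact oracle data fit perfectly; summary.lm warns about that
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  y <- lr - nm[1] * l1 - nm[2] * l2
  lin <- .ols(x, y)
  out <- structure(list(
    Ea = -lin$slope * .Rgas / 1000,
    Ea_se = lin$se_slope * .Rgas / 1000,
    ln_cA = lin$intercept,
    ln_cA_se = unname(se["(Intercept)"]),
    n = nm[1], n_se = unname(se["l1"]),
    m = nm[2], m_se = unname(se["l2"]),
    R2 = -opt$value,
    heating_rate = profile$heating_rate,
    n_obs = length(a),
    adequate = -opt$value >= r2_floor,
    rate_units = "per_minute",
    residuals = y - lin$intercept - lin$slope * x),
    class = "combined_fit")
  if (!out$adequate)
    warning(sprintf(
      "no adequate model: best R2 = %.3f < %.2f over the (n, m) search space",
      out$R2, r2_floor))
  out
}

#' @export
print.combined_fit <- function(x, ...) {
  cat(sprintf(
    "Combined kinetics fit (beta = %g K/min, %d points, rate in 1/min)%s\n",
    x$heating_rate, x$n_obs, if (x$adequate) "" else "  [NO ADEQUATE MODEL]"))
  cat(sprintf("  Ea    = %8.2f +- %.2f kJ/mol\n", x$Ea, x$Ea_se))
  cat(sprintf("  ln(cA)= %8.2f +- %.2f\n", x$ln_cA, x$ln_cA_se))
  cat(sprintf("  n     = %8.3f +- %.3f\n", x$n, x$n_se))
  cat(sprintf("  m     = %8.3f +- %.3f\n", x$m, x$m_se))
  cat(sprintf("  R2    = %8.4f\n", x$R2))
  invisible(x)
}

#' @export
coef.combined_fit <- function(object, ...) {
  c(Ea = object$Ea, ln_cA = object$ln_cA, n = object$n, m = object$m)
}

#' @export
residuals.combined_fit <- function(object, ...) object$residuals

#' @export
summary.combined_fit <- function(object, ...) {
  data.frame(heating_rate = object$heating_rate,
             Ea = object$Ea, Ea_se = object$Ea_se,
             ln_cA = object$ln_cA, ln_cA_se = object$ln_cA_se,
             n = object$n, n_se = object$n_se,
             m = object$m, m_se = object$m_se,
             R2 = object$R2, n_obs = object$n_obs,
             adequate = object$adequate)
}

#' Combined-kinetics table across heating rates
#'
#' Convenience wrapper running [combined_kinetics_fit()] on each profile
#' and stacking one row per heating rate.
#'
#' @param profiles list of `conversion_profile`s.
#' @param ... passed to [combined_kinetics_fit()].
#' @return data frame, one row per heating rate.
#' @export
combined_kinetics_table <- function(profiles, ...) {
  do.call(rbind, lapply(profiles,
                        function(p) summary(combined_kinetics_fit(p, ...))))
}

#' Master-plot mechanism ranking
#'
#' The Friedman intercepts estimate `ln[A f(alpha)]`, so the experimental
#' reduced model function `f(alpha)/f(0.5) = exp(intercept(alpha) -
#' intercept(0.5))` can be formed without knowing `A` (normalization at
#' `alpha = 0.5` cancels it). It is compared by RMSE over the conversion
#' grid against the theoretical reduced curve of every registered ideal
#' model; smaller RMSE means a more plausible mechanism.
#'
#' @param friedman_profile an `ea_profile` from a Friedman fit.
#' @param models model names to rank (default: the whole registry).
#' @return data frame of class `master_rank` with columns `model`, `rmse`,
#'   ranked ascending; the experimental reduced curve is attached as
#'   attribute `"reduced"`.
#' @export
master_plot_rank <- function(friedman_profile, models = model_registry()) {
  stopifnot(inherits(friedman_profile, "ea_profile"))
  a <- friedman_profile$alpha
  ic <- friedman_profile$intercept
  if (any(!is.finite(ic)))
    stop("master-plot ranking needs finite Friedman intercepts")
  i0 <- which(abs(a - 0.5) < 1e-9)
  ic0 <- if (length(i0)) ic[i0[1]] else {
    if (min(a) > 0.5 || max(a) < 0.5)
      stop("alpha = 0.5 is not bracketed by the profile grid; cannot normalize")
    stats::approx(a, ic, xout = 0.5)$y
  }
  reduced_exp <- exp(ic - ic0)
  rows <- lapply(models, function(nm) {
    mod <- ideal_model(nm)
    reduced_th <- mod$f(a) / mod$f(0.5)
    data.frame(model = nm,
               rmse = sqrt(mean((reduced_exp - reduced_th)^2)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rmse), ]
  rownames(out) <- NULL
  attr(out, "reduced") <- data.frame(alpha = a, reduced = reduced_exp)
  class(out) <- c("master_rank", "data.frame")
  out
}
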