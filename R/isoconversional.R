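## Simple OLS of y on x returning slope, intercept, R2 and their se's.
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx < .Machine$double.eps * n * max(1, mx^2))
    return(NULL)                       # degenerate abscissa
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  se_slope <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)),
       se_slope = se_slope, n = n)
}

.new_ea_profile <- function(rows, method, delta_alpha = NA_real_,
                            dropped = NULL) {
  rows <- as.data.frame(rows)
  structure(rows,
            method = method, delta_alpha = delta_alpha, dropped = dropped,
            class = c("ea_profile", "data.frame"))
}

#' Isoconversional (model-free) activation-energy estimation
#'
#' Estimates the activation energy as a function of conversion from
#' measurements at several heating rates, without assuming a reaction
#' model, by one of four standard methods:
#' \describe{
#'   \item{`friedman`}{differential: OLS of `ln(dalpha/dt)` on `1/T` across
#'     heating rates at fixed `alpha`; `Ea = -slope * R`. The intercept
#'     estimates `ln[A f(alpha)]`.}
#'   \item{`fwo`}{Flynn-Wall-Ozawa integral method with the Doyle
#'     linearization: OLS of `ln(beta)` on `1/T_alpha`;
#'     `Ea = -slope * R / 1.052`. The Doyle approximation biases Ea by
#'     roughly 2-3\%.}
#'   \item{`kas`}{Kissinger-Akahira-Sunose: OLS of `ln(beta / T_alpha^2)`
#'     on `1/T_alpha`; `Ea = -slope * R`.}
#'   \item{`popescu`}{OLS of `ln(beta / (T_alpha - T_(alpha-dalpha)))` on
#'     `1/(T_alpha + T_(alpha-dalpha))`; `Ea = -slope * R / 2`.}
#' }
#' Grid points with non-positive rates are dropped (and recorded in the
#' `"dropped"` attribute); a grid conversion ends up with no row when fewer
#' than 2 usable points remain or the abscissa is degenerate.
#'
#' @param iso_table an `iso_table` from [temperatures_at_conversion()].
#' @param method one of `"friedman"`, `"fwo"`, `"kas"`, `"popescu"`.
#' @param delta_alpha Popescu conversion interval; must equal a whole
#'   number of grid steps (default 0.05, one step of the default grid).
#' @return an `ea_profile`: data frame with columns `method`, `alpha`,
#'   `Ea_kJ_per_mol`, `intercept`, `R2`, `n_points`, `Ea_se`.
#' @examples
#' \donttest{
#' tgs <- simulate_biomass(default_biomass_spec(noise_sd = 0), c(5, 10, 20))
#' prof <- lapply(tgs, compute_conversion, window = c(400, 740))
#' iso <- temperatures_at_conversion(prof)
#' isoconv_fit(iso, "friedman")
#' }
#' @export
isoconv_fit <- function(iso_table,
                        method = c("friedman", "fwo", "kas", "popescu"),
                        delta_alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(iso_table, "data.frame"))
  if (length(unique(iso_table$beta)) < 2L)
    stop("isoconversional regression needs at least 2 distinct heating rates")
  grid <- sort(unique(iso_table$alpha))
  dropped <- data.frame(alpha = numeric(), beta = numeric(),
                        reason = character())
  rows <- list()
  if (method == "popescu") {
    step <- if (length(grid) > 1) min(diff(grid)) else NA_real_
    k <- delta_alpha / step
    if (!is.finite(k) || abs(k - round(k)) > 1e-9)
      stop("delta_alpha (", delta_alpha,
           ") must be a whole number of grid steps (step = ", step, ")")
    k <- as.integer(round(k))
    if (k < 1L) stop("delta_alpha must be at least one grid step")
  }
  for (a in grid) {
    sub <- iso_table[abs(iso_table$alpha - a) < 1e-12, ]
    if (method == "friedman") {
      pos <- sub$rate > 0
      if (any(!pos))
        dropped <- rbind(dropped, data.frame(
          alpha = a, beta = sub$beta[!pos], reason = "non-positive rate"))
      sub <- sub[pos, ]
      if (nrow(sub) < 2L) next
      fit <- .ols(1 / sub$T, log(sub$rate))
    } else if (method == "fwo") {
      fit <- .ols(1 / sub$T, log(sub$beta))
    } else if (method == "kas") {
      fit <- .ols(1 / sub$T, log(sub$beta / sub$T^2))
    } else { # popescu: pair (alpha, alpha - delta_alpha)
      a0 <- a - delta_alpha
      if (a0 < min(grid) - 1e-12) next
      prev <- iso_table[abs(iso_table$alpha - a0) < 1e-12, ]
      m <- merge(sub, prev, by = "beta", suffixes = c("", "_prev"))
      dT <- m$T - m$T_prev
      ok <- dT > 0
      if (sum(ok) < 2L) next
      fit <- .ols(1 / (m$T[ok] + m$T_prev[ok]), log(m$beta[ok] / dT[ok]))
    }
    if (is.null(fit)) next
    scale <- switch(method, friedman = 1, kas = 1, fwo = 1 / 1.052,
                    popescu = 1 / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, alpha = a,
      Ea_kJ_per_mol = -fit$slope * .Rgas * scale / 1000,
      intercept = fit$intercept, R2 = fit$r2, n_points = fit$n,
      Ea_se = fit$se_slope * .Rgas * scale / 1000)
  }
  if (!length(rows))
    stop("no conversion level yielded a usable regression ",
         "(degenerate abscissa at every alpha?)")
  .new_ea_profile(do.call(rbind, rows), method, delta_alpha,
                  if (nrow(dropped)) dropped else NULL)
}

#' @export
print.ea_profile <- function(x, ...) {
  cat(sprintf("Activation-energy profile (%s): %d conversion levels\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ea_profile <- function(object, ...) {
  out <- list(method = attr(object, "method"),
              n_levels = nrow(object),
              Ea_range = range(object$Ea_kJ_per_mol),
              Ea_mean = mean(object$Ea_kJ_per_mol),
              Ea_sd = stats::sd(object$Ea_kJ_per_mol),
              min_R2 = min(object$R2))
  class(out) <- "summary.ea_profile"
  out
}

#' @export
print.summary.ea_profile <- function(x, ...) {
  cat(sprintf(
    "%s: Ea %.1f-%.1f kJ/mol over %d levels (mean %.1f +- %.1f), min R2 %.3f\n",
    x$method, x$Ea_range[1], x$Ea_range[2], x$n_levels, x$Ea_mean, x$Ea_sd,
    x$min_R2))
  invisible(x)
}

#' @export
coef.ea_profile <- function(object, ...) {
  stats::setNames(object$Ea_kJ_per_mol, object$alpha)
}

#' @export
plot.ea_profile <- function(x, ...) {
  plot(x$alpha, x$Ea_kJ_per_mol, type = "b", xlab = expression(alpha),
       ylab = "Ea [kJ/mol]", main = attr(x, "method"), ...)
  invisible(x)
}

#' Pre-exponential factor per conversion level
#'
#' Two conventions are offered because the literature rarely states which
#' was used:
#' \describe{
#'   \item{`friedman_intercept_first_order`}{`A = exp(intercept) / f(alpha)`
#'     where the intercept of the Friedman regression estimates
#'     `ln[A f(alpha)]` and `f` comes from an assumed reaction model
#'     (default F1). Errors in the intercept are amplified exponentially,
#'     so order-of-magnitude accuracy is the realistic expectation.}
#'   \item{`kissinger_per_alpha`}{`A = beta * Ea * exp(Ea / (R T_p)) /
#'     (R T_p^2)`, the Kissinger relation evaluated with the per-level Ea
#'     at the DTG peak temperature.}
#' }
#'
#' @param profile an `ea_profile` (from a Friedman fit for the intercept
#'   method).
#' @param method which convention to use.
#' @param T_p DTG peak temperature (K), required for
#'   `kissinger_per_alpha`.
#' @param beta heating rate (K/min), required for `kissinger_per_alpha`.
#' @param assumed_model a [kinetic_model] for the intercept method
#'   (default F1).
#' @return the profile with an added `A_per_min` column; the convention is
#'   recorded in attribute `"preexponential_method"`.
#' @export
preexponential <- function(profile,
                           method = c("friedman_intercept_first_order",
                                      "kissinger_per_alpha"),
                           T_p = NULL, beta = NULL,
                           assumed_model = ideal_model("F1")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "ea_profile"), nrow(profile) >= 1L)
  if (method == "friedman_intercept_first_order") {
    if (any(!is.finite(profile$intercept)))
      stop("missing intercepts; the intercept method needs a Friedman fit")
    A <- exp(profile$intercept) / assumed_model$f(profile$alpha)
  } else {
    if (is.null(T_p) || !is.finite(T_p) || T_p <= 0)
      stop("kissinger_per_alpha requires a positive peak temperature T_p")
    if (is.null(beta) || beta <= 0)
      stop("kissinger_per_alpha requires a positive heating rate beta")
    Ea_J <- profile$Ea_kJ_per_mol * 1000
    if (any(Ea_J <= 0))
      stop("non-positive Ea is non-physical for the Kissinger relation")
    A <- beta * Ea_J * exp(Ea_J / (.Rgas * T_p)) / (.Rgas * T_p^2)
  }
  profile$A_per_min <- A
  attr(profile, "preexponential_method") <- method
  profile
}
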