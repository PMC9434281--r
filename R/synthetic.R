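#' Pseudo-component specification for synthetic biomass TGA
#'
#' Defines a lumped multi-component devolatilization model: each component
#' decomposes independently following its own kinetic triplet
#' (`A`, `Ea`, `f(alpha)`), and the sample mass is
#' `m(T) = m0 * (1 - moisture_fraction * alpha_moisture(T)
#'               - sum_i mass_fraction_i * volatile_fraction_i * alpha_i(T))`,
#' optionally with additive gaussian measurement noise. Mass fractions
#' (components + moisture + ash) must sum to exactly 1.
#'
#' @param components list of component specs; each a list with `name`,
#'   `mass_fraction`, `volatile_fraction`, `A` (1/min), `Ea` (kJ/mol) and
#'   either `model` (an [ideal_model()] name) or exponents `n`, `m` of a
#'   truncated Sestak-Berggren form.
#' @param moisture_fraction mass fraction lost in the drying stage.
#' @param ash_fraction inert mass fraction.
#' @param moisture list with `A` (1/min) and `Ea` (kJ/mol) of the
#'   first-order moisture-release pseudo-component (peak below 400 K).
#' @param noise_sd gaussian mass noise, mg.
#' @param initial_mass initial sample mass, mg.
#' @param T_start,T_end,grid_step temperature ramp and sampling, kelvin.
#' @param seed RNG seed used by [simulate_biomass()].
#' @return an object of class `pseudo_component_spec`.
#' @export
pseudo_component_spec <- function(components,
                                  moisture_fraction = 0,
                                  ash_fraction = 0,
                                  moisture = list(A = 3.86e8, Ea = 60),
                                  noise_sd = 0,
                                  initial_mass = 6,
                                  T_start = 303, T_end = 1073,
                                  grid_step = 0.5,
                                  seed = 1L) {
  stopifnot(is.list(components), length(components) >= 1L)
  for (cp in components) {
    if (is.null(cp$A) || cp$A <= 0) stop("component A must be positive")
    if (is.null(cp$Ea) || cp$Ea <= 0) stop("component Ea must be positive")
    if (is.null(cp$model) && (is.null(cp$n) || is.null(cp$m)))
      stop("each component needs a `model` name or (n, m) exponents")
  }
  fr <- vapply(components, function(cp) cp$mass_fraction, 0)
  total <- sum(fr) + moisture_fraction + ash_fraction
  if (abs(total - 1) > 1e-12)
    stop(sprintf(
      "mass fractions must sum to 1 (components %.6f + moisture %.6f + ash %.6f = %.12f)",
      sum(fr), moisture_fraction, ash_fraction, total))
  structure(list(components = components,
                 moisture_fraction = moisture_fraction,
                 ash_fraction = ash_fraction,
                 moisture = moisture,
                 noise_sd = noise_sd,
                 initial_mass = initial_mass,
                 T_start = T_start, T_end = T_end, grid_step = grid_step,
                 seed = as.integer(seed)),
            class = "pseudo_component_spec")
}

#' @export
print.pseudo_component_spec <- function(x, ...) {
  cat(sprintf(
    "Pseudo-component spec: %d components + moisture %.2f + ash %.2f, m0 = %g mg, noise sd = %g mg\n",
    length(x$components), x$moisture_fraction, x$ash_fraction,
    x$initial_mass, x$noise_sd))
  for (cp in x$components)
    cat(sprintf("  %-14s frac %.2f  vol %.2f  A %.4g /min  Ea %g kJ/mol  %s\n",
                cp$name, cp$mass_fraction, cp$volatile_fraction, cp$A, cp$Ea,
                if (!is.null(cp$model)) cp$model
                else sprintf("SB(n=%g,m=%g)", cp$n, cp$m)))
  invisible(x)
}

#' Default calibrated microalgal biomass spec
#'
#' A three-component (carbohydrate / protein / lipid) devolatilization spec
#' emulating a *Gonium pectorale*-like microalgal biomass: component
#' decomposition windows at 410-540 K, 470-550 K and 560-630 K, a moisture
#' stage below 400 K, and a passive char zone above 760 K. The kinetic
#' triplets were calibrated once so that the simulated main DTG peak
#' temperatures at 5/10/20 K/min fall at about 589.5/596.5/604.0 K,
#' within the reference band 592.72/593.62/606.99 K (+- 6 K), and shift
#' upward with heating rate. The same constants are recorded in the shipped
#' config fixture `extdata/default_biomass_spec.yaml`.
#'
#' @param noise_sd gaussian mass noise in mg (default 0.002, a realistic
#'   microbalance noise floor; use 0 for exact oracle data).
#' @param seed RNG seed.
#' @return a [pseudo_component_spec()].
#' @export
default_biomass_spec <- function(noise_sd = 0.002, seed = 1L) {
  pseudo_component_spec(
    components = list(
      list(name = "carbohydrate", mass_fraction = 0.26,
           volatile_fraction = 0.75, A = 3.983981e10, Ea = 100,
           model = "F1"),
      list(name = "protein", mass_fraction = 0.16,
           volatile_fraction = 0.75, A = 2.694099e12, Ea = 130,
           model = "F1"),
      list(name = "lipid", mass_fraction = 0.30,
           volatile_fraction = 0.95, A = 4.024345e23, Ea = 270,
           model = "F1")),
    moisture_fraction = 0.06,
    ash_fraction = 0.22,
    noise_sd = noise_sd,
    seed = seed)
}

.component_f <- function(cp) {
  if (!is.null(cp$model)) ideal_model(cp$model)$f else sb_model(cp$n, cp$m)$f
}

#' Integrate a single pseudo-component conversion curve
#'
#' Numerically integrates the non-isothermal rate law
#' `dalpha/dT = A / beta * exp(-Ea / (R T)) * f(alpha)` from `alpha = 0`
#' at the start of the temperature range, using an adaptive solver
#' (`deSolve::lsoda`) with local error control at 1e-9 and dense output on
#' the fixed grid.
#'
#' @param A pre-exponential factor, 1/min.
#' @param Ea activation energy, kJ/mol.
#' @param model a [kinetic_model] (e.g. [ideal_model()] output) or a model
#'   name.
#' @param beta heating rate, K/min.
#' @param T_range length-2 increasing temperature interval, kelvin.
#' @param grid_step output grid step, kelvin.
#' @return data frame with `temperature` (K), `alpha`, `dalpha_dT` (1/K).
#' @export
simulate_component <- function(A, Ea, model = "F1", beta,
                               T_range = c(303, 1073), grid_step = 0.5) {
  stopifnot(A > 0, Ea > 0, beta > 0, T_range[2] > T_range[1])
  if (is.character(model)) model <- ideal_model(model)
  f <- model$f
  Ea_J <- Ea * 1000
  Tgrid <- seq(T_range[1], T_range[2], by = grid_step)
  rate <- function(T, y, parms) {
    a <- min(max(y[1], 1e-12), 1 - 1e-12)
    list(A / beta * exp(-Ea_J / (.Rgas * T)) * f(a))
  }
  out <- deSolve::ode(c(alpha = 0), Tgrid, rate, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-12)
  alpha <- pmin(pmax(out[, "alpha"], 0), 1)
  if (any(!is.finite(alpha)))
    stop("integration of the rate law produced non-finite conversion ",
         "(A = ", A, ", Ea = ", Ea, " kJ/mol, beta = ", beta, ")")
  dadT <- A / beta * exp(-Ea_J / (.Rgas * Tgrid)) *
    f(pmin(pmax(alpha, 1e-12), 1 - 1e-12))
  dadT[alpha >= 1] <- 0
  data.frame(temperature = Tgrid, alpha = alpha, dalpha_dT = dadT)
}

#' Simulate multi-heating-rate TGA records of a pseudo-component biomass
#'
#' Integrates every component's conversion curve at each heating rate,
#' assembles the sample mass from the component mass balance, adds seeded
#' gaussian measurement noise, and returns one [thermogram()] per heating
#' rate, sampled at fixed time steps (one sample per `grid_step` kelvin of
#' ramp). The noiseless component conversions are attached as attribute
#' `"truth"` so downstream estimators can be validated against ground
#' truth.
#'
#' @param spec a [pseudo_component_spec()].
#' @param betas heating rates, K/min.
#' @return list of [thermogram()]s, one per heating rate.
#' @export
simulate_biomass <- function(spec, betas) {
  stopifnot(inherits(spec, "pseudo_component_spec"), length(betas) >= 1L)
  set.seed(spec$seed)
  lapply(betas, function(beta) {
    Tgrid <- seq(spec$T_start, spec$T_end, by = spec$grid_step)
    time <- (Tgrid - spec$T_start) / beta
    loss <- rep(0, length(Tgrid))
    truth <- list()
    if (spec$moisture_fraction > 0) {
      am <- simulate_component(spec$moisture$A, spec$moisture$Ea, "F1",
                               beta, c(spec$T_start, spec$T_end),
                               spec$grid_step)
      loss <- loss + spec$moisture_fraction * am$alpha
      truth$moisture <- am$alpha
    }
    for (cp in spec$components) {
      ac <- simulate_component(cp$A, cp$Ea,
                               if (!is.null(cp$model)) ideal_model(cp$model)
                               else sb_model(cp$n, cp$m),
                               beta, c(spec$T_start, spec$T_end),
                               spec$grid_step)
      loss <- loss + cp$mass_fraction * cp$volatile_fraction * ac$alpha
      truth[[cp$name]] <- ac$alpha
    }
    mass <- spec$initial_mass * (1 - loss)
    if (spec$noise_sd > 0)
      mass <- mass + stats::rnorm(length(mass), sd = spec$noise_sd)
    tg <- thermogram(time, Tgrid, mass, heating_rate_nominal = beta,
                     label = sprintf("synthetic biomass, beta = %g K/min", beta),
                     check = FALSE)
    attr(tg, "truth") <- truth
    tg
  })
}

#' Write / read a pseudo-component spec as a YAML config
#'
#' @param spec a [pseudo_component_spec()].
#' @param path file path.
#' @return `path` invisibly (write) / the spec (read).
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pseudo_component_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 12)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pseudo_component_spec, x)
}
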