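# Shared, lazily-built fixtures. Heavy simulations are memoized in this
# environment so several test files can reuse them within one run.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# Noiseless calibrated biomass at the three study heating rates, with
# window-restricted conversion profiles and the isoconversional table.
biomass_fixture <- function() {
  memo("biomass", {
    tgs <- simulate_biomass(default_biomass_spec(noise_sd = 0), c(5, 10, 20))
    profiles <- lapply(tgs, compute_conversion, window = c(400, 740))
    list(tgs = tgs, profiles = profiles,
         iso = temperatures_at_conversion(profiles))
  })
}

# Exact single-component first-order data (A = 1e13 /min, Ea = 150 kJ/mol).
first_order_fixture <- function() {
  memo("first_order", {
    spec <- pseudo_component_spec(
      components = list(list(name = "x", mass_fraction = 1,
                             volatile_fraction = 1, A = 1e13, Ea = 150,
                             model = "F1")),
      noise_sd = 0, seed = 1)
    tgs <- simulate_biomass(spec, c(5, 10, 20))
    profiles <- lapply(tgs, compute_conversion)
    list(spec = spec, tgs = tgs, profiles = profiles,
         iso = temperatures_at_conversion(profiles))
  })
}

# Exact conversion profile of a single kinetic component, bypassing the
# mass-record round trip: alpha from the integrated rate law and the rate
# from its analytic form. An F3 tail converts so slowly that a finite ramp
# leaves 1 - alpha ~ 4e-4 unreacted, and renormalizing conversion over the
# ramp would distort ln(1 - alpha) near alpha = 1; the exact profile keeps
# mechanism-recovery checks about the estimator, not that artifact.
component_profile <- function(A, Ea, model, beta, grid_step = 0.5) {
  sim <- simulate_component(A, Ea, model, beta, T_range = c(303, 1073),
                            grid_step = grid_step)
  structure(list(temperature = sim$temperature, alpha = sim$alpha,
                 dalpha_dT = sim$dalpha_dT,
                 dalpha_dt = beta * sim$dalpha_dT,
                 heating_rate = beta, w0 = NA_real_, wf = NA_real_,
                 zones = NULL, smoothed = FALSE),
            class = "conversion_profile")
}

# Third-order (F3) kinetics for mechanism-selection checks.
f3_fixture <- function() {
  memo("f3", {
    profiles <- lapply(c(5, 10, 20), function(b)
      component_profile(1e13, 150, "F3", b))
    list(profiles = profiles,
         iso = temperatures_at_conversion(profiles))
  })
}

# Write a small thermogram CSV and return its path.
write_tg_csv <- function(time, temperature, mass, sep = ",",
                         path = tempfile(fileext = ".csv")) {
  df <- data.frame(time = time, temperature = temperature, mass = mass)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
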