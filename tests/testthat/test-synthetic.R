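test_that("the rate law reduces to the first-order closed form when the
          Arrhenius factor is flat", {
  ## with Ea ~ 0 the rate is temperature-free: dalpha/dT = (A / beta) (1 - alpha),
  ## i.e. the isothermal first-order solution alpha(t) = 1 - exp(-A t)
  A <- 0.5; beta <- 10
  out <- simulate_component(A, Ea = 1e-9, model = "F1", beta = beta,
                            T_range = c(300, 400), grid_step = 0.5)
  t_min <- (out$temperature - 300) / beta
  expect_equal(out$alpha, 1 - exp(-A * t_min), tolerance = 1e-6)
})

test_that("simulated DTG peaks satisfy the Kissinger stationarity condition", {
  A <- 1e13; Ea <- 150; beta <- 10
  Rg <- 8.314
  ## independent oracle: solve Ea beta / (R T^2) = A exp(-Ea / (R T))
  stat <- function(T) Ea * 1000 * beta / (Rg * T^2) -
    A * exp(-Ea * 1000 / (Rg * T))
  T_oracle <- uniroot(stat, c(400, 900), tol = 1e-10)$root
  out <- simulate_component(A, Ea, "F1", beta, c(303, 1073),
                            grid_step = 0.1)
  T_sim <- out$temperature[which.max(out$dalpha_dT)]
  expect_lt(abs(T_sim - T_oracle), 0.5)

  ## peak temperature strictly increases with heating rate
  out20 <- simulate_component(A, Ea, "F1", 20, c(303, 1073), grid_step = 0.1)
  expect_gt(out20$temperature[which.max(out20$dalpha_dT)], T_sim)
})

test_that("biomass mass balance closes on the residual char", {
  spec <- default_biomass_spec(noise_sd = 0)
  tg <- simulate_biomass(spec, 10)[[1]]
  volatile <- spec$moisture_fraction +
    sum(vapply(spec$components,
               function(cp) cp$mass_fraction * cp$volatile_fraction, 0))
  expect_equal(tg$mass_mg[nrow(tg)],
               spec$initial_mass * (1 - volatile), tolerance = 1e-6)
  expect_true(all(diff(tg$mass_mg) <= 1e-12))  # non-increasing, zero noise
})

test_that("simulation is reproducible bit for bit under a fixed seed", {
  spec <- default_biomass_spec(noise_sd = 0.002, seed = 99)
  a <- simulate_biomass(spec, c(5, 10))
  b <- simulate_biomass(spec, c(5, 10))
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
})

test_that("invalid pseudo-component specs are rejected", {
  comp <- list(name = "x", mass_fraction = 0.5, volatile_fraction = 1,
               A = 1e13, Ea = 150, model = "F1")
  expect_error(pseudo_component_spec(list(comp), ash_fraction = 0.6),
               "sum to 1")
  bad <- comp; bad$A <- -1
  expect_error(pseudo_component_spec(list(bad), ash_fraction = 0.5),
               "positive")
})

test_that("the calibrated default spec reproduces the reference DTG peaks", {
  fx <- biomass_fixture()
  peaks <- do.call(rbind, lapply(fx$profiles, detect_peaks))
  main <- peaks[peaks$is_main, ]
  main <- main[order(main$heating_rate), ]
  ref <- reference_table("dtg_peaks")
  expect_equal(main$heating_rate, ref$heating_rate_K_per_min)
  expect_lt(max(abs(main$T_p - ref$T_p_K)), 6)
  expect_true(all(diff(main$T_p) > 0))
  ## overlapping pseudo-components give multiple active-zone peaks
  expect_gt(nrow(peaks), 3)
})

test_that("spec configs round-trip through YAML", {
  spec <- default_biomass_spec(noise_sd = 0.001, seed = 7)
  path <- tempfile(fileext = ".yaml")
  write_spec(spec, path)
  back <- read_spec(path)
  expect_equal(back$ash_fraction, spec$ash_fraction)
  expect_equal(length(back$components), 3L)
  expect_equal(vapply(back$components, `[[`, 0, "A"),
               vapply(spec$components, `[[`, 0, "A"), tolerance = 1e-10)
})
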