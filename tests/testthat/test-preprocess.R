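test_that("conversion follows (w0 - w) / (w0 - wf) with exact bounds", {
  ## linear mass loss 6 -> 3 mg: alpha is linear, midpoint mass 4.5 -> 0.5
  tg <- thermogram(0:10, seq(400, 500, by = 10), seq(6, 3, by = -0.3),
                   heating_rate_nominal = 10)
  prof <- compute_conversion(tg)
  expect_equal(prof$alpha[1], 0)
  expect_equal(prof$alpha[length(prof$alpha)], 1)
  expect_equal(prof$alpha[6], 0.5)   # w = 4.5, w0 = 6, wf = 3
  expect_equal(prof$w0, 6)
  expect_equal(prof$wf, 3)
  expect_true(all(diff(prof$alpha) >= 0))
})

test_that("degenerate windows are rejected", {
  tg <- thermogram(0:10, seq(400, 500, by = 10), rep(6, 11), check = FALSE)
  expect_error(compute_conversion(tg), "w0 <= wf")
  tg2 <- thermogram(0:10, seq(400, 500, by = 10), seq(6, 3, by = -0.3))
  expect_error(compute_conversion(tg2, window = c(300, 600)), "outside")
})

test_that("recovered conversion matches the simulator's internal alpha", {
  fx <- first_order_fixture()
  for (k in seq_along(fx$profiles)) {
    truth <- attr(fx$tgs[[k]], "truth")$x
    expect_lt(max(abs(fx$profiles[[k]]$alpha - truth)), 1e-6)
  }
})

test_that("rate consistency dalpha/dt = beta * dalpha/dT survives smoothing", {
  fx <- biomass_fixture()
  for (p in fx$profiles) {
    expect_equal(p$dalpha_dt, p$heating_rate * p$dalpha_dT,
                 tolerance = 1e-9)
    ps <- smooth_derivative(p)
    expect_equal(ps$dalpha_dt, ps$heating_rate * ps$dalpha_dT,
                 tolerance = 1e-9)
    expect_identical(ps$alpha, p$alpha)  # smoothing must not touch alpha
  }
})

test_that("local-polynomial smoothing reproduces polynomial derivatives", {
  Tg <- seq(400, 600, length.out = 201)
  a <- 1e-5 * (Tg - 400)^2 / 4    # exactly quadratic, ends at 0.1
  tg <- thermogram((Tg - 400) / 10, Tg, 6 - 3 * a, heating_rate_nominal = 10)
  prof <- compute_conversion(tg)
  sm <- smooth_derivative(prof, window_points = 21, poly_order = 3)
  analytic <- 1e-5 * (prof$temperature - 400) / 2 / max(a)
  expect_equal(sm$dalpha_dT, analytic, tolerance = 1e-8)
})

test_that("smoothing beats finite differences on noisy conversion data", {
  set.seed(11)
  Tg <- seq(400, 740, length.out = 1000)
  a_true <- 1 / (1 + exp(-(Tg - 570) / 25))
  a_noisy <- a_true + rnorm(1000, sd = 1e-3)
  d_true <- (1 / 25) * a_true * (1 - a_true)
  tg <- thermogram((Tg - 400) / 10, Tg, 6 - 3 * pmin(pmax(a_noisy, -0.1), 1.1),
                   check = FALSE)
  prof <- compute_conversion(tg)
  scale <- (prof$w0 - prof$wf) / 3   # conversion rescale from clipping
  ## compare away from the ends, where the shrinking window cannot average
  ## as many points as the interior filter does
  i <- 11:(length(d_true) - 10)
  rmse_fd <- sqrt(mean((prof$dalpha_dT[i] * scale - d_true[i])^2))
  sm <- smooth_derivative(prof, window_points = 21, poly_order = 3)
  rmse_sm <- sqrt(mean((sm$dalpha_dT[i] * scale - d_true[i])^2))
  expect_lt(rmse_sm * 5, rmse_fd)
})

test_that("invalid smoothing windows are rejected", {
  fx <- first_order_fixture()
  expect_error(smooth_derivative(fx$profiles[[1]], window_points = 4),
               "odd")
  expect_error(smooth_derivative(fx$profiles[[1]], window_points = 1000001L),
               "smaller")
  expect_error(smooth_derivative(fx$profiles[[1]], window_points = 3,
                                 poly_order = 3), "exceed")
})

test_that("peak detection equals a brute-force argmax scan", {
  ## triangular DTG profile: apex exactly at the constructed maximum
  Tg <- seq(400, 740, by = 1)
  rate <- pmax(0, 1 - abs(Tg - 580) / 120)
  prof <- structure(list(temperature = Tg, alpha = seq(0, 1, length.out = length(Tg)),
                         dalpha_dT = rate / 10, dalpha_dt = rate,
                         heating_rate = 10, zones = NULL, smoothed = TRUE),
                    class = "conversion_profile")
  pk <- detect_peaks(prof)
  expect_equal(pk$T_p[pk$is_main], 580)

  set.seed(7)
  for (i in 1:50) {
    centers <- runif(3, 420, 720)
    heights <- runif(3, 0.2, 1)
    widths <- runif(3, 8, 40)
    r <- colSums(heights * exp(-outer(centers, Tg, function(c, T)
      ((T - c) / rep(widths, length(Tg)))^2)))
    prof$dalpha_dt <- r
    prof$dalpha_dT <- r / 10
    pk <- detect_peaks(prof)
    expect_equal(pk$T_p[pk$is_main], Tg[which.max(r)])
    expect_true(all(pk$rate_at_peak >= 0.2 * max(r)))
  }
})

test_that("peak detection requires samples in the active zone", {
  Tg <- seq(100, 300, by = 1)
  prof <- structure(list(temperature = Tg, alpha = seq(0, 1, length.out = 201),
                         dalpha_dT = rep(1e-3, 201), dalpha_dt = rep(1e-2, 201),
                         heating_rate = 10, zones = NULL, smoothed = TRUE),
                    class = "conversion_profile")
  expect_error(detect_peaks(prof), "active zone")
})

test_that("isoconversional temperatures come from monotone interpolation", {
  mk <- function(beta, Toff = 0) {
    Tg <- seq(500, 700, by = 1) + Toff
    structure(list(temperature = Tg,
                   alpha = seq(0, 1, length.out = length(Tg)),
                   dalpha_dT = rep(1 / 200, length(Tg)),
                   dalpha_dt = rep(beta / 200, length(Tg)),
                   heating_rate = beta, zones = NULL, smoothed = FALSE),
              class = "conversion_profile")
  }
  iso <- temperatures_at_conversion(list(mk(5), mk(10, 10)),
                                    alpha_grid = c(0.25, 0.5))
  expect_equal(iso$T[iso$alpha == 0.25 & iso$beta == 5], 550)
  expect_equal(iso$T[iso$alpha == 0.25 & iso$beta == 10], 560)

  ## default grid is 0.1..0.8 by 0.05
  iso_d <- temperatures_at_conversion(list(mk(5), mk(10)))
  expect_equal(sort(unique(iso_d$alpha)), seq(0.1, 0.8, by = 0.05))

  ## inverse interpolation reproduces the grid conversions
  fx <- first_order_fixture()
  iso_fx <- temperatures_at_conversion(fx$profiles)
  for (b in c(5, 10, 20)) {
    sub <- iso_fx[iso_fx$beta == b, ]
    p <- fx$profiles[[match(b, c(5, 10, 20))]]
    a_back <- stats::approx(p$temperature, p$alpha, xout = sub$T)$y
    expect_equal(a_back, sub$alpha, tolerance = 1e-9)
  }

  expect_error(temperatures_at_conversion(list(mk(5)), c(0.5)),
               "at least 2")
  ## a profile that never reaches the requested conversion is named
  short <- mk(5)
  short$alpha <- 0.2 + 0.5 * short$alpha   # spans 0.2..0.7 only
  expect_error(temperatures_at_conversion(list(short, mk(10)), c(0.5, 0.8)),
               "profile 1")
})
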