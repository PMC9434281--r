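test_that("the Friedman slope matches a hand-computed least-squares fit", {
  ## three exactly collinear points: slope -12000 K -> Ea = 99.768 kJ/mol
  iso <- structure(data.frame(alpha = 0.5, beta = c(5, 10, 20),
                              T = 1 / c(0.0016, 0.00165, 0.0017),
                              rate = exp(c(-3.0, -3.6, -4.2))),
                   class = c("iso_table", "data.frame"))
  prof <- isoconv_fit(iso, "friedman")
  expect_equal(prof$Ea_kJ_per_mol, 12000 * 8.314 / 1000, tolerance = 1e-9)
  expect_equal(prof$R2, 1)
  expect_equal(prof$n_points, 3L)
})

test_that("all four methods recover a first-order activation energy", {
  fx <- first_order_fixture()
  tol <- c(friedman = 0.005, kas = 0.01, popescu = 0.02, fwo = 0.03)
  for (m in names(tol)) {
    prof <- isoconv_fit(fx$iso, m)
    rel <- abs(prof$Ea_kJ_per_mol - 150) / 150
    expect_lt(max(rel), tol[[m]])
    expect_true(all(prof$R2 > 0.999))
  }
})

test_that("estimates are invariant to the ordering of heating rates", {
  fx <- first_order_fixture()
  shuffled <- fx$iso[rev(seq_len(nrow(fx$iso))), ]
  class(shuffled) <- class(fx$iso)
  for (m in c("friedman", "kas")) {
    a <- isoconv_fit(fx$iso, m)
    b <- isoconv_fit(shuffled, m)
    expect_equal(a$Ea_kJ_per_mol, b$Ea_kJ_per_mol, tolerance = 1e-12)
  }
})

test_that("degenerate regressions are refused", {
  ## identical temperatures at every conversion: no abscissa spread
  iso <- structure(data.frame(alpha = rep(c(0.3, 0.5), each = 2),
                              beta = rep(c(10, 10), 2),
                              T = rep(c(600, 620), each = 2),
                              rate = rep(c(0.05, 0.08), each = 2)),
                   class = c("iso_table", "data.frame"))
  expect_error(isoconv_fit(iso, "friedman"), "2 distinct heating rates")
  iso2 <- structure(data.frame(alpha = rep(0.5, 2), beta = c(5, 10),
                               T = c(600, 600), rate = c(0.05, 0.08)),
                    class = c("iso_table", "data.frame"))
  expect_error(isoconv_fit(iso2, "friedman"), "usable regression")
})

test_that("non-positive rates are dropped and recorded", {
  fx <- first_order_fixture()
  iso <- fx$iso
  iso$rate[iso$alpha == 0.4 & iso$beta == 5] <- 0
  prof <- isoconv_fit(iso, "friedman")
  drp <- attr(prof, "dropped")
  expect_equal(drp$alpha, 0.4)
  expect_equal(drp$beta, 5)
  expect_equal(prof$n_points[prof$alpha == 0.4], 2L)
})

test_that("Popescu requires its interval to sit on the conversion grid", {
  fx <- first_order_fixture()
  expect_error(isoconv_fit(fx$iso, "popescu", delta_alpha = 0.033),
               "whole number of grid steps")
  prof <- isoconv_fit(fx$iso, "popescu", delta_alpha = 0.1)
  expect_gte(min(prof$alpha), 0.2)
})

test_that("FWO and KAS agree closely on multi-component biomass", {
  fx <- biomass_fixture()
  fwo <- isoconv_fit(fx$iso, "fwo")
  kas <- isoconv_fit(fx$iso, "kas")
  rel <- abs(fwo$Ea_kJ_per_mol - kas$Ea_kJ_per_mol) / kas$Ea_kJ_per_mol
  expect_lt(max(rel), 0.05)
})

test_that("multi-component biomass shows a non-constant Ea profile", {
  fx <- biomass_fixture()
  prof <- isoconv_fit(fx$iso, "friedman")
  expect_gt(diff(range(prof$Ea_kJ_per_mol)) / min(prof$Ea_kJ_per_mol), 0.2)
})

test_that("pre-exponential factors follow both conventions", {
  fx <- first_order_fixture()
  fr <- isoconv_fit(fx$iso, "friedman")
  withA <- preexponential(fr)
  mid <- withA$alpha >= 0.2 & withA$alpha <= 0.7
  expect_true(all(withA$A_per_min[mid] / 1e13 < 1.5 &
                    withA$A_per_min[mid] / 1e13 > 1 / 1.5))
  expect_equal(attr(withA, "preexponential_method"),
               "friedman_intercept_first_order")

  ## Kissinger form against direct scalar arithmetic
  kiss <- preexponential(fr, "kissinger_per_alpha", T_p = 593.62, beta = 10)
  Ea_J <- fr$Ea_kJ_per_mol * 1000
  oracle <- 10 * Ea_J * exp(Ea_J / (8.314 * 593.62)) / (8.314 * 593.62^2)
  expect_equal(kiss$A_per_min, oracle, tolerance = 1e-12)

  zero <- fr; zero$Ea_kJ_per_mol <- 0
  expect_error(preexponential(zero, "kissinger_per_alpha",
                              T_p = 593.62, beta = 10), "non-physical")
  expect_error(preexponential(fr, "kissinger_per_alpha", beta = 10),
               "T_p")
})
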