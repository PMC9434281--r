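test_that("combined kinetics recovers a first-order triplet", {
  fx <- first_order_fixture()
  fit <- combined_kinetics_fit(fx$profiles[[2]])
  expect_true(fit$adequate)
  expect_lt(abs(fit$n - 1), 0.1)
  expect_lt(abs(fit$m - 0), 0.1)
  expect_lt(abs(fit$Ea - 150) / 150, 0.02)
  expect_gt(fit$R2, 0.999)
  ## ln(cA) should recover ln(A) for c = 1, f = (1-a)^1
  expect_lt(abs(fit$ln_cA - log(1e13)), 0.5)
})

test_that("combined kinetics recovers Sestak-Berggren exponents at zero noise", {
  spec <- pseudo_component_spec(
    components = list(list(name = "x", mass_fraction = 1,
                           volatile_fraction = 1, A = 5e12, Ea = 140,
                           n = 1.5, m = 0.3)),
    noise_sd = 0, seed = 1)
  tg <- simulate_biomass(spec, 10)[[1]]
  prof <- compute_conversion(tg)
  fit <- combined_kinetics_fit(prof)
  expect_lt(abs(fit$n - 1.5), 0.1)
  expect_lt(abs(fit$m - 0.3), 0.1)
})

test_that("third-order data select F3 over lower orders", {
  fx <- f3_fixture()
  fit <- combined_kinetics_fit(fx$profiles[[2]])
  expect_lt(abs(fit$n - 3), 0.1)
  fr <- isoconv_fit(fx$iso, "friedman")
  rank <- master_plot_rank(fr)
  expect_equal(rank$model[1], "F3")
  expect_lt(rank$rmse[1], 0.05)
  expect_gt(rank$rmse[rank$model == "F1"], 3 * rank$rmse[1])
})

test_that("summary table mirrors the per-heating-rate layout", {
  fx <- first_order_fixture()
  tab <- combined_kinetics_table(fx$profiles)
  expect_equal(tab$heating_rate, c(5, 10, 20))
  expect_true(all(c("Ea", "Ea_se", "ln_cA", "ln_cA_se", "n", "n_se",
                    "m", "m_se", "R2") %in% names(tab)))
  expect_true(all(tab$Ea_se >= 0, na.rm = TRUE))
})

test_that("uninformative data are flagged rather than silently fitted", {
  ## conversion scrambled against temperature: no (n, m) can linearize
  ## random rates against 1/T
  set.seed(3)
  Tg <- seq(450, 700, length.out = 200)
  prof <- structure(list(temperature = Tg,
                         alpha = sample(seq(0.06, 0.94, length.out = 200)),
                         dalpha_dT = rep(0.004, 200),
                         dalpha_dt = exp(rnorm(200, -3, 1)),
                         heating_rate = 10, zones = NULL, smoothed = FALSE),
                    class = "conversion_profile")
  expect_warning(fit <- combined_kinetics_fit(prof), "no adequate model")
  expect_false(fit$adequate)
})

test_that("reduced master curves are normalized and match closed forms", {
  F3 <- ideal_model("F3")
  expect_equal(F3$f(0.25) / F3$f(0.5), 0.421875 / 0.125)
  for (nm in model_registry()) {
    mod <- ideal_model(nm)
    expect_equal(mod$f(0.5) / mod$f(0.5), 1)
  }
})

test_that("mechanism ranking is stable under 1% rate noise", {
  ## multiplicative 1% noise on every rate curve, then the same moving
  ## local smoothing any noisy DTG record would receive before analysis
  fx <- f3_fixture()
  ma21 <- function(x) as.numeric(stats::filter(x, rep(1 / 21, 21),
                                               sides = 2))
  set.seed(17)
  hits <- 0L
  for (i in 1:50) {
    profs <- lapply(fx$profiles, function(p) {
      r <- p$dalpha_dt * exp(rnorm(length(p$dalpha_dt), 0, 0.01))
      r_sm <- ma21(r)
      keep <- !is.na(r_sm)
      p$temperature <- p$temperature[keep]
      p$alpha <- p$alpha[keep]
      p$dalpha_dt <- r_sm[keep]
      p$dalpha_dT <- p$dalpha_dt / p$heating_rate
      p
    })
    iso <- temperatures_at_conversion(profs)
    fr <- isoconv_fit(iso, "friedman")
    hits <- hits + (master_plot_rank(fr)$model[1] == "F3")
  }
  expect_gte(hits, 45L)
})

test_that("normalization interpolates when alpha = 0.5 is not on the grid", {
  fx <- f3_fixture()
  iso <- fx$iso[abs(fx$iso$alpha - 0.5) > 1e-9, ]
  class(iso) <- class(fx$iso)
  fr <- isoconv_fit(iso, "friedman")
  rank <- master_plot_rank(fr)
  expect_equal(rank$model[1], "F3")
  ## not bracketed: only low conversions available
  lo <- fx$iso[fx$iso$alpha < 0.45, ]
  class(lo) <- class(fx$iso)
  fr_lo <- isoconv_fit(lo, "friedman")
  expect_error(master_plot_rank(fr_lo), "not bracketed")
})
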