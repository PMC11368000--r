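test_that("lognormal exposure fit matches both quantiles exactly", {
  fit <- fit_exposure_lognormal(1e-6, 1e-4)
  expect_equal(fit$mu, log(1e-6))
  expect_equal(fit$sigma, log(100) / qnorm(0.95), tolerance = 1e-9)
  expect_equal(fit$sigma, 2.7996, tolerance = 1e-4)
  # fitted 95th percentile reproduces the input upper bound
  expect_equal(exp(fit$mu + qnorm(0.95) * fit$sigma), 1e-4)
  # point mass when the bounds coincide
  fit0 <- fit_exposure_lognormal(2, 2)
  expect_equal(fit0$sigma, 0)
  expect_error(fit_exposure_lognormal(3, 2))
})

test_that("Css per unit dose follows the well-stirred closed form", {
  tk <- tibble::tibble(mw = 500, fup = 0.02, clint = 0,
                       gfr_perkg = 0.0918, q_liver_perkg = 1.24)
  # D = 2 umol/kg/day; CL = 0.02 * 0.0918 * 24 = 0.044064 L/day/kg
  expect_equal(css_per_unit_dose(tk, "steady_state_3c"), 2 / 0.044064)
  expect_equal(css_per_unit_dose(tk, "steady_state_3c"), 45.39, tolerance = 1e-3)
  expect_equal(css_per_unit_dose(tk, "no_hepatic_clearance"),
               css_per_unit_dose(tk, "steady_state_3c"))
  # doubling the molecular weight halves Css
  tk2 <- tk; tk2$mw <- 1000
  expect_equal(css_per_unit_dose(tk2, "steady_state_3c"),
               css_per_unit_dose(tk, "steady_state_3c") / 2)
  # clint -> infinity approaches the flow-limited clearance ceiling
  tk3 <- tk; tk3$clint <- 1e9; tk3$fup <- 0.5
  cl_limit <- 0.5 * 0.0918 * 24 + 24 * 1.24
  expect_equal(css_per_unit_dose(tk3, "steady_state_3c"),
               (1000 / 500) / cl_limit, tolerance = 1e-4)
  # hepatic clearance lowers Css relative to the renal-only method
  tk4 <- tk; tk4$clint <- 5
  expect_lt(css_per_unit_dose(tk4, "steady_state_3c"),
            css_per_unit_dose(tk4, "no_hepatic_clearance"))
})

test_that("degenerate point-mass pipeline equals the deterministic ratio", {
  # point-mass POD 10 uM; exposure tuned so Css is exactly 0.1 uM
  post <- fake_posterior(mu_log_ec50 = log(10 * 0.45 / 0.05),
                         mu_log_emax = log(0.5))
  ps <- pods_from_posterior(post, 0.05, seed = 1)
  expect_equal(ps$summary$pod_median, 10)
  tk <- tibble::tibble(mw = 500, fup = 0.02, clint = 0,
                       gfr_perkg = 0.0918, q_liver_perkg = 1.24)
  css1 <- css_per_unit_dose(tk, "steady_state_3c")
  expo <- tibble::tibble(oral_median = 0.1 / css1, oral_upper95 = 0.1 / css1,
                         biomonitoring_lo = NA, biomonitoring_hi = NA)
  moe <- compute_moe(list(p = ps), list(p = post), expo, tk,
                     n_mc = 1000, seed = 2)
  m <- moe[moe$method == "steady_state_3c", ]
  expect_equal(m$moe_population_median, 100)
  expect_equal(m$moe_random_individual, 100)
  expect_equal(m$band, ">=100")  # boundary: margin >= 100 is protective
})

test_that("Monte-Carlo q95 matches the analytic lognormal quantile", {
  post <- fake_posterior()
  ps <- pods_from_posterior(post, 0.05, seed = 1)
  tk <- tibble::tibble(mw = 250, fup = 0.1, clint = 0,
                       gfr_perkg = 0.0918, q_liver_perkg = 1.24)
  expo <- tibble::tibble(oral_median = 1e-5, oral_upper95 = 1e-3,
                         biomonitoring_lo = NA, biomonitoring_hi = NA)
  moe <- compute_moe(list(p = ps), list(p = post), expo, tk,
                     n_mc = 1e5, seed = 3)
  css1 <- css_per_unit_dose(tk, "steady_state_3c")
  analytic_q95 <- 1e-3 * css1  # the fitted lognormal's 95th pct is upper95
  m <- moe[moe$method == "steady_state_3c", ]
  # empirical q95 of a sigma=2.8 lognormal has ~1.9% relative SE at 1e5
  expect_equal(m$internal_conc_q95, analytic_q95, tolerance = 0.06)
})

test_that("MOE scales inversely with exposure and respects band thresholds", {
  post <- fake_posterior(sigma_log_ec50 = 0.3)
  ps <- pods_from_posterior(post, 0.05, seed = 1)
  tk <- tibble::tibble(mw = 400, fup = 0.05, clint = 1,
                       gfr_perkg = 0.0918, q_liver_perkg = 1.24)
  expo <- tibble::tibble(oral_median = 1e-6, oral_upper95 = 1e-5,
                         biomonitoring_lo = NA, biomonitoring_hi = NA)
  m1 <- compute_moe(list(p = ps), list(p = post), expo, tk,
                    n_mc = 2e4, seed = 4)
  expo10 <- expo; expo10$oral_median <- 1e-5; expo10$oral_upper95 <- 1e-4
  m2 <- compute_moe(list(p = ps), list(p = post), expo10, tk,
                    n_mc = 2e4, seed = 4)
  expect_equal(m2$moe_population_median, m1$moe_population_median / 10,
               tolerance = 0.02)
  # with population variance, the random-individual MOE is not larger
  expect_true(all(m1$moe_random_individual <= m1$moe_population_median))
  # band assignment matches brute force
  expect_identical(moe_band_vals <- m1$band,
                   ifelse(m1$min_moe < 1, "<1",
                          ifelse(m1$min_moe < 100, "1-100", ">=100")))
})

test_that("MOE guards: fup = 0 excluded, biomonitoring used directly, popvar gating", {
  post <- fake_posterior()
  ps <- pods_from_posterior(post, 0.05, seed = 1)
  tk0 <- tibble::tibble(mw = 400, fup = 0, clint = 1,
                        gfr_perkg = 0.0918, q_liver_perkg = 1.24)
  expo <- tibble::tibble(oral_median = 1e-6, oral_upper95 = 1e-5,
                         biomonitoring_lo = 0.01, biomonitoring_hi = 0.05)
  expect_error(compute_moe(list(p = ps), list(p = post), expo, tk0),
               "unbound")
  tk <- tk0; tk$fup <- 0.1
  moe <- compute_moe(list(p = ps), list(p = post), expo, tk,
                     n_mc = 1000, seed = 5,
                     popvar = c(p = FALSE))
  bio <- moe[moe$method == "biomonitoring", ]
  expect_equal(bio$internal_conc_q95, 0.05)
  expect_true(all(is.na(moe$moe_random_individual)))
})
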