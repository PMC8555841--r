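test_that("generated EMU series are level-biased but change-unbiased", {
  spec <- generator_spec(n_countries = 1, start_year = 2000, end_year = 2020,
                         seed = 1)
  spec$emu$level_bias_sd <- 0
  spec$emu$sigma$sigma <- rep(0, 4)  # no increment noise either
  p <- process_params(ptilde = 0.8, omega_l = 0.08, phi_l = 0.3,
                      tau_l = 0.02, omega_r = 0.05, phi_r = 0.3,
                      tau_r = 0.02, eta0 = -1.5, zeta0 = 0)
  g <- generate_country(p, spec, seed = 3, country_code = "AAA",
                        source_types = "comm_clients")
  i <- match(g$emus$year, g$trajectory$year)
  # sigma = 0 and zero bias: z follows mCPR exactly (up to dyadic rounding)
  expect_equal(g$emus$emu, g$trajectory$mcpr[i], tolerance = 2^-25)

  # with a pure level shift the first differences still match mCPR changes,
  # so the EMU likelihood is at its translation-invariant maximum
  shifted <- g$emus
  shifted$emu <- dyadic(shifted$emu + 0.2)
  ll_shift <- emu_loglik(shifted, g$trajectory)
  ll_base <- emu_loglik(g$emus, g$trajectory)
  expect_equal(ll_shift, ll_base, tolerance = 1e-6)
})

test_that("survey sampling noise is applied around the true trajectory", {
  spec <- generator_spec(n_countries = 1, seed = 2)
  spec$survey$sampling_sd <- 0
  p <- process_params(ptilde = 0.8, omega_l = 0.08, phi_l = 0.3,
                      tau_l = 0.02, omega_r = 0.05, phi_r = 0.3,
                      tau_r = 0.02, eta0 = -1.5, zeta0 = 0)
  g <- generate_country(p, spec, seed = 4, country_code = "AAA")
  i <- match(round(g$surveys$year), g$trajectory$year)
  expect_equal(g$surveys$modern, g$trajectory$mcpr[i], tolerance = 1e-12)
  expect_equal(g$surveys$modern + g$surveys$traditional,
               g$trajectory$cpr[i], tolerance = 1e-12)
})

test_that("EMU increments deviate from mCPR increments with sd sigma_s", {
  # long horizon Monte-Carlo check of the generative contract
  p <- process_params(ptilde = 0.8, omega_l = 0, phi_l = 0.3, tau_l = 0.01,
                      omega_r = 0, phi_r = 0.3, tau_r = 0.01,
                      eta0 = 0, zeta0 = 0)
  spec <- generator_spec(n_countries = 1, start_year = 1, end_year = 5000,
                         survey = list(gap_range = c(3, 5),
                                       first_range = c(5, 9),
                                       last_margin = 2, sampling_sd = 0.01),
                         seed = 5)
  spec$emu$length <- 5000
  spec$emu$beyond_last_survey <- 5000
  g <- generate_country(p, spec, seed = 6, country_code = "AAA",
                        source_types = "comm_clients")
  i <- match(g$emus$year, g$trajectory$year)
  resid <- diff(g$emus$emu) - diff(g$trajectory$mcpr[i])
  expect_equal(sd(resid), 0.04, tolerance = 0.002 / 0.04)
  expect_lt(abs(mean(resid)), 0.002)
})

test_that("cohorts are reproducible and shaped like the EMU database", {
  spec <- generator_spec(n_countries = 27, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$emus, b$emus)

  expect_equal(length(a$truth), 27)
  expect_equal(length(unique(a$surveys$country_code)), 27)
  expect_equal(length(unique(a$emus$country_code)), 27)
  types_per_country <- tapply(a$emus$source_type, a$emus$country_code,
                              function(x) length(unique(x)))
  expect_true(all(types_per_country >= 1 & types_per_country <= 3))
  expect_true(all(a$emus$emu >= 0 & a$emus$emu <= 1))
  # every observation year lies inside the trajectory span
  expect_true(all(a$surveys$year >= spec$start_year &
                    a$surveys$year <= spec$end_year))
  expect_true(all(a$emus$year >= spec$start_year &
                    a$emus$year <= spec$end_year))
  expect_error(generator_spec(n_countries = 0), "n_countries")
})

test_that("round trip: change pairs from generated data recover sigma_s", {
  spec <- generator_spec(n_countries = 40, seed = 12)
  spec$emu$length <- 10
  cohort <- generate_cohort(spec)
  truth <- do.call(rbind, lapply(names(cohort$truth), function(cc) {
    data.frame(country_code = cc, year = cohort$truth[[cc]]$year,
               mcpr = cohort$truth[[cc]]$mcpr)
  }))
  # use the true trajectories as the estimate series; widen the window to
  # the full span so all pairs enter
  window <- data.frame(country_code = rep(unique(cohort$emus$country_code),
                                          each = 2),
                       year = rep(c(spec$start_year, spec$end_year),
                                  length(unique(cohort$emus$country_code))))
  pairs <- build_change_pairs(cohort$emus, truth, window)
  st <- estimate_sigma(pairs)
  for (ty in st$source_type) {
    if (st$n_pairs[st$source_type == ty] < 100) next
    expect_equal(st$sigma[st$source_type == ty],
                 default_sigma_table()$sigma[
                   default_sigma_table()$source_type == ty],
                 tolerance = 0.1)
  }
  expect_gt(sum(st$n_pairs >= 100), 0)
})
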