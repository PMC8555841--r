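test_that("survey log likelihood matches the two-normal hand oracle", {
  traj <- make_traj(2000:2010, cpr = rep(0.4, 11), mcpr = rep(0.3, 11))
  obs <- data.frame(country_code = "AAA", year = 2005, modern = 0.3,
                    traditional = 0.1, se_modern = NA_real_,
                    se_traditional = NA_real_, source_label = "X")
  # total log-ratio sd 0.1 per component, observation at the model mode:
  # the density is the product of two centred normal densities
  ll <- survey_loglik(obs, traj, nonsampling_sd = c(default = 0.1))
  expect_equal(ll, 2 * (-log(0.1) - 0.5 * log(2 * pi)), tolerance = 1e-12)
  expect_equal(ll, 2.7671, tolerance = 1e-4)

  # any perturbation of the observation lowers the log density
  for (d in c(-0.03, 0.02, 0.05)) {
    pert <- obs
    pert$modern <- obs$modern + d
    expect_lt(survey_loglik(pert, traj, nonsampling_sd = c(default = 0.1)), ll)
  }

  # doubling the sd lowers the density at the mode (normalisation)
  expect_lt(survey_loglik(obs, traj, nonsampling_sd = c(default = 0.2)), ll)
})

test_that("survey likelihood adds delta-method sampling variance and maps labels", {
  traj <- make_traj(2000:2010, cpr = rep(0.4, 11), mcpr = rep(0.3, 11))
  obs <- data.frame(country_code = "AAA", year = 2005, modern = 0.3,
                    traditional = 0.1, se_modern = 0.01,
                    se_traditional = 0.01, source_label = "DHS")
  m <- 0.3; tr <- 0.1; none <- 0.6
  v1 <- (1 / m + 1 / none)^2 * 1e-4 + (1 / none)^2 * 1e-4 + 0.1^2
  v2 <- (1 / none)^2 * 1e-4 + (1 / tr + 1 / none)^2 * 1e-4 + 0.1^2
  expected <- dnorm(0, 0, sqrt(v1), log = TRUE) +
    dnorm(0, 0, sqrt(v2), log = TRUE)
  expect_equal(survey_loglik(obs, traj), expected, tolerance = 1e-12)

  # unlisted source labels fall back to the default non-sampling sd
  obs$source_label <- "WFS"
  v1 <- v1 - 0.1^2 + 0.2^2
  v2 <- v2 - 0.1^2 + 0.2^2
  expected <- dnorm(0, 0, sqrt(v1), log = TRUE) +
    dnorm(0, 0, sqrt(v2), log = TRUE)
  expect_equal(survey_loglik(obs, traj), expected, tolerance = 1e-12)
})

test_that("survey likelihood handles boundaries per the documented rules", {
  traj <- make_traj(2000:2010, cpr = rep(0.4, 11), mcpr = rep(0.3, 11))
  base <- data.frame(country_code = "AAA", year = 2005, modern = 0.3,
                     traditional = 0.1, se_modern = NA_real_,
                     se_traditional = NA_real_, source_label = "X")
  over <- base
  over$traditional <- 0.7
  expect_error(survey_loglik(over, traj), ">= 1")

  out <- base
  out$year <- 1995
  expect_error(survey_loglik(out, traj), "1995")

  # a zero component is clamped to 0.25/ess before the transform
  z <- base
  z$traditional <- 0
  ll <- survey_loglik(z, traj, nonsampling_sd = c(default = 0.1))
  clamped <- z
  clamped$traditional <- 0.25 / 1000
  expect_equal(ll,
               survey_loglik(clamped, traj, nonsampling_sd = c(default = 0.1)),
               tolerance = 1e-12)
  expect_true(is.finite(ll))

  # decimal years are rounded half-up onto the grid
  half <- base
  half$year <- 2004.5
  expect_equal(survey_loglik(half, traj, nonsampling_sd = c(default = 0.1)),
               survey_loglik(base, traj, nonsampling_sd = c(default = 0.1)))
})

test_that("EMU likelihood is a first-difference model", {
  traj <- make_traj(2000:2010, cpr = seq(0.30, 0.50, by = 0.02),
                    mcpr = seq(0.20, 0.40, by = 0.02))
  # z changes exactly equal mCPR changes: centred normal density per pair
  z <- 0.5 + cumsum(c(0, diff(traj$mcpr[6:7])))
  series <- emu_table(c(2005, 2006), z)
  ll <- emu_loglik(series, traj)
  expect_equal(ll, -log(0.04) - 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(ll, 2.2999, tolerance = 1e-4)

  # levels never enter: a constant shift leaves the value bit-identical
  shifted <- series
  shifted$emu <- series$emu + 0.125
  expect_identical(emu_loglik(shifted, traj), ll)

  # fewer than 2 observations: zero contribution plus a warning
  expect_warning(l1 <- emu_loglik(emu_table(2005, 0.5), traj),
                 "at least 2 years")
  expect_identical(l1, 0)

  expect_error(emu_loglik(emu_table(c(2005, 2006), c(0.5, 0.5),
                                    type = "satellite"), traj),
               "unknown source_type")
})

test_that("non-adjacent EMU pairs are skipped unless gap scaling is on", {
  traj <- make_traj(2000:2010, cpr = seq(0.30, 0.50, by = 0.02),
                    mcpr = seq(0.20, 0.40, by = 0.02))
  gappy <- emu_table(c(2004, 2006), c(0.50, 0.53))
  expect_message(ll <- emu_loglik(gappy, traj), "skipped")
  expect_identical(ll, 0)

  s <- 0.04
  drho <- traj$mcpr[traj$year == 2006] - traj$mcpr[traj$year == 2004]
  expected <- dnorm(0.03, drho, s * sqrt(2), log = TRUE)
  expect_equal(emu_loglik(gappy, traj, gap_scaling = TRUE), expected,
               tolerance = 1e-12)
})

test_that("sigma estimator is the per-type RMS of change residuals", {
  pairs <- data.frame(
    country_code = "AAA",
    source_type = c("fp_users", "fp_users", "comm_clients"),
    year_to = c(2011, 2012, 2011),
    d_emu = c(0.05, 0.01, 0.02),
    d_mcpr = c(0.02, 0.04, 0.06))
  st <- estimate_sigma(pairs)
  expect_equal(st$sigma[st$source_type == "fp_users"], 0.03)
  expect_equal(st$n_pairs[st$source_type == "fp_users"], 2)
  # a single pair gives |residual|
  expect_equal(st$sigma[st$source_type == "comm_clients"], 0.04)
  expect_false("comm_facilities" %in% st$source_type)

  degen <- data.frame(country_code = "AAA", source_type = "fp_users",
                      year_to = 2011, d_emu = 0.03, d_mcpr = 0.03)
  expect_warning(st0 <- estimate_sigma(degen), "degenerate")
  expect_equal(st0$sigma, 0)
  expect_true(st0$degenerate)
})

test_that("sigma estimator is consistent at large n", {
  set.seed(2024)
  for (s in c(0.02, 0.04, 0.09)) {
    dp <- rnorm(10000, 0.01, 0.01)
    pairs <- data.frame(country_code = "AAA", source_type = "fp_users",
                        year_to = 2011, d_emu = dp + rnorm(10000, 0, s),
                        d_mcpr = dp)
    expect_equal(estimate_sigma(pairs)$sigma, s, tolerance = 0.03)
  }
})

test_that("change pairs respect the survey-overlap window and adjacency", {
  emus <- emu_table(2010:2015, seq(0.40, 0.50, by = 0.02), country = "MOZ")
  est <- data.frame(country_code = "MOZ", year = 2000:2020,
                    mcpr = seq(0.2, 0.4, by = 0.01))
  surveys <- data.frame(country_code = "MOZ", year = c(2000, 2008, 2013))
  pairs <- build_change_pairs(emus, est, surveys)
  # data retained only through the most recent survey year (2013)
  expect_equal(sort(pairs$year_to), c(2011, 2012, 2013))
  expect_equal(pairs$d_emu, rep(0.02, 3), tolerance = 1e-12)
  expect_equal(pairs$d_mcpr, rep(0.01, 3), tolerance = 1e-12)

  # a year gap yields no pairs
  gappy <- emu_table(c(2010, 2012), c(0.40, 0.44), country = "MOZ")
  expect_equal(nrow(build_change_pairs(gappy, est, surveys)), 0)

  # no surveys -> no overlap period -> no pairs
  expect_equal(nrow(build_change_pairs(
    emus, est, data.frame(country_code = "ZZZ", year = 2000))), 0)

  # country missing from the estimate series is skipped with a notice
  expect_message(
    none <- build_change_pairs(emus,
                               data.frame(country_code = "ZZZ", year = 2000,
                                          mcpr = 0.1), surveys),
    "absent")
  expect_equal(nrow(none), 0)
})
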