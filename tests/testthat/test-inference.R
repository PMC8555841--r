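make_fake_fit <- function(rho, years) {
  structure(list(rho = rho, years = years,
                 quantiles = fpemu:::trajectory_quantiles(
                   rho, years, c(0.025, 0.1, 0.5, 0.9, 0.975))),
            class = "fpem_fit")
}

toy_inputs <- function() {
  p <- process_params(ptilde = 0.8, omega_l = 0.08, phi_l = 0.3,
                      tau_l = 0.02, omega_r = 0.05, phi_r = 0.3,
                      tau_r = 0.02, eta0 = -2, zeta0 = -0.5)
  traj <- simulate_trajectory(p, 1995:2022, seed = 17)
  set.seed(17)
  sv <- surveys_from_traj(traj, c(2000, 2005, 2010, 2015), noise = 1)
  list(traj = traj, surveys = sv)
}

test_that("posterior summaries are empirical quantiles, monotone per year", {
  rho <- matrix(c(0.1, 0.2, 0.3), nrow = 3, ncol = 2)
  f <- make_fake_fit(rho, years = c(2000, 2001))
  s <- summarize_fit(f, probs = 0.5)
  expect_equal(s[["q0.5"]], c(0.2, 0.2))

  # constant samples: every quantile equals that value
  const <- make_fake_fit(matrix(0.42, nrow = 5, ncol = 3), 2000:2002)
  s <- summarize_fit(const)
  for (col in c("q0.025", "q0.5", "q0.975"))
    expect_equal(s[[col]], rep(0.42, 3))

  s <- summarize_fit(f)
  expect_true(all(s[["q0.025"]] <= s[["q0.5"]] & s[["q0.5"]] <= s[["q0.975"]]))
  expect_error(summarize_fit(f, probs = c(0, 0.5)), "inside")
})

test_that("run comparison reports percentage-point differences", {
  years <- 2018:2022
  a <- data.frame(year = years, `q0.025` = 0.25, `q0.5` = 0.30,
                  `q0.975` = 0.35, check.names = FALSE)
  b <- data.frame(year = years, `q0.025` = 0.19, `q0.5` = 0.25,
                  `q0.975` = 0.31, check.names = FALSE)
  cmp <- compare_runs(a, b, 2020)
  expect_equal(cmp$median_diff_pp, 5)
  expect_equal(cmp$abs_median_diff_pp, 5)
  # widths 0.10 vs 0.12 -> -2 pp
  expect_equal(cmp$width95_diff_pp, -2)

  same <- compare_runs(a, a, 2020)
  expect_equal(same$median_diff_pp, 0)
  expect_equal(same$width95_diff_pp, 0)
  expect_error(compare_runs(a, b, 1990), "grid")
})

test_that("fits are bit-reproducible given config, data and seed", {
  inp <- toy_inputs()
  cfg <- fit_config(chains = 2, iter = 300, warmup = 200, seed = 5,
                    end_year = 2022)
  f1 <- suppressWarnings(fit_mcpr(inp$surveys, config = cfg))
  f2 <- suppressWarnings(fit_mcpr(inp$surveys, config = cfg))
  expect_identical(f1$rho, f2$rho)
  expect_identical(summarize_fit(f1), summarize_fit(f2))
})

test_that("empty EMU data and a disabled EMU flag give identical posteriors", {
  inp <- toy_inputs()
  emus <- emu_table(2013:2016, dyadic(c(0.30, 0.32, 0.35, 0.36)))
  cfg_off <- fit_config(chains = 2, iter = 300, warmup = 200, seed = 5,
                        end_year = 2022, use_emu = FALSE)
  cfg_on <- fit_config(chains = 2, iter = 300, warmup = 200, seed = 5,
                       end_year = 2022, use_emu = TRUE)
  f_none <- suppressWarnings(fit_mcpr(inp$surveys, emus = NULL,
                                      config = cfg_on))
  f_off <- suppressWarnings(fit_mcpr(inp$surveys, emus = emus,
                                     config = cfg_off))
  expect_identical(f_none$rho, f_off$rho)
  expect_identical(f_none$params, f_off$params)
  expect_equal(f_off$variant, "survey_only")
})

test_that("zero surveys are rejected: the model is survey-anchored", {
  expect_error(fit_mcpr(data.frame()), "survey-anchored")
  inp <- toy_inputs()
  expect_error(fit_mcpr(inp$surveys,
                        config = fit_config(chains = 1)), "chains")
})

test_that("projection uncertainty is non-decreasing beyond the last survey", {
  inp <- toy_inputs()
  cfg <- fit_config(chains = 2, iter = 800, warmup = 500, seed = 9,
                    end_year = 2022)
  f <- suppressWarnings(fit_mcpr(inp$surveys, config = cfg))
  s <- summarize_fit(f)
  w <- s[["q0.975"]] - s[["q0.025"]]
  horizon <- which(s$year %in% c(2016, 2019, 2022))
  expect_true(all(diff(w[horizon]) > -0.05 * w[horizon[-length(horizon)]]))
})

test_that("shrinking sigma pulls the posterior change toward the EMU change", {
  inp <- toy_inputs()
  # EMU series rising much faster than the survey trend
  z <- dyadic(0.30 + 0.03 * (0:4))
  emus <- emu_table(2015:2019, z)
  d_emu <- z[5] - z[1]
  small <- default_sigma_table()
  small$sigma <- small$sigma / 10
  cfg_wide <- fit_config(chains = 2, iter = 600, warmup = 400, seed = 13,
                         end_year = 2022)
  cfg_tight <- fit_config(chains = 2, iter = 600, warmup = 400, seed = 13,
                          end_year = 2022, sigma = small)
  f_wide <- suppressWarnings(fit_mcpr(inp$surveys, emus, cfg_wide))
  f_tight <- suppressWarnings(fit_mcpr(inp$surveys, emus, cfg_tight))
  chg <- function(f) {
    i <- match(c(2015, 2019), f$years)
    median(f$rho[, i[2]] - f$rho[, i[1]])
  }
  expect_lt(abs(chg(f_tight) - d_emu), abs(chg(f_wide) - d_emu))
  expect_equal(f_tight$variant, "survey_emu")
})

test_that("convergence diagnostics detect healthy and unhealthy sampling", {
  set.seed(41)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.01)
  expect_gt(ess_bulk(good), 1000)
  bad <- matrix(c(rnorm(500), rnorm(500, 5)), ncol = 2)
  expect_gt(split_rhat(bad), 1.5)
})
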