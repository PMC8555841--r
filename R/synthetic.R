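#' Specification for the synthetic survey + EMU cohort generator
#'
#' The generator emulates the structure of the national survey and EMU
#' databases the model is designed for: per country a latent prevalence
#' trajectory drawn from the process-parameter hyper-distributions, surveys
#' every 3-5 years with proportion-scale sampling noise, and EMU series that
#' are level-biased but change-unbiased with source-type-specific increment
#' noise (an EMU series equals mCPR plus a persistent level offset plus a
#' random walk whose increments have sd `sigma_s`, so that annual EMU changes
#' are exactly mCPR changes plus `N(0, sigma_s^2)` noise).
#'
#' @param n_countries Number of countries.
#' @param start_year,end_year Calendar span of the latent trajectories.
#' @param hyper Hyper-distributions for the process parameters; by default
#'   identical to [prior_settings()] defaults so that model priors are
#'   correctly specified for generated cohorts, plus location/scale for the
#'   initial states (`eta0 ~ N(-2.5, 1)`, `zeta0 ~ N(0, 1)`, putting early
#'   total prevalence around 5-10% and rising).
#' @param survey List: `gap_range` (inter-survey gap bounds, years),
#'   `first_range` (years after `start_year` for the first survey),
#'   `last_margin` (years kept free after the last survey),
#'   `sampling_sd` (proportion-scale sd of survey noise).
#' @param emu List: `n_types_prob` (probabilities of a country carrying 1, 2
#'   or 3 source types), `level_bias_sd` (sd of the per-series level offset),
#'   `sigma` (a `sigma_table` of increment sds), `length` (series length,
#'   years), `beyond_last_survey` (how far past the country's last survey
#'   the series extends).
#' @param seed Integer seed.
#' @return A list of class `fpem_generator_spec`.
#' @export
generator_spec <- function(n_countries = 20,
                           start_year = 1990, end_year = 2025,
                           hyper = list(logit_ptilde = c(1.4, 0.5),
                                        omega_l = c(0.05, 0.05),
                                        omega_r = c(0.05, 0.05),
                                        phi_max = 0.95, tau_scale = 0.1,
                                        eta0 = c(-2.5, 1), zeta0 = c(0, 1)),
                           survey = list(gap_range = c(3, 5),
                                         first_range = c(5, 9),
                                         last_margin = 2,
                                         sampling_sd = 0.01),
                           emu = list(n_types_prob = c(0.5, 0.364, 0.136),
                                      level_bias_sd = 0.1,
                                      sigma = default_sigma_table(),
                                      length = 8,
                                      beyond_last_survey = 2),
                           seed = 1) {
  if (n_countries < 1) stop("n_countries must be >= 1", call. = FALSE)
  gr <- survey$gap_range
  if (gr[1] < 1 || gr[2] > 15 || gr[1] > gr[2])
    stop("survey gap_range must lie within [1, 15]", call. = FALSE)
  if (survey$sampling_sd < 0 || emu$level_bias_sd < 0)
    stop("all generator sds must be >= 0", call. = FALSE)
  structure(list(n_countries = as.integer(n_countries),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 hyper = hyper, survey = survey, emu = emu,
                 seed = as.integer(seed)),
            class = "fpem_generator_spec")
}

# Round to the 2^-26 dyadic grid. EMU values are stored on this grid so that
# adding a dyadic level offset and taking first differences are exact in
# floating point: the change-unbiasedness of the series then holds bitwise,
# not just to rounding error.
dyadic_round <- function(x) round(x * 2^26) / 2^26

#' Generate one country's surveys and EMU series
#'
#' Simulates a latent trajectory and emits (i) surveys at the scheduled
#' years, with modern and traditional proportions observed with independent
#' Gaussian sampling noise and clipped to the interior of the simplex, and
#' (ii) one EMU series per requested source type, constructed so that
#' `z_t - z_{t-1} = (mcpr_t - mcpr_{t-1}) + N(0, sigma_s^2)` exactly while a
#' per-series level offset persists.
#'
#' @param params An `fpem_params` for the country.
#' @param spec A [generator_spec()].
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @param country_code Code used in the emitted tables.
#' @param source_types Character vector of EMU source types to emit; `NULL`
#'   draws the number of types from `spec$emu$n_types_prob` and picks types
#'   at random.
#' @return List with `trajectory`, `surveys`, `emus`, `level_bias` (named by
#'   source type) and `n_clipped` (EMU values clipped into \[0, 1\]).
#' @export
generate_country <- function(params, spec, seed = NULL,
                             country_code = "C01", source_types = NULL) {
  run <- function() {
    years <- spec$start_year:spec$end_year
    traj <- simulate_trajectory(params, years, seed = NULL)

    # survey schedule: first survey a few years in, then gaps of 3-5 years
    first <- spec$start_year +
      sample(spec$survey$first_range[1]:spec$survey$first_range[2], 1)
    sched <- first
    repeat {
      gap <- sample(spec$survey$gap_range[1]:spec$survey$gap_range[2], 1)
      nxt <- sched[length(sched)] + gap
      if (nxt > spec$end_year - spec$survey$last_margin) break
      sched <- c(sched, nxt)
    }
    if (length(sched) == 0L || sched[1] > spec$end_year)
      stop("survey schedule produced zero surveys", call. = FALSE)
    ti <- match(sched, years)
    sd0 <- spec$survey$sampling_sd
    m_obs <- traj$mcpr[ti] + stats::rnorm(length(ti), 0, sd0)
    t_obs <- (traj$cpr[ti] - traj$mcpr[ti]) + stats::rnorm(length(ti), 0, sd0)
    m_obs <- pmin(pmax(m_obs, 1e-4), 0.98)
    t_obs <- pmin(pmax(t_obs, 1e-4), 0.98)
    over <- m_obs + t_obs >= 0.995
    if (any(over)) {
      sc <- 0.995 / (m_obs[over] + t_obs[over])
      m_obs[over] <- m_obs[over] * sc
      t_obs[over] <- t_obs[over] * sc
    }
    surveys <- data.frame(
      country_code = country_code, year = as.numeric(sched),
      modern = m_obs, traditional = t_obs,
      se_modern = sd0, se_traditional = sd0,
      source_label = rep_len(c("DHS", "MICS"), length(sched)),
      stringsAsFactors = FALSE)

    if (is.null(source_types)) {
      k <- sample(1:3, 1, prob = spec$emu$n_types_prob)
      source_types <- sample(emu_source_types(), k)
    }
    last_sv <- sched[length(sched)]
    emu_end <- min(spec$end_year, last_sv + spec$emu$beyond_last_survey)
    emu_start <- max(spec$start_year, emu_end - spec$emu$length + 1)
    eyrs <- emu_start:emu_end
    ei <- match(eyrs, years)

    emu_rows <- list()
    bias <- numeric(0)
    n_clipped <- 0L
    for (ty in source_types) {
      s <- sigma_for(spec$emu$sigma, ty, floor = 0)
      b <- stats::rnorm(1, 0, spec$emu$level_bias_sd)
      walk <- c(0, cumsum(stats::rnorm(length(eyrs) - 1, 0, s)))
      z <- dyadic_round(traj$mcpr[ei] + b + walk)
      clip <- z < 0 | z > 1
      n_clipped <- n_clipped + sum(clip)
      z <- pmin(pmax(z, 0), 1)
      bias[ty] <- b
      emu_rows[[ty]] <- data.frame(
        country_code = country_code, year = eyrs, emu = z,
        source_type = ty, stringsAsFactors = FALSE)
    }
    emus <- do.call(rbind, c(emu_rows, list(make.row.names = FALSE)))
    list(trajectory = traj, surveys = surveys, emus = emus,
         level_bias = bias, n_clipped = n_clipped)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a multi-country synthetic cohort
#'
#' Draws per-country process parameters from the spec's hyper-distributions
#' and calls [generate_country()] for each; fully reproducible from the
#' spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return A list of class `fpem_synthetic`: `truth` (named list of
#'   trajectories), `surveys` and `emus` (stacked tables), `params` (named
#'   list of the true process parameters), `n_clipped`, and the `spec`.
#' @export
generate_cohort <- function(spec) {
  run <- function() {
    truth <- list(); params <- list(); sv <- list(); em <- list()
    n_clipped <- 0L
    for (i in seq_len(spec$n_countries)) {
      cc <- sprintf("C%03d", i)
      h <- spec$hyper
      # rejection keeps generated countries inside the method's operating
      # range: a draw whose realized mCPR never reaches 2% emulates a
      # country without a family planning programme, which the log-ratio
      # survey model (and the databases this generator stands in for) does
      # not cover
      for (attempt in 1:100) {
        p <- process_params(
          ptilde = stats::plogis(stats::rnorm(1, h$logit_ptilde[1],
                                              h$logit_ptilde[2])),
          omega_l = stats::rnorm(1, h$omega_l[1], h$omega_l[2]),
          phi_l = stats::runif(1, 0, h$phi_max),
          tau_l = abs(stats::rnorm(1, 0, h$tau_scale)),
          omega_r = stats::rnorm(1, h$omega_r[1], h$omega_r[2]),
          phi_r = stats::runif(1, 0, h$phi_max),
          tau_r = abs(stats::rnorm(1, 0, h$tau_scale)),
          eta0 = stats::rnorm(1, h$eta0[1], h$eta0[2]),
          zeta0 = stats::rnorm(1, h$zeta0[1], h$zeta0[2]))
        g <- generate_country(p, spec, seed = NULL, country_code = cc)
        last <- nrow(g$trajectory)
        if (g$trajectory$mcpr[last] >= 0.02) break
      }
      truth[[cc]] <- g$trajectory
      params[[cc]] <- p
      sv[[cc]] <- g$surveys
      em[[cc]] <- g$emus
      n_clipped <- n_clipped + g$n_clipped
    }
    structure(list(truth = truth, params = params,
                   surveys = do.call(rbind, c(sv, list(make.row.names = FALSE))),
                   emus = do.call(rbind, c(em, list(make.row.names = FALSE))),
                   n_clipped = n_clipped, spec = spec),
              class = "fpem_synthetic")
  }
  with_seed(spec$seed, run())
}
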