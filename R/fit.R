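#' Prior settings for the process parameters
#'
#' Defaults: `qlogis(ptilde) ~ N(1.4, 0.5^2)` (asymptote median ~ 0.80),
#' `omega_l, omega_r ~ N(0.05, 0.05^2)`, `phi ~ Uniform(0, 0.95)`,
#' `tau ~ half-Normal(0, 0.1^2)`, and `eta0, zeta0 ~ N(anchor, 1)` where the
#' anchor is back-projected from the earliest survey's log-ratios (see
#' Details). Any parameter can be fixed at a point value through `fixed`,
#' which removes it from sampling.
#'
#' @details The anchor for `eta0` is `qlogis(min(L1/median(ptilde), 0.95))`
#'   minus the prior-mean drift times the offset between the grid start and
#'   the first survey year, with `L1` the first survey's total prevalence;
#'   `zeta0` is anchored analogously from the modern/total ratio.
#'
#' @param logit_ptilde,omega_l,omega_r Length-2 numeric `(mean, sd)`.
#' @param phi_max Upper bound of the uniform prior on the AR coefficients.
#' @param tau_scale Scale of the half-normal prior on innovation sds.
#' @param eta0_sd,zeta0_sd Prior sds around the data-derived anchors.
#' @param fixed Named list of parameters to fix (names among
#'   `logit_ptilde`, `omega_l`, `phi_l`, `tau_l`, `omega_r`, `phi_r`,
#'   `tau_r`, `eta0`, `zeta0`).
#' @return A list of prior settings.
#' @export
prior_settings <- function(logit_ptilde = c(1.4, 0.5),
                           omega_l = c(0.05, 0.05),
                           omega_r = c(0.05, 0.05),
                           phi_max = 0.95, tau_scale = 0.1,
                           eta0_sd = 1, zeta0_sd = 1,
                           fixed = list()) {
  ok <- c("logit_ptilde", "omega_l", "phi_l", "tau_l", "omega_r", "phi_r",
          "tau_r", "eta0", "zeta0")
  bad <- setdiff(names(fixed), ok)
  if (length(bad) > 0)
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(logit_ptilde = logit_ptilde, omega_l = omega_l, omega_r = omega_r,
       phi_max = phi_max, tau_scale = tau_scale,
       eta0_sd = eta0_sd, zeta0_sd = zeta0_sd, fixed = fixed)
}

#' Configuration for a model fit
#'
#' @param start_year First year of the annual grid; default (`NULL`) is five
#'   years before the earliest survey year.
#' @param end_year Last year of the grid (projection horizon).
#' @param chains Number of MCMC chains (at least 2).
#' @param iter Post-warmup iterations per chain.
#' @param warmup Adaptation iterations per chain (discarded).
#' @param seed Integer seed governing all sampling.
#' @param priors Output of [prior_settings()].
#' @param sigma A `sigma_table` for the EMU data model; defaults to the
#'   packaged source-type values.
#' @param use_emu Include EMU likelihood terms when EMU data are supplied.
#' @param single_source Keep only one EMU source type per country, preferring
#'   the type with the smallest change-bias sd (comm_facilities, then
#'   service_visits, comm_clients, fp_users).
#' @param gap_scaling Passed to the EMU likelihood: include non-adjacent
#'   pairs with gap-scaled variance.
#' @param nonsampling_sd Named non-sampling sds on the log-ratio scale per
#'   survey source label (`default` entry required).
#' @param ess Effective sample size for the zero-proportion clamp.
#' @return A list of class `fpem_config`.
#' @export
fit_config <- function(start_year = NULL, end_year = 2030, chains = 4,
                       iter = 5000, warmup = 2000, seed = 1,
                       priors = prior_settings(),
                       sigma = default_sigma_table(), use_emu = TRUE,
                       single_source = FALSE, gap_scaling = FALSE,
                       nonsampling_sd = c(DHS = 0.1, default = 0.2),
                       ess = 1000) {
  if (chains < 2) stop("invalid config field 'chains': need at least 2",
                       call. = FALSE)
  if (iter < 50) stop("invalid config field 'iter': need at least 50",
                      call. = FALSE)
  if (warmup < 0) stop("invalid config field 'warmup': must be >= 0",
                       call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1)
    stop("invalid config field 'seed': must be a single integer",
         call. = FALSE)
  if (!"default" %in% names(nonsampling_sd))
    stop("invalid config field 'nonsampling_sd': needs a 'default' entry",
         call. = FALSE)
  structure(list(start_year = start_year, end_year = end_year,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 priors = priors, sigma = sigma, use_emu = isTRUE(use_emu),
                 single_source = isTRUE(single_source),
                 gap_scaling = isTRUE(gap_scaling),
                 nonsampling_sd = nonsampling_sd, ess = ess),
            class = "fpem_config")
}

# EMU source types in ascending order of default change-bias sd
single_source_priority <- function() {
  c("comm_facilities", "service_visits", "comm_clients", "fp_users")
}

select_single_source <- function(emus) {
  if (nrow(emus) == 0L) return(emus)
  present <- unique(as.character(emus$source_type))
  keep <- single_source_priority()[single_source_priority() %in% present][1]
  emus[emus$source_type == keep, , drop = FALSE]
}

theta_names <- function() {
  c("logit_ptilde", "omega_l", "phi_l", "tau_l", "omega_r", "phi_r",
    "tau_r", "eta0", "zeta0")
}

# Assemble the data list consumed by the compiled sampler.
build_sampler_data <- function(surveys, emus, config, years) {
  pr <- config$priors
  n <- length(years)

  yr <- round_year(surveys$year)
  idx <- match(yr, years)
  if (anyNA(idx))
    stop("survey year(s) outside the model grid: ",
         paste(unique(yr[is.na(idx)]), collapse = ", "), call. = FALSE)
  y <- survey_logratios(surveys$modern, surveys$traditional, ess = config$ess)
  se_m <- if ("se_modern" %in% names(surveys)) surveys$se_modern else rep(NA_real_, nrow(surveys))
  se_t <- if ("se_traditional" %in% names(surveys)) surveys$se_traditional else rep(NA_real_, nrow(surveys))
  vs <- logratio_sampling_var(surveys$modern, surveys$traditional,
                              se_m, se_t, ess = config$ess)
  lab <- if ("source_label" %in% names(surveys))
    as.character(surveys$source_label) else rep("default", nrow(surveys))
  ns <- config$nonsampling_sd[lab]
  ns[is.na(ns)] <- config$nonsampling_sd[["default"]]

  emu_to <- integer(0); emu_from <- integer(0)
  emu_dz <- numeric(0); emu_sd <- numeric(0)
  if (config$use_emu && !is.null(emus) && nrow(emus) > 0L) {
    if (config$single_source) emus <- select_single_source(emus)
    for (ty in unique(as.character(emus$source_type))) {
      es <- emus[emus$source_type == ty, , drop = FALSE]
      es <- es[order(es$year), , drop = FALSE]
      if (nrow(es) < 2L) {
        warning("EMU series of type '", ty, "' has fewer than 2 ",
                "observations and cannot inform changes; it is ignored",
                call. = FALSE)
        next
      }
      eyr <- as.integer(es$year)
      ei <- match(eyr, years)
      if (anyNA(ei))
        stop("EMU year(s) outside the model grid: ",
             paste(eyr[is.na(ei)], collapse = ", "), call. = FALSE)
      gap <- diff(eyr)
      use <- if (config$gap_scaling) gap >= 1L else gap == 1L
      s <- sigma_for(config$sigma, ty)
      if (any(use)) {
        emu_to <- c(emu_to, ei[-1][use])
        emu_from <- c(emu_from, ei[-length(ei)][use])
        emu_dz <- c(emu_dz, diff(es$emu)[use])
        emu_sd <- c(emu_sd, if (config$gap_scaling) s * sqrt(gap[use])
                            else rep(s, sum(use)))
      }
    }
  }

  # anchor the initial states to the earliest survey, back-projected to the
  # grid start at the prior-mean drift
  first <- which.min(surveys$year)
  L1 <- min(max(surveys$modern[first] + surveys$traditional[first], 0.01), 0.95)
  R1 <- min(max(surveys$modern[first] / L1, 0.01), 0.99)
  p_med <- stats::plogis(pr$logit_ptilde[1])
  off <- idx[first] - 1L
  eta0_mean <- stats::qlogis(min(L1 / p_med, 0.95)) - off * pr$omega_l[1]
  zeta0_mean <- stats::qlogis(R1) - off * pr$omega_r[1]

  fx <- pr$fixed
  fixed <- theta_names() %in% names(fx)
  list(T = n,
       surv_t = idx - 1L, surv_y1 = y[, 1], surv_y2 = y[, 2],
       surv_sd1 = sqrt(vs[, 1] + ns^2), surv_sd2 = sqrt(vs[, 2] + ns^2),
       emu_to = emu_to - 1L, emu_from = emu_from - 1L,
       emu_dz = emu_dz, emu_sd = emu_sd,
       p_mean = pr$logit_ptilde[1], p_sd = pr$logit_ptilde[2],
       omL_mean = pr$omega_l[1], omL_sd = pr$omega_l[2],
       omR_mean = pr$omega_r[1], omR_sd = pr$omega_r[2],
       phi_max = pr$phi_max, tau_scale = pr$tau_scale,
       eta0_mean = eta0_mean, eta0_sd = pr$eta0_sd,
       zeta0_mean = zeta0_mean, zeta0_sd = pr$zeta0_sd,
       fixed = fixed)
}

theta_init <- function(dat, fixed_values) {
  init <- c(dat$p_mean, dat$omL_mean, 0.3, dat$tau_scale / 2,
            dat$omR_mean, 0.3, dat$tau_scale / 2,
            dat$eta0_mean, dat$zeta0_mean)
  names(init) <- theta_names()
  for (nm in names(fixed_values)) init[nm] <- fixed_values[[nm]]
  init
}

#' Fit the prevalence model to one country's data
#'
#' Samples the posterior of the latent annual trajectory (total CPR,
#' modern/total ratio, and mCPR) and the process parameters given the
#' country's survey record and, optionally, its EMU series. The sampler is an
#' adaptive random-walk Metropolis-within-Gibbs over the process parameters
#' and the non-centred distortion innovations; EMU series contribute only
#' through first differences, so the posterior is invariant to the level bias
#' of the service statistics.
#'
#' @param surveys Data frame of survey observations of one country (at least
#'   one row; the model is survey-anchored).
#' @param emus Optional data frame of EMU observations of the same country.
#' @param config An [fit_config()] object.
#' @return An object of class `fpem_fit`: list with sampled trajectories
#'   (`rho`, `cpr`, `ratio`; iterations x years), sampled parameters
#'   (`params`), `years`, `chain` index per sample, per-year `quantiles`,
#'   convergence `diagnostics` (split-chain R-hat and effective sample size
#'   for mCPR at the first, middle and last grid year), and `provenance`.
#' @export
fit_mcpr <- function(surveys, emus = NULL, config = fit_config()) {
  if (is.null(surveys) || nrow(surveys) == 0L)
    stop("at least one survey observation is required: the model is ",
         "survey-anchored and EMU levels cannot identify mCPR", call. = FALSE)
  cc <- unique(as.character(surveys$country_code))
  if (length(cc) > 1L)
    stop("surveys span multiple countries: ", paste(cc, collapse = ", "),
         call. = FALSE)
  if (!is.null(emus) && nrow(emus) > 0L) {
    ecc <- unique(as.character(emus$country_code))
    if (length(ecc) > 1L || (length(cc) == 1L && ecc != cc))
      stop("EMU data do not match the survey country", call. = FALSE)
  }
  start <- if (is.null(config$start_year))
    min(round_year(surveys$year)) - 5L else as.integer(config$start_year)
  years <- start:as.integer(config$end_year)

  dat <- build_sampler_data(surveys, emus, config, years)
  init0 <- theta_init(dat, config$priors$fixed)

  chains <- vector("list", config$chains)
  with_seed(config$seed, {
    for (ch in seq_len(config$chains)) {
      th <- init0
      free <- !dat$fixed
      th[free] <- th[free] + stats::rnorm(sum(free), 0, 0.1)
      # keep jittered inits inside their supports
      th["phi_l"] <- min(max(th["phi_l"], 0), config$priors$phi_max - 1e-6)
      th["phi_r"] <- min(max(th["phi_r"], 0), config$priors$phi_max - 1e-6)
      th["tau_l"] <- max(th["tau_l"], 1e-4)
      th["tau_r"] <- max(th["tau_r"], 1e-4)
      for (nm in names(config$priors$fixed))
        th[nm] <- config$priors$fixed[[nm]]
      xiL <- stats::rnorm(dat$T, 0, 0.1)
      xiR <- stats::rnorm(dat$T, 0, 0.1)
      chains[[ch]] <- run_mcmc_chain(dat, config$warmup, config$iter,
                                     unname(th), xiL, xiR)
    }
  })

  rho <- do.call(rbind, lapply(chains, `[[`, "rho"))
  cpr <- do.call(rbind, lapply(chains, `[[`, "cpr"))
  ratio <- do.call(rbind, lapply(chains, `[[`, "ratio"))
  params <- do.call(rbind, lapply(chains, `[[`, "theta"))
  colnames(params) <- theta_names()
  chain <- rep(seq_len(config$chains), each = config$iter)

  mon <- unique(c(1L, (length(years) + 1L) %/% 2L, length(years)))
  diagnostics <- do.call(rbind, lapply(mon, function(t) {
    m <- matrix(rho[, t], ncol = config$chains)
    data.frame(year = years[t], rhat = split_rhat(m), ess = ess_bulk(m))
  }))
  nwarn <- 0L
  if (any(diagnostics$rhat > 1.05, na.rm = TRUE)) {
    nwarn <- nwarn + 1L
    warning("convergence: split-chain R-hat exceeds 1.05 for mCPR at ",
            "monitored year(s); consider more iterations", call. = FALSE)
  }
  if (any(diagnostics$ess < 400, na.rm = TRUE)) {
    nwarn <- nwarn + 1L
    warning("convergence: effective sample size below 400 for mCPR at ",
            "monitored year(s); consider more iterations", call. = FALSE)
  }

  qs <- trajectory_quantiles(rho, years, c(0.025, 0.1, 0.5, 0.9, 0.975))
  res <- list(country_code = if (length(cc)) cc else NA_character_,
              years = years, rho = rho, cpr = cpr, ratio = ratio,
              params = params, chain = chain, quantiles = qs,
              diagnostics = diagnostics, n_warnings = nwarn,
              variant = if (length(dat$emu_dz) > 0) "survey_emu"
                        else "survey_only",
              provenance = list(
                config_hash = obj_digest(config),
                data_hash = obj_digest(list(surveys, emus)),
                seed = config$seed),
              config = config)
  class(res) <- "fpem_fit"
  res
}

trajectory_quantiles <- function(draws, years, probs) {
  qm <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(year = years, qm, check.names = FALSE)
  names(out) <- c("year", paste0("q", probs))
  out
}

#' Posterior quantiles of mCPR per year
#'
#' @param fit An `fpem_fit`.
#' @param probs Probabilities strictly inside (0, 1).
#' @return Data frame with column `year` and one `q<prob>` column per
#'   requested probability (monotone within each row).
#' @export
summarize_fit <- function(fit, probs = c(0.025, 0.1, 0.5, 0.9, 0.975)) {
  if (!inherits(fit, "fpem_fit")) stop("fit must be an fpem_fit", call. = FALSE)
  if (nrow(fit$rho) == 0L) stop("empty sample set", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("probs must lie strictly inside (0, 1)", call. = FALSE)
  trajectory_quantiles(fit$rho, fit$years, sort(probs))
}

#' Compare two fitted runs at a target year
#'
#' Differences between two posterior summaries of mCPR at one calendar year,
#' on the percentage-point scale: difference in medians (a - b), its absolute
#' value, and the difference in the widths of the central 95% intervals.
#' Accepts `fpem_fit` objects or estimate summaries (data frames with
#' columns `year`, `q0.025`, `q0.5`, `q0.975`).
#'
#' @param a,b The two runs.
#' @param year Calendar year covered by both runs.
#' @return A list of class `fpem_comparison` with `year`, `median_diff_pp`,
#'   `abs_median_diff_pp`, and `width95_diff_pp`.
#' @export
compare_runs <- function(a, b, year) {
  qa <- comparison_row(a, year)
  qb <- comparison_row(b, year)
  out <- list(year = as.integer(year),
              median_diff_pp = 100 * (qa$med - qb$med),
              abs_median_diff_pp = abs(100 * (qa$med - qb$med)),
              width95_diff_pp = 100 * ((qa$hi - qa$lo) - (qb$hi - qb$lo)))
  class(out) <- "fpem_comparison"
  out
}

comparison_row <- function(x, year) {
  s <- if (inherits(x, "fpem_fit")) x$quantiles else x
  need <- c("year", "q0.025", "q0.5", "q0.975")
  if (!all(need %in% names(s)))
    stop("run summary lacks required quantile columns", call. = FALSE)
  i <- match(as.integer(year), as.integer(s$year))
  if (is.na(i)) stop("year ", year, " is outside the run's grid", call. = FALSE)
  list(med = s[["q0.5"]][i], lo = s[["q0.025"]][i], hi = s[["q0.975"]][i])
}

#' @export
print.fpem_fit <- function(x, ...) {
  cat("fpem_fit:", x$country_code, "(", x$variant, ")\n")
  cat("  years:", min(x$years), "-", max(x$years),
      " samples:", nrow(x$rho), "\n")
  cat("  diagnostics (mCPR):\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' @export
print.fpem_comparison <- function(x, ...) {
  cat(sprintf("mCPR comparison at %d: median diff %+0.2f pp (abs %0.2f), ",
              x$year, x$median_diff_pp, x$abs_median_diff_pp))
  cat(sprintf("95%% UI width diff %+0.2f pp\n", x$width95_diff_pp))
  invisible(x)
}
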