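#' @keywords internal
emu_source_types <- function() {
  c("comm_clients", "comm_facilities", "service_visits", "fp_users")
}

#' Packaged source-type standard deviations of annual EMU change-bias
#'
#' Default standard deviations of the difference between annual changes in
#' EMU and annual changes in mCPR, per service-statistics source type, on the
#' proportion scale, together with the number of change pairs behind each
#' estimate. These are the packaged defaults used by [emu_loglik()] when no
#' freshly estimated table is supplied; [estimate_sigma()] produces a table
#' of the same shape from data.
#'
#' @return A data frame of class `sigma_table` with columns `source_type`,
#'   `sigma`, `n_pairs`.
#' @export
default_sigma_table <- function() {
  out <- data.frame(
    source_type = c("comm_clients", "comm_facilities", "fp_users",
                    "service_visits"),
    sigma = c(0.04, 0.02, 0.09, 0.03),
    n_pairs = c(52L, 16L, 25L, 21L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sigma_table", "data.frame")
  out
}

# sigma lookup with the documented floor for degenerate estimates
sigma_for <- function(sigma_table, source_type, floor = 0.005) {
  i <- match(source_type, sigma_table$source_type)
  if (is.na(i))
    stop("unknown source_type '", source_type, "'; known types: ",
         paste(sigma_table$source_type, collapse = ", "), call. = FALSE)
  s <- sigma_table$sigma[i]
  if (s < floor) {
    warning("sigma for source_type '", source_type, "' (", signif(s, 3),
            ") floored at ", floor, " for likelihood use", call. = FALSE)
    s <- floor
  }
  s
}

# Log-ratio transform of (modern, traditional) with the boundary clamp:
# exact zeros are replaced by 0.25/ess before transformation.
survey_logratios <- function(modern, traditional, ess = 1000) {
  eps <- 0.25 / ess
  modern <- ifelse(modern == 0, eps, modern)
  traditional <- ifelse(traditional == 0, eps, traditional)
  none <- 1 - modern - traditional
  if (any(none <= 0))
    stop("modern + traditional must be < 1 for the log-ratio transform",
         call. = FALSE)
  cbind(log(modern / none), log(traditional / none))
}

# Delta-method sampling variances of the two log-ratios, treating the
# proportion-scale errors as independent (diagonal covariance).
logratio_sampling_var <- function(modern, traditional, se_modern,
                                  se_traditional, ess = 1000) {
  eps <- 0.25 / ess
  m <- ifelse(modern == 0, eps, modern)
  tr <- ifelse(traditional == 0, eps, traditional)
  none <- 1 - m - tr
  sm <- ifelse(is.na(se_modern), 0, se_modern)
  st <- ifelse(is.na(se_traditional), 0, se_traditional)
  v1 <- (1 / m + 1 / none)^2 * sm^2 + (1 / none)^2 * st^2
  v2 <- (1 / none)^2 * sm^2 + (1 / tr + 1 / none)^2 * st^2
  cbind(v1, v2)
}

round_year <- function(y) as.integer(floor(y + 0.5))

#' Survey data-model log likelihood
#'
#' The observed modern and traditional prevalence proportions are linked to
#' the modelled ones through a bivariate normal distribution on the log-ratios
#' of modern and traditional prevalence to non-use, with diagonal covariance:
#' per component, the variance is the survey sampling variance mapped to the
#' log-ratio scale by the delta method (when standard errors are recorded)
#' plus a source-specific non-sampling variance.
#'
#' @param obs Data frame of survey observations (columns `year`, `modern`,
#'   `traditional`, optionally `se_modern`, `se_traditional`, `source_label`)
#'   for the country of the trajectory. Decimal years are rounded half-up to
#'   the annual grid.
#' @param traj An `fpem_trajectory` covering the observation years.
#' @param nonsampling_sd Named numeric vector of non-sampling standard
#'   deviations on the log-ratio scale, looked up by `source_label`; the
#'   `default` entry covers unlisted sources.
#' @param ess Effective sample size used to clamp exact-zero proportions
#'   (clamp value `0.25/ess`).
#' @return The summed log likelihood over the rows of `obs`.
#' @export
survey_loglik <- function(obs, traj,
                          nonsampling_sd = c(DHS = 0.1, default = 0.2),
                          ess = 1000) {
  if (nrow(obs) == 0L) return(0)
  if (any(obs$modern + obs$traditional >= 1))
    stop("survey rows with modern + traditional >= 1 are not permitted",
         call. = FALSE)
  yr <- round_year(obs$year)
  idx <- match(yr, traj$year)
  if (anyNA(idx))
    stop("survey year(s) outside the trajectory grid: ",
         paste(unique(yr[is.na(idx)]), collapse = ", "), call. = FALSE)

  y <- survey_logratios(obs$modern, obs$traditional, ess = ess)
  se_m <- if ("se_modern" %in% names(obs)) obs$se_modern else rep(NA_real_, nrow(obs))
  se_t <- if ("se_traditional" %in% names(obs)) obs$se_traditional else rep(NA_real_, nrow(obs))
  vs <- logratio_sampling_var(obs$modern, obs$traditional, se_m, se_t, ess = ess)

  lab <- if ("source_label" %in% names(obs)) as.character(obs$source_label)
         else rep("default", nrow(obs))
  ns <- nonsampling_sd[lab]
  ns[is.na(ns)] <- nonsampling_sd[["default"]]

  m_star <- traj$mcpr[idx]
  t_star <- traj$cpr[idx] - traj$mcpr[idx]
  none_star <- 1 - traj$cpr[idx]
  if (any(m_star <= 0 | t_star <= 0 | none_star <= 0))
    stop("trajectory implies boundary proportions at an observation year",
         call. = FALSE)
  mu1 <- log(m_star / none_star)
  mu2 <- log(t_star / none_star)

  sd1 <- sqrt(vs[, 1] + ns^2)
  sd2 <- sqrt(vs[, 2] + ns^2)
  sum(stats::dnorm(y[, 1], mu1, sd1, log = TRUE) +
      stats::dnorm(y[, 2], mu2, sd2, log = TRUE))
}

#' EMU data-model log likelihood (first differences)
#'
#' Annual changes in an EMU series are unbiased for the corresponding changes
#' in mCPR: for observations in adjacent calendar years,
#' `z_t - z_{t-1} ~ N(mcpr_t - mcpr_{t-1}, sigma_s^2)`. Observation levels
#' never enter, so the likelihood is invariant to a constant shift of the
#' whole series (the level bias of service statistics is absorbed by design).
#' A series needs at least two observations to contribute; pairs separated by
#' a gap are skipped unless `gap_scaling` is on, in which case a k-year gap
#' contributes with variance `k * sigma_s^2`.
#'
#' @param series Data frame of EMU observations (`year`, `emu`,
#'   `source_type`) of a single country and single source type.
#' @param traj An `fpem_trajectory` covering the series years.
#' @param sigma A `sigma_table`; defaults to [default_sigma_table()].
#' @param gap_scaling Include non-adjacent pairs with variance scaled by the
#'   gap length. Default `FALSE` (gaps are skipped with a message).
#' @return The summed log likelihood over usable pairs (0 when fewer than two
#'   observations are available, with a warning).
#' @export
emu_loglik <- function(series, traj, sigma = default_sigma_table(),
                       gap_scaling = FALSE) {
  st <- unique(as.character(series$source_type))
  if (length(st) > 1L)
    stop("series mixes source types: ", paste(st, collapse = ", "),
         call. = FALSE)
  if (nrow(series) < 2L) {
    warning("EMU series has fewer than 2 observations; at least 2 years of ",
            "data are needed to compute a rate of change - contribution is 0",
            call. = FALSE)
    return(0)
  }
  s <- sigma_for(sigma, st)
  series <- series[order(series$year), , drop = FALSE]
  yr <- as.integer(series$year)
  idx <- match(yr, traj$year)
  if (anyNA(idx))
    stop("EMU year(s) outside the trajectory grid: ",
         paste(yr[is.na(idx)], collapse = ", "), call. = FALSE)
  gap <- diff(yr)
  dz <- diff(series$emu)
  drho <- traj$mcpr[idx[-1]] - traj$mcpr[idx[-length(idx)]]
  use <- if (gap_scaling) gap >= 1 else gap == 1L
  skipped <- sum(!use)
  if (skipped > 0)
    message(skipped, " non-adjacent EMU pair(s) skipped (gap > 1 year)")
  if (!any(use)) return(0)
  sds <- if (gap_scaling) s * sqrt(gap[use]) else rep(s, sum(use))
  sum(stats::dnorm(dz[use], drho[use], sds, log = TRUE))
}

#' Estimate source-type change-bias standard deviations
#'
#' Root-mean-square of the residuals `d_emu - d_mcpr` per source type, with
#' denominator `n_s` (no degrees-of-freedom correction): the estimator used
#' to parameterise the EMU data model from observed change pairs.
#'
#' @param pairs Data frame of change pairs as produced by
#'   [build_change_pairs()] (columns `source_type`, `d_emu`, `d_mcpr`).
#' @return A `sigma_table` with one row per source type present in `pairs`.
#'   An exactly zero estimate is flagged in a `degenerate` column and floored
#'   before likelihood use by [emu_loglik()].
#' @examples
#' pairs <- data.frame(source_type = "fp_users",
#'                     d_emu = c(0.05, 0.01), d_mcpr = c(0.02, 0.04))
#' estimate_sigma(pairs) # RMS of {+0.03, -0.03} = 0.03
#' @export
estimate_sigma <- function(pairs) {
  if (nrow(pairs) == 0L)
    stop("no change pairs supplied", call. = FALSE)
  resid <- pairs$d_emu - pairs$d_mcpr
  types <- unique(as.character(pairs$source_type))
  out <- do.call(rbind, lapply(types, function(ty) {
    r <- resid[pairs$source_type == ty]
    data.frame(source_type = ty, sigma = sqrt(mean(r^2)),
               n_pairs = length(r), stringsAsFactors = FALSE)
  }))
  out$degenerate <- out$sigma == 0
  if (any(out$degenerate))
    warning("zero residual variance for source type(s): ",
            paste(out$source_type[out$degenerate], collapse = ", "),
            " - estimate is degenerate and will be floored in likelihood use",
            call. = FALSE)
  class(out) <- c("sigma_table", "data.frame")
  out
}

#' Build EMU/mCPR annual change pairs over survey-overlap periods
#'
#' For each country, EMU observations are kept only from the country's first
#' survey year through its most recent survey year (the period where EMUs
#' overlap the survey record), and within each source type pairs are formed
#' only between observations in adjacent calendar years. The matching mCPR
#' change is taken from an annual point-estimate series at the same pair of
#' years.
#'
#' @param emus Data frame of EMU observations (`country_code`, `year`, `emu`,
#'   `source_type`).
#' @param estimates Data frame of annual mCPR point estimates
#'   (`country_code`, `year`, `mcpr`).
#' @param surveys Data frame of surveys (`country_code`, `year`) supplying
#'   each country's overlap window.
#' @return Data frame of change pairs: `country_code`, `source_type`,
#'   `year_to`, `d_emu`, `d_mcpr`.
#' @export
build_change_pairs <- function(emus, estimates, surveys) {
  out <- list()
  for (cc in unique(emus$country_code)) {
    sv <- surveys[surveys$country_code == cc, , drop = FALSE]
    if (nrow(sv) == 0L) next  # no overlap period exists
    est <- estimates[estimates$country_code == cc, , drop = FALSE]
    if (nrow(est) == 0L) {
      message("country ", cc, " absent from the estimate series; ",
              "its EMU observations are skipped")
      next
    }
    win <- range(round_year(sv$year))
    e <- emus[emus$country_code == cc & emus$year >= win[1] &
                emus$year <= win[2], , drop = FALSE]
    for (ty in unique(as.character(e$source_type))) {
      es <- e[e$source_type == ty, , drop = FALSE]
      es <- es[order(es$year), , drop = FALSE]
      if (nrow(es) < 2L) next
      adj <- which(diff(as.integer(es$year)) == 1L)
      for (i in adj) {
        y_to <- as.integer(es$year[i + 1])
        p_to <- est$mcpr[match(y_to, est$year)]
        p_from <- est$mcpr[match(y_to - 1L, est$year)]
        if (is.na(p_to) || is.na(p_from)) next
        out[[length(out) + 1L]] <- data.frame(
          country_code = cc, source_type = ty, year_to = y_to,
          d_emu = es$emu[i + 1] - es$emu[i], d_mcpr = p_to - p_from,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(country_code = character(0), source_type = character(0),
                      year_to = integer(0), d_emu = numeric(0),
                      d_mcpr = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
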