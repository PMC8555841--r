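#' Process-model parameters for one country
#'
#' Bundles the parameters of the latent prevalence process. Total contraceptive
#' prevalence (CPR) is modelled as `L_t = ptilde * plogis(eta_t)` where the
#' transformed state `eta_t` drifts at `omega_l` per year (constant drift on
#' this scale is logistic growth towards the asymptote `ptilde`) and carries
#' AR(1) time-series distortions with coefficient `phi_l` and innovation
#' standard deviation `tau_l`. The ratio of modern to total prevalence follows
#' the same construction with asymptote 1 (`omega_r`, `phi_r`, `tau_r`), and
#' mCPR is the product of the two components.
#'
#' @param ptilde Asymptote of total CPR, a proportion strictly inside (0, 1).
#' @param omega_l Drift of the transformed total-CPR state, logit units/year.
#' @param phi_l AR(1) coefficient of the total-CPR distortions, in \[0, 0.95\].
#' @param tau_l Innovation standard deviation of the total-CPR distortions
#'   (logit units, non-negative).
#' @param omega_r,phi_r,tau_r Same three quantities for the modern/total ratio.
#' @param eta0 Initial transformed state of total CPR, `qlogis(L_0 / ptilde)`.
#' @param zeta0 Initial transformed state of the ratio, `qlogis(R_0)`.
#' @return An object of class `fpem_params` (a named list).
#' @examples
#' p <- process_params(ptilde = 0.8, omega_l = 0.1, tau_l = 0, tau_r = 0)
#' simulate_trajectory(p, years = 2000:2005, seed = 1)
#' @export
process_params <- function(ptilde = 0.8, omega_l = 0.05, phi_l = 0.5,
                           tau_l = 0.05, omega_r = 0.05, phi_r = 0.5,
                           tau_r = 0.05, eta0 = 0, zeta0 = 0) {
  p <- list(ptilde = ptilde, omega_l = omega_l, phi_l = phi_l, tau_l = tau_l,
            omega_r = omega_r, phi_r = phi_r, tau_r = tau_r,
            eta0 = eta0, zeta0 = zeta0)
  validate_params(p)
  class(p) <- "fpem_params"
  p
}

#' @keywords internal
validate_params <- function(p) {
  chk <- function(ok, name, rule) {
    if (!isTRUE(ok)) stop("invalid process parameter '", name, "': ", rule,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("ptilde", "omega_l", "phi_l", "tau_l", "omega_r", "phi_r",
               "tau_r", "eta0", "zeta0")) {
    chk(num1(p[[nm]]), nm, "must be a single finite number")
  }
  chk(p$ptilde > 0 && p$ptilde < 1, "ptilde", "must lie strictly in (0, 1)")
  chk(p$tau_l >= 0, "tau_l", "must be >= 0")
  chk(p$tau_r >= 0, "tau_r", "must be >= 0")
  chk(p$phi_l >= 0 && p$phi_l < 1, "phi_l", "must lie in [0, 1)")
  chk(p$phi_r >= 0 && p$phi_r < 1, "phi_r", "must lie in [0, 1)")
  invisible(p)
}

#' One step of the distorted drift recursion
#'
#' Advances the transformed state of either prevalence component by one year:
#' the distortion is updated as `eps = phi * eps_prev + innovation` and the
#' state as `eta = eta_prev + drift + eps`. Pure arithmetic; the stochastic
#' part lives in the caller, which supplies the innovation.
#'
#' @param eta_prev State at the previous year (logit scale).
#' @param eps_prev Distortion at the previous year.
#' @param drift Expected per-year change of the state (logit units).
#' @param phi AR(1) coefficient in \[0, 1).
#' @param innovation Innovation added to the distortion this year.
#' @return A list with elements `eta` and `eps`.
#' @examples
#' step_state(0, 0.2, 0, 0.5, 0) # eps = 0.1, eta = 0.1
#' @export
step_state <- function(eta_prev, eps_prev, drift, phi, innovation) {
  if (!is.numeric(phi) || phi < 0 || phi >= 1)
    stop("phi must lie in [0, 1)", call. = FALSE)
  eps <- phi * eps_prev + innovation
  list(eta = eta_prev + drift + eps, eps = eps)
}

#' Simulate a latent prevalence trajectory
#'
#' Evolves both transformed states over an annual grid with independent
#' Gaussian innovations and maps them back to the natural scale:
#' `cpr_t = ptilde * plogis(eta_t)`, `ratio_t = plogis(zeta_t)`,
#' `mcpr_t = cpr_t * ratio_t`. The initial distortion of each component is
#' drawn from its stationary distribution `N(0, tau^2 / (1 - phi^2))`.
#'
#' @param params An `fpem_params` object.
#' @param years Non-empty vector of consecutive integer calendar years.
#' @param seed Optional integer seed. When supplied, the global RNG state is
#'   restored on exit so the simulation is reproducible and side-effect free;
#'   when `NULL` the current RNG stream is consumed (used by the cohort
#'   generator to keep a single seeded stream).
#' @return A data frame of class `fpem_trajectory` with columns `year`,
#'   `cpr`, `ratio`, `mcpr` and attribute `ptilde`.
#' @export
simulate_trajectory <- function(params, years, seed = NULL) {
  validate_params(params)
  if (length(years) < 1L) stop("years must be non-empty", call. = FALSE)
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be consecutive integers", call. = FALSE)
  n <- length(years)

  draw <- function() {
    sL <- if (params$tau_l > 0)
      params$tau_l / sqrt(1 - params$phi_l^2) else 0
    sR <- if (params$tau_r > 0)
      params$tau_r / sqrt(1 - params$phi_r^2) else 0
    list(eps0_l = stats::rnorm(1, 0, sL),
         eps0_r = stats::rnorm(1, 0, sR),
         innov_l = if (n > 1) stats::rnorm(n - 1, 0, params$tau_l) else numeric(0),
         innov_r = if (n > 1) stats::rnorm(n - 1, 0, params$tau_r) else numeric(0))
  }
  z <- if (is.null(seed)) draw() else with_seed(seed, draw())

  eta <- zeta <- numeric(n)
  eta[1] <- params$eta0
  zeta[1] <- params$zeta0
  eL <- z$eps0_l
  eR <- z$eps0_r
  if (n > 1) {
    for (t in 2:n) {
      sl <- step_state(eta[t - 1], eL, params$omega_l, params$phi_l,
                       z$innov_l[t - 1])
      eta[t] <- sl$eta
      eL <- sl$eps
      sr <- step_state(zeta[t - 1], eR, params$omega_r, params$phi_r,
                       z$innov_r[t - 1])
      zeta[t] <- sr$eta
      eR <- sr$eps
    }
  }
  cpr <- params$ptilde * stats::plogis(eta)
  ratio <- stats::plogis(zeta)
  traj <- data.frame(year = years, cpr = cpr, ratio = ratio,
                     mcpr = cpr * ratio)
  attr(traj, "ptilde") <- params$ptilde
  class(traj) <- c("fpem_trajectory", "data.frame")
  traj
}

#' Modern contraceptive prevalence from its two components
#'
#' @param L Total contraceptive prevalence, proportion in \[0, 1\].
#' @param R Ratio of modern to total prevalence, proportion in \[0, 1\].
#' @return `L * R`, the mCPR. Vectorised.
#' @examples
#' mcpr(0.6, 0.5)
#' @export
mcpr <- function(L, R) {
  if (any(!is.finite(L)) || any(L < 0) || any(L > 1))
    stop("L must be a proportion in [0, 1]", call. = FALSE)
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("R must be a proportion in [0, 1]", call. = FALSE)
  L * R
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
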