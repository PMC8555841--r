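#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the usual between/within variance ratio
#' is computed on the resulting 2m sequences.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return The split R-hat (1 indicates convergence; NA for constant draws).
#' @export
split_rhat <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  if (n < 2L) return(NA_real_)
  mu <- colMeans(sp)
  W <- mean(apply(sp, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of posterior draws
#'
#' Autocorrelation-based bulk effective sample size on split chains, with
#' chain-averaged autocorrelations truncated by Geyer's initial monotone
#' positive-pair sequence.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Estimated effective sample size (capped at the total draw count).
#' @export
ess_bulk <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(sp, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B / n

  max_lag <- min(n - 1L, 250L)
  acov <- sapply(seq_len(m), function(j) {
    x <- sp[, j] - mean(sp[, j])
    vapply(0:max_lag, function(k) {
      sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
    }, numeric(1))
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1

  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 1
  k <- 2
  prev_pair <- Inf
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    k <- k + 2
  }
  min(m * n / tau, m * n)
}

split_chains <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2L
  if (half < 1L) return(draws)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1):n, , drop = FALSE])
}
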