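#' Hold out each country's most recent survey
#'
#' Splits a multi-country survey table into a training set and a test set
#' that contains, per country, the single most recent observation (latest
#' decimal year; ties broken by stable input order with a message). A
#' country with exactly one survey cannot be trained on and is dropped from
#' both sets with a message.
#'
#' @param surveys Multi-country survey data frame.
#' @return List with elements `train` and `test` (disjoint; their union is
#'   the input minus dropped single-survey countries).
#' @export
holdout_split <- function(surveys) {
  train_idx <- integer(0)
  test_idx <- integer(0)
  for (cc in unique(surveys$country_code)) {
    rows <- which(surveys$country_code == cc)
    if (length(rows) == 1L) {
      message("country ", cc, " has a single survey and is dropped from ",
              "the hold-out split")
      next
    }
    yrs <- surveys$year[rows]
    tied <- rows[yrs == max(yrs)]
    if (length(tied) > 1L)
      message("country ", cc, " has tied most-recent survey years; ",
              "the last in input order goes to the test set")
    tst <- tied[length(tied)]
    test_idx <- c(test_idx, tst)
    train_idx <- c(train_idx, setdiff(rows, tst))
  }
  list(train = surveys[sort(train_idx), , drop = FALSE],
       test = surveys[sort(test_idx), , drop = FALSE])
}

#' Interval score of a central prediction interval
#'
#' Proper scoring rule for a `(1 - alpha)` central interval: the interval
#' width, plus `2/alpha` times the breach distance when the observation
#' falls outside. Smaller is better; equals the width when the observation
#' is covered.
#'
#' @param lower,upper Interval endpoints (`lower <= upper`).
#' @param x Observed value.
#' @param alpha Nominal non-coverage level in (0, 1).
#' @return The score (vectorised over its arguments).
#' @examples
#' interval_score(0.2, 0.4, 0.45, 0.05) # 0.2 + 40 * 0.05 = 2.2
#' @export
interval_score <- function(lower, upper, x, alpha = 0.05) {
  if (any(lower > upper)) stop("lower must not exceed upper", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  (upper - lower) +
    (2 / alpha) * pmax(lower - x, 0) +
    (2 / alpha) * pmax(x - upper, 0)
}

#' Score held-out survey predictions
#'
#' @param predictions Data frame with one row per test point: columns
#'   `country_code`, `median`, `lower95`, `upper95`.
#' @param test Held-out surveys (columns `country_code`, `modern`); the
#'   observed value scored is the modern prevalence proportion.
#' @return A list of class `fpem_metrics`: `n`, `coverage`, `mean_error`
#'   (observed - predicted median), `rmse`, and `mean_interval_score` at
#'   `alpha = 0.05`, all on the proportion scale.
#' @export
evaluate_predictions <- function(predictions, test) {
  i <- match(test$country_code, predictions$country_code)
  if (anyNA(i))
    stop("no prediction for test country/countries: ",
         paste(test$country_code[is.na(i)], collapse = ", "), call. = FALSE)
  pred <- predictions[i, , drop = FALSE]
  obs <- test$modern
  err <- obs - pred$median
  out <- list(
    n = length(obs),
    coverage = mean(obs >= pred$lower95 & obs <= pred$upper95),
    mean_error = mean(err),
    rmse = sqrt(mean(err^2)),
    mean_interval_score = mean(interval_score(pred$lower95, pred$upper95,
                                              obs, alpha = 0.05)))
  class(out) <- "fpem_metrics"
  out
}

#' @export
print.fpem_metrics <- function(x, ...) {
  cat(sprintf("n = %d  coverage = %.2f  mean error = %+.4f  rmse = %.4f  interval score = %.4f\n",
              x$n, x$coverage, x$mean_error, x$rmse, x$mean_interval_score))
  invisible(x)
}

metrics_row <- function(m, variant) {
  data.frame(model_variant = variant, n = m$n, coverage = m$coverage,
             mean_error = m$mean_error, rmse = m$rmse,
             interval_score = m$mean_interval_score,
             stringsAsFactors = FALSE)
}

#' Out-of-sample hold-out validation of both model variants
#'
#' Excludes each country's most recent survey, fits the survey-only model
#' and the survey+EMU model on the remainder, predicts the held-out modern
#' prevalence, and scores both variants against the same test set. The EMU
#' arm keeps a single source type per country (smallest change-bias sd
#' first) and drops countries that have no EMU observation after the most
#' recent training survey; the paired comparison is restricted to countries
#' completing both arms. When the EMU table is empty the two arms coincide.
#'
#' @param surveys Multi-country survey data frame (>= 2 surveys somewhere).
#' @param emus Multi-country EMU data frame (may have zero rows).
#' @param config An [fit_config()]; per-country fits derive their seeds from
#'   `config$seed`.
#' @return List with `survey_only` and `survey_emu` (class `fpem_metrics`),
#'   `table` (metrics data frame, one row per variant), `per_country`
#'   (test-point predictions for both arms), and `skipped` (named counts).
#' @export
run_validation <- function(surveys, emus, config = fit_config()) {
  sp <- holdout_split(surveys)
  if (nrow(sp$test) == 0L)
    stop("no country has at least 2 surveys; validation impossible",
         call. = FALSE)
  have_emus <- !is.null(emus) && nrow(emus) > 0L
  countries <- unique(sp$train$country_code)
  rows <- list()
  skipped_fit <- 0L
  skipped_emu <- 0L

  for (k in seq_along(countries)) {
    cc <- countries[k]
    tr <- sp$train[sp$train$country_code == cc, , drop = FALSE]
    ts <- sp$test[sp$test$country_code == cc, , drop = FALSE]
    test_year <- round_year(ts$year[1])
    last_train <- max(round_year(tr$year))

    ce <- if (have_emus) emus[emus$country_code == cc, , drop = FALSE]
          else emus
    arm_emu <- NULL
    if (have_emus) {
      sel <- select_single_source(ce)
      if (nrow(sel) == 0L || !any(sel$year > last_train)) {
        skipped_emu <- skipped_emu + 1L
        arm_emu <- NA  # country leaves the EMU arm
      } else arm_emu <- sel
    }

    cfg <- config
    cfg$seed <- config$seed + 101L * k
    cfg$end_year <- max(config$end_year, test_year)
    pred <- tryCatch({
      fit_a <- suppressWarnings(fit_mcpr(tr, emus = NULL, config = cfg))
      qa <- fit_a$quantiles[match(test_year, fit_a$quantiles$year), ]
      qb <- NULL
      if (have_emus && is.data.frame(arm_emu)) {
        fit_b <- suppressWarnings(fit_mcpr(tr, emus = arm_emu, config = cfg))
        qb <- fit_b$quantiles[match(test_year, fit_b$quantiles$year), ]
      } else if (!have_emus) {
        qb <- qa  # arms coincide when no EMU data exist at all
      }
      list(qa = qa, qb = qb)
    }, error = function(e) {
      message("country ", cc, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(pred)) {
      skipped_fit <- skipped_fit + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      country_code = cc, test_year = test_year, observed = ts$modern[1],
      so_median = pred$qa[["q0.5"]], so_lower = pred$qa[["q0.025"]],
      so_upper = pred$qa[["q0.975"]],
      emu_median = if (is.null(pred$qb)) NA_real_ else pred$qb[["q0.5"]],
      emu_lower = if (is.null(pred$qb)) NA_real_ else pred$qb[["q0.025"]],
      emu_upper = if (is.null(pred$qb)) NA_real_ else pred$qb[["q0.975"]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no country completed validation", call. = FALSE)
  per_country <- do.call(rbind, rows)

  # paired comparison on the intersection of completed arms
  both <- per_country[!is.na(per_country$emu_median), , drop = FALSE]
  if (nrow(both) == 0L)
    stop("no country completed both validation arms", call. = FALSE)
  test_tbl <- data.frame(country_code = both$country_code,
                         modern = both$observed, stringsAsFactors = FALSE)
  m_so <- evaluate_predictions(
    data.frame(country_code = both$country_code, median = both$so_median,
               lower95 = both$so_lower, upper95 = both$so_upper), test_tbl)
  m_emu <- evaluate_predictions(
    data.frame(country_code = both$country_code, median = both$emu_median,
               lower95 = both$emu_lower, upper95 = both$emu_upper), test_tbl)

  list(survey_only = m_so, survey_emu = m_emu,
       table = rbind(metrics_row(m_emu, "survey_emu"),
                     metrics_row(m_so, "survey_only")),
       per_country = per_country,
       skipped = c(fit_errors = skipped_fit, emu_arm_dropped = skipped_emu))
}
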