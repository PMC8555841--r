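#' Read a survey CSV
#'
#' Strict schema: header columns `country_code, year, modern, traditional,
#' se_modern, se_traditional, source_label` (the last three optional, blanks
#' allowed), UTF-8, comma-separated, period decimal marker. Proportions must
#' lie in \[0, 1); rows violating invariants are rejected with their row
#' numbers.
#'
#' @param path Path to the CSV file.
#' @return Validated survey data frame (all seven columns present).
#' @export
read_surveys <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("country_code", "year", "modern", "traditional")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("survey file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (opt in c("se_modern", "se_traditional"))
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  if (!"source_label" %in% names(df)) df$source_label <- ""
  df <- df[, c(required, "se_modern", "se_traditional", "source_label")]
  if (nrow(df) == 0L) return(df)

  df$country_code <- trimws(as.character(df$country_code))
  for (col in c("year", "modern", "traditional", "se_modern",
                "se_traditional"))
    df[[col]] <- as.numeric(df[[col]])

  if (any(df$modern > 1 | df$traditional > 1, na.rm = TRUE))
    stop("survey proportions exceed 1; values look like percentages - ",
         "divide by 100 to get proportions", call. = FALSE)
  bad <- which(is.na(df$year) | is.na(df$modern) | is.na(df$traditional) |
                 df$modern < 0 | df$traditional < 0 |
                 df$modern + df$traditional >= 1 |
                 (!is.na(df$se_modern) & df$se_modern < 0) |
                 (!is.na(df$se_traditional) & df$se_traditional < 0))
  if (length(bad) > 0)
    stop("invalid survey row(s) (violating proportion invariants): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

normalize_source_type <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[. ]+", "_", y)
  y
}

#' Read an EMU CSV
#'
#' Schema: `country_code, year, emu, source_type` with source types among
#' comm_clients, comm_facilities, service_visits, fp_users (case
#' insensitive; dots and spaces are normalised to underscores, so
#' "comm.clients" and "service visits" are accepted).
#'
#' @param path Path to the CSV file.
#' @return Validated EMU data frame sorted by country, source type, year.
#' @export
read_emu <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("country_code", "year", "emu", "source_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("EMU file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, required]
  if (nrow(df) == 0L) return(df)
  df$country_code <- trimws(as.character(df$country_code))
  df$year <- as.integer(df$year)
  df$emu <- as.numeric(df$emu)
  df$source_type <- normalize_source_type(df$source_type)

  unknown <- setdiff(unique(df$source_type), emu_source_types())
  if (length(unknown) > 0)
    stop("unknown EMU source_type(s): ", paste(unknown, collapse = ", "),
         "; allowed values: ", paste(emu_source_types(), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$emu) | df$emu < 0 | df$emu > 1))
    stop("EMU values must be proportions in [0, 1]", call. = FALSE)
  key <- paste(df$country_code, df$source_type, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    stop("duplicate (country, source_type, year) EMU rows at data line(s): ",
         paste(d + 1L, collapse = ", "), call. = FALSE)  # +1 for the header
  }
  df[order(df$country_code, df$source_type, df$year), , drop = FALSE]
}

#' Write survey / EMU / estimate tables
#'
#' Plain UTF-8 comma-separated files with a header row and empty strings for
#' missing values, matching what [read_surveys()] and [read_emu()] expect.
#'
#' @param df The table to write.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an estimates CSV from a fitted run
#'
#' Columns: `country_code, year, q0.025, q0.1, q0.5, q0.9, q0.975,
#' model_variant`.
#'
#' @param fit An `fpem_fit`.
#' @param path Destination path.
#' @return The estimates data frame, invisibly.
#' @export
write_estimates <- function(fit, path) {
  est <- cbind(country_code = fit$country_code, fit$quantiles,
               model_variant = fit$variant)
  utils::write.csv(est, path, row.names = FALSE, quote = FALSE)
  invisible(est)
}

#' Read an estimates CSV
#' @param path Path written by [write_estimates()].
#' @return Data frame with quantile columns (names preserved).
#' @export
read_estimates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 digest of a file
file_digest <- function(path) unname(tools::md5sum(path))

# md5 digest of an arbitrary R object via its serialization
obj_digest <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 3)
  close(con)
  file_digest(f)
}

#' Build a run manifest
#'
#' Records input-file digests, a config echo, the seed, the package version,
#' any warnings emitted, and a timestamp, so a run can be audited and its
#' inputs re-verified.
#'
#' @param inputs Named character vector of input file paths.
#' @param config The configuration used (echoed as-is).
#' @param seed Integer seed of the run.
#' @param warnings Character vector of warnings emitted during the run.
#' @return A list of class `fpem_manifest`.
#' @export
run_manifest <- function(inputs = character(0), config = NULL, seed = NA,
                         warnings = character(0)) {
  digests <- if (length(inputs) > 0) {
    stats::setNames(vapply(inputs, file_digest, character(1)),
                    if (is.null(names(inputs))) basename(inputs)
                    else names(inputs))
  } else character(0)
  structure(list(inputs = as.list(digests),
                 config = config,
                 seed = seed,
                 package_version = as.character(utils::packageVersion("fpemu")),
                 warnings = as.character(warnings),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC")),
            class = "fpem_manifest")
}

#' Write a run manifest as JSON
#' @param manifest Output of [run_manifest()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  m$config <- config_echo(m$config)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# strip classes recursively so the config echo serialises as plain JSON
config_echo <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) return(lapply(unclass(x), config_echo))
  x
}

#' Load a fit configuration from a YAML file
#'
#' Recognised top-level keys mirror [fit_config()] arguments; `priors` may
#' be a nested map of [prior_settings()] arguments. Unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return An `fpem_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(fit_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$priors)) {
    pknown <- names(formals(prior_settings))
    punknown <- setdiff(names(y$priors), pknown)
    if (length(punknown) > 0)
      stop("unknown prior key(s): ", paste(punknown, collapse = ", "),
           call. = FALSE)
    y$priors <- do.call(prior_settings, y$priors)
  }
  if (!is.null(y$nonsampling_sd)) y$nonsampling_sd <- unlist(y$nonsampling_sd)
  if (!is.null(y$sigma)) {
    s <- as.data.frame(y$sigma, stringsAsFactors = FALSE)
    class(s) <- c("sigma_table", "data.frame")
    y$sigma <- s
  }
  do.call(fit_config, y)
}
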