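# Shared fixture builders. Everything is generated in code; no files.

# A trajectory object with prescribed total CPR and mCPR sequences.
make_traj <- function(years, cpr, mcpr, ptilde = 0.9) {
  traj <- data.frame(year = as.integer(years), cpr = cpr,
                     ratio = mcpr / cpr, mcpr = mcpr)
  attr(traj, "ptilde") <- ptilde
  class(traj) <- c("fpem_trajectory", "data.frame")
  traj
}

# Noise-free surveys read off a trajectory at given years.
surveys_from_traj <- function(traj, years, country = "AAA", sd = 0.01,
                              noise = 0, source_label = "DHS") {
  i <- match(round(years), traj$year)
  stopifnot(!anyNA(i))
  m <- traj$mcpr[i] + noise * rnorm(length(i), 0, sd)
  tr <- (traj$cpr[i] - traj$mcpr[i]) + noise * rnorm(length(i), 0, sd)
  data.frame(country_code = country, year = as.numeric(years),
             modern = pmin(pmax(m, 1e-4), 0.98),
             traditional = pmin(pmax(tr, 1e-4), 0.98),
             se_modern = sd, se_traditional = sd,
             source_label = source_label, stringsAsFactors = FALSE)
}

# Round to the 2^-26 dyadic grid (exact under addition of dyadic constants).
dyadic <- function(x) round(x * 2^26) / 2^26

# EMU table for a single country/source type.
emu_table <- function(years, z, country = "AAA", type = "comm_clients") {
  data.frame(country_code = country, year = as.integer(years), emu = z,
             source_type = type, stringsAsFactors = FALSE)
}

# Small, fast fit configuration for tests.
test_config <- function(...) {
  fit_config(chains = 2, iter = 600, warmup = 400, ...)
}
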