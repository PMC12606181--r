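# Shared fixture builders and brute-force oracles.

# A tiny roster: sites given as a named list site -> bird ids.
fixture_roster <- function(sites = list(s1 = c("A", "B"), s2 = c("C", "D")),
                           sex = NULL) {
  ids <- unlist(sites, use.names = FALSE)
  data.frame(
    id = ids,
    sex = if (is.null(sex)) rep(c("F", "M"), length.out = length(ids)) else sex,
    site = rep(names(sites), lengths(sites))
  )
}

# A schedule of `n_sessions` consecutive sessions of `hours` hours each.
fixture_schedule <- function(n_sessions = 2, hours = 1) {
  data.frame(
    session_id = sprintf("S%02d", seq_len(n_sessions)),
    date = as.character(as.Date("2021-04-01") + (seq_len(n_sessions) - 1L)),
    start = "08:00:00",
    end = sprintf("%02d:00:00", 8L + hours)
  )
}

# Observation records from a compact spec: data.frame-like arguments.
fixture_records <- function(session, t, behavior, actor, receiver,
                            observer = "O1") {
  data.frame(
    session_id = session, observer_id = observer, timestamp = t,
    behavior = behavior, actor = actor, receiver = receiver
  )
}

# Write a records data.frame to a temp CSV and return the path.
records_csv <- function(records) {
  path <- tempfile(fileext = ".csv")
  write.csv(records, path, row.names = FALSE, na = "")
  path
}

# All permutations of a vector (for exhaustive permutation oracles).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Directly build a dyad_bins object from an occurrence table (bypassing raw
# records) for classification-level fixtures.
fixture_bins <- function(occ_df, roster, n_bins = 100L, bin_width = 300) {
  occ <- data.table::as.data.table(occ_df)
  occ[, tier := as.character(tier_of(behavior))]
  occ <- unique(occ, by = c("dyad_id", "behavior", "bin"))
  data.table::setcolorder(occ, c("dyad_id", "behavior", "tier", "bin"))
  structure(
    list(occ = occ, dyads = enumerate_dyads(roster),
         n_bins = n_bins, bin_width = bin_width,
         hours_observed = n_bins * bin_width / 3600, sessions = NULL),
    class = "dyad_bins"
  )
}
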