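# Observation-stream ingestion: rosters, session schedules, raw records,
# dyad enumeration, and 5-minute binarization into a dyad x behaviour x bin
# presence/absence structure.

#' Canonical dyad identifier
#'
#' Dyads are unordered pairs; the identifier joins the two bird ids in
#' lexicographic order with `"--"`, so both orderings of a pair map to the
#' same dyad.
#'
#' @param a,b Character vectors of bird ids (recycled pairwise).
#' @return Character vector of dyad ids.
#' @export
dyad_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

#' Read a bird roster
#'
#' @param path CSV with header columns `id`, `sex` (F/M), `site`.
#' @return Validated data.frame with character columns `id`, `sex`, `site`.
#' @export
read_roster <- function(path) {
  ros <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_roster(ros)
}

validate_roster <- function(roster) {
  need <- c("id", "sex", "site")
  miss <- setdiff(need, names(roster))
  if (length(miss) > 0L) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  roster <- as.data.frame(roster)[need]
  if (anyDuplicated(roster$id)) {
    stop("duplicate bird id(s) in roster: ",
         paste(unique(roster$id[duplicated(roster$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(roster$sex %in% c("F", "M"))) {
    stop("roster sex must be 'F' or 'M'", call. = FALSE)
  }
  if (any(is.na(roster$site) | roster$site == "")) {
    stop("roster site must be non-empty", call. = FALSE)
  }
  roster
}

#' Read an observation-session schedule
#'
#' @param path CSV with header columns `session_id`, `date` (ISO date),
#'   `start`, `end` (clock times `HH:MM:SS`, or numeric seconds from
#'   midnight).
#' @return data.frame ordered chronologically, with added numeric columns
#'   `start_s`, `end_s`, `length_s`.
#' @export
read_schedule <- function(path) {
  sch <- read.csv(path, stringsAsFactors = FALSE)
  validate_schedule(sch)
}

validate_schedule <- function(schedule) {
  need <- c("session_id", "date", "start", "end")
  miss <- setdiff(need, names(schedule))
  if (length(miss) > 0L) {
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  schedule <- as.data.frame(schedule)
  if (anyDuplicated(schedule$session_id)) {
    stop("duplicate session_id in schedule", call. = FALSE)
  }
  schedule$start_s <- clock_to_seconds(schedule$start)
  schedule$end_s <- clock_to_seconds(schedule$end)
  if (any(schedule$end_s <= schedule$start_s)) {
    stop("schedule has sessions with end <= start", call. = FALSE)
  }
  schedule$length_s <- schedule$end_s - schedule$start_s
  schedule[order(schedule$date, schedule$start_s), , drop = FALSE]
}

clock_to_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || length(p) < 2L || length(p) > 3L) {
      stop("unparseable clock time", call. = FALSE)
    }
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

#' Enumerate all dyads of a roster
#'
#' Returns one row per unordered pair of birds, labelled `familiar` when both
#' members share a capture site and `stranger` otherwise, with the dyad's sex
#' composition (`FF`, `MF`, `MM`).
#'
#' @param roster data.frame with columns `id`, `sex`, `site`.
#' @return data.frame with columns `dyad_id`, `member_low`, `member_high`,
#'   `familiarity`, `sex_composition`; `choose(n, 2)` rows.
#' @examples
#' ros <- data.frame(id = c("a", "b", "c"), sex = c("F", "M", "M"),
#'                   site = c("s1", "s1", "s2"))
#' enumerate_dyads(ros)
#' @export
enumerate_dyads <- function(roster) {
  roster <- validate_roster(roster)
  n <- nrow(roster)
  if (n < 2L) {
    return(data.frame(dyad_id = character(), member_low = character(),
                      member_high = character(), familiarity = character(),
                      sex_composition = character()))
  }
  pairs <- utils::combn(sort(roster$id), 2L)
  lo <- pairs[1L, ]
  hi <- pairs[2L, ]
  sex <- setNames(roster$sex, roster$id)
  site <- setNames(roster$site, roster$id)
  nf <- (sex[lo] == "F") + (sex[hi] == "F")
  data.frame(
    dyad_id = paste(lo, hi, sep = "--"),
    member_low = lo,
    member_high = hi,
    familiarity = ifelse(site[lo] == site[hi], "familiar", "stranger"),
    sex_composition = c("MM", "MF", "FF")[nf + 1L],
    row.names = NULL
  )
}

#' Read and validate raw observation records
#'
#' Rows naming a bird outside the roster, a behaviour outside the repertoire,
#' an actor equal to its receiver, or (when a schedule is supplied) a
#' timestamp outside its session are rejected with a warning naming the rows;
#' solitary records (empty receiver) are dropped. ISO-8601 timestamps are
#' normalised to seconds from session start using the schedule.
#'
#' @param path CSV with header columns `session_id`, `observer_id`,
#'   `timestamp`, `behavior`, `actor`, `receiver`.
#' @param roster Roster data.frame (see [read_roster()]).
#' @param schedule Optional schedule data.frame (see [read_schedule()]);
#'   required when timestamps are ISO-8601 date-times.
#' @return data.frame of validated records with numeric `timestamp` in
#'   seconds from session start. The number of rows dropped per reason is
#'   attached as attribute `"dropped"`.
#' @export
read_observations <- function(path, roster, schedule = NULL) {
  obs <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  need <- c("session_id", "observer_id", "timestamp", "behavior",
            "actor", "receiver")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0L) {
    stop("observations file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(obs) == 0L) {
    warning("empty observations file: ", path, call. = FALSE)
  }
  validate_observations(obs[need], roster, schedule)
}

validate_observations <- function(obs, roster, schedule = NULL) {
  roster <- validate_roster(roster)
  obs <- as.data.frame(obs)
  n0 <- nrow(obs)
  dropped <- c(solitary = 0L, unknown_bird = 0L, unknown_behavior = 0L,
               self_directed = 0L, bad_timestamp = 0L, unknown_session = 0L)
  reject <- function(bad, reason) {
    if (any(bad)) {
      dropped[[reason]] <<- dropped[[reason]] + sum(bad)
      warning(sprintf("rejected %d row(s) [%s]: %s", sum(bad), reason,
                      paste(utils::head(which(bad), 10L), collapse = ", ")),
              call. = FALSE)
      obs <<- obs[!bad, , drop = FALSE]
    }
  }

  # solitary sightings carry no dyadic information; drop silently but count
  solitary <- is.na(obs$receiver)
  if (any(solitary)) {
    dropped[["solitary"]] <- sum(solitary)
    obs <- obs[!solitary, , drop = FALSE]
  }

  reject(!(obs$behavior %in% .REPERTOIRE), "unknown_behavior")
  reject(!(obs$actor %in% roster$id) | !(obs$receiver %in% roster$id),
         "unknown_bird")
  reject(obs$actor == obs$receiver, "self_directed")

  ts <- suppressWarnings(as.numeric(obs$timestamp))
  iso <- is.na(ts) & !is.na(obs$timestamp)
  if (any(iso)) {
    if (is.null(schedule)) {
      stop("ISO-8601 timestamps require a schedule to normalise", call. = FALSE)
    }
    schedule <- validate_schedule(schedule)
    origin <- as.POSIXct(paste(schedule$date,
                               sprintf("%02d:%02d:%02d",
                                       schedule$start_s %/% 3600,
                                       (schedule$start_s %% 3600) %/% 60,
                                       schedule$start_s %% 60)),
                         tz = "UTC")
    names(origin) <- schedule$session_id
    t_iso <- as.POSIXct(obs$timestamp[iso], tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS"))
    ts[iso] <- as.numeric(difftime(t_iso, origin[obs$session_id[iso]],
                                   units = "secs"))
  }
  obs$timestamp <- ts
  reject(is.na(obs$timestamp), "bad_timestamp")

  if (!is.null(schedule)) {
    schedule <- validate_schedule(schedule)
    reject(!(obs$session_id %in% schedule$session_id), "unknown_session")
    len <- setNames(schedule$length_s, schedule$session_id)
    reject(obs$timestamp < 0 | obs$timestamp >= len[obs$session_id],
           "bad_timestamp")
  } else {
    reject(obs$timestamp < 0, "bad_timestamp")
  }

  if (sum(dropped) > 0L) {
    message(sprintf("read_observations: kept %d of %d rows (%s)",
                    nrow(obs), n0,
                    paste(sprintf("%s=%d", names(dropped), dropped)[dropped > 0L],
                          collapse = ", ")))
  }
  rownames(obs) <- NULL
  attr(obs, "dropped") <- dropped
  obs
}

#' Binarize observation records into dyad x behaviour x time-bin occurrences
#'
#' Each session is cut into half-open bins `[k*w, (k+1)*w)` of width `w`
#' seconds anchored at the session start; sessions are concatenated in
#' chronological order into one global bin index, so consecutive bin indices
#' always represent observed time. Duplicate sightings of the same dyad,
#' behaviour and bin (e.g. two observers logging one interaction) collapse to
#' a single occurrence.
#'
#' @param records Validated observation records (see [read_observations()]).
#' @param schedule Session schedule (see [read_schedule()]).
#' @param roster Optional roster; when given, the full dyad enumeration
#'   (including never-observed dyads) is attached, which downstream
#'   classification and modelling require.
#' @param bin_width Bin width in seconds (default 300 = 5 minutes).
#' @return An object of class `dyad_bins`: a list with `occ` (data.table of
#'   unique `dyad_id`, `behavior`, `tier`, `bin`), `dyads`, `n_bins`,
#'   `bin_width`, `hours_observed` and the session table.
#' @export
binarize <- function(records, schedule, roster = NULL, bin_width = 300) {
  stopifnot(bin_width > 0)
  schedule <- validate_schedule(schedule)
  schedule$n_bins <- as.integer(ceiling(schedule$length_s / bin_width))
  schedule$bin_offset <- cumsum(c(0L, schedule$n_bins[-nrow(schedule)]))

  records <- as.data.frame(records)
  records <- records[!is.na(records$receiver), , drop = FALSE]
  known <- records$session_id %in% schedule$session_id
  len <- setNames(schedule$length_s, schedule$session_id)
  inside <- known
  inside[known] <- records$timestamp[known] >= 0 &
    records$timestamp[known] < len[records$session_id[known]]
  if (any(!inside)) {
    warning(sprintf("binarize: rejected %d record(s) outside the schedule",
                    sum(!inside)), call. = FALSE)
    records <- records[inside, , drop = FALSE]
  }

  offset <- setNames(schedule$bin_offset, schedule$session_id)
  occ <- data.table::data.table(
    dyad_id = dyad_id(records$actor, records$receiver),
    behavior = records$behavior,
    bin = as.integer(offset[records$session_id] +
                       records$timestamp %/% bin_width)
  )
  occ <- unique(occ, by = c("dyad_id", "behavior", "bin"))
  occ[, tier := as.character(tier_of(behavior))]
  data.table::setcolorder(occ, c("dyad_id", "behavior", "tier", "bin"))
  data.table::setkey(occ, dyad_id, tier, bin)

  dyads <- if (is.null(roster)) NULL else enumerate_dyads(roster)
  if (!is.null(dyads) && nrow(occ) > 0L &&
      !all(occ$dyad_id %in% dyads$dyad_id)) {
    stop("records name dyads absent from the roster", call. = FALSE)
  }

  structure(
    list(
      occ = occ,
      dyads = dyads,
      n_bins = sum(schedule$n_bins),
      bin_width = bin_width,
      hours_observed = sum(schedule$length_s) / 3600,
      sessions = schedule
    ),
    class = "dyad_bins"
  )
}

#' @export
print.dyad_bins <- function(x, ...) {
  cat(sprintf(
    "<dyad_bins> %d occurrence(s) | %d bins of %ds | %.1f h observed | %s dyads enumerated\n",
    nrow(x$occ), x$n_bins, x$bin_width, x$hours_observed,
    if (is.null(x$dyads)) "no" else nrow(x$dyads)
  ))
  invisible(x)
}

#' Long-format audit table of a binarized stream
#'
#' @param x A `dyad_bins` object.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return data.frame with columns `dyad_id`, `behavior`, `tier`, `bin`,
#'   `occurred` (all 1 by construction).
#' @export
as.data.frame.dyad_bins <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- as.data.frame(x$occ)
  out$occurred <- 1L
  out
}
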