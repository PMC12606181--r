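# Synthetic observation-stream generator.
#
# Emulates the study design the pipeline assumes: four capture-site groups
# released together (default sizes 5/6/7/4, 8 of 22 female), observed over
# 22 days of twice-daily sessions (~6 h/day), with nearest-neighbour scans
# every 5 minutes and all-occurrence sampling of five contact behaviours by
# multiple observers (with duplicate logging). Dyad-level ground truth
# (latent progression type, drawn tier order) is returned alongside the
# emitted CSV-shaped tables, so every downstream stage can be checked
# against known structure.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: 22 birds
#' from four sites (5/6/7/4), 8 females, 22 days x 6 observation hours in
#' two sessions, 5-minute scans and bins. Behavioural parameters are set to
#' the observed cohort summaries: 31% of stranger dyads ever progress to
#' contact (9% of those reaching HIGH), 69% of familiar dyads are bonded
#' (44% reaching HIGH), stranger progressers follow the predicted
#' LOW-before-contact order with probability 0.95 and familiar ones with
#' probability 0.86, and pre-contact proximity runs at 0.03 events/h for
#' progressing dyads versus 0.01 events/h background.
#'
#' @param site_sizes Integer vector of birds per capture site.
#' @param n_female Number of females in the roster.
#' @param n_days Observation days.
#' @param sessions_per_day Sessions per day.
#' @param session_hours Hours per session.
#' @param bin_width Bin and scan interval, seconds.
#' @param adherence_stranger,adherence_familiar Probability that a
#'   progressing dyad's first-occurrence order follows the predicted
#'   sequence; otherwise a uniformly random order of its expressed tiers is
#'   drawn.
#' @param preference_fraction Fraction of stranger dyads that ever progress
#'   to contact.
#' @param contact_fraction_familiar Fraction of familiar dyads with an
#'   established (contact) bond.
#' @param p_high_stranger,p_high_familiar Probability that a contact dyad's
#'   repertoire includes the HIGH tier.
#' @param rate_base,rate_pref,rate_bonded Proximity rates in events per
#'   observed hour: background (non-preferred partners), pre-contact with a
#'   preferred partner, and post-contact between bonded partners (bonded
#'   pairs perch together, so scans pick them up far more often than
#'   contact events recur).
#' @param escalation_hazard Per-bin probability governing the geometric gaps
#'   between successive tier onsets of a progressing dyad.
#' @param recur_moderate,recur_high Per-bin recurrence probability of a tier
#'   after its onset (behaviour frequency structure for the permutation
#'   null).
#' @param onset_window_stranger,onset_window_familiar Fraction of the study
#'   within which a progressing dyad's first onset falls (familiar bonds
#'   resume early).
#' @param observer_duplication_rate Probability a contact event is also
#'   logged by a second observer.
#' @param n_observers Number of observers.
#' @param escalation_mode `"staged"` (default): onsets follow the latent
#'   escalation chain above. `"homogeneous"`: every expressed tier of every
#'   contact dyad emits at a constant per-bin rate from the first bin, with
#'   no onset structure -- the no-preferential-ordering null under which
#'   time bins are exchangeable.
#' @param start_date First session date (ISO).
#' @param seed Integer seed; the emitted tables are byte-identical given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(site_sizes = c(5L, 6L, 7L, 4L),
                       n_female = 8L,
                       n_days = 22L,
                       sessions_per_day = 2L,
                       session_hours = 3,
                       bin_width = 300,
                       adherence_stranger = 0.95,
                       adherence_familiar = 0.86,
                       preference_fraction = 0.31,
                       contact_fraction_familiar = 0.69,
                       p_high_stranger = 0.09,
                       p_high_familiar = 0.44,
                       rate_base = 0.01,
                       rate_pref = 0.03,
                       rate_bonded = 0.12,
                       escalation_hazard = 0.02,
                       recur_moderate = 0.003,
                       recur_high = 0.001,
                       onset_window_stranger = 0.7,
                       onset_window_familiar = 0.1,
                       observer_duplication_rate = 0.25,
                       n_observers = 4L,
                       escalation_mode = c("staged", "homogeneous"),
                       start_date = "2021-04-01",
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$escalation_mode <- match.arg(escalation_mode)
  probs <- c(cfg$adherence_stranger, cfg$adherence_familiar,
             cfg$preference_fraction, cfg$contact_fraction_familiar,
             cfg$p_high_stranger, cfg$p_high_familiar,
             cfg$observer_duplication_rate, cfg$escalation_hazard,
             cfg$recur_moderate, cfg$recur_high)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(cfg$site_sizes) < 2L) stop("need at least 2 birds", call. = FALSE)
  if (cfg$n_female > sum(cfg$site_sizes)) {
    stop("more females than birds", call. = FALSE)
  }
  if (cfg$n_days < 1L || cfg$sessions_per_day < 1L || cfg$session_hours <= 0) {
    stop("schedule must contain at least one session", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML / key-value file
#'
#' @param path YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  do.call(sim_config, yaml::read_yaml(path))
}

# Contact behaviour labels drawn within a tier (fixed field weights).
.MOD_BEHAVIORS <- c(shoulder_contact = 0.4, allopreen = 0.4, beak_touch = 0.2)
.HIGH_BEHAVIORS <- c(allofeed = 0.7, copulation = 0.3)

#' Simulate a full observation cohort
#'
#' Draws a roster, a session schedule and an observation stream under the
#' configured generative model, together with per-dyad ground truth.
#'
#' Generative model (per dyad, `"staged"` mode): stranger dyads progress
#' with probability `preference_fraction`, familiar dyads are bonded with
#' probability `contact_fraction_familiar`. A progressing dyad expresses
#' LOW and MODERATE (plus HIGH with the stratum's `p_high`), draws whether
#' it adheres to the predicted order (stratum's `adherence`), places its
#' first onset uniformly in the stratum's onset window, and spaces further
#' tier onsets by geometric gaps (`escalation_hazard`). Adherent dyads
#' order onsets LOW < MODERATE < HIGH; non-adherent dyads apply a uniformly
#' random permutation of their expressed tiers. Proximity is emitted only
#' at scan marks (bin starts): at `rate_pref` before the dyad's first
#' contact (progressing dyads) and `rate_base` otherwise; contact events
#' recur after onset at tier recurrence rates and are duplicated by a
#' second observer with probability `observer_duplication_rate`.
#'
#' @param config A `sim_config` list.
#' @return List of class `sim_cohort`: `roster`, `schedule`, `observations`
#'   (data.frames in the CSV dialects [read_observations()] consumes),
#'   `truth` (per-dyad latent state) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$site_sizes)

  roster <- data.frame(
    id = sprintf("B%02d", seq_len(n)),
    sex = "M",
    site = rep(sprintf("S%d", seq_along(config$site_sizes)),
               times = config$site_sizes)
  )
  roster$sex[sample.int(n, config$n_female)] <- "F"

  session_len <- round(config$session_hours * 3600)
  bins_per_session <- as.integer(ceiling(session_len / config$bin_width))
  starts <- c("08:00:00", "16:00:00", "12:00:00", "06:00:00")
  days <- seq.Date(as.Date(config$start_date), by = "day",
                   length.out = config$n_days)
  schedule <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
    data.frame(
      session_id = sprintf("D%02dS%d", d, seq_len(config$sessions_per_day)),
      date = as.character(days[d]),
      start = starts[seq_len(config$sessions_per_day)],
      end = format_clock(clock_to_seconds(
        starts[seq_len(config$sessions_per_day)]) + session_len)
    )
  }))
  total_bins <- config$n_days * config$sessions_per_day * bins_per_session
  # map a global bin to (session, local bin)
  bin_session <- rep(schedule$session_id, each = bins_per_session)
  bin_local <- rep(seq_len(bins_per_session) - 1L,
                   times = nrow(schedule))

  dyads <- enumerate_dyads(roster)
  nd <- nrow(dyads)
  stranger <- dyads$familiarity == "stranger"

  progresses <- ifelse(stranger,
                       runif(nd) < config$preference_fraction,
                       runif(nd) < config$contact_fraction_familiar)
  has_high <- progresses & (runif(nd) < ifelse(stranger,
                                               config$p_high_stranger,
                                               config$p_high_familiar))
  adherent <- progresses & (runif(nd) < ifelse(stranger,
                                               config$adherence_stranger,
                                               config$adherence_familiar))

  p_scan_base <- config$rate_base * config$bin_width / 3600
  p_scan_pref <- config$rate_pref * config$bin_width / 3600
  p_scan_bonded <- config$rate_bonded * config$bin_width / 3600

  truth <- data.frame(dyads, progresses = progresses, has_high = has_high,
                      adherent = adherent,
                      tier_order = NA_character_,
                      onset_low = NA_integer_, onset_moderate = NA_integer_,
                      onset_high = NA_integer_)
  rec <- vector("list", nd)

  for (k in seq_len(nd)) {
    tiers <- if (!progresses[k]) character(0)
             else if (has_high[k]) .TIER_LEVELS else c("LOW", "MODERATE")
    onsets <- rep(NA_integer_, 3L)
    names(onsets) <- .TIER_LEVELS

    if (length(tiers) > 0L) {
      if (config$escalation_mode == "homogeneous") {
        # exchangeable null: no onset structure at all
        onsets[tiers] <- 0L
        order_lab <- "homogeneous"
      } else {
        window <- if (stranger[k]) config$onset_window_stranger
                  else config$onset_window_familiar
        b0 <- as.integer(floor(runif(1) * max(1, floor(window * total_bins))))
        gaps <- 1L + rgeom(length(tiers) - 1L, config$escalation_hazard)
        slots <- cumsum(c(b0, gaps))
        ord <- if (adherent[k]) tiers else sample(tiers)
        onsets[ord] <- slots
        order_lab <- paste(ord, collapse = "<")
      }
      truth$tier_order[k] <- order_lab
      truth$onset_low[k] <- onsets[["LOW"]]
      truth$onset_moderate[k] <- onsets[["MODERATE"]]
      truth$onset_high[k] <- onsets[["HIGH"]]
    }

    rec[[k]] <- emit_dyad_records(
      k, dyads, onsets, progresses[k], config, total_bins,
      bins_per_session, bin_session, bin_local,
      p_scan_base, p_scan_pref, p_scan_bonded
    )
  }

  obs <- data.table::rbindlist(rec)
  data.table::setorder(obs, session_id, timestamp, behavior, actor)
  obs <- as.data.frame(obs)

  cohort <- list(roster = roster, schedule = schedule, observations = obs,
                 truth = truth, config = config)
  class(cohort) <- "sim_cohort"
  cohort
}

# Emit the raw records of one dyad. Proximity only at scan marks (bin
# starts); contact events at a uniform second within their bin, possibly
# double-logged.
emit_dyad_records <- function(k, dyads, onsets, progressing, config,
                              total_bins, bins_per_session,
                              bin_session, bin_local,
                              p_scan_base, p_scan_pref, p_scan_bonded) {
  a <- dyads$member_low[k]
  b <- dyads$member_high[k]
  homog <- config$escalation_mode == "homogeneous"
  contact_onset <- suppressWarnings(
    min(onsets[["MODERATE"]], onsets[["HIGH"]], na.rm = TRUE))

  # -- proximity scans ------------------------------------------------------
  # Progressing dyads (staged mode) are silent in LOW before their assigned
  # onset so that the emitted first occurrence equals the drawn one; they
  # then run at the preferred-partner rate until first contact and at the
  # background rate afterwards. Everyone else runs at the background rate.
  bin_idx <- seq_len(total_bins) - 1L
  if (homog) {
    expressed_low <- progressing && !is.na(onsets[["LOW"]])
    p_low <- rep(if (expressed_low) p_scan_pref else p_scan_base, total_bins)
  } else if (progressing && !is.na(onsets[["LOW"]])) {
    o <- onsets[["LOW"]]
    p_low <- numeric(total_bins)
    after <- bin_idx > o
    pre_contact <- if (is.finite(contact_onset)) bin_idx < contact_onset
                   else rep(TRUE, total_bins)
    p_low[after & pre_contact] <- p_scan_pref
    p_low[after & !pre_contact] <- p_scan_bonded
  } else {
    p_low <- rep(p_scan_base, total_bins)
  }
  low_bins <- which(runif(total_bins) < p_low) - 1L
  # guarantee the assigned LOW onset actually emits
  if (!homog && progressing && !is.na(onsets[["LOW"]]) &&
      onsets[["LOW"]] < total_bins) {
    low_bins <- sort(unique(c(low_bins, onsets[["LOW"]])))
  }

  recs <- list()
  if (length(low_bins) > 0L) {
    swap <- runif(length(low_bins)) < 0.5
    recs[[1L]] <- data.table::data.table(
      session_id = bin_session[low_bins + 1L],
      observer_id = sprintf("O%d", sample.int(config$n_observers,
                                              length(low_bins), replace = TRUE)),
      timestamp = bin_local[low_bins + 1L] * config$bin_width,
      behavior = "proximity",
      actor = ifelse(swap, b, a),
      receiver = ifelse(swap, a, b)
    )
  }

  # -- contact events -------------------------------------------------------
  for (tl in c("MODERATE", "HIGH")) {
    onset <- onsets[[tl]]
    if (is.na(onset) || onset >= total_bins) next
    recur <- if (tl == "MODERATE") config$recur_moderate else config$recur_high
    if (homog) {
      ev_bins <- which(runif(total_bins) < recur) - 1L
    } else {
      later <- which(seq_len(total_bins) - 1L > onset &
                       runif(total_bins) < recur) - 1L
      ev_bins <- sort(unique(c(onset, later)))
    }
    if (length(ev_bins) == 0L) next
    weights <- if (tl == "MODERATE") .MOD_BEHAVIORS else .HIGH_BEHAVIORS
    beh <- sample(names(weights), length(ev_bins), replace = TRUE,
                  prob = weights)
    secs <- bin_local[ev_bins + 1L] * config$bin_width +
      floor(runif(length(ev_bins)) * config$bin_width)
    obs1 <- sample.int(config$n_observers, length(ev_bins), replace = TRUE)
    swap <- runif(length(ev_bins)) < 0.5
    ev <- data.table::data.table(
      session_id = bin_session[ev_bins + 1L],
      observer_id = sprintf("O%d", obs1),
      timestamp = secs,
      behavior = beh,
      actor = ifelse(swap, b, a),
      receiver = ifelse(swap, a, b)
    )
    dup <- which(runif(length(ev_bins)) < config$observer_duplication_rate)
    if (length(dup) > 0L) {
      obs2 <- 1L + (obs1[dup] %% config$n_observers)   # a different observer
      jitter <- floor(runif(length(dup)) *
                        (config$bin_width - secs[dup] %% config$bin_width))
      dup_ev <- ev[dup]
      dup_ev[, `:=`(observer_id = sprintf("O%d", obs2),
                    timestamp = timestamp + jitter)]
      ev <- rbind(ev, dup_ev)
    }
    recs[[length(recs) + 1L]] <- ev
  }

  if (length(recs) == 0L) return(NULL)
  data.table::rbindlist(recs)
}

format_clock <- function(s) {
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Write a simulated cohort to CSV files
#'
#' @param cohort A `sim_cohort` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of `roster.csv`, `schedule.csv`,
#'   `observations.csv`, `truth.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("roster.csv", "schedule.csv",
                            "observations.csv", "truth.csv"))
  write.csv(cohort$roster, paths[1L], row.names = FALSE, quote = FALSE)
  write.csv(cohort$schedule, paths[2L], row.names = FALSE, quote = FALSE)
  write.csv(cohort$observations, paths[3L], row.names = FALSE, quote = FALSE)
  write.csv(cohort$truth, paths[4L], row.names = FALSE, quote = FALSE)
  invisible(setNames(paths, c("roster", "schedule", "observations", "truth")))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d birds, %d dyads | %d sessions | %d records | seed %d (%s mode)\n",
    nrow(x$roster), nrow(x$truth), nrow(x$schedule), nrow(x$observations),
    x$config$seed, x$config$escalation_mode))
  invisible(x)
}

#' Simulate dyadic outcomes directly from the multi-membership model
#'
#' Bypasses the event stream: draws bird random effects and Bernoulli
#' sequence-adherence outcomes straight from the logistic multi-membership
#' model, for parameter-recovery studies with exactly known coefficients.
#'
#' @param site_sizes Birds per site (familiarity follows shared site).
#' @param beta_stranger True log-odds contrast stranger vs familiar.
#' @param intercept True intercept (log-odds of adherence for familiar
#'   dyads at `u = 0`).
#' @param sigma_u True SD of bird random effects.
#' @param seed Integer seed.
#' @return An `mm_data` list ready for [fit_mm()], with the truth attached
#'   as attribute `"truth"`.
#' @export
simulate_mm_cohort <- function(site_sizes = c(4L, 4L, 4L, 4L),
                               beta_stranger = 1.2, intercept = 1.8,
                               sigma_u = 0.7, seed = 1L) {
  set.seed(seed)
  n <- sum(site_sizes)
  roster <- data.frame(
    id = sprintf("B%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    site = rep(sprintf("S%d", seq_along(site_sizes)), times = site_sizes)
  )
  dyads <- enumerate_dyads(roster)
  u <- stats::rnorm(n, 0, sigma_u)
  names(u) <- roster$id
  stranger <- as.integer(dyads$familiarity == "stranger")
  eta <- intercept + beta_stranger * stranger +
    u[dyads$member_low] + u[dyads$member_high]
  y <- rbinom(nrow(dyads), 1L, plogis(eta))
  birds <- sort(roster$id)
  out <- list(
    y = y,
    stranger = stranger,
    i1 = match(dyads$member_low, birds),
    i2 = match(dyads$member_high, birds),
    birds = birds,
    dyad_id = dyads$dyad_id,
    sequence_type = "generalized",
    include_sex = FALSE
  )
  class(out) <- "mm_data"
  attr(out, "truth") <- list(beta_stranger = beta_stranger,
                             intercept = intercept, sigma_u = sigma_u, u = u)
  out
}

#' Supported probability and familiarity contrast implied by a configuration
#'
#' Under the staged generator, a progressing dyad supports the predicted
#' sequence either by adhering (probability `adherence`) or by luck in the
#' random-order branch: a uniformly random order puts LOW first with
#' probability 1/2 for a two-tier (LOW, MODERATE) dyad and 1/3 for a
#' three-tier dyad; the full precise order arises with probability 1/2 and
#' 1/6 respectively. `implied_log_odds()` is the stranger-minus-familiar
#' contrast of `qlogis()` of these probabilities -- the event-stream
#' analogue of the model's `b_stranger` (the generator has no bird-level
#' heterogeneity, so no attenuation adjustment is needed).
#'
#' @param adherence Probability of following the predicted order.
#' @param p_high Probability that a contact dyad's repertoire includes HIGH.
#' @param sequence_type `"generalized"` or `"precise"`.
#' @return `implied_supported_prob()`: a probability;
#'   `implied_log_odds()`: a log-odds difference.
#' @export
implied_supported_prob <- function(adherence, p_high,
                                   sequence_type = c("generalized", "precise")) {
  sequence_type <- match.arg(sequence_type)
  p_luck3 <- if (sequence_type == "generalized") 1 / 3 else 1 / 6
  adherence + (1 - adherence) * ((1 - p_high) / 2 + p_high * p_luck3)
}

#' @rdname implied_supported_prob
#' @param config A `sim_config` list.
#' @export
implied_log_odds <- function(config,
                             sequence_type = c("generalized", "precise")) {
  sequence_type <- match.arg(sequence_type)
  qlogis(implied_supported_prob(config$adherence_stranger,
                                config$p_high_stranger, sequence_type)) -
    qlogis(implied_supported_prob(config$adherence_familiar,
                                  config$p_high_familiar, sequence_type))
}
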