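# One-call orchestration: (simulate | read) -> binarize -> classify ->
# permutation null -> multi-membership model -> paired rate test ->
# consolidated report.

#' Run the full analysis pipeline
#'
#' Executes every stage on either a simulated cohort or CSV inputs and
#' (optionally) writes the stage artifacts plus a single consolidated
#' report. Every random stage takes its own named seed derived from `seed`.
#'
#' @param cohort A `sim_cohort` (see [simulate_cohort()]), or `NULL` to read
#'   CSVs from `paths`.
#' @param paths Named list with `observations`, `roster`, `schedule` when
#'   `cohort` is `NULL`.
#' @param out_dir Output directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @param sequence_types Sequence classifications to analyse.
#' @param n_iter_sequence_perm Iterations of the time-bin-shuffle null
#'   (default 1000).
#' @param n_iter_paired_perm Iterations of the sign-flip paired test
#'   (default 5000).
#' @param chains,iter,warmup MCMC settings for the model (defaults 4, 8000,
#'   4000).
#' @param skip_model Skip the Bayesian model stage.
#' @param include_sex Add sex-composition fixed effects to the model.
#' @param seed Master integer seed.
#' @return List of class `dyadseq_report` with elements `counts`,
#'   `classification`, `permutation`, `model`, `rates`, `timing_s`, `seeds`.
#' @export
run_pipeline <- function(cohort = NULL, paths = NULL, out_dir = NULL,
                         sequence_types = c("generalized", "precise"),
                         n_iter_sequence_perm = 1000,
                         n_iter_paired_perm = 5000,
                         chains = 4, iter = 8000, warmup = 4000,
                         skip_model = FALSE, include_sex = FALSE,
                         seed = 1L) {
  sequence_types <- match.arg(sequence_types, several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  seeds <- list(perm = seed + 1L, model = seed + 2L, paired = seed + 3L)
  timing <- c()
  tick <- function(label) {
    t <- proc.time()[["elapsed"]]
    timing[[label]] <<- round(t - t0, 2)
    t0 <<- t
  }

  if (is.null(cohort)) {
    stopifnot(all(c("observations", "roster", "schedule") %in% names(paths)))
    roster <- read_roster(paths$roster)
    schedule <- read_schedule(paths$schedule)
    records <- read_observations(paths$observations, roster, schedule)
  } else {
    stopifnot(inherits(cohort, "sim_cohort"))
    roster <- cohort$roster
    schedule <- validate_schedule(cohort$schedule)
    records <- validate_observations(cohort$observations, roster, schedule)
  }
  tick("ingest")

  bins <- binarize(records, schedule, roster = roster)
  cls <- classify_all(bins)
  summary_tbl <- classification_summary(cls)
  tick("classify")

  perms <- list()
  for (type in sequence_types) {
    for (stratum in c("stranger", "familiar")) {
      key <- paste(type, stratum, sep = "_")
      perms[[key]] <- suppressWarnings(null_distribution(
        bins, sequence_type = type, stratum = stratum,
        n_iter = n_iter_sequence_perm, seed = seeds$perm))
    }
  }
  tick("permutation")

  model <- NULL
  if (!skip_model) {
    model <- lapply(setNames(sequence_types, sequence_types), function(type) {
      md <- build_model_data(cls, sequence_type = type,
                             include_sex = include_sex)
      fit <- fit_mm(md, chains = chains, iter = iter, warmup = warmup,
                    seed = seeds$model)
      list(summary = summarize_mm(fit), n_dyads = length(md$y))
    })
    tick("model")
  }

  pr <- paired_rates(bins, cls)
  paired <- tryCatch(
    permuted_paired_test(pr, n_iter = n_iter_paired_perm,
                         seed = seeds$paired),
    error = function(e) {
      warning("paired test skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  tick("rates")

  report <- structure(list(
    counts = list(
      n_birds = nrow(roster),
      n_dyads = nrow(bins$dyads),
      n_familiar = sum(bins$dyads$familiarity == "familiar"),
      n_stranger = sum(bins$dyads$familiarity == "stranger"),
      n_records = nrow(records),
      n_occurrences = nrow(bins$occ),
      hours_observed = bins$hours_observed
    ),
    classification = summary_tbl,
    permutation = perms,
    model = model,
    rates = list(pairs = pr, test = paired),
    timing_s = as.list(timing),
    seeds = seeds
  ), class = "dyadseq_report")

  if (!is.null(out_dir)) {
    write_report(report, cls, out_dir)
  }
  report
}

# Write stage artifacts: classifications, paired rates, null vectors as CSV;
# permutation and headline summaries as JSON.
write_report <- function(report, cls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(cls), file.path(out_dir, "classifications.csv"),
            row.names = FALSE)
  write.csv(report$classification,
            file.path(out_dir, "classification_summary.csv"),
            row.names = FALSE)
  write.csv(report$rates$pairs, file.path(out_dir, "paired_rates.csv"),
            row.names = FALSE)
  for (key in names(report$permutation)) {
    p <- report$permutation[[key]]
    write.csv(data.frame(iteration = seq_along(p$null_values),
                         proportion = p$null_values),
              file.path(out_dir, sprintf("null_%s.csv", key)),
              row.names = FALSE)
  }
  if (!is.null(report$model)) {
    for (type in names(report$model)) {
      write.csv(report$model[[type]]$summary,
                file.path(out_dir, sprintf("posterior_%s.csv", type)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(report_headline(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Headline statistics of a pipeline report
#'
#' @param report A `dyadseq_report`.
#' @return Flat named list of the main quantities: dyad counts, observed
#'   supported proportions, permutation p-values, model odds factors, and
#'   the paired rate comparison.
#' @export
report_headline <- function(report) {
  out <- list(
    n_familiar_dyads = report$counts$n_familiar,
    n_stranger_dyads = report$counts$n_stranger,
    hours_observed = report$counts$hours_observed
  )
  for (key in names(report$permutation)) {
    p <- report$permutation[[key]]
    out[[paste0("observed_", key)]] <- p$observed
    out[[paste0("null_mean_", key)]] <- p$null_mean
    out[[paste0("perm_p_", key)]] <- p$p_one_sided
  }
  if (!is.null(report$model)) {
    for (type in names(report$model)) {
      s <- report$model[[type]]$summary
      row <- s[s$parameter == "b_stranger", ]
      out[[paste0("log_odds_stranger_", type)]] <- row$mean
      out[[paste0("odds_factor_stranger_", type)]] <- row$odds_factor
      out[[paste0("odds_ci_low_", type)]] <- row$odds_ci_low
      out[[paste0("odds_ci_high_", type)]] <- row$odds_ci_high
    }
  }
  t <- report$rates$test
  if (!is.null(t)) {
    out$rate_contact_mean <- unname(t$group_means["contact"])
    out$rate_noncontact_mean <- unname(t$group_means["noncontact"])
    out$paired_t <- t$observed
    out$paired_p <- t$p_one_sided
    out$n_pairs <- t$n_pairs
  }
  out
}

#' @export
print.dyadseq_report <- function(x, ...) {
  cat("<dyadseq_report>\n")
  cat(sprintf("  %d birds; %d dyads (%d familiar, %d stranger); %.1f h observed\n",
              x$counts$n_birds, x$counts$n_dyads, x$counts$n_familiar,
              x$counts$n_stranger, x$counts$hours_observed))
  print(x$classification, digits = 3)
  for (p in x$permutation) print(p)
  if (!is.null(x$model)) {
    for (type in names(x$model)) {
      cat(sprintf("model [%s sequence], %d dyads:\n", type,
                  x$model[[type]]$n_dyads))
      print(x$model[[type]]$summary, digits = 3)
    }
  }
  if (!is.null(x$rates$test)) print(x$rates$test)
  invisible(x)
}
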