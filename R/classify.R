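# Per-dyad first-occurrence extraction and sequence classification.
#
# A dyad supports the generalized sequence when no-contact proximity (LOW)
# strictly precedes every contact tier; it supports the precise sequence
# when, in addition, MODERATE precedes or shares a bin with HIGH. Dyads
# never observed in contact have nothing to order and are not evaluable.

#' First occurrence of each risk tier for every dyad
#'
#' @param bins A `dyad_bins` object (see [binarize()]).
#' @return data.frame with one row per enumerated dyad (or per observed dyad
#'   when no roster was attached): `dyad_id`, `first_low`, `first_moderate`,
#'   `first_high` (global bin index of the tier's earliest occurrence across
#'   all its behaviours, `NA` if the tier was never observed).
#' @export
first_occurrence_table <- function(bins) {
  stopifnot(inherits(bins, "dyad_bins"))
  occ <- bins$occ
  ids <- if (is.null(bins$dyads)) sort(unique(occ$dyad_id)) else bins$dyads$dyad_id
  out <- data.frame(dyad_id = ids, first_low = NA_integer_,
                    first_moderate = NA_integer_, first_high = NA_integer_)
  if (nrow(occ) > 0L) {
    f <- occ[, .(first_bin = min(bin)), by = .(dyad_id, tier)]
    for (tl in .TIER_LEVELS) {
      col <- paste0("first_", tolower(tl))
      fi <- f[f$tier == tl, ]
      out[[col]][match(fi$dyad_id, out$dyad_id)] <- fi$first_bin
    }
  }
  out
}

#' First occurrences for a single dyad
#'
#' @param bins A `dyad_bins` object.
#' @param dyad A dyad id (see [dyad_id()]).
#' @return Named integer vector `c(LOW=, MODERATE=, HIGH=)` of first bins,
#'   `NA` where the tier was never observed.
#' @export
first_occurrences <- function(bins, dyad) {
  ft <- first_occurrence_table(bins)
  row <- ft[ft$dyad_id == dyad, ]
  if (nrow(row) == 0L) stop("dyad not present: ", dyad, call. = FALSE)
  setNames(as.integer(row[1, c("first_low", "first_moderate", "first_high")]),
           .TIER_LEVELS)
}

# first-bin vectors with NA -> Inf so pmin works tier-wise
.inf_na <- function(x) ifelse(is.na(x), Inf, as.numeric(x))

#' Classify dyads against the generalized sequence
#'
#' Supported when LOW was observed and its first bin strictly precedes the
#' first bin of every contact tier; violated when contact was observed but
#' LOW was absent or did not strictly precede it (a tie between LOW and a
#' contact tier in the same bin counts as violated); not evaluable when no
#' contact tier was ever observed.
#'
#' @param firsts data.frame with columns `first_low`, `first_moderate`,
#'   `first_high` (one row per dyad), or a named vector as returned by
#'   [first_occurrences()].
#' @return Character vector of verdicts in
#'   `{"supported", "violated", "not_evaluable"}`.
#' @export
classify_generalized <- function(firsts) {
  f <- .firsts_frame(firsts)
  fl <- .inf_na(f$first_low)
  contact <- pmin(.inf_na(f$first_moderate), .inf_na(f$first_high))
  ifelse(!is.finite(contact), "not_evaluable",
         ifelse(fl < contact, "supported", "violated"))
}

#' Classify dyads against the precise sequence
#'
#' Supported when the generalized sequence holds and MODERATE precedes HIGH
#' or shares its time bin (or HIGH was never observed); violated when the
#' generalized sequence is violated, when HIGH occurs with no MODERATE ever
#' observed, or when HIGH strictly precedes MODERATE; not evaluable when no
#' contact tier was ever observed.
#'
#' @inheritParams classify_generalized
#' @return Character vector of verdicts.
#' @export
classify_precise <- function(firsts) {
  f <- .firsts_frame(firsts)
  gen <- classify_generalized(f)
  fm <- .inf_na(f$first_moderate)
  fh <- .inf_na(f$first_high)
  ok_high <- !is.finite(fh) | (is.finite(fm) & fm <= fh)
  ifelse(gen == "not_evaluable", "not_evaluable",
         ifelse(gen == "supported" & ok_high, "supported", "violated"))
}

.firsts_frame <- function(firsts) {
  if (is.data.frame(firsts)) return(firsts)
  if (is.numeric(firsts) && !is.null(names(firsts))) {
    return(data.frame(first_low = firsts[["LOW"]],
                      first_moderate = firsts[["MODERATE"]],
                      first_high = firsts[["HIGH"]]))
  }
  stop("firsts must be a data.frame or a named tier vector", call. = FALSE)
}

#' Classify every dyad and attach familiarity labels
#'
#' @param bins A `dyad_bins` object built with a roster (so that familiarity
#'   and sex composition are known).
#' @return data.frame of class `dyad_classifications`: one row per dyad with
#'   the dyad labels, first bins per tier, and `generalized` / `precise`
#'   verdicts.
#' @export
classify_all <- function(bins) {
  stopifnot(inherits(bins, "dyad_bins"))
  if (is.null(bins$dyads)) {
    stop("classify_all needs dyad labels; rebuild bins with a roster",
         call. = FALSE)
  }
  ft <- first_occurrence_table(bins)
  cls <- merge(bins$dyads, ft, by = "dyad_id", sort = TRUE)
  cls$generalized <- classify_generalized(cls)
  cls$precise <- classify_precise(cls)
  class(cls) <- c("dyad_classifications", "data.frame")
  cls
}

#' Summarise supported proportions by familiarity stratum
#'
#' @param cls A `dyad_classifications` data.frame (see [classify_all()]).
#' @param include_noncontact_as_supported Sensitivity flag: when `TRUE`,
#'   dyads never observed in contact are counted as supported (and
#'   evaluable) instead of excluded. Default `FALSE`, the primary analysis.
#' @return data.frame with one row per stratum (`stranger`, `familiar`,
#'   `all`) and sequence type: counts of evaluable and supported dyads and
#'   the supported proportion (`NaN` when no dyad is evaluable).
#' @export
classification_summary <- function(cls, include_noncontact_as_supported = FALSE) {
  strata <- list(stranger = "stranger", familiar = "familiar",
                 all = c("stranger", "familiar"))
  rows <- list()
  for (st in names(strata)) {
    for (type in c("generalized", "precise")) {
      v <- cls[[type]][cls$familiarity %in% strata[[st]]]
      if (include_noncontact_as_supported) {
        v[v == "not_evaluable"] <- "supported"
      }
      n_eval <- sum(v != "not_evaluable")
      n_sup <- sum(v == "supported")
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, sequence = type, n_dyads = length(v),
        n_evaluable = n_eval, n_supported = n_sup,
        proportion_supported = n_sup / n_eval
      )
    }
  }
  do.call(rbind, rows)
}

# Supported proportion for one stratum/sequence; the permutation statistic.
supported_proportion <- function(cls, sequence_type = "generalized",
                                 stratum = "stranger") {
  s <- classification_summary(cls)
  s$proportion_supported[s$stratum == stratum & s$sequence == sequence_type]
}
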