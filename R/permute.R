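# Time-bin-shuffling permutation null for sequence classification.
#
# The null hypothesis is "no preferential ordering of behaviours": bin
# labels of the deduplicated occurrence records are permuted jointly across
# all dyads and behaviours, which preserves exactly both the multiset of
# occupied bins and each dyad's per-behaviour record counts, so behaviours
# that are simply frequent stay frequent under the null.

#' Shuffle time bins among occurrence records
#'
#' Permutes the `bin` column of a deduplicated long-format occurrence table
#' uniformly at random across all records, then collapses any post-shuffle
#' collisions (same dyad, behaviour and bin) to a single occurrence,
#' consistent with the binary coding.
#'
#' @param occ data.table with columns `dyad_id`, `behavior`, `tier`, `bin`
#'   (the `occ` element of a `dyad_bins` object).
#' @param per_dyad Alternative mode: permute bins within each dyad only,
#'   preserving every dyad's personal bin multiset. Default `FALSE` (global
#'   shuffle).
#' @return data.table of the same shape with permuted bins (possibly fewer
#'   rows after collision collapse).
#' @export
shuffle_bins <- function(occ, per_dyad = FALSE) {
  if (nrow(occ) < 2L) {
    warning("fewer than 2 records; nothing to shuffle", call. = FALSE)
    return(data.table::copy(occ))
  }
  out <- data.table::copy(occ)
  if (per_dyad) {
    out[, bin := bin[sample.int(.N)], by = dyad_id]
  } else {
    out[, bin := bin[sample.int(.N)]]
  }
  unique(out, by = c("dyad_id", "behavior", "bin"))
}

#' Permutation null distribution of the sequence-support proportion
#'
#' Repeatedly shuffles bins among records ([shuffle_bins()]), rebuilds each
#' dyad's per-tier first occurrences, reclassifies, and records the
#' supported proportion among evaluable dyads of the chosen stratum. Which
#' dyads are evaluable is invariant under the shuffle (tier presence is a
#' record-count property), so observed and null proportions share one
#' denominator. The one-sided p-value uses the add-one rule
#' `(1 + #(null >= observed)) / (1 + n_iter)` and can never be zero.
#'
#' @param bins A `dyad_bins` object built with a roster.
#' @param sequence_type `"generalized"` or `"precise"`.
#' @param stratum `"stranger"`, `"familiar"` or `"all"`.
#' @param n_iter Number of shuffles (default 1000).
#' @param seed Integer seed; the full null vector is reproducible from it.
#' @param per_dyad Passed to [shuffle_bins()].
#' @return Object of class `perm_result`: list with `statistic_name`,
#'   `observed`, `null_values`, `null_mean`, `upper95`, `p_one_sided`,
#'   `n_iter`, `seed`, `n_evaluable`. When the stratum has no evaluable
#'   dyad the result is flagged `not_evaluable` and the statistic is `NA`.
#' @export
null_distribution <- function(bins,
                              sequence_type = c("generalized", "precise"),
                              stratum = c("stranger", "familiar", "all"),
                              n_iter = 1000, seed = 1L, per_dyad = FALSE) {
  sequence_type <- match.arg(sequence_type)
  stratum <- match.arg(stratum)
  stopifnot(inherits(bins, "dyad_bins"), n_iter >= 1)
  if (is.null(bins$dyads)) {
    stop("null_distribution needs dyad labels; rebuild bins with a roster",
         call. = FALSE)
  }
  occ <- bins$occ
  fams <- if (stratum == "all") c("stranger", "familiar") else stratum

  # Evaluable dyads of the stratum: contact tier present (shuffle-invariant).
  tiers_present <- occ[, .(has_contact = any(tier != "LOW")), by = dyad_id]
  in_stratum <- bins$dyads$dyad_id[bins$dyads$familiarity %in% fams]
  eval_ids <- intersect(tiers_present$dyad_id[tiers_present$has_contact],
                        in_stratum)
  m <- length(eval_ids)
  name <- sprintf("P(%s sequence | %s dyads)", sequence_type, stratum)
  if (m == 0L) {
    warning("no evaluable dyad in stratum '", stratum, "'", call. = FALSE)
    return(structure(list(statistic_name = name, observed = NA_real_,
                          null_values = rep(NA_real_, n_iter),
                          null_mean = NA_real_, upper95 = NA_real_,
                          p_one_sided = NA_real_, n_iter = as.integer(n_iter),
                          seed = as.integer(seed), n_evaluable = 0L,
                          not_evaluable = TRUE,
                          sequence_type = sequence_type, stratum = stratum),
                     class = "perm_result"))
  }

  # Group index over (evaluable dyad, tier); records of non-evaluable or
  # out-of-stratum dyads still take part in the shuffle, only aggregation
  # is restricted.
  drow <- match(occ$dyad_id, eval_ids)             # NA outside the stratum
  tcol <- match(occ$tier, .TIER_LEVELS)
  keep <- !is.na(drow)
  grp <- (tcol[keep] - 1L) * m + drow[keep]        # column-major cell index
  split_idx <- split(which(keep), grp)
  cells <- as.integer(names(split_idx))
  binvec <- occ$bin
  n_rec <- length(binvec)

  firsts_mat <- function(b) {
    f <- matrix(Inf, nrow = m, ncol = 3L)
    f[cells] <- vapply(split_idx, function(ii) min(b[ii]), numeric(1))
    f
  }
  count_supported <- function(f) {
    gen <- f[, 1L] < pmin(f[, 2L], f[, 3L])
    if (sequence_type == "generalized") return(sum(gen))
    sum(gen & (!is.finite(f[, 3L]) | f[, 2L] <= f[, 3L]))
  }

  obs_count <- count_supported(firsts_mat(binvec))
  set.seed(seed)
  null_counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    null_counts[it] <- count_supported(firsts_mat(binvec[sample.int(n_rec)]))
  }

  null_values <- null_counts / m
  structure(list(
    statistic_name = name,
    observed = obs_count / m,
    null_values = null_values,
    null_mean = mean(null_values),
    upper95 = unname(quantile(null_values, 0.95)),
    p_one_sided = (1 + sum(null_counts >= obs_count)) / (1 + n_iter),
    n_iter = as.integer(n_iter),
    seed = as.integer(seed),
    n_evaluable = m,
    not_evaluable = FALSE,
    sequence_type = sequence_type,
    stratum = stratum
  ), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s\n", x$statistic_name))
  if (isTRUE(x$not_evaluable)) {
    cat("  not evaluable: no dyad in this stratum was observed in contact\n")
    return(invisible(x))
  }
  n_units <- if (!is.null(x$n_evaluable)) {
    sprintf("%d dyads", x$n_evaluable)
  } else {
    sprintf("%d pairs", x$n_pairs)
  }
  cat(sprintf(
    "  observed = %.3f | null mean = %.3f | null 95%% = %.3f | one-sided p = %.4g (%d iter, %s)\n",
    x$observed, x$null_mean, x$upper95, x$p_one_sided, x$n_iter, n_units))
  invisible(x)
}
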