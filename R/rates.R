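# Pre-contact proximity rates and the sign-flip paired permutation test.
#
# Question: did birds maintain more no-contact proximity with the stranger
# partners they later contacted than with strangers they never contacted?
# Rates are events per observed hour, truncated at each dyad's first
# contact so that the comparison never conditions on post-contact time.

#' Hourly no-contact proximity rate of one dyad
#'
#' Counts LOW-tier occurrence bins strictly before `truncate_at` and divides
#' by the observation hours those bins represent. Because the global bin
#' index concatenates sessions, `truncate_at` bins always represent
#' `truncate_at * bin_width` seconds of observation.
#'
#' @param bins A `dyad_bins` object.
#' @param dyad A dyad id.
#' @param truncate_at Global bin index of the dyad's first contact, or
#'   `NULL` to use the whole study (never-contacted dyads).
#' @return Rate per hour, or `NA_real_` when the truncation window is empty
#'   (first contact in bin 0).
#' @export
dyad_hourly_rate <- function(bins, dyad, truncate_at = NULL) {
  stopifnot(inherits(bins, "dyad_bins"))
  occ <- bins$occ
  low_bins <- occ$bin[occ$dyad_id == dyad & occ$tier == "LOW"]
  if (is.null(truncate_at)) {
    return(length(low_bins) / bins$hours_observed)
  }
  if (truncate_at <= 0L) {
    warning("empty pre-contact window for dyad ", dyad, "; excluded",
            call. = FALSE)
    return(NA_real_)
  }
  hours <- truncate_at * bins$bin_width / 3600
  sum(low_bins < truncate_at) / hours
}

#' Per-bird paired pre-contact proximity rates
#'
#' Splits each bird's stranger partners into those ever observed in
#' affiliative contact (any MODERATE or HIGH occurrence) and those never
#' contacted. Contacted dyads contribute their proximity rate truncated at
#' the dyad's first contact bin; never-contacted dyads contribute their
#' whole-study rate. Each bird's class rate is the unweighted mean over its
#' partner dyads in that class.
#'
#' @param bins A `dyad_bins` object built with a roster.
#' @param cls Optional precomputed [classify_all()] result.
#' @return data.frame with one row per bird: `bird`, `rate_contact`,
#'   `rate_noncontact` (`NA` when the bird has no partner in a class),
#'   `n_partners_contact`, `n_partners_noncontact`.
#' @export
paired_rates <- function(bins, cls = NULL) {
  stopifnot(inherits(bins, "dyad_bins"))
  if (is.null(cls)) cls <- classify_all(bins)
  st <- cls[cls$familiarity == "stranger", , drop = FALSE]
  first_contact <- pmin(.inf_na(st$first_moderate), .inf_na(st$first_high))
  contacted <- is.finite(first_contact)

  rate <- numeric(nrow(st))
  for (k in seq_len(nrow(st))) {
    rate[k] <- if (contacted[k]) {
      dyad_hourly_rate(bins, st$dyad_id[k], truncate_at = first_contact[k])
    } else {
      dyad_hourly_rate(bins, st$dyad_id[k])
    }
  }

  birds <- sort(unique(c(cls$member_low, cls$member_high)))
  out <- data.frame(bird = birds, rate_contact = NA_real_,
                    rate_noncontact = NA_real_,
                    n_partners_contact = 0L, n_partners_noncontact = 0L)
  for (b in seq_along(birds)) {
    mine <- st$member_low == birds[b] | st$member_high == birds[b]
    for (cl in c(TRUE, FALSE)) {
      r <- rate[mine & contacted == cl]
      r <- r[!is.na(r)]                     # drop empty-window dyads
      col <- if (cl) "rate_contact" else "rate_noncontact"
      ncol_ <- if (cl) "n_partners_contact" else "n_partners_noncontact"
      out[[ncol_]][b] <- length(r)
      if (length(r) > 0L) out[[col]][b] <- mean(r)
    }
  }
  out
}

# Paired t statistic on differences; 0/0 -> 0, c/0 -> signed Inf.
.paired_t <- function(d) {
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(n))
}

#' Sign-flip paired permutation test on proximity-rate differences
#'
#' Tests whether per-bird mean rates with later-contacted stranger partners
#' exceed rates with never-contacted partners. The statistic is the paired
#' t on within-bird differences; the null is built by independently flipping
#' the sign of each bird's difference (valid when differences are symmetric
#' about zero under the null). One-sided alternative: contact > non-contact.
#'
#' @param pairs data.frame from [paired_rates()]; birds missing either class
#'   are dropped (with a message).
#' @param n_iter Monte-Carlo iterations (default 5000); p uses the add-one
#'   rule. Ignored when `exact = TRUE`.
#' @param seed Integer seed for the Monte-Carlo flips.
#' @param exact Enumerate all `2^n` sign patterns instead of sampling
#'   (feasible for small n); p is then the exact proportion of patterns with
#'   statistic at or above the observed one (the identity pattern makes it
#'   positive).
#' @return Object of class `perm_result` with the observed t, the null t
#'   distribution, one-sided p, and the group means/SD/SE of both rate
#'   classes. All differences zero yields p = 1 and a `degenerate` flag.
#' @export
permuted_paired_test <- function(pairs, n_iter = 5000, seed = 1L,
                                 exact = FALSE) {
  ok <- !is.na(pairs$rate_contact) & !is.na(pairs$rate_noncontact)
  if (any(!ok)) {
    message(sprintf(
      "permuted_paired_test: dropped %d bird(s) lacking a partner class",
      sum(!ok)))
  }
  d <- pairs$rate_contact[ok] - pairs$rate_noncontact[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)

  obs <- .paired_t(d)
  degenerate <- all(d == 0)
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null_t <- apply(signs * rep(d, each = nrow(signs)), 1L, .paired_t)
    p <- mean(null_t >= obs)
    n_iter <- nrow(signs)
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), nrow = n)
    dm <- flips * d
    mns <- colMeans(dm)
    sds <- sqrt((colSums(dm^2) - n * mns^2) / (n - 1))
    null_t <- ifelse(sds == 0, ifelse(mns == 0, 0, sign(mns) * Inf),
                     mns / (sds / sqrt(n)))
    p <- (1 + sum(null_t >= obs)) / (1 + n_iter)
  }
  if (degenerate) p <- 1

  rc <- pairs$rate_contact[ok]
  rn <- pairs$rate_noncontact[ok]
  structure(list(
    statistic_name = "paired t (contact - noncontact proximity rate)",
    observed = obs,
    null_values = null_t,
    null_mean = mean(null_t),
    upper95 = unname(quantile(null_t, 0.95)),
    p_one_sided = p,
    n_iter = as.integer(n_iter),
    seed = as.integer(seed),
    n_pairs = n,
    exact = exact,
    degenerate = degenerate,
    group_means = c(contact = mean(rc), noncontact = mean(rn)),
    group_sd = c(contact = sd(rc), noncontact = sd(rn)),
    group_se = c(contact = sd(rc) / sqrt(n), noncontact = sd(rn) / sqrt(n))
  ), class = "perm_result")
}
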