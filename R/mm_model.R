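# Bayesian multi-membership Bernoulli (logit) model of sequence adherence.
#
# Each evaluable dyad contributes one Bernoulli outcome (supported = 1).
# The linear predictor loads the random effects of BOTH member birds with
# equal weight -- the classic multi-membership structure that accounts for
# the non-independence of dyads sharing an individual:
#
#   logit P(y_ij = 1) = b0 + b_stranger * stranger_ij (+ sex terms)
#                       + u_i + u_j,   u_k ~ Normal(0, sigma_u)
#
# Priors: Normal(0, sd 10) on fixed effects, half-Student-t(3, 0, 2.5) on
# sigma_u. Sampling is Gibbs/slice via JAGS; convergence is checked with
# split-free Rhat (Gelman-Rubin over chains) and effective sample size.

#' Build model data from dyad classifications
#'
#' Drops non-evaluable dyads (never observed in contact), codes the outcome
#' as supported = 1, the familiarity contrast as stranger = 1, and indexes
#' both member birds.
#'
#' @param cls A `dyad_classifications` data.frame (see [classify_all()]).
#' @param sequence_type `"generalized"` or `"precise"`.
#' @param include_sex Add the dyad sex composition (MF reference, MM and FF
#'   dummies) as fixed effects.
#' @param include_noncontact_as_supported Sensitivity flag as in
#'   [classification_summary()].
#' @return List of class `mm_data`: `y`, `stranger`, `i1`, `i2`, `birds`
#'   (id lookup), optional `sex_mm`/`sex_ff`, and the retained dyad ids.
#' @export
build_model_data <- function(cls, sequence_type = c("generalized", "precise"),
                             include_sex = FALSE,
                             include_noncontact_as_supported = FALSE) {
  sequence_type <- match.arg(sequence_type)
  v <- cls[[sequence_type]]
  if (include_noncontact_as_supported) v[v == "not_evaluable"] <- "supported"
  keep <- v != "not_evaluable"
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("build_model_data: dropped %d non-evaluable dyad(s)", n_drop))
  }
  d <- cls[keep, , drop = FALSE]
  v <- v[keep]
  for (fam in c("stranger", "familiar")) {
    if (!any(d$familiarity == fam)) {
      stop("no evaluable dyad in stratum '", fam,
           "'; the familiarity contrast cannot be fit", call. = FALSE)
    }
  }
  birds <- sort(unique(c(d$member_low, d$member_high)))
  out <- list(
    y = as.integer(v == "supported"),
    stranger = as.integer(d$familiarity == "stranger"),
    i1 = match(d$member_low, birds),
    i2 = match(d$member_high, birds),
    birds = birds,
    dyad_id = d$dyad_id,
    sequence_type = sequence_type,
    include_sex = include_sex
  )
  if (include_sex) {
    out$sex_mm <- as.integer(d$sex_composition == "MM")
    out$sex_ff <- as.integer(d$sex_composition == "FF")
  }
  class(out) <- "mm_data"
  out
}

.mm_model_string <- function(include_sex, prior_sd_fixed = 10,
                             prior_scale_sigma = 2.5) {
  tau_fixed <- sprintf("%.6g", 1 / prior_sd_fixed^2)
  tau_sigma <- sprintf("%.6g", 1 / prior_scale_sigma^2)
  sex_terms <- if (include_sex) " + b_sexMM * sex_mm[d] + b_sexFF * sex_ff[d]" else ""
  sex_priors <- if (include_sex) {
    sprintf("  b_sexMM ~ dnorm(0, %s)\n  b_sexFF ~ dnorm(0, %s)\n",
            tau_fixed, tau_fixed)
  } else ""
  paste0(
    "model {\n",
    "  for (d in 1:N) {\n",
    "    y[d] ~ dbern(p[d])\n",
    "    logit(p[d]) <- b0 + b_stranger * stranger[d]", sex_terms,
    " + u[i1[d]] + u[i2[d]]\n",
    "  }\n",
    "  for (k in 1:K) { u[k] ~ dnorm(0, tau_u) }\n",
    sprintf("  b0 ~ dnorm(0, %s)\n", tau_fixed),
    sprintf("  b_stranger ~ dnorm(0, %s)\n", tau_fixed),
    sex_priors,
    # half-Student-t(3, 0, scale) on the random-effect SD
    sprintf("  sigma_u ~ dt(0, %s, 3) T(0,)\n", tau_sigma),
    "  tau_u <- pow(sigma_u, -2)\n",
    "}\n"
  )
}

#' Fit the multi-membership model
#'
#' @param data An `mm_data` list (see [build_model_data()]).
#' @param chains Number of MCMC chains (default 4).
#' @param iter Total iterations per chain including warmup (default 8000).
#' @param warmup Adaptation + burn-in iterations per chain (default 4000);
#'   `iter - warmup` draws per chain are retained.
#' @param seed Integer seed; per-chain RNGs are seeded from it, so two fits
#'   with the same seed are identical.
#' @param prior_sd_fixed SD of the Normal(0, sd) prior on fixed effects
#'   (default 10, a proper but effectively flat prior on the logit scale).
#' @param prior_scale_sigma Scale of the half-Student-t(3, 0, scale) prior
#'   on `sigma_u` (default 2.5).
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `mm_fit`: the `coda::mcmc.list` of retained draws
#'   for the fixed effects and `sigma_u`, plus fitting metadata. A warning
#'   is raised when any Rhat exceeds 1.01.
#' @export
fit_mm <- function(data, chains = 4, iter = 8000, warmup = 4000, seed = 1L,
                   prior_sd_fixed = 10, prior_scale_sigma = 2.5,
                   quiet = TRUE) {
  stopifnot(inherits(data, "mm_data"), iter > warmup, warmup >= 2, chains >= 1)
  jd <- list(y = data$y, stranger = data$stranger, i1 = data$i1, i2 = data$i2,
             N = length(data$y), K = length(data$birds))
  params <- c("b0", "b_stranger", "sigma_u")
  if (isTRUE(data$include_sex)) {
    jd$sex_mm <- data$sex_mm
    jd$sex_ff <- data$sex_ff
    params <- c("b0", "b_stranger", "b_sexMM", "b_sexFF", "sigma_u")
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 97L + ch) %% .Machine$integer.max)
  })
  n_adapt <- as.integer(min(1000, floor(warmup / 2)))
  n_burn <- as.integer(warmup - n_adapt)
  model_str <- .mm_model_string(data$include_sex, prior_sd_fixed,
                                prior_scale_sigma)
  model <- rjags::jags.model(textConnection(model_str),
                             data = jd, inits = inits, n.chains = chains,
                             n.adapt = n_adapt, quiet = quiet)
  if (n_burn > 0L) update(model, n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, params, n.iter = iter - warmup,
                                 progress.bar = "none")
  fit <- structure(list(samples = samples, data = data, chains = chains,
                        iter = iter, warmup = warmup, seed = seed,
                        params = params),
                   class = "mm_fit")
  rh <- mm_diagnostics(fit)$rhat
  if (any(rh > 1.01, na.rm = TRUE)) {
    warning("possible non-convergence: Rhat > 1.01 for ",
            paste(names(rh)[which(rh > 1.01)], collapse = ", "),
            call. = FALSE)
  }
  fit
}

#' MCMC convergence diagnostics
#'
#' @param fit An `mm_fit` object.
#' @return List with per-parameter `rhat` (Gelman-Rubin potential scale
#'   reduction; `NA` with one chain) and `ess` (effective sample size).
#' @export
mm_diagnostics <- function(fit) {
  s <- fit$samples
  pars <- coda::varnames(s)
  rhat <- if (length(s) >= 2L) {
    g <- coda::gelman.diag(s, multivariate = FALSE, autoburnin = FALSE)
    setNames(g$psrf[, 1L], rownames(g$psrf))[pars]
  } else {
    setNames(rep(NA_real_, length(pars)), pars)
  }
  list(rhat = rhat, ess = coda::effectiveSize(s)[pars])
}

#' Posterior summaries with odds factors
#'
#' Means and equal-tailed 95% credible intervals on the log-odds scale, and
#' odds factors obtained by exponentiating the draws samplewise and then
#' summarising (never `exp()` of the mean summary; the CI endpoints of a
#' monotone transform are the transformed endpoints). `sigma_u` is a scale,
#' not a log-odds, so its odds-factor columns are `NA`.
#'
#' @param fit An `mm_fit` object, or a draws matrix / `coda::mcmc.list`
#'   whose columns are parameters on the log-odds scale.
#' @return data.frame with columns `parameter`, `mean`, `ci_low`, `ci_high`,
#'   `odds_factor`, `odds_ci_low`, `odds_ci_high`, `rhat`, `ess`.
#' @export
summarize_mm <- function(fit) {
  if (inherits(fit, "mm_fit")) {
    draws <- as.matrix(fit$samples)
    diag <- mm_diagnostics(fit)
  } else {
    draws <- as.matrix(fit)
    if (is.null(colnames(draws))) {
      colnames(draws) <- paste0("par", seq_len(ncol(draws)))
    }
    diag <- list(rhat = setNames(rep(NA_real_, ncol(draws)), colnames(draws)),
                 ess = setNames(rep(NA_real_, ncol(draws)), colnames(draws)))
  }
  out <- lapply(colnames(draws), function(p) {
    x <- draws[, p]
    ci <- unname(quantile(x, c(0.025, 0.975)))
    is_scale <- identical(p, "sigma_u")
    data.frame(
      parameter = p,
      mean = mean(x), ci_low = ci[1L], ci_high = ci[2L],
      odds_factor = if (is_scale) NA_real_ else mean(exp(x)),
      odds_ci_low = if (is_scale) NA_real_ else exp(ci[1L]),
      odds_ci_high = if (is_scale) NA_real_ else exp(ci[2L]),
      rhat = unname(diag$rhat[p]), ess = unname(diag$ess[p])
    )
  })
  do.call(rbind, out)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> %s sequence | %d dyads, %d birds | %d chain(s) x %d iter (%d warmup)\n",
    x$data$sequence_type, length(x$data$y), length(x$data$birds),
    x$chains, x$iter, x$warmup))
  print(summarize_mm(x), digits = 3)
  invisible(x)
}
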