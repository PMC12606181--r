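# First-occurrence extraction and sequence classification.

test_that("first occurrences take the minimum bin over each tier's behaviours", {
  ros <- fixture_roster()
  occ <- data.frame(
    dyad_id = "A--B",
    behavior = c("allopreen", "allopreen", "allopreen", "shoulder_contact"),
    bin = c(10L, 4L, 30L, 7L)
  )
  bins <- fixture_bins(occ, ros)
  f <- first_occurrences(bins, "A--B")
  expect_equal(f[["MODERATE"]], 4L)
  expect_true(is.na(f[["LOW"]]))
  expect_true(is.na(f[["HIGH"]]))

  # brute-force oracle on a 6-record fixture: scan records by tier directly
  occ6 <- data.frame(
    dyad_id = c("A--B", "A--B", "A--B", "A--C", "A--C", "C--D"),
    behavior = c("proximity", "beak_touch", "allofeed", "proximity",
                 "proximity", "copulation"),
    bin = c(3L, 9L, 2L, 50L, 11L, 0L)
  )
  bins6 <- fixture_bins(occ6, ros)
  ft <- first_occurrence_table(bins6)
  tiers <- as.character(tier_of(occ6$behavior))
  for (d in unique(occ6$dyad_id)) {
    for (tl in risk_tiers()) {
      expected <- suppressWarnings(min(occ6$bin[occ6$dyad_id == d & tiers == tl]))
      got <- ft[[paste0("first_", tolower(tl))]][ft$dyad_id == d]
      if (is.finite(expected)) expect_equal(got, expected)
      else expect_true(is.na(got))
    }
  }
  # a dyad never observed at all is present with all-NA firsts
  expect_true(all(is.na(ft[ft$dyad_id == "B--C",
                           c("first_low", "first_moderate", "first_high")])))
})

test_that("verdicts match the hand-derived truth table over tier configurations", {
  # columns: first bins (NA = tier absent), expected generalized / precise
  cases <- list(
    #    L   M   H   generalized      precise
    list(NA, NA, NA, "not_evaluable", "not_evaluable"),
    list(3L, NA, NA, "not_evaluable", "not_evaluable"),
    list(NA, 2L, NA, "violated", "violated"),
    list(NA, NA, 2L, "violated", "violated"),
    list(3L, 10L, NA, "supported", "supported"),
    list(5L, 2L, NA, "violated", "violated"),
    list(3L, NA, 10L, "supported", "violated"),   # HIGH with no MODERATE
    list(5L, NA, 2L, "violated", "violated"),
    list(NA, 2L, 8L, "violated", "violated"),
    list(NA, 8L, 2L, "violated", "violated"),
    list(3L, 10L, 50L, "supported", "supported"),
    list(3L, 50L, 10L, "supported", "violated"),  # HIGH before MODERATE
    list(10L, 3L, 50L, "violated", "violated"),
    list(10L, 50L, 3L, "violated", "violated"),
    list(50L, 3L, 10L, "violated", "violated"),
    list(50L, 10L, 3L, "violated", "violated"),
    # ties: only the MODERATE/HIGH tie is granted simultaneity
    list(3L, 7L, 7L, "supported", "supported"),
    list(3L, 3L, 10L, "violated", "violated"),
    list(3L, 10L, 3L, "violated", "violated"),
    list(3L, 3L, 3L, "violated", "violated")
  )
  firsts <- data.frame(
    first_low = vapply(cases, function(x) as.integer(x[[1]]), 1L),
    first_moderate = vapply(cases, function(x) as.integer(x[[2]]), 1L),
    first_high = vapply(cases, function(x) as.integer(x[[3]]), 1L)
  )
  expect_equal(classify_generalized(firsts),
               vapply(cases, function(x) x[[4]], ""))
  expect_equal(classify_precise(firsts),
               vapply(cases, function(x) x[[5]], ""))
})

test_that("precise support implies generalized support, and verdicts are invariant under monotone bin relabelling", {
  set.seed(101)
  n <- 500
  rand_col <- function() {
    x <- sample(0:20, n, replace = TRUE)
    x[runif(n) < 0.3] <- NA
    x
  }
  firsts <- data.frame(first_low = rand_col(), first_moderate = rand_col(),
                       first_high = rand_col())
  gen <- classify_generalized(firsts)
  prec <- classify_precise(firsts)
  expect_true(all(gen[prec == "supported"] == "supported"))
  expect_true(all(prec[gen == "violated"] == "violated"))
  expect_equal(gen == "not_evaluable", prec == "not_evaluable")

  # strictly increasing relabelling of bins preserves all verdicts
  mono <- function(x) 3L * x^2L + x + 7L   # strictly increasing on 0:20
  relabelled <- data.frame(first_low = mono(firsts$first_low),
                           first_moderate = mono(firsts$first_moderate),
                           first_high = mono(firsts$first_high))
  expect_equal(classify_generalized(relabelled), gen)
  expect_equal(classify_precise(relabelled), prec)
})

test_that("classify_all matches a hand count on a crafted 10-dyad fixture", {
  ros <- fixture_roster(sites = list(s1 = c("A", "B", "C"),
                                     s2 = c("D", "E")))
  occ <- data.frame(
    dyad_id = c("A--D", "A--D", "A--E", "A--E", "B--D", "B--D", "B--E",
                "A--B", "A--B", "A--C", "D--E", "D--E", "D--E"),
    behavior = c("proximity", "allopreen",        # A--D: L2 < M9: supported
                 "shoulder_contact", "proximity", # A--E: M1 < L6: violated
                 "proximity", "allofeed",         # B--D: L3 < H4, no M: gen only
                 "proximity",                     # B--E: LOW only: not evaluable
                 "proximity", "beak_touch",       # A--B (familiar): L0 < M5
                 "copulation",                    # A--C (familiar): H only
                 "proximity", "allopreen", "allofeed"), # D--E: L1 < M2 < H8
    bin = c(2L, 9L, 1L, 6L, 3L, 4L, 5L, 0L, 5L, 7L, 1L, 2L, 8L)
  )
  bins <- fixture_bins(occ, ros)
  cls <- classify_all(bins)
  expect_equal(nrow(cls), 10)   # C(5,2)

  verdict <- function(d, col) cls[[col]][cls$dyad_id == d]
  expect_equal(verdict("A--D", "generalized"), "supported")
  expect_equal(verdict("A--E", "generalized"), "violated")
  expect_equal(verdict("B--D", "generalized"), "supported")
  expect_equal(verdict("B--D", "precise"), "violated")
  expect_equal(verdict("B--E", "generalized"), "not_evaluable")
  expect_equal(verdict("A--C", "generalized"), "violated")
  expect_equal(verdict("D--E", "precise"), "supported")

  # hand count: strangers evaluable {A--D, A--E, B--D, D--E}... D--E is
  # familiar? D,E share s2 -> familiar. strangers evaluable: A--D, A--E, B--D
  s <- classification_summary(cls)
  expect_equal(s$n_evaluable[s$stratum == "stranger" & s$sequence == "generalized"], 3)
  expect_equal(s$n_supported[s$stratum == "stranger" & s$sequence == "generalized"], 2)
  expect_equal(s$proportion_supported[s$stratum == "stranger" & s$sequence == "precise"], 1 / 3)
  # familiar evaluable: A--B (sup/sup), A--C (viol), D--E (sup/sup)
  expect_equal(s$n_supported[s$stratum == "familiar" & s$sequence == "generalized"], 2)
  expect_equal(s$proportion_supported[s$stratum == "all" & s$sequence == "generalized"], 4 / 6)

  # sensitivity flag: non-contact dyads counted as supported
  s2 <- classification_summary(cls, include_noncontact_as_supported = TRUE)
  expect_equal(s2$n_evaluable[s2$stratum == "stranger" & s2$sequence == "generalized"],
               nrow(cls[cls$familiarity == "stranger", ]))
  expect_equal(s2$n_supported[s2$stratum == "stranger" & s2$sequence == "generalized"], 2 + 3)
})

test_that("all-noncontact data yields undefined proportions, full-adherence data yields 1", {
  ros <- fixture_roster()
  occ <- data.frame(dyad_id = c("A--C", "B--D"), behavior = "proximity",
                    bin = c(1L, 2L))
  s <- classification_summary(classify_all(fixture_bins(occ, ros)))
  expect_true(all(is.nan(s$proportion_supported)))

  co <- simulate_cohort(sim_config(
    site_sizes = c(4L, 4L), n_female = 4L, n_days = 6L,
    adherence_stranger = 1, adherence_familiar = 1,
    preference_fraction = 1, contact_fraction_familiar = 1, seed = 5
  ))
  recs <- suppressMessages(
    dyadseq:::validate_observations(co$observations, co$roster, co$schedule))
  cls <- classify_all(binarize(recs, co$schedule, roster = co$roster))
  s <- classification_summary(cls)
  expect_true(all(s$proportion_supported[s$n_evaluable > 0] == 1))
})
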