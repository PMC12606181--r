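# Ingestion, dyad enumeration, tier mapping and 5-minute binarization.

test_that("tier mapping is total over the repertoire and rejects strangers to it", {
  expect_equal(as.character(tier_of("proximity")), "LOW")
  expect_equal(as.character(tier_of("allopreen")), "MODERATE")
  expect_equal(as.character(tier_of("copulation")), "HIGH")
  expect_equal(
    as.character(tier_of(behavior_repertoire())),
    c("LOW", "MODERATE", "MODERATE", "MODERATE", "HIGH", "HIGH")
  )
  expect_error(tier_of("flying"), "repertoire")
})

test_that("dyad enumeration returns C(n,2) pairs with site-based familiarity", {
  # study roster structure: sites of 5, 6, 7, 4 birds
  ros <- fixture_roster(sites = list(s1 = sprintf("a%d", 1:5),
                                     s2 = sprintf("b%d", 1:6),
                                     s3 = sprintf("c%d", 1:7),
                                     s4 = sprintf("d%d", 1:4)))
  dy <- enumerate_dyads(ros)
  expect_equal(nrow(dy), choose(22, 2))
  expect_equal(sum(dy$familiarity == "familiar"), 52)
  expect_equal(sum(dy$familiarity == "stranger"), 179)

  # brute force on a 3-bird single-site roster: all pairs familiar
  ros3 <- fixture_roster(sites = list(s1 = c("x", "y", "z")))
  dy3 <- enumerate_dyads(ros3)
  expect_equal(nrow(dy3), 3)
  expect_equal(sum(dy3$familiarity == "familiar"), 3)
  expect_true(all(dy3$member_low < dy3$member_high))

  expect_equal(nrow(enumerate_dyads(fixture_roster(sites = list(s1 = "solo")))), 0)
  expect_error(
    enumerate_dyads(data.frame(id = c("a", "a"), sex = "M", site = "s1")),
    "duplicate"
  )
})

test_that("familiar and stranger counts always sum to choose(n, 2)", {
  set.seed(42)
  for (rep in 1:20) {
    n_sites <- sample(1:5, 1)
    sizes <- sample(1:6, n_sites, replace = TRUE)
    ids <- sprintf("b%02d", seq_len(sum(sizes)))
    ros <- data.frame(id = ids,
                      sex = sample(c("F", "M"), length(ids), replace = TRUE),
                      site = rep(sprintf("s%d", seq_len(n_sites)), sizes))
    dy <- enumerate_dyads(ros)
    expect_equal(nrow(dy), choose(length(ids), 2))
    expect_equal(sum(dy$familiarity == "familiar"),
                 sum(choose(sizes, 2)))
    expect_equal(dy$sex_composition,
                 c("MM", "MF", "FF")[1 +
                   (ros$sex[match(dy$member_low, ros$id)] == "F") +
                   (ros$sex[match(dy$member_high, ros$id)] == "F")])
  }
})

test_that("read_observations validates rows and reports rejections", {
  ros <- fixture_roster()
  sch <- fixture_schedule(n_sessions = 1)
  good <- fixture_records("S01", c(10, 400, 3000), "allopreen", "A",
                          c("B", "C", "D"))
  expect_silent(recs <- read_observations(records_csv(good), ros, sch))
  expect_equal(nrow(recs), 3)
  expect_type(recs$timestamp, "double")

  bad <- rbind(good,
               fixture_records("S01", 5, "flying", "A", "B"),
               fixture_records("S01", 5, "allopreen", "A", "Z"),
               fixture_records("S01", 5, "allopreen", "A", "A"),
               fixture_records("S01", 9999, "allopreen", "A", "B"))
  w <- capture_warnings(
    suppressMessages(recs2 <- read_observations(records_csv(bad), ros, sch)))
  for (reason in c("unknown_behavior", "unknown_bird", "self_directed",
                   "bad_timestamp")) {
    expect_true(any(grepl(reason, w)), info = reason)
  }
  expect_equal(nrow(recs2), 3)
  expect_equal(sum(attr(recs2, "dropped")), 4)

  # solitary records (no receiver) are dropped with a count message only
  sol <- rbind(good, fixture_records("S01", 5, "proximity", "A", NA))
  expect_message(recs3 <- read_observations(records_csv(sol), ros, sch),
                 "solitary")
  expect_equal(nrow(recs3), 3)

  expect_error(
    read_observations(records_csv(good[, -1]), ros, sch),
    "missing column"
  )
  empty <- good[0, ]
  expect_warning(r0 <- read_observations(records_csv(empty), ros, sch), "empty")
  expect_equal(nrow(r0), 0)
})

test_that("exact duplicate rows survive reading and collapse at bin level", {
  ros <- fixture_roster()
  sch <- fixture_schedule(n_sessions = 1)
  two <- fixture_records("S01", c(100, 100), "allopreen", "A", "B")
  recs <- read_observations(records_csv(two), ros, sch)
  expect_equal(nrow(recs), 2)
  bins <- binarize(recs, sch, roster = ros)
  expect_equal(nrow(bins$occ), 1)
})

test_that("binarization uses half-open session-anchored 5-minute bins", {
  ros <- fixture_roster()
  sch <- fixture_schedule(n_sessions = 2, hours = 1)

  # two observers log the same interaction at 601 s and 655 s: bin 2 once
  recs <- fixture_records("S01", c(601, 655), "allopreen",
                          c("A", "B"), c("B", "A"), observer = c("O1", "O2"))
  bins <- binarize(recs, sch, roster = ros)
  expect_equal(nrow(bins$occ), 1)
  expect_equal(bins$occ$bin, 2L)
  expect_equal(bins$occ$dyad_id, "A--B")

  # t = 0 and t = 299 share bin 0; t = 300 opens bin 1
  recs2 <- fixture_records("S01", c(0, 299, 300), "proximity", "A", "B")
  bins2 <- binarize(recs2, sch, roster = ros)
  expect_equal(sort(bins2$occ$bin), c(0L, 1L))

  # sessions concatenate chronologically: second session starts at bin 12
  recs3 <- fixture_records(c("S01", "S02"), c(0, 0), "proximity", "A", "B")
  bins3 <- binarize(recs3, sch, roster = ros)
  expect_equal(sort(bins3$occ$bin), c(0L, 12L))
  expect_equal(bins3$n_bins, 24L)
  expect_equal(bins3$hours_observed, 2)

  # records outside the schedule are rejected with a warning
  recs4 <- fixture_records(c("S01", "S99"), c(100, 100), "proximity", "A", "B")
  expect_warning(bins4 <- binarize(recs4, sch, roster = ros), "outside")
  expect_equal(nrow(bins4$occ), 1)

  expect_equal(nrow(binarize(recs2[0, ], sch, roster = ros)$occ), 0)
})

test_that("binarize is order-invariant and idempotent under duplication", {
  ros <- fixture_roster(sites = list(s1 = c("A", "B", "C"),
                                     s2 = c("D", "E")))
  sch <- fixture_schedule(n_sessions = 3, hours = 1)
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    birds <- sample(ros$id, 2 * n, replace = TRUE)
    a <- birds[1:n]
    b <- birds[(n + 1):(2 * n)]
    keep <- a != b
    recs <- fixture_records(sample(sch$session_id, sum(keep), replace = TRUE),
                            floor(runif(sum(keep), 0, 3600)),
                            sample(behavior_repertoire(), sum(keep),
                                   replace = TRUE),
                            a[keep], b[keep])
    base <- binarize(recs, sch, roster = ros)
    shuffled <- binarize(recs[sample.int(nrow(recs)), ], sch, roster = ros)
    duplicated <- binarize(rbind(recs, recs[sample.int(nrow(recs), 5), ]),
                           sch, roster = ros)
    key <- function(b) {
      o <- as.data.frame(b$occ)
      o[order(o$dyad_id, o$behavior, o$bin), ]
    }
    expect_equal(key(shuffled), key(base), ignore_attr = TRUE)
    expect_equal(key(duplicated), key(base), ignore_attr = TRUE)
    # reachability: every occurrence has a contributing raw record
    o <- as.data.frame(base$occ)
    raw_dyads <- dyad_id(recs$actor, recs$receiver)
    for (k in seq_len(nrow(o))) {
      expect_true(any(raw_dyads == o$dyad_id[k] &
                        recs$behavior == o$behavior[k]))
    }
  }
})

test_that("roster and schedule readers validate their files", {
  ros <- fixture_roster()
  path <- tempfile(fileext = ".csv")
  write.csv(ros, path, row.names = FALSE)
  expect_equal(read_roster(path), ros, ignore_attr = TRUE)

  sch <- fixture_schedule(2)
  path2 <- tempfile(fileext = ".csv")
  write.csv(sch, path2, row.names = FALSE)
  got <- read_schedule(path2)
  expect_equal(got$length_s, c(3600, 3600))

  bad <- sch
  bad$end <- bad$start
  expect_error(dyadseq:::validate_schedule(bad), "end")
})
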