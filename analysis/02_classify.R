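#!/usr/bin/env Rscript
# Stage 2: binarize the observation stream and classify dyad sequences.
#
# Reads the cohort CSVs from stage 1, collapses raw sightings into 5-minute
# dyad x behaviour presence bins (deduplicating multi-observer records),
# extracts each dyad's first occurrence of the LOW / MODERATE / HIGH risk
# tiers, and scores every dyad against the generalized (LOW before any
# contact) and precise (LOW before MODERATE before-or-with HIGH) sequences.

suppressPackageStartupMessages(library(dyadseq))

roster <- read_roster("results/cohort/roster.csv")
schedule <- read_schedule("results/cohort/schedule.csv")
records <- read_observations("results/cohort/observations.csv", roster, schedule)

bins <- binarize(records, schedule, roster = roster)
print(bins)

cls <- classify_all(bins)
s <- classification_summary(cls)
print(s, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(cls), "results/classifications.csv", row.names = FALSE)
write.csv(s, "results/classification_summary.csv", row.names = FALSE)
write.csv(as.data.frame(bins), "results/binarized_long.csv", row.names = FALSE)

g <- s[s$sequence == "generalized", ]
cat(sprintf(
  "\nsupported proportion (generalized): strangers %.2f (%d evaluable), familiar %.2f (%d evaluable)\n",
  g$proportion_supported[g$stratum == "stranger"],
  g$n_evaluable[g$stratum == "stranger"],
  g$proportion_supported[g$stratum == "familiar"],
  g$n_evaluable[g$stratum == "familiar"]))
cat("wrote results/classifications.csv, classification_summary.csv, binarized_long.csv\n")
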