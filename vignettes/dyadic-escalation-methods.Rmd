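---
title: "Methods: detecting low-to-high escalation in dyadic affiliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting low-to-high escalation in dyadic affiliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadseq)
```

## The question and the data model

When two unfamiliar animals begin a relationship, do they "test the waters"
— escalating from cheap, low-risk investment (approaching and sitting near
each other without contact) through moderate-risk contact (shoulder
contact, allopreening, beak touching) to high-risk investment (allofeeding,
copulation) — rather than jumping straight to costly contact? `dyadseq`
implements a complete analysis of that question for observation streams
from a newly merged captive group: birds from several capture sites
released together, where same-site pairs ("familiar" dyads) carry
established relationships and cross-site pairs ("stranger" dyads) must
build them from scratch.

The raw data are time-stamped sightings: nearest-neighbour **scan samples**
(one `proximity` record per scan interval when two birds sat peacefully
within reach of each other without touching) and **all-occurrence** records
of five contact behaviours, logged by several observers in parallel. The
unit of analysis is the **dyad**, the unordered pair of birds; with
`r sum(c(5, 6, 7, 4))` birds from sites of 5, 6, 7 and 4, there are
`choose(22, 2) = 231` dyads: 52 familiar and 179 stranger.

Everything downstream works on a single derived structure: for each dyad,
behaviour and 5-minute **time bin**, did the behaviour occur (1) or not
(0)? Bins are half-open intervals anchored at each session's start (the
protocol splits days into morning and evening sessions, so midnight-anchored
bins would have no meaning), and sessions are concatenated chronologically
into one global bin index. Consequently `k` bins always represent `k/12`
*observed* hours, which the rate analysis relies on. Binarizing also
performs the deduplication the multi-observer protocol requires: two
observers logging one interaction, or one behaviour continuing across a
scan, collapse to the same (dyad, behaviour, bin) cell.

Behaviours map onto three ordered **risk tiers** — LOW (`proximity`),
MODERATE (`shoulder_contact`, `allopreen`, `beak_touch`), HIGH
(`allofeed`, `copulation`). Two predicted sequences are scored from each
dyad's per-tier *first* occurrences:

* **generalized**: the first LOW bin strictly precedes the first bin of any
  contact tier;
* **precise**: generalized holds, and additionally the first MODERATE bin
  precedes or equals the first HIGH bin (HIGH absent also qualifies).

Ties are resolved asymmetrically on purpose: MODERATE and HIGH occurring in
the same 5-minute bin still support the precise sequence (at 5-minute
resolution their order is genuinely unobservable, and the prediction treats
them as one escalation step), but a LOW that shares its first bin with a
contact tier does *not* count as preceding it — the hypothesis requires
no-contact proximity to come first, and granting ties would manufacture
support out of resolution limits.

Dyads never observed in any contact tier have nothing to order and are
scored `not_evaluable`; they are excluded from all sequence denominators.
The alternative reading — counting contact-free dyads as (vacuous)
supporters — is available everywhere via
`include_noncontact_as_supported = TRUE` for sensitivity analysis, since
published denominators for this kind of probability are rarely explicit.
A related open protocol question is whether a contact record should imply a
simultaneous LOW record (two birds touching are certainly within reach of
one another); the pipeline deliberately does not auto-add proximity when
contact occurs, keeping the tiers' evidence independent.

## Inference 1: the time-bin-shuffling null

A high supported proportion is not evidence by itself: proximity scans are
far more frequent than contact events, so LOW tends to come first even if
behaviours were ordered at random. The reference model therefore asks: *if
every record kept its dyad and behaviour but the time bins were dealt out
at random, how often would dyads match the sequences?* `shuffle_bins()`
permutes the bin column of the deduplicated occurrence records jointly
across all dyads and behaviours, preserving exactly (i) the multiset of
occupied bins and (ii) every dyad's per-behaviour record count — the
behaviour-frequency control that motivates the design. Post-shuffle
collisions collapse to one occurrence, consistent with binary coding
(collisions never affect first occurrences, so the statistic is unaffected;
only audit counts shrink). A per-dyad-only shuffle mode exists as an
alternative, but the joint shuffle is the default because the question is
about order, not about which dyad owns which bins.

One thousand shuffles (the default) rebuild the supported proportion among
evaluable dyads of a stratum; the one-sided p-value uses the add-one rule
`(1 + #{null >= observed}) / (1 + n_iter)`, which can never return zero and
matches the resolution of a discrete permutation test. Which dyads are
evaluable is invariant under the shuffle (tier presence is a record-count
property), so observed and null proportions always share a denominator.
Proportions are compared as integer supported-counts internally, avoiding
floating-point ties. Records are permuted without replacement (exact margin
conservation); a bootstrap-style resampling of bins would preserve margins
only in expectation and has no advantage here.

A subtlety worth stating: this permutation null conditions on behaviour
frequencies. Data in which first occurrences are ordered uniformly at
random but records then *recur* in clusters (many contact events after a
contact onset, as real bonded pairs produce) are **not** draws from this
null — with contact records outnumbering a dyad's LOW records, the shuffle
puts LOW first less than a third of the time, and a uniformly-random-order
cohort looks significant. The test's own null is *exchangeable bins*:
behaviours emitted at constant rates with no onset structure. The
generator's `escalation_mode = "homogeneous"` produces exactly that, and
the calibration study in the test suite runs there. This mirrors how the
test should be read for real data too: it rejects "bins are exchangeable
given frequencies", not merely "first occurrences are in random order".

## Inference 2: the multi-membership model

Dyadic outcomes are not independent — every bird sits in up to 21 dyads.
The familiarity effect is therefore estimated with a Bernoulli
(logit-link) **multi-membership** model over evaluable dyads:

$$\mathrm{logit}\,P(y_{ij} = 1) = \beta_0 + \beta_{\mathrm{stranger}}
\cdot \mathrm{stranger}_{ij} + u_i + u_j, \qquad u_k \sim
\mathcal{N}(0, \sigma_u^2),$$

where $y_{ij} = 1$ when dyad $(i,j)$ supported the sequence and both
members' random effects enter with equal weight (no weighting scheme is
justified for an unordered pair). An optional additive sex-composition
fixed effect (MF reference; MM and FF dummies) covers the secondary
question of whether pair sex predicts escalation.

Sampling runs on JAGS (Gibbs/slice) through `rjags`, with 4 chains of
8 000 iterations and 4 000 warmup per chain by default. Priors are proper
but weak — Normal(0, 10²) on fixed effects, half-Student-t(3, 0, 2.5) on
$\sigma_u$ — and both scales are exposed (`prior_sd_fixed`,
`prior_scale_sigma`). Convergence is judged by Gelman–Rubin Rhat across
chains (warning above 1.01) and effective sample sizes; divergence counts,
an HMC-specific diagnostic, have no Gibbs analogue, so Rhat/ESS carry the
full diagnostic load. Per-chain RNGs are seeded deterministically from one
seed, so a fit is exactly reproducible.

Summaries report posterior means and equal-tailed 95% credible intervals on
the log-odds scale, plus an **odds factor** computed samplewise: the
posterior mean of $e^\beta$, with interval endpoints $e^{q_{.025}},
e^{q_{.975}}$. For a skewed posterior the samplewise mean exceeds
$e^{\bar\beta}$ (Jensen); both are reported, and the distinction is tested.
Two caveats from the simulation work belong in any reading of real fits:
first, when a stratum happens to contain *zero* violations the familiarity
contrast is quasi-separated and its posterior becomes diffuse and
prior-driven — wide intervals in that situation are honest, not a bug;
second, with near-boundary proportions $\sigma_u$ mixes slowly and its
Rhat is usually the first to complain.

## Inference 3: pre-contact proximity rates

If strangers select future partners and then build familiarity through
proximity, birds should show *more* no-contact proximity with the stranger
partners they eventually contact than with those they never contact. For
each stranger dyad the hourly LOW rate is computed **truncated at the
dyad's first contact bin** — counting post-contact proximity would make the
comparison circular — and divided by the observed hours the pre-contact
bins represent (a session-schedule quantity, not elapsed wall-clock time).
Never-contacted dyads use the whole study. Dyads whose first contact falls
in bin 0 have an empty window and are excluded with a warning. Each bird
then contributes one unweighted mean per partner class, and the per-bird
difference is tested with a **sign-flip paired t test** (5 000 iterations,
one-sided: contact > non-contact, add-one p). For small cohorts an exact
mode enumerates all $2^n$ sign patterns. The sign-flip null requires
differences symmetric about zero under H0; the unit calibration in the
test suite checks the attained size under heteroscedastic symmetric
differences, and the group summaries report both SD and SE (published
"±" values are frequently ambiguous between the two).

## The synthetic cohort generator

No observation data ship with the package; `simulate_cohort()` generates
streams with the statistical structure the analysis assumes and known
ground truth, so every stage is testable end to end. Defaults *are* the
study conditions: sites of 5/6/7/4 birds, 8 of 22 female, 22 days × 6
observed hours in two sessions, 300-s scans and bins. Behavioural defaults
are set once from the cohort summaries the analysis is meant to recover:
31% of stranger dyads ever progress to contact and 69% of familiar dyads
hold an established bond (with 9% and 44% of those reaching HIGH);
progressing stranger dyads follow the predicted order with probability
0.95 and familiar ones with 0.86; pre-contact proximity runs at 0.03
events/h against a 0.01 background. Post-contact ("bonded") proximity, a
quantity no summary pins down, is set to 0.12 events/h on the reasoning
that bonded pairs perch together and are picked up by scans far more often
than contact events recur (0.036/h MODERATE, 0.012/h HIGH) — this ratio of
proximity to contact records is what makes LOW-first common under the
shuffle null, as in the field situation.

In the default `"staged"` mode each progressing dyad draws an onset
uniformly within its stratum's onset window (strangers anywhere in the
first 70% of the study; familiar bonds resume in the first 10%), spaces
tier onsets by geometric gaps (hazard 0.02/bin, i.e. a mean of ~4 observed
hours between escalation steps), and orders them either as predicted
(probability = the stratum's adherence) or by a uniformly random
permutation of its expressed tiers. Proximity is emitted only on scan
marks; contact events land at uniform seconds within bins, recur after
onset, and are double-logged by a second observer with probability 0.25.
Progressing dyads are silent in LOW before their assigned onset so that
the planted order *is* the emitted order — a consistency the tests check
record by record. The `"homogeneous"` mode strips all onset structure
(constant per-bin rates from the first bin) and is the exchangeable null
used for calibrating both permutation tests.

The generator's event-level truth implies a model-level truth: a
progressing dyad supports the generalized sequence with probability
$\theta + (1-\theta)\,r$, where $r$ is the random-order success chance
(1/2 for two-tier dyads, 1/3 for three-tier; 1/6 for the precise sequence
with three tiers), and `implied_log_odds()` turns the stranger/familiar
pair of these into the contrast the model should recover. Because the
generator has no bird-level heterogeneity, recovery of $\sigma_u$ itself is
exercised instead by `simulate_mm_cohort()`, which draws outcomes directly
from the multi-membership model with exactly known coefficients; that is
the ground for the coverage and simulation-based-calibration checks.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: spatial structure (proximity is a rate, not
a position process), diurnal and weather-driven activity variation,
observer bias or misidentification (all records name true birds),
behaviour durations, and any bird-level sociability differences in the
event stream. Conclusions about the pipeline's correctness transfer to
real data; conclusions about power and calibration transfer only insofar
as these simplifications are harmless.

## Sizes, seeds and numerical choices

Every stochastic routine takes an integer seed and is bit-reproducible
from it; cohort CSVs are byte-identical given a seed. The test suite runs
its heavier studies at deliberately reduced sizes chosen to keep the whole
suite in the low minutes on one core while leaving the checks sharp: the
permutation-oracle comparisons use ≤5-record toys against exhaustive
enumeration; calibration of both tests uses 200 replicate 4-day cohorts at
199 iterations each; model-recovery coverage uses 50 fits of 16-bird
cohorts at 2 × 1 500 iterations; SBC uses 40 single-chain fits with
narrowed priors (rank uniformity is checked against the *fitted* prior, so
the narrowing is applied consistently on both sides). The full-size
end-to-end run — 22 birds, 22 days, 1 000 + 5 000 permutation iterations
and the 4 × 8 000 model — completes in well under a minute and is exactly
what `scripts/acceptance.R` executes.

Remaining degenerate-input conventions: fewer than two records cannot be
shuffled (returned unchanged, with a warning); a stratum with no evaluable
dyad yields a flagged, NA-valued permutation result rather than an error;
an all-zero difference vector gives p = 1 with a `degenerate` flag; empty
pre-contact windows are excluded from partner means with a warning; and
`read_observations()` rejects — with named-row warnings and per-reason
counts — rather than repairs rows naming unknown birds, unknown
behaviours, self-directed interactions, or timestamps outside their
session.
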