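# dyadseq

Do unfamiliar animals "test the waters" when they build new relationships —
escalating from cheap, low-risk behaviour (sitting close without contact)
through moderate-risk contact (shoulder contact, allopreening, beak
touching) to high-risk investment (allofeeding, copulation) — while
already-familiar pairs skip the ramp? `dyadseq` is a complete, tested R
pipeline for answering that question from multi-observer ethogram streams
of a newly merged captive group, written for behavioural ecologists working
with scan-sampled proximity plus all-occurrence contact data.

The pipeline:

1. **Binarize** — time-stamped sightings become a dyad × behaviour ×
   5-minute-bin presence/absence structure (session-anchored half-open
   bins; multi-observer duplicates collapse), with behaviours mapped to
   LOW / MODERATE / HIGH risk tiers.
2. **Classify** — each dyad's per-tier first occurrences are scored
   against the *generalized* sequence (LOW strictly before any contact)
   and the *precise* sequence (additionally MODERATE before or
   simultaneous with HIGH); dyads never seen in contact are not evaluable.
3. **Permutation null** — bin labels are shuffled (1000 iterations) among
   all records, preserving behaviour frequencies, to get the probability
   of matching each sequence under random ordering and a one-sided
   add-one p-value.
4. **Multi-membership model** — a Bayesian Bernoulli (logit) model of
   sequence support with a stranger-vs-familiar fixed effect and a random
   effect loading *both* member birds,
   `logit P(y_ij) = b0 + b_stranger·stranger_ij + u_i + u_j`,
   `u ~ N(0, sigma_u)`, fit by MCMC (4 chains × 8000 iterations, 4000
   warmup; JAGS via rjags) with Rhat/ESS diagnostics and samplewise odds
   factors.
5. **Proximity rates** — each bird's mean hourly no-contact proximity
   rate with later-contacted vs never-contacted stranger partners
   (truncated before each dyad's first contact), compared with a
   sign-flip permuted paired t-test (5000 iterations, one-sided).

A synthetic cohort generator (`simulate_cohort()`) emulates the study
design — 22 birds from four capture sites (5/6/7/4), 22 days / 132
observation hours, 5-minute scans, four observers with duplicate logging —
with known per-dyad ground truth, so calibration and parameter recovery
are testable without any field data. See the methods vignette
(`vignettes/dyadic-escalation-methods.Rmd`) for the model, its
assumptions, and every numerical convention.

## Worked example

```r
library(dyadseq)

cohort <- simulate_cohort(sim_config(seed = 2026))
report <- run_pipeline(cohort, seed = 2026)
print(report)
```

```
<dyadseq_report>
  22 birds; 231 dyads (52 familiar, 179 stranger); 132.0 h observed
   stratum    sequence n_dyads n_evaluable n_supported proportion_supported
1 stranger generalized     179          64          62                0.969
3 familiar generalized      52          35          33                0.943
...
<perm_result> P(generalized sequence | stranger dyads)
  observed = 0.969 | null mean = 0.728 | null 95% = 0.812 | one-sided p = 0.000999 (1000 iter, 64 dyads)
model [generalized sequence], 99 dyads:
   parameter  mean  ci_low ci_high odds_factor odds_ci_low odds_ci_high rhat
1         b0 3.380  1.7926    5.87       64.99       6.005        355.5 1.01
2 b_stranger 0.635 -1.7219    2.96        3.96       0.179         19.2 1.00
3    sigma_u 0.602  0.0243    2.06          NA          NA           NA 1.02
<perm_result> paired t (contact - noncontact proximity rate)
  observed = 5.377 | null mean = -0.030 | null 95% = 1.684 | one-sided p = 0.0002 (5000 iter, 22 pairs)
```

Reading it: of the 64 stranger dyads ever observed in contact, 96.9%
passed through no-contact proximity before touching, against 72.8%
expected if time bins were dealt at random given behaviour frequencies
(one-sided permutation p ≈ 0.001). Being a stranger dyad shifts the
log-odds of following the sequence by 0.635 (posterior mean; odds factor
3.96, wide interval — with only two violations among strangers the
contrast is weakly identified in a single cohort). Birds kept markedly
higher pre-contact proximity rates with the stranger partners they later
contacted than with those they never did (paired t = 5.4, sign-flip
p = 0.0002, 22 birds).

The numbered drivers under `analysis/` run the same stages against CSV
files on disk (`01_simulate` → `05_rates`, plus a `06_recovery` sweep
against planted ground truth), writing their tables under `results/`.

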