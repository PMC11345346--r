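---
title: "Models and methods: simulating and fitting the fake-news correction paradigm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and fitting the fake-news correction paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrmem)
```

# The paradigm and what the package computes

The package analyses a three-phase experiment on correcting fake news.
Participants first rate real and fake headlines (fake items appear once or
three times, yielding the `CORRECTED_1X` and `CORRECTED_3X` conditions; a
third set of topics shows only real news, `AFFIRMED_REAL`). They then read
real news that affirms or corrects what they saw and indicate when they
detect a correction. After a retention interval they take a memory test:
retrieve the real detail, rate belief in it, say whether the topic was
corrected, and, if so, identify the fake detail.

Four analysis layers operate on a single tidy trial table:
signal-detection estimates of detecting and remembering corrections, a
hierarchical Bayesian dual-process multinomial processing tree (MPT) of the
test choices, a descriptive chain of conditionalized retrieval proportions,
and belief-accuracy summaries. A generative simulator produces complete
cohorts with the same statistical structure, so every estimator can be
validated by parameter recovery without access to any empirical data set.

# The dual-process MPT

On corrected topics, the test response is one of three categories: the real
detail, the previously seen fake detail, or a novel foil. The tree assumes
retrieval succeeds by recollection with probability $P_r$; failing that
($1-P_r$), the studied details are familiar with probability $P_f$, in
which case real and fake details are equally attractive (a 0.5 split that
is fixed, not estimated, for identifiability); failing both, the
participant guesses. Two readings of the guessing stage are implemented
because the verbal model description admits both: `"uniform"` (default)
guesses among all three categories equally, giving

$$P(\text{real}) = P_r + (1-P_r)\tfrac{P_f}{2} + \tfrac{(1-P_r)(1-P_f)}{3},$$

with analogous fake and novel branches; `"sequential"` applies two
successive 0.5 splits, giving guessing probabilities (0.5, 0.25, 0.25).
The two variants genuinely differ (thirds vs. halves at the no-memory
leaf), so both are exposed via the `branching` argument of every tree
function and fit; all identities and the closed-form inverse
(`mpt_moments()`) are tested for both.

## Hierarchical structure

Participant $i$ carries a probit-scale parameter vector
$\theta_i = (\Phi^{-1}(P_{r,ic}), \Phi^{-1}(P_{f,ic}))_{c}$ across the
modelled conditions, drawn from $\mathcal N(\mu, \Sigma)$ with unknown
group mean and *full* covariance (the latent-trait structure). The full
covariance matters: the posterior-predictive covariance check (T2) is only
meaningful if the model can represent correlated individual differences
across parameters and conditions. Group-level estimates are reported as
$\Phi(\mu)$ — the probability-scale location of the group distribution, not
the population average of $\Phi(\theta_i)$, which is smaller in magnitude
whenever heterogeneity is present. The generator uses the same convention,
so recovery compares like with like.

## Priors and sampling

Priors are weakly informative: $\mu_j \sim \mathcal N(0, 1)$ on the probit
scale (centred on probability 0.5, effectively flat over the plausible
range) and $\Sigma \sim$ inverse-Wishart$(P+2, I_P)$. The inverse-Wishart
was chosen over a separated scale/correlation prior because it is conjugate
given $\theta$, allowing exact Gibbs draws of $\mu$ and $\Sigma$; at the
cohort sizes this package targets (dozens to low hundreds of participants)
the data dominate the covariance posterior, and parameter recovery is the
test of whether the prior distorts anything.

Sampling is Metropolis-within-Gibbs. Each participant coordinate gets a
random-walk Metropolis update (vectorised over participants); proposal
scales adapt toward 44% acceptance in warm-up batches of 50 iterations and
are frozen afterwards, preserving detailed balance in the retained draws.
$\mu$ and $\Sigma$ are drawn exactly from their full conditionals. Chains
are initialised at jittered moment estimates (`mpt_moments()` of each
participant's observed proportions, clipped to $[0.05, 0.95]$ before the
probit) so the sampler starts in the right region. Runs are deterministic
given `seed`; convergence is monitored by split-chain R-hat (flagged above
1.05, with summaries still returned) and effective sample size, both via
`coda`. The default run length ("desk" profile, 4 chains × 5,000 retained
after 1,000 warm-up) is sized for interactive work and for the recovery
studies below; `mcmc_profile("paper")` provides the full published-scale
settings (4 × 100,000 with 22,000 discarded and thinning 5) for final
analyses.

Boundary data (participants with zero novel counts, or `p_fake < p_novel`)
need no special handling in the Bayesian fit: the hierarchical prior
regularises them. The closed-form `mpt_moments()` clips such estimates into
$[0,1]$ and flags them instead of failing.

## Posterior-predictive checks

T1 and T2 are conditioned on retained participant-level draws: for each
stored draw, a replicate data set is generated at the same participant
parameters and trial totals, and the squared deviation of (T1) the mean
category proportions and (T2) their between-participant covariance matrix
from their draw-conditional expectations is compared between observed and
replicate data. The reported p-values are the proportions of draws in which
the replicate discrepancy exceeds the observed one; values near 0 or 1
signal misfit of the means or the covariance structure respectively. T2's
expectation includes the multinomial sampling covariance at the observed
trial totals, not just the spread of expected proportions — without that
term T2 is extreme even for data generated from the model itself.

# Signal detection

Detection ("did this headline correct fake news?") and remembering (the
same question at test) are summarised by the equal-variance Gaussian model:
$d' = z(H) - z(F)$, $c = -(z(H)+z(F))/2$, computed per participant, with
"yes" responses in each correction condition as separate hit rates and the
affirmed-real condition as the shared false-alarm source. The generative
convention in the simulator is the exact inverse,
$H = \Phi(d'/2 - c)$, $F = \Phi(-d'/2 - c)$, so estimation on simulated
data is a closed-loop recovery test. With *unequal* sensitivities across
the two correction conditions sharing one noise pool, no single convention
can hold exactly for both; the simulator places the shared false-alarm rate
at $\Phi(-\bar d/2 - c)$ with $\bar d$ the mean of the two sensitivities,
which reduces to the exact inverse when they coincide (the setting used by
the recovery tests).

Extreme proportions are handled by the log-linear rule — add 0.5 to each
count and 1 to each trial total — applied to *every* cell, not only extreme
ones, to avoid a discontinuity between corrected and uncorrected cells. The
$1/(2N)$ replacement rule (touching only 0 and 1) and a strict no-correction
mode are selectable via `rule`; which rule the original analyses used is
not documented, so both are exposed and recorded in the output.

# The synthetic-data generator

`simulate_study()` generates a full two-group cohort. Design: topics rotate
through the three conditions across three formats (a Latin square, so each
topic serves in each condition exactly once across formats); Phase 1 Block A
interleaves the first two presentations of thrice-shown fake news with real
fillers in two full cycles; Block B carries everything shown once plus the
third fake presentation; presentation orders are drawn under the constraint
that at most three same-condition items run consecutively (rejection
sampling with a greedy fallback). The equating of average serial position
across conditions is *not* enforced — only the run cap — a deliberate
simplification of the scheduler.

Ordinal ratings (familiarity, accuracy, belief; all 1–6) come from a
cumulative-probit process: a latent standard normal around a structured
mean, cut at five thresholds (default $\pm 1.5, \pm 0.75, 0$, giving a
centred distribution over the six categories). Latent-mean shifts carry the
psychological structure:

* familiarity grows by `familiarity_shift_per_exposure` (default 0.15) per
  prior presentation;
* fake-news accuracy ratings grow by `illusory_truth_shift` (default 0.08)
  per prior exposure — the illusory truth effect — while real news sits
  above fake news at baseline;
* belief ratings at test gain `belief_base_real` (0.3) for real-news
  choices and `belief_shift_recollected` (0.8) when the choice was
  recollection-generated.

Magnitudes were chosen once to produce means in the realistic range of the
published rating tables (familiarity around 2.6–3.3, accuracy around
3.1–3.8) and clear qualitative directions; they are not calibrated to any
specific cell mean.

Test choices are drawn from the tree at the participant's
condition-specific $(P_r, P_f)$; group defaults follow the recognition
experiment's estimates (recollection near 0.47, familiarity near 0.70, with
a familiarity repetition benefit and slightly lower older-adult
familiarity after a single exposure). Participant heterogeneity defaults to
probit SD 0.4 with exchangeable correlation 0.3. This level matters:
recovery of the group means degrades as heterogeneity grows, because with
15 trials per condition the participant-level familiarity parameter is
weakly identified and the posterior increasingly shrinks condition
differences; at SD 0.4 the fit recovers group means and a 0.10 familiarity
repetition effect essentially without bias at 100 participants (the
acceptance suite averages recovery error over replicate cohorts to separate
bias from single-cohort binomial noise, which is itself ±0.05–0.08).

The gated question flow is reproduced exactly: the fake-identification
question is asked if and only if the remember question was answered "yes"
(`fake_retrieved = "NOT_ASKED"` otherwise), and a trial whose *choice* was
the fake detail cannot also identify that detail among the remaining
alternatives. Success on the fake-identification question depends on the
generating branch (0.9 recollection / 0.6 familiarity / 0.5 guessing),
which induces the paradigm's characteristic dependence between fake-news
retrieval and real-news accuracy.

One generative dependency deserves emphasis: on correction trials where the
fake detail was erroneously chosen, the remember-question evidence is
lowered by `remember_suppression_fake` (default 0.5 probit units) *per
prior fake exposure*. This encodes the dual-process account directly —
familiarity without recollection suppresses attribution of a correction —
and it is what concentrates fake-retrieval errors in the
correction-not-remembered stratum, increasingly so after repeated
exposure, while leaving the *marginal* category frequencies exactly at the
tree probabilities. Without such a mechanism, a familiarity difference of
$\Delta P_f$ moves the conditional error rate by only about $\Delta P_f/6$,
far below the binomial noise of a few-hundred-trial conditional cell; the
repetition effects estimated from the tree alone cannot reproduce the
conditional signature, which in real data reflects encoding dependencies
outside the tree.

What the generator does **not** emulate: serial-position equating, reaction
times, dropout and exclusions, free-text recall (cued-recall mode emits the
same three pre-scored categories, pooling other errors and omissions into
`NOVEL`), item-level difficulty variation, and any dependence of Phase-3
retrieval on Phase-2 detection (detection gates the *analysis*, not the
generative retrieval process). Passing recovery tests therefore shows the
estimators are correct for data satisfying the model's assumptions — not
that real data satisfy them.

# Conditional analyses

`conditionalize()` restricts correction trials to those whose correction
was detected in Phase 2 (the analysis gate, switchable), then computes a
target proportion within strata of another response: real-news retrieval by
fake-retrieval status, and fake-news errors by remembering status. Strata
partition the gated trials, each cell reporting its observation count and
weight, so the pooled proportions reconstruct the marginal exactly
(law of total probability) — an identity the test suite checks on
randomized tables. Because published figures can be read either as
participant means or pooled trials, both aggregations are always reported
(`prop` and `prop_pooled`); weights are defined from pooled counts, so
exact reconstruction holds for `prop_pooled`. Cells below `min_n = 5`
observations are flagged `sparse`, never silently dropped. Belief accuracy
is the difference in mean belief ratings between correctly retrieved real
news and erroneously retrieved fake news; within the fake-retrieved stratum
the erroneous-fake side is structurally empty (see above), so that cell is
`NA` with a warning rather than a number.

Uncertainty for descriptive quantities uses a percentile cluster bootstrap
over participants (default 2,000 resamples, seed-deterministic); degenerate
inputs yield zero-width intervals with a warning. Model-based inference
(mixed-effects modelling of these proportions) is deliberately out of
scope.

# Numerical choices and problem sizes

Exact identities are tested to 1e−12 (normalization) and 1e−9 (inversions);
stochastic checks state their Monte-Carlo tolerances explicitly. The test
suite and the acceptance script size their simulations for a single CPU:
recovery uses cohorts of 100 participants × 15 trials/condition with the
desk MCMC profile, averaged over replicate cohorts (five in the test suite,
three in the script); calibration of the credible flag uses 40-participant
cohorts with shortened chains, sized so that interval coverage — not
sampler throughput — is the binding factor. These sizes are the package's
own choices and can be scaled up freely.

# Known limitations

* The sampler is plain Metropolis-within-Gibbs; for very small cohorts with
  extreme counts, mixing on the familiarity dimension is the slowest part
  (watch its ESS). The "paper" profile exists for final runs.
* Group comparisons across fits (age effects) use pooled draws from two
  independent fits; that is valid for difference summaries but assumes both
  fits converged.
* The affirmed-real condition is simulated (as knowledge/guessing baselines)
  but never modelled by the MPT, mirroring the paradigm's analysis choices.
* With a single shared noise pool and unequal condition sensitivities, the
  SDT convention cannot be exactly self-inverse for both conditions at
  once; the discrepancy is second-order for nearby sensitivities.
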