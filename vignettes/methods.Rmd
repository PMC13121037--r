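---
title: "Modelling recency-weighted evidence integration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recency-weighted evidence integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaES)
```

## The scientific problem

In sequential information-gathering ("beads"-style) tasks, a participant
watches evidence accumulate draw by draw — each draw reveals one or more
instances of two stimulus types — and decides at each step whether to keep
sampling or to commit to a binary choice about which type is more abundant.
The number of draws taken before committing is a classic index of
indecisiveness, and excessive sampling has repeatedly been linked to
obsessive–compulsive (OC) symptoms. This package implements a pipeline for
asking a sharper question: not *how much* people sample, but *how they
weight* the evidence they see — in particular, whether the most recently
revealed information (the evidence-strength update) carries extra weight in
the decision to stop, and whether that recency weighting is attenuated in
people with high OC symptom scores, both behaviourally and in the strength
of the corresponding neural representation decoded from multichannel
(MEG-style) recordings.

## Evidence-strength quantities

For a game with per-draw counts of the two stimulus types, the cumulative
counts up to draw $d$ are $ES_{d,A}$ and $ES_{d,B}$. The total evidence
strength is defined relative to the *current majority*,
$$ES_{d,\mathrm{total}} = ES_{d,\mathrm{majority}} - ES_{d,\mathrm{minority}}
 = |ES_{d,A} - ES_{d,B}| \ge 0,$$
and the evidence-strength update is its signed change,
$$\Delta ES_d = ES_{d,\mathrm{total}} - ES_{d-1,\mathrm{total}}.$$
Each term carries its own draw's majority, so $\Delta ES$ stays signed
across majority flips. For lagged recency regressions the evidence is
instead signed with respect to the eventually chosen option,
$ES_{d,\mathrm{chosen}} - ES_{d,\mathrm{unchosen}}$.

Two conventions the definitions do not pin down, fixed here once:

* **Draw 1.** We set $ES_{0,\mathrm{total}} = 0$, so the first-draw update
  equals the first-draw evidence. Any other convention would leave
  $\Delta ES_1$ undefined and discard the most informative draw of short
  games.
* **Ties.** Equal cumulative counts give $ES_{d,\mathrm{total}} = 0$ and no
  majority; chosen-relative evidence remains well defined (it is zero).

Design tables contain one row per viewed draw *up to and including* the
decision draw. The horizon task keeps presenting draws after the response,
but the probability of deciding is undefined once a decision has been made,
so post-decision draws are excluded. Games where the horizon ran out
undeclared contribute all presented draws as `decide = 0` rows and are
flagged `non_decision`; whether such forced final draws belong in the fits
is not settled, so the flag lets the analyst drop them. Lags that would
index a draw before the first are emitted as missing — never zero-filled —
and the modelling layer drops incomplete rows.

## The stopping model and its fits

The per-draw probability of declaring is modelled with a logistic
regression,
$$p(\mathrm{decide}) \approx N_d + \Delta ES + ES_{d-1}\ (+\ \mathrm{horizon}),$$
where $N_d$ is the draw number (urgency), and the horizon condition is
coded $-0.5$ (short) / $+0.5$ (long). A separate recency formula regresses
deciding on chosen-relative evidence at lags 0–2; the **recency-bias
metric** is the difference between the lag-0 and lag-1 weights (a ratio
variant exists but is non-default, since a difference is what the group
results report and it is stable when the lag-1 weight is near zero).

Per-subject fits use maximum likelihood with a small ridge penalty
(`ridge_eps = 1e-4`) on the slopes. The penalty exists purely to keep
estimates finite under complete separation — short games with strong
evidence can make the decide indicator perfectly predictable — and is small
enough to leave well-identified fits unchanged to several decimals; Firth
correction would also work but adds nothing at these sample sizes.
Continuous regressors are z-scored within subject by default so betas are
comparable across subjects; a raw-scale option (`standardize = FALSE`) is
retained, and is what the parameter-recovery simulations use, since the
generator defines agents on the raw feature scale.

The group level is a **two-stage** estimator rather than a joint
random-slopes GLMM: stage 1 fits each subject, stage 2 combines the
per-subject coefficients in a random-effects meta-analysis
(DerSimonian–Laird, via `metafor`), with the OC score as a moderator for
the individual-difference interactions (e.g. $\Delta ES \times$ OC). The
two-stage route is consistent for the fixed effects, makes the
between-subject heterogeneity explicit ($\tau^2$), and keeps stage-2
standard errors calibrated — a plain precision-weighted mean would ignore
genuine between-subject spread and overstate null interactions. The cost
relative to a full GLMM is some efficiency at small per-subject trial
counts; at 160 games per subject the per-subject likelihoods are well
behaved and the approximation is benign. Absolute beta magnitudes depend on
predictor coding, which published group coefficients generally do not fully
specify, so the pipeline's group tests are directional and calibrated
rather than coefficient-matching.

Participant filters implement the published inclusion rules for a 15-game
session (mean draws in $[2, 23]$, accuracy strictly above 80%, at least 3
unique draw counts; separately, mean confidence in $[15, 98]$ with at least
3 unique values), and outlier exclusion removes subjects with any stopping
coefficient outside the closed Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},
Q_3 + 1.5\,\mathrm{IQR}]$ computed across subjects.

## Mediation

The mediation module tests whether the association between OC symptoms (X)
and mean confidence (Y) runs through the per-subject $\Delta ES$
sensitivity (M): `a` from $M \sim X$, `b` and the direct effect `c'` from
$Y \sim X + M$, the total effect `c` from $Y \sim X$, and the indirect
effect $ab$. With intercepts fitted throughout, $c = c' + ab$ holds to
machine precision on every dataset — the suite asserts it at $10^{-10}$.
Inference is by case-resampling bootstrap (default 10,000 resamples) with
percentile intervals; bias-corrected intervals are a reasonable
alternative, but the percentile flavour is the more conservative default
when the toolbox conventions differ across versions. One calibration fact
worth knowing when interpreting the suite: tests of a *product* of two
coefficients are conservative under the complete null (both paths zero),
where the rejection rate sits far below the nominal level; the test only
attains its nominal level at the composite-null boundary where one path is
nonzero. The calibration checks are therefore designed at that boundary
(e.g. $a \ne 0$, $b = 0$), with the complete null asserting only that the
test is not anticonservative. Variables are
standardized by default (flagged in the result) with a raw option, since
the published analysis does not state its scaling; the decomposition
identity is scale-invariant either way. Directionality is fixed as
OC → $\Delta ES$ weight → confidence on substantive grounds; the module
makes no causal-discovery claims.

## Synthetic data: what it emulates, and what it does not

The generator produces the two task variants under their stated conditions:
grid games of 25 single-stimulus draws, and horizon games of five-stimulus
draws with maxima uniform on 4–8 (short) or 10–14 (long), 80 games per
condition in a standard 160-game session. Each game's majority identity is
randomized; each revealed stimulus is the majority type with probability
`p_majority = 0.65` by default, which yields accuracy and draws-to-decision
in the range real participants produce. An optional rejection-sampling
decorrelation regenerates the sequence set until the pooled correlations
among $N_d$, $\Delta ES$, $ES_{d-1}$ fall below a bound, emulating
deliberately constructed low-collinearity sequences; with i.i.d. binomial
draws, bounds much below ~0.5 are structurally unreachable because
$ES_{d-1}$ accumulates with draw number — this is a known limitation of the
scheme, and the achieved maximum is reported when the bound is missed.

Stopping agents follow exactly the logistic model the fitting layer
estimates. Default agent parameters (`beta0 = -4`, `beta_nd = 0.15`,
`beta_des = 0.6`, `beta_esprev = 0.25`, `beta_hor = -0.8`) were chosen so
that simulated sessions land in a realistic regime — mean draws around 4 on
horizon games, non-decision rates in the 10–20% range, accuracy above 85% —
and are held fixed across all validation runs. Populations draw
$\mathrm{oc} \sim N(0,1)$ and tie the recency weight to it,
$\beta_{\Delta ES} = \mu + \mathrm{slope} \cdot \mathrm{oc} + \varepsilon$
(default slope $-0.3$), while confidence is generated from
$\beta_{\Delta ES}$ with an optional direct OC path (default 0), so the
mediation structure holds by construction and its recovery is a genuine
end-to-end test.

Synthetic epochs embed each decision variable as a rank-one spatiotemporal
pattern — a unit-norm spatial map over channels times a Gaussian temporal
kernel times the trial's z-scored value — in i.i.d. Gaussian sensor noise,
on a 135-sample, 100 Hz time axis from −100 to 1240 ms. Targets are
z-scored within subject before embedding so pattern amplitudes are
comparable across variables. The $\Delta ES$ amplitude declines linearly
with the subject's OC score (floored at zero), which is the ground truth
the decodability individual-difference analyses must recover. Trials are
partitioned into 4 contiguous blocks for the block/channel standardization.
Deliberately *not* modelled: 1/f and oscillatory background, artifacts,
forward-model field spread, channel covariance. Passing tests therefore
demonstrate the correctness and calibration of the analysis machinery on
data satisfying its assumptions — not robustness to physiological noise
structure.

Sensor layouts are sunflower-packed discs (default 273 usable channels,
matching a 275-channel system with two unusable sensors) with
direct-neighbor adjacency by distance threshold — symmetric by
construction, mean degree around 5–6, which is also how standard M/EEG
toolboxes define sensor neighbours by default.

## Decoding

Decoding follows the iterative random-subset approach: per timepoint, an
L1-penalized linear map from 50 random channels to the target is estimated
2,000 times (reference budget) under 5-fold cross-validation;
*decodability* is the correlation between pooled held-out predictions and
the true values, averaged over iterations. Choices the description leaves
open, fixed here: fold-wise predictions are concatenated before
correlating (rather than averaging fold-wise r's); iterations re-randomize
both the channel subset and the folds under one master seed; raw r values
are averaged without Fisher-z (a flagged alternative was considered and
left out of the default to keep the measure on the published scale); folds
stratify by game whenever game identities are available, so that all draws
of a game land in the same fold — within-game autocorrelation would
otherwise leak across folds and inflate decodability; a trial-level option
reproduces the literal per-trial scheme. Under the null, cross-validated
correlations are slightly *negative* in expectation (held-out predictions
lean on training-fold means); the test suite bands its null checks
accordingly rather than centering them at zero.

The penalty is tuned once on an *orthogonal* variable (one checked to be
essentially uncorrelated with all analysis targets), by maximizing its mean
cross-validated decodability over the grid with all channels in a single
iteration; exact ties break toward the stronger penalty, and the chosen
value is then frozen for every analysis target (reference values: 0.01 for
whole-array decoding, 0.001 for searchlights). The searchlight estimates
one decoder per sensor from that sensor plus its direct neighbours and maps
the mean decodability within a time window of interest. Peak latency is the
per-subject argmax of the decodability timecourse (first sample on tie
plateaus), compared between variables by paired t-tests with Cohen's d on
the differences.

The coordinate-descent lasso at the decoder's core is implemented in
compiled code with covariance (Gram) updates, tolerance $10^{-4}$ and an
iteration cap of $10^4$; the test suite cross-checks its solutions against
an independent solver (`glmnet`) to $10^{-4}$ on randomized problems.

## Group inference

Cluster-based permutation tests control family-wise error over timepoints:
per-timepoint one-sample t statistics (threshold 3.1), contiguous
suprathreshold runs scored by their mass (sum of t), a null of maximum
cluster mass per sign from 1,000 sign-flips of whole subject timecourses,
and p-values with the $+1$ correction, so they are never exactly zero.
Positive and negative clusters are tested separately; comparing each sign's
p to $\alpha/2$ gives two-sided control. For individual differences, the
decodability of each subject at each timepoint is regressed on the three
factor scores (OLS with intercept; threshold 2.1), and the permutation null
shuffles the factor-score *rows* jointly, preserving their
intercorrelations. Constant timepoints are skipped with a warning rather
than poisoning neighbouring clusters. Negative decodability values are
retained throughout — flooring them would bias the group statistics.
Display normalization (dividing a timecourse by its maximum) is exposed as
a separate function that no statistical routine calls.

## Validation scale and known limitations

The shipped test suite validates the pipeline end to end at sizes chosen to
make each check statistically meaningful while keeping a full run on one
CPU in the tens of minutes: parameter recovery over 200 subjects × 160
games; directional replication of the OC × $\Delta ES$ interaction over 20
effect and 20 null cohorts of 100 subjects; mediation calibration over 500
null replicates at 1,000 bootstrap resamples; cluster-test false-positive
calibration over 500 noise cohorts of 40 subjects × 135 timepoints at 500
permutations; and decoding validation with 200 × 50-channel iterations on a
273-channel array, plus 20 cohorts of 28 subjects at a reduced per-subject
iteration budget for the attenuation-transfer check. Reference-scale
decoding (2,000 iterations) is a parameter change, not a code path change.

Known limitations, beyond the noise-structure simplifications above: the
two-stage group model is not a joint GLMM and will be less efficient for
very short sessions; absolute group-level beta magnitudes are
coding-dependent and not comparable across studies without knowing the
standardization; the sequence decorrelation is rejection sampling rather
than constructive design; and no reaction-time, spatial-position, or
response-locked analyses are included.
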