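# deltaES

Analysis pipeline for **recency-weighted evidence integration in sequential
information gathering**, with end-to-end validation on synthetic task,
agent, and multichannel-epoch data.

## The problem and who this is for

In beads-style information-gathering tasks, participants watch evidence
accumulate draw by draw (counts of two stimulus types) and choose at every
step between sampling further and committing to a binary choice. The number
of draws before committing indexes indecisiveness, which is elevated across
the obsessive–compulsive (OC) spectrum. This package targets the sharper
mechanistic question: how is each new piece of evidence *weighted* in the
decision to stop — and is the weight on the most recent update attenuated
in people with high OC scores, behaviourally and in the strength of the
corresponding neural representation?

It is intended for computational-psychiatry and cognitive-neuroscience
researchers who want a tested, reproducible implementation of this analysis
stack: evidence features, stopping models, individual differences,
mediation, multivariate decoding, and cluster-based permutation inference —
plus a synthetic-data generator that makes every stage falsifiable against
ground truth.

## The model at the core

For cumulative counts $ES_{d,A}, ES_{d,B}$ up to draw $d$, total evidence
strength is defined relative to the current majority,

$$ES_{d,\mathrm{total}} = |ES_{d,A} - ES_{d,B}| \ge 0, \qquad
\Delta ES_d = ES_{d,\mathrm{total}} - ES_{d-1,\mathrm{total}},$$

with $ES_{0,\mathrm{total}} = 0$. The per-draw stopping decision follows a
logistic model,

$$p(\mathrm{decide}) \approx \beta_0 + \beta_{N} N_d +
\beta_{\Delta ES}\,\Delta ES_d + \beta_{ES}\, ES_{d-1,\mathrm{total}}
\;(+\; \beta_{H}\,\mathrm{horizon}),$$

fit per subject (ridge-stabilized ML) and aggregated in a two-stage
random-effects model with the OC score as moderator ($\Delta ES \times$ OC
interaction). A recency-bias metric contrasts chosen-relative evidence
weights at lag 0 vs lag 1. Downstream modules: bootstrap mediation
(OC → $\beta_{\Delta ES}$ → confidence), iterative random-subset lasso
decoding of decision variables from trial × channel × time epochs,
searchlight maps, peak latencies, and cluster-based permutation tests
(one-sample and individual-difference GLM variants).

## Worked example

```r
library(deltaES)

games <- generate_games("horizon", n_games = 160, seed = 42)  # 80 short + 80 long
agent <- simulate_agent(games, agent_params(beta_des = 0.6), seed = 43)
agent$summary
#  subject_id n_games n_decided mean_draws  accuracy mean_confidence
#          s1     160       141   4.333333 0.9503546        73.24262
#  n_unique_draws n_unique_confidence
#              13                  40

fit_subject_glm(agent$design, "main_horizon")
# <fit_result s1> formula=main_horizon n=719 converged=TRUE
#          term estimate    se  ci_lo  ci_hi      z        p
# 1 (Intercept)   -1.791 0.127 -2.039 -1.543 -14.15 1.82e-45
# 2         n_d    0.158 0.133 -0.103  0.418   1.19 2.35e-01
# 3    delta_es    1.085 0.125  0.839  1.331   8.66 4.75e-18
# 4     es_prev    0.699 0.127  0.450  0.948   5.50 3.71e-08
# 5     horizon   -0.597 0.227 -1.042 -0.152  -2.63 8.49e-03
```

The agent declared on 141 of 160 games after 4.3 draws on average (the
remaining 19 games hit their horizon undeclared), chose the true majority
95% of the time, and its refit stopping weights are on the standardized
scale: the evidence-strength update (`delta_es`, z = 8.7) and the
accumulated prior evidence (`es_prev`) both push toward declaring, and the
negative `horizon` coefficient means declaring is more likely under the
short-horizon condition (coded −0.5) than the long one (+0.5).

Group-level use follows the same grammar: `generate_population()` +
`simulate_cohort()` to build a cohort with an OC-linked recency weight,
`fit_two_stage(design, "main_horizon", oc = ...)` for fixed effects and
OC interactions, `mediation_bootstrap()` for the confidence mediation, and
`standardize_epochs()` → `iterative_subset_decode()` →
`cbpt_one_sample()` / `cbpt_glm()` for the decoding arm. The methods
vignette (`vignettes/methods.Rmd`) documents every modelling choice,
default, and limitation.

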