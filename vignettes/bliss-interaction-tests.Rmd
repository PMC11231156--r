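---
title: "Bliss-independence interaction tests for two-agent survival bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bliss-independence interaction tests for two-agent survival bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blisstox)
```

## The scientific problem

Pesticide mixtures can kill more (synergism) or fewer (antagonism)
organisms than their components' effects predict. The reference null for
"no interaction" used here is **Bliss independence**: if `s0` is control
survival and `s0·sA`, `s0·sB` are the single-agent survival rates — so
`sA` and `sB` are Abbott-corrected survivals, with natural mortality
divided out — then under independent action the combined-exposure survival
is the product `s0·sA·sB`. Observed combination survival below that
product indicates synergism; above it, antagonism.

Bliss independence needs two biological assumptions: the agents act by
independent mechanisms, *and* individual susceptibilities to the two
agents are uncorrelated. The second is easy to overlook: if the same frail
individuals are susceptible to both agents, those killed by agent A would
also have been killed by agent B, the observed combined survival stays
near `s0·sA < s0·sA·sB`, and an analysis will read this as *antagonism*
even with fully independent chemistry. The package does not try to
estimate such correlation from a single 2×2 design — it is not
identifiable there — but the data generator exposes a frailty knob
(below) so users can see the artefact for themselves.

## The test

Survivorship over a scope (the whole assay, or one developmental stage) is
modelled per subject as Bernoulli with a **log-linear** survival
probability:

$$\log p_{\text{surv}} = \beta_0 + \beta_A x_A + \beta_B x_B +
  \beta_{AB} x_A x_B + \gamma_{t},$$

with 0/1 exposure indicators and reference-coded trial effects
$\gamma_t$ ($\gamma_1 = 0$). On this scale the Bliss product is additivity,
so independence is exactly $\beta_{AB} = 0$ and the natural test is the
likelihood ratio between the full model and the model without the
interaction, referred to $\chi^2_1$. The sign of $\hat\beta_{AB}$ gives
the direction: negative = synergism, positive = antagonism. Each test uses
only its four exposure cells (control, A, B, A+B at one dosage); dosages
are tested separately because mixture interactions are dose-dependent.

The acetone solvent control is the reference cell, since every treatment
contains the solvent; the solvent-free negative control is excluded from
model fits by default. Within the reduced model the fitted probabilities
satisfy the Bliss identity exactly — predicted combination survival equals
predicted control survival times both corrected single-agent survivals —
which is the property that makes the GLM formulation equivalent to the
classical arithmetic.

## Constrained estimation under the log link

A log link on a probability requires every fitted linear predictor to be
≤ 0. Standard IRLS ignores the constraint and fails whenever the optimum
sits near the boundary, so the package fits the model as a **linearly
constrained concave program**: the Bernoulli log-likelihood, aggregated
over distinct covariate patterns, is maximized subject to
$\eta_j \le 0$ for every pattern $j$. The solver is deterministic:

* start at the least-squares projection of the shrunken empirical
  log-survivals $\log\{(k_j + 0.5)/(n_j + 1)\}$, shifted to be strictly
  feasible;
* minimize the negative log-likelihood plus a log-barrier
  $-\mu \sum_j \log(-\eta_j)$ with BFGS and analytic gradients, for a
  fixed ladder of barrier weights $\mu = 10^{-2}, \dots, 10^{-9}$;
* finish with damped Newton steps on the unpenalized likelihood while the
  iterate stays strictly interior, which removes the residual barrier bias
  (interior optima are recovered to near machine precision — on a
  saturated design the fitted probabilities equal the observed proportions).

A solution with some $\eta_j$ within `1e-6` of 0 is flagged `boundary`;
the LR statistic is still reported but the $\chi^2$ reference is then
approximate, and downstream results carry the flag. A covariate pattern
with *zero survivors* has no finite log-link MLE (its coefficient diverges
to $-\infty$); the fit aborts with a named degenerate-group error rather
than applying a silent continuity correction, and the simulation harness
counts such replicates separately. Convergence uses relative
log-likelihood change below `1e-10` with at most 500 inner iterations per
barrier stage. Tiny negative LR values (numerical noise when the null is
exact) are clamped to zero with a warning. The logit link is also exposed
for comparison; it is an ordinary unconstrained fit delegated to
`stats::glm.fit`.

## Stage-resolved risk sets

Stage-partitioned testing conditions on stage entry: the risk set of a
stage contains the subjects alive when it starts, with outcome 0 only for
deaths *in* that stage. Stage membership of a death prefers an explicitly
recorded `fate_stage`; the day-range attribution (larva days 1–6, prepupa
7–9, pupa 10–14, observation through day 22) is the fallback, with deaths
after day 14 assigned to the pupa stage, the last pre-emergence stage.
Subjects removed from the assay (e.g. contaminated wells) are treated as
uninformatively censored: they contribute only to stages fully completed
before removal, are excluded from the overall risk set, and their count is
reported on every risk table. The per-stage mortality summaries are
therefore conditional on stage entry, not fractions of the initial cohort;
both readings are obtainable from the risk tables.

## Multiple testing

The default battery is 3 dosages × (overall + 3 stages) = 12 tests. Holm's
step-down is applied within two declared families: the nine stage-specific
tests, and the three overall tests. The split reflects that the stage
battery answers one question (where in development does the interaction
act?) while the overall tests answer another; with nine stage tests, a raw
p of 0.004858 (LR = 7.932 on 1 df) adjusts to 9 × 0.004858 ≈ 0.044, the
worked anchor reproduced by `scripts/acceptance.R`. Family membership is a
user-facing choice (`family = "split"`, `"joint"`, or `"per_scope"`), and
direction calls always report the sign of $\hat\beta_{AB}$ even when
non-significant. Reported p-values keep full precision in the tibble;
human-readable writers round to 3 significant figures (adjusted values to
3 decimals).

## What the generator emulates

`simulate_assay()` draws, for every subject, independent per-stage
Bernoulli survivals with probability `exp(linear predictor)`, assigns a
death day uniformly within the fatal stage's day range (the models use the
day only for stage attribution, so any within-stage distribution is
admissible and uniform is the least informative), and marks survivors of
all stages as emerged. A single integer seed drives everything, with
per-trial substreams derived deterministically, so identical configs give
byte-identical CSVs.

`default_paper_design()` mirrors the motivating 11-group, 3-trial larval
assay: two controls (n = 235, 236), captan at 100/500/2000 ng/ml
(n = 92/96/96), thiamethoxam at 10/70/1440 ng/ml (n = 94/95/94), and
captan-2000 crossed with each thiamethoxam dose (n = 109/109/103) — 1,359
subjects in all, split as evenly as possible across trials (remainders to
the earliest trials, since the published per-trial splits are not in the
main text). Default coefficients are chosen once from the published
summary statistics: control overall survival 0.74 spread evenly over the
three stages on the log scale; single-agent effects matched to the
reported mortality increases over the solvent control (captan roughly
+85% at all doses — realized as 1.80/1.85/1.90 multipliers so the dose
series is realistic but nearly flat, as reported; thiamethoxam
+90/120/150%); interaction coefficients zero in every stage (the Bliss
null *is* the default condition); trial effects 0, −0.08, +0.04 nats.
Dose potency differences enter as per-group log-survival offsets, with the
combination groups sharing the matching insecticide dose's offset, so the
Bliss null remains exactly representable in every test's four cells.
`inject_interaction()` perturbs one stage (or spreads an effect over all
stages) for power and recovery studies.

What the generator does **not** emulate: correlated susceptibilities
(unless the gamma frailty below is switched on), overdispersion between
wells or plates beyond the trial effect, dose–response curvature within an
agent beyond the fixed per-dose offsets, chronic-exposure kinetics, and
non-uniform death timing within a stage. Passing simulation suites
therefore demonstrates that the *test works when its assumptions hold* and
that its operating characteristics are nominal under the design's group
sizes — not that real larval data satisfy those assumptions.

The frailty option multiplies every stage's log-survival by a per-subject
gamma(k, k) draw (mean 1; smaller `k` = stronger heterogeneity). This is
the standard frailty form on the log-survival scale and keeps each
probability in (0, 1] automatically; it induces exactly the correlated
susceptibilities whose artefactual "antagonism" the Bliss framework warns
about, and is off by default.

## Operating characteristics and problem sizes

The simulation harness reports rejection rates with Monte-Carlo standard
errors $\sqrt{r(1-r)/\text{reps}}$, and the mean and RMSE of
$\hat\beta_{AB}$. Degenerate replicates are excluded from rate
denominators and counted; full determinism given (config, reps, alpha,
seed) is part of the contract. The shipped studies use: 1,000 replicates
for single-test type-I error under the standard design; 300 replicates for
the family-wise error of the Holm-corrected 12-test battery (each
replicate fits 24 constrained models); 500 replicates per effect size for
recovery at roughly 1,000 subjects per group; and 40–200 replicate smoke
profiles in the unit tests. These sizes put Monte-Carlo uncertainty well
inside the assertion bands while keeping the default suite fast enough to
run routinely.

Observed behaviour worth knowing: at the published design's group sizes
(roughly 100 per treatment group), the stage-specific LR test runs
slightly hot (empirical type-I error around 0.06 at nominal 0.05) — a
small-sample property of the $\chi^2$ approximation, not of the
implementation, which matches brute-force optimizers to better than
$10^{-6}$ in log-likelihood on every oracle case. The same inflation
propagates to the Holm-corrected battery: Holm controls the family-wise
error at the *actual* size of its member tests, so the observed
family-wise rate sits mildly above 0.05 as well (within Monte-Carlo
uncertainty of the per-test inflation).

## Known limitations

* Boundary MLEs get an approximate $\chi^2$ reference; a proper mixture
  reference (or bootstrap) is not implemented.
* No overdispersion or random-effect machinery: trials are fixed effects,
  as in the displayed model.
* The correlated-susceptibility caveat is demonstrable with the generator
  but not estimable from a single 2×2 design; nothing in the test
  distinguishes genuine antagonism from frailty-induced apparent
  antagonism.
* Stage-conditional risk sets assume removals are uninformative; if
  contamination correlates with treatment, stage-specific estimates can be
  biased.
```{r family-demo}
assay <- read_assay_csv(system.file("extdata", "example_assay_synthetic.csv",
                                    package = "blisstox"))
run_interaction_family(
  assay,
  dosages = tibble::tibble(dosage = "high", control = "control_pos",
                           group_A = "captan_high", group_B = "thiam_high",
                           group_AB = "combo_high"))
```
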