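# blisstox

Tests for **synergism and antagonism between two toxicants** in binary
survival bioassays, using **Bliss independence** as the null model and a
**log-binomial GLM** as the inference engine. The motivating application is
honey bee (*Apis mellifera*) larval toxicity testing of a fungicide
(captan) crossed with a neonicotinoid insecticide (thiamethoxam) in an
in vitro rearing design (OECD 239-style: two controls, three doses of each
agent, and the high fungicide dose crossed with every insecticide dose,
replicated across trials), but the machinery applies to any two-agent
assay with per-subject binary survival, optionally partitioned by
developmental stage (larva, prepupa, pupa).

## The model

Let `s0` be control survival and `s0·sA`, `s0·sB` the survival rates under
each single agent, so that `sA`, `sB` are Abbott-corrected survival rates.
Under Bliss independence — independent biological action and uncorrelated
individual susceptibilities — combined-exposure survival is `s0·sA·sB`.
Survivorship is fitted with a binomial GLM with a **log link**,

```
log(p_surv) = β0 + βA·xA + βB·xB + βAB·xA·xB + (trial effects)
```

where `xA`, `xB` are 0/1 exposure indicators. Coefficients are log
survival ratios, so Bliss independence is exactly `βAB = 0`, tested with a
likelihood-ratio statistic against `χ²₁`. A significant `βAB < 0` means
synergism (lower-than-expected combined survival), `βAB > 0` antagonism.
Trial-to-trial variation in natural mortality enters as reference-coded
fixed effects. Because the log link requires every fitted survival
probability to stay at or below 1, the fit is a **linearly constrained
maximum-likelihood problem**; `blisstox` solves it with a deterministic
log-barrier method plus Newton polish, and flags boundary solutions where
the `χ²` reference is approximate. Batteries of tests across dosages and
developmental stages are corrected with the **Holm step-down**.

## Worked example

```r
library(blisstox)

path <- system.file("extdata", "example_assay_synthetic.csv", package = "blisstox")
assay <- read_assay_csv(path)          # validated per-subject records
summarize_groups(build_risk_table(assay, "overall"))
#> # A tibble: 4 × 4
#>   group_label n_at_risk n_survived proportion
#> 1 captan_high        50         22       0.44
#> 2 combo_high         50         12       0.24
#> 3 control_pos        50         28       0.56
#> 4 thiam_high         50         15       0.3

bliss_lr_test(assay, "control_pos", "captan_high", "thiam_high", "combo_high")
#> <bliss_test> scope = overall
#>   beta_AB = -0.00119, LR = 0.0000 (df = 1), p_raw = 0.9976
```

Here observed combination survival (0.24) is essentially the Bliss
expectation `0.56 × (0.44/0.56) × (0.30/0.56) ≈ 0.236`, so the interaction
coefficient is near zero and the data are not distinguishable from
independent action. `run_interaction_family()` runs the full
dosage-by-stage battery and applies Holm within each family;
`simulate_assay(default_paper_design())` generates the full 11-group,
3-trial design; `type1_error_study()`, `power_study()` and
`recovery_study()` quantify the test's operating characteristics. A thin
command-line wrapper lives at `inst/cli/blisstox`
(`simulate` / `family` / `simstudy` subcommands).

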