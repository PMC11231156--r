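#' Configuration for the synthetic assay generator
#'
#' Describes a stage-partitioned two-agent bioassay as the survival models
#' assume it: each subject survives each developmental stage independently
#' with probability `exp(b0_s + bA_s * x_A + bB_s * x_B + bAB_s * x_A * x_B +
#' gamma_t)` — log-linear exposure main effects, an interaction term, and
#' additive trial effects, all on the log-survival (nats) scale.
#'
#' @param groups Tibble with columns `group_label`, `dose_A_ng_ml`,
#'   `dose_B_ng_ml`, `n` (total subjects, split as evenly as possible across
#'   trials, remainders to the earliest trials), and optionally
#'   `stage_offset` — a per-group additive log-survival offset applied to
#'   every stage (nats, default 0), used to give different doses of the same
#'   agent different potencies while the model's single (`x_A`, `x_B`)
#'   effects describe the doses entering the interaction tests.
#' @param n_trials Number of trials (>= 1).
#' @param stage_coefs Tibble with columns `stage`, `b0`, `bA`, `bB`, `bAB`,
#'   one row per stage of `schedule`, coefficients in nats.
#' @param trial_effects Numeric vector of length `n_trials`; the first entry
#'   must be 0 (reference trial).
#' @param schedule A [stage_schedule()].
#' @param seed Integer seed; per-trial substreams are derived from it
#'   deterministically.
#' @param frailty_shape Optional gamma shape `k`: a per-subject mean-1
#'   gamma(k, k) frailty multiplies the log-survival of every stage, inducing
#'   the correlated susceptibilities that violate Bliss independence. `NULL`
#'   (default) draws stages independently.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(groups, n_trials, stage_coefs, trial_effects,
                             schedule = default_stage_schedule(), seed = 1L,
                             frailty_shape = NULL) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("group_label", "dose_A_ng_ml", "dose_B_ng_ml", "n") %in%
                  names(groups)),
            all(groups$n >= 1), n_trials >= 1,
            length(trial_effects) == n_trials,
            all(c("stage", "b0", "bA", "bB", "bAB") %in% names(stage_coefs)),
            setequal(stage_coefs$stage, schedule$stages))
  if (trial_effects[1] != 0)
    stop("the first trial is the reference: trial_effects[1] must be 0",
         call. = FALSE)
  if (!"stage_offset" %in% names(groups)) groups$stage_offset <- 0
  cfg <- structure(
    list(groups = groups, n_trials = as.integer(n_trials),
         stage_coefs = tibble::as_tibble(stage_coefs),
         trial_effects = trial_effects, schedule = schedule,
         seed = as.integer(seed), frailty_shape = frailty_shape),
    class = "generator_config"
  )
  bad <- config_infeasible(cfg)
  if (nrow(bad) > 0)
    stop("infeasible config (linear predictor > 0, survival probability > 1) ",
         "for stage/trial/group: ",
         paste(sprintf("%s/%d/%s", bad$stage, bad$trial, bad$group_label),
               collapse = "; "), call. = FALSE)
  cfg
}

# linear predictor per group x stage x trial; rows where eta > 0
config_infeasible <- function(cfg) {
  g <- cfg$groups
  xA <- as.integer(g$dose_A_ng_ml > 0)
  xB <- as.integer(g$dose_B_ng_ml > 0)
  out <- tidyr::expand_grid(gi = seq_len(nrow(g)),
                            si = seq_len(nrow(cfg$stage_coefs)),
                            trial = seq_len(cfg$n_trials))
  sc <- cfg$stage_coefs
  out$eta <- sc$b0[out$si] + sc$bA[out$si] * xA[out$gi] +
    sc$bB[out$si] * xB[out$gi] + sc$bAB[out$si] * xA[out$gi] * xB[out$gi] +
    g$stage_offset[out$gi] + cfg$trial_effects[out$trial]
  out$group_label <- g$group_label[out$gi]
  out$stage <- sc$stage[out$si]
  out[out$eta > 1e-12, c("stage", "trial", "group_label", "eta")]
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d groups x %d trials, %d subjects, seed %d\n",
              nrow(x$groups), x$n_trials, sum(x$groups$n), x$seed))
  if (!is.null(x$frailty_shape))
    cat(sprintf("  shared gamma frailty, shape %.3g\n", x$frailty_shape))
  invisible(x)
}

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1013904223 + 1664525 * stream) %% 2147483629 + 1)
}

split_n <- function(n, n_trials) {
  base <- n %/% n_trials
  extra <- n %% n_trials
  base + as.integer(seq_len(n_trials) <= extra)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' Simulate a per-subject assay dataset
#'
#' Draws independent per-stage Bernoulli survival for every subject under the
#' config's log-linear model. A death in stage `s` receives a `fate_day`
#' uniform over `s`'s day range; subjects surviving all stages are marked
#' with the terminal event. Identical config (including seed) yields an
#' identical dataset; each trial uses its own deterministic substream.
#'
#' @param config A [generator_config()].
#' @return A validated assay tibble.
#' @examples
#' cfg <- four_group_config(n_per_group_per_trial = 20, seed = 42)
#' sim <- simulate_assay(cfg)
#' dplyr::count(sim, group_label, fate)
#' @export
simulate_assay <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sch <- config$schedule
  sc <- config$stage_coefs[match(sch$stages, config$stage_coefs$stage), ]
  g <- config$groups
  xA <- as.integer(g$dose_A_ng_ml > 0)
  xB <- as.integer(g$dose_B_ng_ml > 0)
  n_split <- lapply(g$n, split_n, n_trials = config$n_trials)

  trials <- vector("list", config$n_trials)
  with_preserved_rng({
    for (t in seq_len(config$n_trials)) {
      set.seed(derive_seed(config$seed, t))
      per_group <- vector("list", nrow(g))
      for (i in seq_len(nrow(g))) {
        n <- n_split[[i]][t]
        if (n == 0) next
        log_p <- sc$b0 + sc$bA * xA[i] + sc$bB * xB[i] +
          sc$bAB * xA[i] * xB[i] + g$stage_offset[i] +
          config$trial_effects[t]
        frail <- if (is.null(config$frailty_shape)) rep(1, n)
                 else stats::rgamma(n, shape = config$frailty_shape,
                                    rate = config$frailty_shape)
        alive <- rep(TRUE, n)
        death_stage <- rep(NA_integer_, n)
        for (s in seq_along(sch$stages)) {
          p <- exp(pmin(log_p[s] * frail, 0))
          surv <- stats::runif(n) < p
          died_now <- alive & !surv
          death_stage[died_now] <- s
          alive <- alive & surv
        }
        fate_day <- rep(NA_integer_, n)
        for (s in seq_along(sch$stages)) {
          r <- sch$day_ranges[[s]]
          ds <- which(death_stage == s)
          if (length(ds) > 0)
            fate_day[ds] <- as.integer(
              r[1] + floor(stats::runif(length(ds)) * (r[2] - r[1] + 1)))
        }
        per_group[[i]] <- tibble::tibble(
          subject_id = sprintf("%s_t%d_%04d", g$group_label[i], t, seq_len(n)),
          trial_id = sprintf("trial%d", t),
          group_label = g$group_label[i],
          x_A = xA[i], x_B = xB[i],
          dose_A_ng_ml = g$dose_A_ng_ml[i], dose_B_ng_ml = g$dose_B_ng_ml[i],
          fate = ifelse(alive, sch$terminal, "died"),
          fate_day = fate_day,
          fate_stage = ifelse(alive, NA_character_,
                              sch$stages[death_stage])
        )
      }
      trials[[t]] <- dplyr::bind_rows(per_group)
    }
  })
  out <- dplyr::bind_rows(trials)
  validate_assay(out, sch)
}

# per-stage log-survival from an overall survival rate, split evenly
stage_log_survival <- function(overall, n_stages = 3) log(overall) / n_stages

#' Generator preset mirroring the 11-group, 3-trial larval co-exposure design
#'
#' Two controls (solvent-free negative, acetone-treated positive), captan at
#' 100/500/2000 ng/ml, thiamethoxam at 10/70/1440 ng/ml, and captan-2000
#' crossed with each thiamethoxam dose; published group sizes (total 1359)
#' split across 3 trials. Default coefficients put control overall survival
#' at 0.74, scale single-agent survival to the reported mortality increases
#' relative to the acetone control (captan roughly +85% mortality at every
#' dose; thiamethoxam +90/120/150%), set every stage's interaction
#' coefficient to zero (the Bliss null), and add small trial effects
#' (0, -0.08, +0.04 nats).
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
default_paper_design <- function(seed = 1L) {
  s0 <- 0.74
  mort_mult <- function(m) 1 - pmin(0.26 * m, 0.99)   # survival after m-fold mortality
  sA <- mort_mult(c(1.80, 1.85, 1.90))   # captan low/med/high
  sB <- mort_mult(c(1.90, 2.20, 2.50))   # thiamethoxam low/med/high
  # dose potency as per-group offsets relative to the model's single (x_A,
  # x_B) effects, which carry the high doses; lower doses survive better.
  # Combo offsets match the matching thiamethoxam dose so the Bliss null is
  # exactly representable within every interaction-test cell set.
  off_A <- stage_log_survival(sA / sA[3])
  off_B <- stage_log_survival(sB / sB[3])
  groups <- tibble::tibble(
    group_label = c("control_neg", "control_pos",
                    "captan_low", "captan_med", "captan_high",
                    "thiam_low", "thiam_med", "thiam_high",
                    "combo_low", "combo_med", "combo_high"),
    dose_A_ng_ml = c(0, 0, 100, 500, 2000, 0, 0, 0, 2000, 2000, 2000),
    dose_B_ng_ml = c(0, 0, 0, 0, 0, 10, 70, 1440, 10, 70, 1440),
    n = c(235L, 236L, 92L, 96L, 96L, 94L, 95L, 94L, 109L, 109L, 103L),
    stage_offset = c(0, 0, off_A[1], off_A[2], 0,
                     off_B[1], off_B[2], 0, off_B[1], off_B[2], 0)
  )
  stage_coefs <- tibble::tibble(
    stage = c("larva", "prepupa", "pupa"),
    b0 = stage_log_survival(s0),
    bA = stage_log_survival(sA[3] / s0),
    bB = stage_log_survival(sB[3] / s0),
    bAB = 0
  )
  generator_config(groups, n_trials = 3, stage_coefs = stage_coefs,
                   trial_effects = c(0, -0.08, 0.04),
                   schedule = default_stage_schedule(), seed = seed)
}

#' Four-cell config for simulation studies
#'
#' The minimal design an interaction test consumes: acetone control, captan
#' high, thiamethoxam high, and their combination, with the same default
#' coefficients as [default_paper_design()].
#'
#' @param n_per_group_per_trial Subjects per group per trial.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param trial_effects Trial effects (nats), first must be 0.
#' @return A [generator_config()].
#' @export
four_group_config <- function(n_per_group_per_trial = 200, n_trials = 3,
                              seed = 1L,
                              trial_effects = c(0, -0.08, 0.04)[seq_len(n_trials)]) {
  s0 <- 0.74
  sA <- 1 - 0.26 * 1.90
  sB <- 1 - 0.26 * 2.50
  groups <- tibble::tibble(
    group_label = c("control_pos", "captan_high", "thiam_high", "combo_high"),
    dose_A_ng_ml = c(0, 2000, 0, 2000),
    dose_B_ng_ml = c(0, 0, 1440, 1440),
    n = as.integer(n_per_group_per_trial) * n_trials
  )
  stage_coefs <- tibble::tibble(
    stage = c("larva", "prepupa", "pupa"),
    b0 = stage_log_survival(s0),
    bA = stage_log_survival(sA / s0),
    bB = stage_log_survival(sB / s0),
    bAB = 0
  )
  generator_config(groups, n_trials = n_trials, stage_coefs = stage_coefs,
                   trial_effects = trial_effects, seed = seed)
}

#' Inject an interaction effect into a generator config
#'
#' Returns a copy of the config with the interaction coefficient of one stage
#' (or every stage) set to `beta_AB`; all else unchanged. Negative values are
#' always feasible under the log model; positive values are checked against
#' the probability constraint.
#'
#' @param config A [generator_config()].
#' @param stage A stage name, or `"all"` to spread `beta_AB` evenly across
#'   stages (each stage receives `beta_AB / n_stages` so the overall
#'   interaction equals `beta_AB`).
#' @param beta_AB Interaction coefficient (nats, log survival-ratio).
#' @return A modified [generator_config()].
#' @export
inject_interaction <- function(config, stage, beta_AB) {
  stopifnot(inherits(config, "generator_config"))
  sc <- config$stage_coefs
  if (identical(stage, "all")) {
    sc$bAB <- beta_AB / nrow(sc)
  } else {
    i <- match(stage, sc$stage)
    if (is.na(i)) stop("unknown stage: ", stage, call. = FALSE)
    sc$bAB[i] <- beta_AB
  }
  out <- config
  out$stage_coefs <- sc
  bad <- config_infeasible(out)
  if (nrow(bad) > 0)
    stop("injected interaction makes some survival probability exceed 1",
         call. = FALSE)
  out
}

#' Serialize a generator config to a flat key-value file
#'
#' @param config A [generator_config()].
#' @param path Output path (YAML-like flat key-value text).
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("n_trials: %d", config$n_trials),
    sprintf("trial_effects: %s", paste(config$trial_effects, collapse = ",")),
    sprintf("frailty_shape: %s",
            if (is.null(config$frailty_shape)) "none" else config$frailty_shape),
    sprintf("stage %s: b0=%.10g bA=%.10g bB=%.10g bAB=%.10g",
            config$stage_coefs$stage, config$stage_coefs$b0,
            config$stage_coefs$bA, config$stage_coefs$bB,
            config$stage_coefs$bAB),
    sprintf("group %s: dose_A=%.10g dose_B=%.10g n=%d offset=%.10g",
            config$groups$group_label, config$groups$dose_A_ng_ml,
            config$groups$dose_B_ng_ml, config$groups$n,
            config$groups$stage_offset)
  )
  writeLines(lines, path)
  invisible(path)
}
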