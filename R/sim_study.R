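default_test_groups <- function() {
  list(control = "control_pos", group_A = "captan_high",
       group_B = "thiam_high", group_AB = "combo_high")
}

run_replicates <- function(config, reps, seed, scope, test_groups, alpha) {
  beta <- p <- rep(NA_real_, reps)
  boundary <- rep(FALSE, reps)
  n_degenerate <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    sim <- simulate_assay(cfg)
    res <- tryCatch(
      bliss_lr_test(sim, test_groups$control, test_groups$group_A,
                    test_groups$group_B, test_groups$group_AB, scope = scope),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_degenerate <- n_degenerate + 1L
    } else {
      beta[r] <- res$beta_AB
      p[r] <- res$p_raw
      boundary[r] <- res$boundary
    }
  }
  ok <- !is.na(p)
  rate <- mean(p[ok] < alpha)
  list(beta = beta[ok], p = p[ok], rate = rate,
       mc_se = sqrt(rate * (1 - rate) / sum(ok)),
       n_degenerate = n_degenerate, n_boundary = sum(boundary[ok]))
}

study_result <- function(scenario, beta_true, config, reps, alpha, seed, rr) {
  tibble::tibble(
    scenario = scenario, beta_AB_true = beta_true,
    replicates = as.integer(reps), n_used = length(rr$p),
    n_per_group = sum(config$groups$n) %/% nrow(config$groups),
    rejection_rate = rr$rate, mc_se = rr$mc_se,
    mean_beta_AB = mean(rr$beta), rmse_beta_AB =
      sqrt(mean((rr$beta - beta_true)^2)),
    n_degenerate = rr$n_degenerate, n_boundary = rr$n_boundary,
    alpha = alpha, seed = as.integer(seed)
  )
}

#' Monte-Carlo type-I error of the interaction test
#'
#' Simulates replicate assays under the Bliss null (every stage's interaction
#' coefficient zero), runs the likelihood-ratio interaction test on one
#' declared dosage/scope cell per replicate, and reports the rejection rate
#' at `alpha` with its Monte-Carlo standard error. Replicates where the test
#' is undefined (a zero-survivor group under the log link) are excluded from
#' the rate and counted.
#'
#' @param config A [generator_config()] with `bAB = 0` in all stages.
#' @param reps Number of replicates.
#' @param alpha Significance level.
#' @param seed Integer seed; replicate substreams derive from it.
#' @param scope Scope of the tested cell (default `"larva"`).
#' @param test_groups Named list with `control`, `group_A`, `group_B`,
#'   `group_AB` labels.
#' @return A one-row study tibble (rates, MC SE, estimator summaries,
#'   degenerate/boundary counts).
#' @export
type1_error_study <- function(config, reps = 1000, alpha = 0.05, seed = 1L,
                              scope = "larva",
                              test_groups = default_test_groups()) {
  if (any(config$stage_coefs$bAB != 0))
    stop("type-I error study requires bAB = 0 in every stage", call. = FALSE)
  rr <- run_replicates(config, reps, seed, scope, test_groups, alpha)
  study_result("type1_error", 0, config, reps, alpha, seed, rr)
}

#' Monte-Carlo power curve of the interaction test
#'
#' One [type1_error_study()]-style run per value of the interaction
#' coefficient, injected into `stage` and tested on the same scope.
#'
#' @inheritParams type1_error_study
#' @param beta_AB_grid Interaction coefficients to inject (nats).
#' @param stage Stage receiving the injected effect and tested.
#' @return A study tibble with one row per grid value.
#' @export
power_study <- function(config, beta_AB_grid, reps = 1000, alpha = 0.05,
                        seed = 1L, stage = "larva",
                        test_groups = default_test_groups()) {
  rows <- lapply(beta_AB_grid, function(b) {
    cfg <- inject_interaction(config, stage, b)
    rr <- run_replicates(cfg, reps, seed, stage, test_groups, alpha)
    study_result("power", b, cfg, reps, alpha, seed, rr)
  })
  dplyr::bind_rows(rows)
}

#' Monte-Carlo recovery of the interaction coefficient
#'
#' Reports the mean and RMSE of the estimated interaction coefficient across
#' replicates with a known injected value.
#'
#' @inheritParams power_study
#' @param beta_AB_true Injected interaction coefficient (nats).
#' @return A one-row study tibble.
#' @export
recovery_study <- function(config, beta_AB_true, reps = 500, seed = 1L,
                           stage = "larva",
                           test_groups = default_test_groups()) {
  cfg <- inject_interaction(config, stage, beta_AB_true)
  rr <- run_replicates(cfg, reps, seed, stage, test_groups, alpha = 0.05)
  study_result("recovery", beta_AB_true, cfg, reps, 0.05, seed, rr)
}

#' Monte-Carlo family-wise error of the Holm-corrected battery
#'
#' Simulates replicate assays under the global Bliss null, runs the full
#' dosage-by-scope battery with Holm correction, and reports the proportion
#' of replicates with at least one synergism or antagonism call.
#'
#' @inheritParams type1_error_study
#' @param dosages Dosage table (see [default_dosage_table()]).
#' @param scopes Scopes tested (default overall plus all stages).
#' @param family Family definition passed to [run_interaction_family()].
#' @return A one-row tibble with the family-wise error rate and MC SE.
#' @export
familywise_error_study <- function(config, reps = 300, alpha = 0.05,
                                   seed = 1L,
                                   dosages = default_dosage_table(),
                                   scopes = NULL, family = "split") {
  if (any(config$stage_coefs$bAB != 0))
    stop("family-wise error study requires bAB = 0 in every stage",
         call. = FALSE)
  any_call <- rep(NA, reps)
  n_failed_tests <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    sim <- simulate_assay(cfg)
    fam <- run_interaction_family(sim, dosages = dosages, scopes = scopes,
                                  alpha = alpha, family = family)
    n_failed_tests <- n_failed_tests + sum(!is.na(fam$error))
    any_call[r] <- any(fam$call %in% c("synergism", "antagonism"))
  }
  rate <- mean(any_call)
  tibble::tibble(
    scenario = "familywise_error", replicates = as.integer(reps),
    rejection_rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
    n_failed_tests = n_failed_tests, alpha = alpha, seed = as.integer(seed)
  )
}

#' Plot a power curve
#'
#' @param results A study tibble from [power_study()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(.data$beta_AB_true, .data$rejection_rate)) +
    ggplot2::geom_hline(yintercept = unique(results$alpha), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$rejection_rate - .data$mc_se,
                   ymax = .data$rejection_rate + .data$mc_se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta[AB]), y = "Rejection rate") +
    ggplot2::theme_minimal()
}

#' Write study results to TSV
#'
#' @param results A study tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
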