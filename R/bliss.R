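#' Abbott-corrected survival
#'
#' Rescales a treated group's survival by the control survival, removing
#' natural mortality: the corrected rate is `s_treated / s0`. Ratios above 1
#' (treated outliving controls by sampling noise) are capped at 1 with a
#' warning.
#'
#' @param s_treated Treated-group survival rate in `[0, 1]`.
#' @param s0 Control survival rate in `(0, 1]`.
#' @return The corrected survival rate.
#' @examples
#' abbott_corrected_survival(0.63, 0.90)
#' @export
abbott_corrected_survival <- function(s_treated, s0) {
  stopifnot(all(s_treated >= 0 & s_treated <= 1), all(s0 <= 1))
  if (any(s0 <= 0)) stop("control survival must be > 0", call. = FALSE)
  r <- s_treated / s0
  if (any(r > 1)) {
    warning("corrected survival above 1 capped at 1", call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Expected survival under Bliss independence
#'
#' If two agents act independently, combined-exposure survival is the product
#' of the control survival and the two Abbott-corrected single-agent
#' survivals, `s0 * sA * sB`. Observed combination survival below this value
#' indicates synergism; above it, antagonism.
#'
#' @param s0 Control survival in `[0, 1]`.
#' @param sA,sB Abbott-corrected single-agent survivals in `[0, 1]`.
#' @return The Bliss-independent expectation.
#' @examples
#' expected_bliss_survival(0.9, 0.8, 0.7)
#' @export
expected_bliss_survival <- function(s0, sA, sB) {
  stopifnot(all(c(s0, sA, sB) >= 0), all(c(s0, sA, sB) <= 1))
  s0 * sA * sB
}

#' Holm step-down adjustment
#'
#' Holm's step-down multiple-testing correction: p-values are sorted
#' ascending, the i-th smallest is multiplied by `m - i + 1`, the sequence is
#' made monotone non-decreasing, capped at 1, and returned in the original
#' order. Controls the family-wise error rate and dominates Bonferroni.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value list", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

resolve_trial_design <- function(tab, include_trial) {
  X <- cbind(`(Intercept)` = 1, x_A = tab$x_A, x_B = tab$x_B,
             `x_A:x_B` = tab$x_A * tab$x_B)
  trials <- sort(unique(tab$trial_id))
  if (include_trial && length(trials) > 1) {
    for (t in trials[-1])
      X <- cbind(X, as.integer(tab$trial_id == t))
    colnames(X)[-(1:4)] <- paste0("trial_", trials[-1])
  }
  X
}

#' Bliss-independence likelihood-ratio test for one dosage and scope
#'
#' Fits the log-binomial survival model
#' `log(p_surv) = b0 + bA * x_A + bB * x_B + bAB * x_A * x_B (+ trial)` on the
#' four exposure cells (control, agent A, agent B, combination) of a risk
#' table, and tests the Bliss-independence null `bAB = 0` with a
#' likelihood-ratio test against the reduced model without the interaction.
#' A significant negative `bAB` indicates synergism (lower-than-expected
#' combined survival), a significant positive one antagonism.
#'
#' @param data A validated assay tibble.
#' @param control,group_A,group_B,group_AB Group labels of the four cells.
#' @param scope `"overall"` or a stage name.
#' @param include_trial Include reference-coded trial fixed effects (default
#'   `TRUE`; ignored when only one trial is present).
#' @param schedule A [stage_schedule()].
#' @return An object of class `bliss_test`: `beta_AB`, `LR`, `df`, `p_raw`,
#'   `p_holm` (`NA` until set by a family runner), `boundary`, per-group
#'   sizes, and the full/reduced fits.
#' @export
bliss_lr_test <- function(data, control, group_A, group_B, group_AB,
                          scope = "overall", include_trial = TRUE,
                          schedule = assay_schedule(data)) {
  groups <- c(control = control, A = group_A, B = group_B, AB = group_AB)
  if (anyDuplicated(groups) > 0)
    stop("the four test groups must be distinct", call. = FALSE)
  design <- assay_groups(data)
  missing <- setdiff(groups, design$group_label)
  if (length(missing) > 0)
    stop("group(s) not in dataset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- design[match(groups, design$group_label), ]
  if (!isTRUE(all.equal(as.numeric(unlist(g[, c("x_A", "x_B")])),
                        c(0, 1, 0, 1, 0, 0, 1, 1))))
    stop("groups must be (control: 0/0, A: 1/0, B: 0/1, AB: 1/1) in exposure",
         call. = FALSE)
  if (g$dose_A_ng_ml[4] != g$dose_A_ng_ml[2] ||
      g$dose_B_ng_ml[4] != g$dose_B_ng_ml[3])
    stop("combination group's doses must equal the union of A's and B's",
         call. = FALSE)

  tab <- build_risk_table(data, scope, schedule)
  tab <- tab[tab$group_label %in% groups, ]
  n_by <- table(factor(tab$group_label, levels = groups))
  if (any(n_by == 0))
    stop("no subjects at risk in scope '", scope, "' for group(s): ",
         paste(groups[n_by == 0], collapse = ", "), call. = FALSE)

  X <- resolve_trial_design(tab, include_trial)
  full <- fit_binomial_glm(X, tab$outcome, link = "log")
  reduced <- fit_binomial_glm(X[, colnames(X) != "x_A:x_B", drop = FALSE],
                              tab$outcome, link = "log")
  lr <- lr_statistic(full, reduced)
  structure(
    list(scope = scope, groups = groups,
         n_groups = stats::setNames(as.integer(n_by), names(groups)),
         beta_AB = unname(full$coefficients["x_A:x_B"]),
         LR = lr, df = 1L, p_raw = chi2_upper_tail(lr, 1L), p_holm = NA_real_,
         boundary = full$boundary || reduced$boundary,
         full = full, reduced = reduced),
    class = "bliss_test"
  )
}

#' @export
print.bliss_test <- function(x, ...) {
  cat(sprintf("<bliss_test> scope = %s\n", x$scope))
  cat(sprintf("  beta_AB = %.5f, LR = %.4f (df = %d), p_raw = %.4g",
              x$beta_AB, x$LR, x$df, x$p_raw))
  if (!is.na(x$p_holm)) cat(sprintf(", p_Holm = %.4g", x$p_holm))
  cat("\n")
  if (x$boundary) cat("  boundary solution: chi-squared reference approximate\n")
  invisible(x)
}

#' @export
tidy.bliss_test <- function(x, ...) {
  tibble::tibble(scope = x$scope, beta_AB = x$beta_AB, LR = x$LR, df = x$df,
                 p_raw = x$p_raw, p_holm = x$p_holm, boundary = x$boundary)
}

#' Classify an interaction test result
#'
#' Direction call from the sign of the interaction coefficient and the
#' Holm-adjusted p-value: significant negative means synergism, significant
#' positive means antagonism, otherwise the data are not distinguishable from
#' Bliss independence.
#'
#' @param result A `bliss_test` with `p_holm` set (see
#'   [run_interaction_family()]; for a standalone test, Holm with one member
#'   leaves `p_holm = p_raw`).
#' @param alpha Family-wise significance level.
#' @return `"synergism"`, `"antagonism"`, or
#'   `"not-distinguishable-from-independence"`.
#' @export
classify_interaction <- function(result, alpha = 0.05) {
  p <- result$p_holm
  if (is.na(p)) stop("adjusted p-value not set; run the family adjustment first",
                     call. = FALSE)
  if (p < alpha && result$beta_AB < 0) return("synergism")
  if (p < alpha && result$beta_AB > 0) return("antagonism")
  "not-distinguishable-from-independence"
}

#' Dosage table for the standard 11-group co-exposure design
#'
#' One row per dosage of the varying agent (B, thiamethoxam), with agent A
#' (captan) fixed at its high dose and the acetone-treated (solvent) control
#' as reference — the four cells used by each interaction test.
#'
#' @return A tibble with columns `dosage`, `control`, `group_A`, `group_B`,
#'   `group_AB`.
#' @export
default_dosage_table <- function() {
  tibble::tibble(
    dosage = c("low", "medium", "high"),
    control = "control_pos",
    group_A = "captan_high",
    group_B = c("thiam_low", "thiam_med", "thiam_high"),
    group_AB = c("combo_low", "combo_med", "combo_high")
  )
}

#' Run the interaction-test battery across dosages and stages
#'
#' Runs [bliss_lr_test()] for every dosage-by-scope combination and applies
#' the Holm step-down within each declared family. The default family split
#' follows the testing structure of stage-partitioned batteries: the
#' stage-specific tests (dosages x stages) form one family and the
#' overall-survival tests a second; `family = "joint"` pools all tests into
#' one family, `family = "per_scope"` adjusts within each scope.
#'
#' @param data A validated assay tibble.
#' @param dosages Tibble like [default_dosage_table()] naming the four groups
#'   per dosage.
#' @param scopes Scopes to test; default overall plus every stage.
#' @param alpha Family-wise significance level for direction calls.
#' @param family Family definition: `"split"` (default), `"joint"`, or
#'   `"per_scope"`.
#' @param include_trial Include trial fixed effects.
#' @param schedule A [stage_schedule()].
#' @return A `bliss_family` tibble, one row per test: `family`, `scope`,
#'   `dosage`, per-group sizes, `beta_AB`, `LR`, `df`, `p_raw`, `p_holm`,
#'   `call`, `boundary`, `error` (message for failed members, which are
#'   recorded, not dropped). Attribute `alpha` stores the level.
#' @export
run_interaction_family <- function(data, dosages = default_dosage_table(),
                                   scopes = NULL, alpha = 0.05,
                                   family = c("split", "joint", "per_scope"),
                                   include_trial = TRUE,
                                   schedule = assay_schedule(data)) {
  family <- match.arg(family)
  if (is.null(scopes)) scopes <- c("overall", schedule$stages)
  grid <- tidyr::expand_grid(scope = scopes, dosages)
  rows <- purrr::pmap(grid, function(scope, dosage, control, group_A, group_B,
                                     group_AB) {
    res <- tryCatch(
      bliss_lr_test(data, control, group_A, group_B, group_AB, scope = scope,
                    include_trial = include_trial, schedule = schedule),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res))
      return(tibble::tibble(
        scope = scope, dosage = dosage, n_control = NA_integer_,
        n_A = NA_integer_, n_B = NA_integer_, n_AB = NA_integer_,
        beta_AB = NA_real_, LR = NA_real_, df = 1L, p_raw = NA_real_,
        boundary = NA, error = res))
    tibble::tibble(
      scope = scope, dosage = dosage,
      n_control = res$n_groups[["control"]], n_A = res$n_groups[["A"]],
      n_B = res$n_groups[["B"]], n_AB = res$n_groups[["AB"]],
      beta_AB = res$beta_AB, LR = res$LR, df = res$df, p_raw = res$p_raw,
      boundary = res$boundary, error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$family <- switch(family,
    split = ifelse(out$scope == "overall", "overall", "stages"),
    joint = "all",
    per_scope = out$scope
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$family),
    p_holm = holm_adjust(.data$p_raw)
  )
  out <- dplyr::ungroup(out)
  out$call <- dplyr::case_when(
    is.na(out$p_holm) ~ NA_character_,
    out$p_holm < alpha & out$beta_AB < 0 ~ "synergism",
    out$p_holm < alpha & out$beta_AB > 0 ~ "antagonism",
    TRUE ~ "not-distinguishable-from-independence"
  )
  out <- dplyr::relocate(out, "family", "scope", "dosage")
  out <- dplyr::relocate(out, "p_holm", .after = "p_raw")
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("bliss_family", class(out)))
  out
}

#' @export
glance.bliss_family <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x), n_failed = sum(!is.na(x$error)),
    n_synergism = sum(x$call == "synergism", na.rm = TRUE),
    n_antagonism = sum(x$call == "antagonism", na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.bliss_family <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot an interaction-test battery
#'
#' Interaction coefficients by dosage and scope, coloured by direction call;
#' points below zero lean synergistic, above zero antagonistic.
#'
#' @param object A `bliss_family`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bliss_family <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$dosage <- factor(df$dosage, levels = unique(df$dosage))
  ggplot2::ggplot(df, ggplot2::aes(.data$dosage, .data$beta_AB,
                                   colour = .data$call)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "Dosage", y = expression(hat(beta)[AB]),
                  colour = "Call") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

format_family <- function(x) {
  df <- tibble::as_tibble(x)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_holm <- round(signif(df$p_holm, 3), 3)
  df
}

#' Write an interaction-test battery to TSV
#'
#' One row per test with p-values to 3 significant figures (adjusted values
#' additionally rounded to 3 decimals).
#'
#' @param x A `bliss_family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_tsv <- function(x, path) {
  readr::write_tsv(format_family(x), path)
  invisible(path)
}

#' Write an interaction-test battery to JSON
#'
#' @param x A `bliss_family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_json <- function(x, path) {
  obj <- list(alpha = attr(x, "alpha"), tests = tibble::as_tibble(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
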