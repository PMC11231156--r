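#' Build a risk table for overall or stage-specific survival
#'
#' Converts per-subject fates into the binary outcome table the survival GLMs
#' consume. For `scope = "overall"` every non-removed subject contributes one
#' row with outcome 1 iff it reached the terminal event. For a stage scope,
#' only subjects alive at stage entry appear, with outcome 1 iff the subject
#' did not die in that stage; removed subjects contribute only to stages fully
#' completed before their removal day (uninformative censoring).
#'
#' @param data A validated assay tibble.
#' @param scope `"overall"` or a stage name from the schedule.
#' @param schedule A [stage_schedule()]; defaults to the one attached to
#'   `data`.
#' @return A tibble (`subject_id`, `trial_id`, `group_label`, `x_A`, `x_B`,
#'   `outcome`) with attributes `scope` and `n_removed` (count of removed
#'   subjects excluded from this scope).
#' @export
build_risk_table <- function(data, scope = "overall",
                             schedule = assay_schedule(data)) {
  data <- tibble::as_tibble(data)
  all_groups <- unique(data$group_label)
  keep_cols <- c("subject_id", "trial_id", "group_label", "x_A", "x_B")

  if (identical(scope, "overall")) {
    removed <- data$fate == "removed"
    out <- dplyr::mutate(
      dplyr::select(data[!removed, ], dplyr::all_of(keep_cols)),
      outcome = as.integer(data$fate[!removed] == schedule$terminal)
    )
    n_removed <- sum(removed)
  } else {
    s <- match(scope, schedule$stages)
    if (is.na(s))
      stop("unknown stage: ", scope, call. = FALSE)
    stage_end <- schedule$day_ranges[[s]][2]
    died_idx <- ifelse(data$fate == "died",
                       match(data$fate_stage, schedule$stages), NA_integer_)
    alive_at_entry <- is.na(died_idx) | died_idx >= s
    # removed subjects stay only while the stage completed before removal
    removed <- data$fate == "removed"
    removed_out <- removed & !(data$fate_day > stage_end)
    keep <- alive_at_entry & !removed_out
    out <- dplyr::mutate(
      dplyr::select(data[keep, ], dplyr::all_of(keep_cols)),
      outcome = as.integer(!(data$fate[keep] == "died" & died_idx[keep] == s))
    )
    n_removed <- sum(removed & !keep)
  }
  attr(out, "scope") <- scope
  attr(out, "n_removed") <- n_removed
  attr(out, "all_groups") <- all_groups
  out
}

#' Per-group survival summaries of a risk table
#'
#' @param table A risk table from [build_risk_table()].
#' @param pool_trials If `TRUE` (default) trials are pooled; otherwise one
#'   summary per group and trial.
#' @return A tibble with `group_label` (and `trial_id` unless pooled),
#'   `n_at_risk`, `n_survived`, and the exact survival `proportion`.
#' @export
summarize_groups <- function(table, pool_trials = TRUE) {
  if (nrow(table) == 0) stop("empty risk table", call. = FALSE)
  keys <- if (pool_trials) "group_label" else c("group_label", "trial_id")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table),
                    dplyr::across(dplyr::all_of(keys))),
    n_at_risk = dplyr::n(),
    n_survived = sum(.data$outcome),
    proportion = .data$n_survived / .data$n_at_risk,
    .groups = "drop"
  )
  absent <- setdiff(attr(table, "all_groups"), table$group_label)
  if (length(absent) > 0)
    warning("group(s) with no subjects in scope omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Descriptive survival curve over observation days. With no censoring this
#' equals one minus the empirical distribution of death days.
#'
#' @param fate_days Integer days of death or censoring (>= 1).
#' @param event_flags Binary vector, 1 = death observed, 0 = censored.
#' @return A tibble (`day`, `n_risk`, `n_event`, `survival`) with one row per
#'   observed event day; the estimate is the right-continuous step function
#'   through these points (survival 1 before the first event).
#' @examples
#' km_estimate(c(2, 2, 4, 14), c(1, 1, 1, 0))
#' @export
km_estimate <- function(fate_days, event_flags) {
  if (length(fate_days) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(fate_days) == length(event_flags),
            all(fate_days >= 1), all(event_flags %in% c(0, 1)))
  fit <- survival::survfit(
    survival::Surv(fate_days, event_flags) ~ 1,
    conf.type = "none"
  )
  out <- tibble::tibble(
    day = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv
  )
  dplyr::filter(out, .data$n_event > 0)
}

#' Evaluate a Kaplan-Meier estimate at given days
#'
#' @param km A tibble from [km_estimate()].
#' @param days Days at which to evaluate the step function.
#' @return Numeric survival probabilities (right-continuous).
#' @export
km_survival <- function(km, days) {
  if (nrow(km) == 0) return(rep(1, length(days)))
  stats::stepfun(km$day, c(1, km$survival), right = FALSE)(days)
}

#' Plot group survival curves
#'
#' Kaplan-Meier survival curves per treatment group, computed from death and
#' emergence days; removed subjects are censored at removal.
#'
#' @param data An assay tibble.
#' @param schedule A [stage_schedule()].
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(data, schedule = assay_schedule(data)) {
  df <- dplyr::mutate(
    tibble::as_tibble(data),
    day = dplyr::coalesce(.data$fate_day, schedule$last_day),
    event = as.integer(.data$fate == "died")
  )
  km <- dplyr::group_modify(
    dplyr::group_by(df, .data$group_label),
    ~ {
      k <- km_estimate(.x$day, .x$event)
      dplyr::bind_rows(
        tibble::tibble(day = 0, n_risk = nrow(.x), n_event = 0L, survival = 1),
        k,
        tibble::tibble(day = schedule$last_day,
                       n_risk = min(k$n_risk - k$n_event, na.rm = TRUE),
                       n_event = 0L,
                       survival = min(c(1, k$survival)))
      )
    }
  )
  ggplot2::ggplot(km, ggplot2::aes(.data$day, .data$survival,
                                   colour = .data$group_label)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Day", y = "Survival", colour = "Group") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
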