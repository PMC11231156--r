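# Shared builders for the 2x2 exposure toy problems and small assay tables.

# design matrix of the four exposure cells, one row per subject
cell_design <- function(n = rep(100, 4)) {
  X <- cbind(`(Intercept)` = 1, x_A = c(0, 1, 0, 1), x_B = c(0, 0, 1, 1),
             `x_A:x_B` = c(0, 0, 0, 1))
  X[rep(1:4, n), , drop = FALSE]
}

# outcome vector with k survivors of n per cell (control, A, B, AB)
cell_outcomes <- function(k, n = rep(100, 4)) {
  unlist(mapply(function(kk, nn) c(rep(1, kk), rep(0, nn - kk)), k, n,
                SIMPLIFY = FALSE))
}

# single-trial assay tibble with four groups, k survivors of n each;
# deaths occur in the larva stage (day 3) unless death_day is given
toy_assay <- function(k, n = rep(100, 4), death_day = 3,
                      labels = c("control_pos", "captan_high", "thiam_high",
                                 "combo_high"),
                      trial = "trial1") {
  sch <- default_stage_schedule()
  doses <- data.frame(dose_A = c(0, 2000, 0, 2000), dose_B = c(0, 0, 1440, 1440))
  rows <- lapply(1:4, function(i) {
    surv <- c(rep(TRUE, k[i]), rep(FALSE, n[i] - k[i]))
    tibble::tibble(
      subject_id = sprintf("%s_%s_%03d", labels[i], trial, seq_len(n[i])),
      trial_id = trial, group_label = labels[i],
      x_A = as.integer(doses$dose_A[i] > 0), x_B = as.integer(doses$dose_B[i] > 0),
      dose_A_ng_ml = doses$dose_A[i], dose_B_ng_ml = doses$dose_B[i],
      fate = ifelse(surv, "emerged", "died"),
      fate_day = ifelse(surv, NA_integer_, death_day),
      fate_stage = ifelse(surv, NA_character_,
                          attribute_stage(death_day, sch))
    )
  })
  validate_assay(dplyr::bind_rows(rows), sch)
}

toy_dosage_table <- function() {
  tibble::tibble(dosage = "high", control = "control_pos",
                 group_A = "captan_high", group_B = "thiam_high",
                 group_AB = "combo_high")
}

# minimal well-formed 4-row assay tibble, one subject per exposure cell
four_row_assay <- function() {
  tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s4"),
    trial_id = "trial1",
    group_label = c("control_pos", "captan_high", "thiam_high", "combo_high"),
    x_A = c(0L, 1L, 0L, 1L), x_B = c(0L, 0L, 1L, 1L),
    dose_A_ng_ml = c(0, 2000, 0, 2000), dose_B_ng_ml = c(0, 0, 1440, 1440),
    fate = c("emerged", "died", "emerged", "died"),
    fate_day = c(NA, 8L, NA, 12L),
    fate_stage = c(NA, "prepupa", NA, "pupa")
  )
}
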