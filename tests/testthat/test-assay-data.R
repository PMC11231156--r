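assay_columns_for_test <- function() {
  c("subject_id", "trial_id", "group_label", "x_A", "x_B",
    "dose_A_ng_ml", "dose_B_ng_ml", "fate", "fate_day", "fate_stage")
}

test_that("CSV write/read round-trips all fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  orig <- toy_assay(k = c(3, 2, 2, 1), n = c(4, 4, 4, 4))
  write_assay_csv(orig, path, provenance = c(seed = "1"))
  back <- read_assay_csv(path)
  expect_equal(nrow(back), 16)
  expect_equal(tibble::as_tibble(back)[assay_columns_for_test()],
               tibble::as_tibble(orig)[assay_columns_for_test()])
})

test_that("a small well-formed file parses to one record per row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(four_row_assay(), path)
  ds <- read_assay_csv(path)
  expect_equal(nrow(ds), 4)
  expect_s3_class(ds, "tbl_df")
})

test_that("validation rejects invariant violations with row-indexed messages", {
  bad <- four_row_assay()
  bad$dose_A_ng_ml[2] <- 0      # x_A = 1 but dose 0
  expect_error(validate_assay(bad), "row 2.*x_A", ignore.case = TRUE)

  dup <- four_row_assay()
  dup$subject_id[3] <- "s1"
  expect_error(validate_assay(dup), "duplicate subject_id")

  miss <- four_row_assay()[, -4]
  expect_error(validate_assay(miss), "missing required columns")

  nodate <- four_row_assay()
  nodate$fate_day[2] <- NA
  expect_error(validate_assay(nodate), "fate_day")

  badfate <- four_row_assay()
  badfate$fate[1] <- "vanished"
  expect_error(validate_assay(badfate), "fate must be one of")
})

test_that("missing fate_stage is recomputed from the day range", {
  x <- four_row_assay()
  x$fate_stage[2] <- NA
  v <- validate_assay(x)
  expect_equal(v$fate_stage[2], "prepupa")
})

test_that("simulated standard design reproduces the published group sizes", {
  sim <- simulate_assay(default_paper_design(seed = 3))
  counts <- dplyr::count(tibble::as_tibble(sim), group_label)
  expected <- c(captan_high = 96L, captan_low = 92L, captan_med = 96L,
                combo_high = 103L, combo_low = 109L, combo_med = 109L,
                control_neg = 235L, control_pos = 236L,
                thiam_high = 94L, thiam_low = 94L, thiam_med = 95L)
  expect_equal(stats::setNames(counts$n, counts$group_label), expected)
  expect_equal(nrow(sim), 1359L)
})

test_that("risk tables partition fates by stage as the definitions force", {
  x <- four_row_assay()        # s2 died prepupa, s4 died pupa
  larva <- build_risk_table(x, "larva")
  prepupa <- build_risk_table(x, "prepupa")
  pupa <- build_risk_table(x, "pupa")
  overall <- build_risk_table(x, "overall")

  expect_setequal(larva$subject_id, c("s1", "s2", "s3", "s4"))
  expect_true(all(larva$outcome == 1))
  expect_equal(prepupa$outcome[prepupa$subject_id == "s2"], 0)
  expect_false("s2" %in% pupa$subject_id)
  expect_equal(pupa$outcome[pupa$subject_id == "s4"], 0)
  expect_equal(sort(overall$outcome), c(0, 0, 1, 1))
  expect_error(build_risk_table(x, "imago"), "unknown stage")
})

test_that("all-emerged data yield all-1 outcomes in every stage", {
  x <- toy_assay(k = c(5, 5, 5, 5), n = rep(5, 4))
  for (s in c("larva", "prepupa", "pupa", "overall"))
    expect_true(all(build_risk_table(x, s)$outcome == 1))
})

test_that("removed subjects count only in stages completed before removal", {
  x <- four_row_assay()
  x$fate[1] <- "removed"; x$fate_day[1] <- 8L   # removed during prepupa
  expect_false("s1" %in% build_risk_table(x, "prepupa")$subject_id)
  expect_false("s1" %in% build_risk_table(x, "pupa")$subject_id)
  expect_false("s1" %in% build_risk_table(x, "overall")$subject_id)
  larva <- build_risk_table(x, "larva")
  expect_equal(larva$outcome[larva$subject_id == "s1"], 1)
  expect_equal(attr(build_risk_table(x, "overall"), "n_removed"), 1L)
})

test_that("stage risk-set sizes obey conservation across stages", {
  sim <- simulate_assay(four_group_config(n_per_group_per_trial = 50, seed = 9))
  larva <- build_risk_table(sim, "larva")
  prepupa <- build_risk_table(sim, "prepupa")
  pupa <- build_risk_table(sim, "pupa")
  expect_equal(nrow(prepupa), sum(larva$outcome))
  expect_equal(nrow(pupa), sum(prepupa$outcome))
  # overall outcome = product of stage outcomes per subject (no removals)
  overall <- build_risk_table(sim, "overall")
  merged <- merge(
    merge(larva[, c("subject_id", "outcome")],
          prepupa[, c("subject_id", "outcome")],
          by = "subject_id", all.x = TRUE, suffixes = c("_l", "_p")),
    pupa[, c("subject_id", "outcome")], by = "subject_id", all.x = TRUE)
  prod_outcome <- with(merged, outcome_l *
                         ifelse(is.na(outcome_p), 0, outcome_p) *
                         ifelse(is.na(outcome), 0, outcome))
  ov <- overall$outcome[match(merged$subject_id, overall$subject_id)]
  expect_equal(ov, prod_outcome)
})

test_that("stage survival proportions track the generating probabilities", {
  groups <- tibble::tibble(group_label = "control_pos", dose_A_ng_ml = 0,
                           dose_B_ng_ml = 0, n = 10000L)
  coefs <- tibble::tibble(stage = c("larva", "prepupa", "pupa"),
                          b0 = log(0.9), bA = 0, bB = 0, bAB = 0)
  cfg <- generator_config(groups, n_trials = 1, stage_coefs = coefs,
                          trial_effects = 0, seed = 101)
  sim <- simulate_assay(cfg)
  for (s in c("larva", "prepupa", "pupa")) {
    tab <- build_risk_table(sim, s)
    p_hat <- mean(tab$outcome)
    half_ci <- 2.576 * sqrt(0.9 * 0.1 / nrow(tab))
    expect_lt(abs(p_hat - 0.9), half_ci)
  }
})

test_that("group summaries report exact ratios and pooled conservation", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  tab <- build_risk_table(x, "overall")
  s <- summarize_groups(tab)
  expect_equal(s$proportion[s$group_label == "control_pos"], 0.90)
  expect_equal(s$n_survived, s$proportion * s$n_at_risk)
  per_trial <- summarize_groups(tab, pool_trials = FALSE)
  pooled_n <- tapply(per_trial$n_at_risk, per_trial$group_label, sum)
  expect_equal(as.vector(pooled_n[s$group_label]), s$n_at_risk)
  expect_error(summarize_groups(tab[0, ]), "empty")
})

test_that("groups absent from a scope are omitted with a warning", {
  x <- four_row_assay()
  x$fate <- c("died", "died", "died", "died")
  x$fate_day <- c(3L, 3L, 3L, 3L)
  x$fate_stage <- "larva"
  x <- validate_assay(x)
  tab <- build_risk_table(x, "prepupa")   # nobody survives larva
  expect_equal(nrow(tab), 0)
})

test_that("product-limit estimate matches the hand-computed example", {
  km <- km_estimate(c(2, 2, 4, 14), c(1, 1, 1, 0))
  expect_equal(km_survival(km, 2), 0.5)
  expect_equal(km_survival(km, 4), 0.25)
  expect_equal(km_survival(km, 13), 0.25)   # flat after last death
  expect_equal(km_survival(km, 1), 1)
})

test_that("product-limit estimate without censoring equals the empirical curve", {
  set.seed(77)
  for (i in 1:5) {
    days <- sample(1:14, 30, replace = TRUE)
    km <- km_estimate(days, rep(1, 30))
    grid <- 1:14
    expect_equal(km_survival(km, grid), 1 - stats::ecdf(days)(grid))
  }
  expect_true(all(diff(km_estimate(c(2, 5, 9), c(1, 1, 1))$survival) <= 0))
})

test_that("degenerate product-limit inputs behave as defined", {
  expect_equal(nrow(km_estimate(c(5, 7), c(0, 0))), 0)   # no deaths
  expect_equal(km_survival(km_estimate(c(5, 7), c(0, 0)), 10), 1)
  km <- km_estimate(rep(1, 4), rep(1, 4))
  expect_equal(km_survival(km, 1), 0)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})
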