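test_that("Abbott correction rescales by control survival", {
  expect_equal(abbott_corrected_survival(0.63, 0.90), 0.70)
  expect_equal(abbott_corrected_survival(0.74, 0.74), 1.0)
  expect_warning(r <- abbott_corrected_survival(0.95, 0.90), "capped")
  expect_equal(r, 1)
  expect_error(abbott_corrected_survival(0.80, 0.0), "control survival")
})

test_that("Bliss expectation is the survival product", {
  expect_equal(expected_bliss_survival(1, 1, 1), 1)
  expect_equal(expected_bliss_survival(0.9, 0.8, 0.7), 0.504)
  s0 <- 0.85; sB <- 0.6
  expect_equal(expected_bliss_survival(s0, 1, sB), s0 * sB)
})

test_that("Holm step-down matches hand-computed examples", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  p <- c(0.004858, rep(0.2, 8))
  expect_equal(min(holm_adjust(p)), 9 * 0.004858, tolerance = 1e-12)
})

test_that("Holm adjustment is equivariant, monotone, and Bonferroni-dominated", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(2:12, 1)
    p <- stats::runif(m)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, m * p)))
    perm <- sample(m)
    expect_equal(holm_adjust(p[perm]), adj[perm])
    # monotone: raising one p-value never lowers any adjusted value
    p2 <- p; j <- sample(m, 1)
    p2[j] <- min(1, p2[j] + stats::runif(1, 0, 1 - p2[j]))
    expect_true(all(holm_adjust(p2) >= adj - 1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(holm_adjust(numeric(0)), "empty")
})

test_that("interaction LR test matches the saturated closed form on the toy", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  res <- bliss_lr_test(x, "control_pos", "captan_high", "thiam_high",
                       "combo_high", scope = "overall")
  expect_equal(res$beta_AB, log(0.40 * 0.90 / (0.72 * 0.63)),
               tolerance = 1e-5)
  lr_oracle <- 2 * (oracle_saturated_loglik(c(90, 72, 63, 40), rep(100, 4)) -
                      oracle_reduced_loglik(c(90, 72, 63, 40), rep(100, 4)))
  expect_equal(res$LR, lr_oracle, tolerance = 1e-4)
  expect_equal(res$p_raw, chi2_upper_tail(res$LR, 1))
  expect_equal(unname(res$n_groups), rep(100L, 4))
})

test_that("Bliss-exact data give a null interaction", {
  x <- toy_assay(k = c(900, 720, 630, 504), n = rep(1000, 4))
  res <- bliss_lr_test(x, "control_pos", "captan_high", "thiam_high",
                       "combo_high", scope = "overall")
  expect_equal(res$beta_AB, 0, tolerance = 1e-4)
  expect_lt(res$LR, 1e-5)
  expect_equal(res$p_raw, 1, tolerance = 1e-2)
})

test_that("reduced-model predictions satisfy the Bliss identity exactly", {
  # conservation under the log link: predicted combination survival equals
  # predicted control x corrected-A x corrected-B survival
  x <- toy_assay(k = c(88, 70, 61, 38))
  tab <- build_risk_table(x, "overall")
  X <- cbind(`(Intercept)` = 1, x_A = tab$x_A, x_B = tab$x_B)
  red <- fit_binomial_glm(X, tab$outcome, link = "log")
  b <- red$coefficients
  p0 <- exp(b[1]); pA <- exp(b[1] + b[2]); pB <- exp(b[1] + b[3])
  p_combo <- exp(sum(b))
  expect_equal(unname(p_combo),
               unname(expected_bliss_survival(p0, pA / p0, pB / p0)),
               tolerance = 1e-12)
})

test_that("test specification errors are caught", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  expect_error(bliss_lr_test(x, "control_pos", "captan_high", "thiam_high",
                             "thiam_high"), "distinct")
  expect_error(bliss_lr_test(x, "control_pos", "captan_high", "thiam_high",
                             "nope"), "not in dataset")
  expect_error(bliss_lr_test(x, "captan_high", "control_pos", "thiam_high",
                             "combo_high"), "exposure")
})

test_that("direction calls follow the sign rule and significance", {
  res <- list(beta_AB = -0.5, p_holm = 0.044)
  expect_equal(classify_interaction(res, alpha = 0.05), "synergism")
  res$p_holm <- 0.50
  expect_equal(classify_interaction(res, alpha = 0.05),
               "not-distinguishable-from-independence")
  res <- list(beta_AB = 0.4, p_holm = 0.01)
  expect_equal(classify_interaction(res, alpha = 0.05), "antagonism")
  expect_error(classify_interaction(list(beta_AB = 1, p_holm = NA)),
               "adjusted p")
  # quantified: synergism is never called with a nonnegative coefficient
  set.seed(11)
  for (i in 1:50) {
    r <- list(beta_AB = abs(stats::rnorm(1)), p_holm = stats::runif(1))
    expect_false(classify_interaction(r, alpha = 0.5) == "synergism")
  }
})

test_that("a single-test family leaves the adjusted p equal to the raw p", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  fam <- run_interaction_family(x, dosages = toy_dosage_table(),
                                scopes = "overall")
  expect_equal(nrow(fam), 1)
  expect_equal(fam$p_holm, fam$p_raw)
  expect_equal(glance(fam)$n_tests, 1)
})

test_that("family batteries adjust within the declared families", {
  sim <- simulate_assay(default_paper_design(seed = 21))
  fam <- run_interaction_family(sim)
  expect_equal(nrow(fam), 12)
  expect_setequal(unique(fam$family), c("overall", "stages"))
  for (f in unique(fam$family)) {
    sub <- fam[fam$family == f, ]
    expect_equal(sub$p_holm, holm_adjust(sub$p_raw))
    expect_true(all(sub$p_holm >= sub$p_raw))
    expect_true(all(sub$p_holm <= 1))
  }
  joint <- run_interaction_family(sim, family = "joint")
  expect_equal(joint$p_holm, holm_adjust(joint$p_raw))
})

test_that("an injected larval synergism is flagged there and nowhere else", {
  cfg <- default_paper_design(seed = 77)
  cfg$groups$n <- rep(400L, nrow(cfg$groups))
  cfg <- inject_interaction(cfg, "larva", -0.45)
  fam <- run_interaction_family(simulate_assay(cfg))
  high_larva <- fam$scope == "larva" & fam$dosage == "high"
  expect_equal(fam$call[high_larva], "synergism")
  expect_true(all(fam$call[fam$scope %in% c("prepupa", "pupa")] !=
                    "synergism"))
})

test_that("failed member tests are recorded, not dropped", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  dos <- dplyr::bind_rows(
    toy_dosage_table(),
    tibble::tibble(dosage = "low", control = "control_pos",
                   group_A = "captan_high", group_B = "missing_group",
                   group_AB = "combo_low"))
  fam <- run_interaction_family(x, dosages = dos, scopes = "overall")
  expect_equal(nrow(fam), 2)
  expect_true(any(!is.na(fam$error)))
  expect_true(any(is.na(fam$error)))
})

test_that("family results serialize to TSV and JSON", {
  x <- toy_assay(k = c(90, 72, 63, 40))
  fam <- run_interaction_family(x, dosages = toy_dosage_table(),
                                scopes = "overall")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_family_tsv(fam, tsv)
  write_family_json(fam, js)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$alpha, 0.05)
  expect_equal(parsed$tests$LR, fam$LR, tolerance = 1e-12)
})
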