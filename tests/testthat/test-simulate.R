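test_that("simulation is reproducible and has the declared dimensions", {
  tr <- risk_truth()
  s1 <- simulate_choices(tr, seed = 7)
  s2 <- simulate_choices(tr, seed = 7)
  s3 <- simulate_choices(tr, seed = 8)
  expect_identical(s1$records, s2$records)
  expect_false(identical(s1$records, s3$records))
  expect_equal(nrow(s1$records), 84L * 20L)
  expect_equal(nrow(s3$records), 84L * 20L)
  expect_equal(length(unique(s1$records$subject_id)), 84L)
  expect_true(all(table(s1$records$subject_id) == 20L))
  # simulated data always pass dataset validation (constructed through it)
  expect_s3_class(choice_data(s1$records, s1$designs), "choice_data")
})

test_that("simulation truths are validated", {
  expect_error(risk_truth(n_subjects = 1), "at least 2")
  expect_error(risk_truth(indifference_rate = 0.5), "0, 0.2")
  expect_error(risk_truth("EUT", "FP", params = c(r = 0.5, mu = -1)), "mu")
  expect_error(recovery_study(risk_truth(), n_reps = 0), "positive")
})

test_that("near-deterministic expected-utility agents switch at the implied row", {
  # r = 0.5 lies in the interval (0.41, 0.68): option A up to row 6, B from 7
  tr <- risk_truth("EUT", "FP", params = c(r = 0.5, mu = 1e-8),
                   n_subjects = 12)
  sim <- simulate_choices(tr, seed = 99)
  rec <- sim$records
  expect_true(all(rec$response[rec$row_index <= 6] == "A"))
  expect_true(all(rec$response[rec$row_index >= 7] == "B"))
})

test_that("simulated choice shares match the generating probability", {
  # a single-row design simulated for many subjects: the B share must sit
  # within 3 binomial standard errors of P(B)
  one_row <- structure(list(pairs = hl_design(1)$pairs[6], scale = 1),
                       class = "mpl_design")
  tr <- risk_truth("EUT", "FP", params = c(r = 0.682, mu = 0.428),
                   n_subjects = 10000, designs = list(low = one_row))
  pb <- choice_prob(hl_design(1)$pairs[[6]], "EUT", "FP", r = 0.682,
                    mu = 0.428)
  sim <- simulate_choices(tr, seed = 13)
  share <- mean(sim$records$response == "B")
  expect_lt(abs(share - pb), 3 * sqrt(pb * (1 - pb) / 10000))
})

test_that("indifference is injected at the requested rate and no more", {
  s0 <- simulate_choices(risk_truth(indifference_rate = 0), seed = 3)
  expect_false(any(s0$records$response == "INDIFFERENT"))
  s5 <- simulate_choices(risk_truth(indifference_rate = 0.1), seed = 3)
  rate <- mean(s5$records$response == "INDIFFERENT")
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(s5$records)))
})

test_that("choice-level and subject-level class assignment differ as designed", {
  par <- c(r_eut = 0.5, r_rdu = -1.2, gamma = 1, mu = 1e-8, pi_eut = 0.5)
  # deterministic agents: the EUT class (r = 0.5) switches to B at row 7,
  # the RDU class (r = -1.2, linear weighting) at row 2, so each record
  # reveals its latent class
  subj <- simulate_choices(risk_truth("MIX", "FP", params = par,
                                      n_subjects = 40, subject_class = TRUE),
                           seed = 21)
  chc <- simulate_choices(risk_truth("MIX", "FP", params = par,
                                     n_subjects = 40, subject_class = FALSE),
                          seed = 21)
  consistent <- function(sim) {
    vapply(split(sim$records, sim$records$subject_id), function(d) {
      pattern <- d$response[order(d$task_id, d$row_index)]
      eut <- rep(c("A", "B"), c(6, 4)); rdu <- rep(c("A", "B"), c(1, 9))
      identical(pattern, c(eut, eut)) || identical(pattern, c(rdu, rdu))
    }, logical(1))
  }
  expect_true(all(consistent(subj)))
  expect_false(all(consistent(chc)))
})

test_that("the recovery harness summarizes bias, spread and coverage", {
  rs <- recovery_study(risk_truth("EUT", "FP", n_subjects = 30), n_reps = 5,
                       seed = 10)
  expect_s3_class(rs, "recovery_study")
  expect_equal(nrow(rs$summary), 2L)
  expect_named(rs$summary,
               c("parameter", "truth", "mean", "bias", "mcse", "rmse",
                 "coverage"))
  expect_equal(rs$n_failed + sum(!is.na(rs$estimates[, 1])), 5L)
  expect_true(all(rs$summary$rmse >= abs(rs$summary$bias) - 1e-12))
  expect_true(all(rs$summary$coverage >= 0 & rs$summary$coverage <= 1))
  expect_output(print(rs), "Parameter recovery")
})

test_that("estimation is indifferent to injected indifference, end to end", {
  tr <- risk_truth("RDU", "CP", n_subjects = 25, indifference_rate = 0.05)
  sim <- simulate_choices(tr, seed = 71)
  stripped <- choice_data(
    sim$records[sim$records$response != "INDIFFERENT", ], sim$designs)
  f1 <- riskfit(sim, "RDU", "CP", compute_vcov = FALSE)
  f2 <- riskfit(stripped, "RDU", "CP", compute_vcov = FALSE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})
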