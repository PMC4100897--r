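test_that("the price list is built correctly at any payout scale", {
  d1 <- hl_design(1)
  expect_length(d1$pairs, 10L)
  for (k in 1:10) {
    pr <- d1$pairs[[k]]
    p_hi <- if (k == 10) 1 else k / 10
    expect_equal(pr$option_a$probs, c(p_hi, 1 - p_hi))
    expect_equal(pr$option_b$probs, c(p_hi, 1 - p_hi))
    expect_equal(pr$option_a$prizes, c(2.00, 1.60))
    expect_equal(pr$option_b$prizes, c(3.85, 0.10))
  }
  d5 <- hl_design(5)
  expect_equal(d5$pairs[[1]]$option_a$prizes, c(10, 8))
  expect_equal(d5$pairs[[1]]$option_b$prizes, c(19.25, 0.5))
  expect_error(hl_design(0), "positive")
  expect_error(hl_design(-2), "positive")
})

test_that("lottery construction enforces its invariants", {
  expect_error(lottery(c(2, 1.6), c(0.5, 0.4)), "sum to 1")
  expect_error(lottery(c(2, -1), c(0.5, 0.5)), "positive")
  expect_error(lottery(c(2, 1.6), c(1.2, -0.2)), "\\[0, 1\\]")
  expect_error(lottery(2, c(0.5, 0.5)), "equal length")
  expect_error(
    lottery_pair(lottery(c(2, 1.6), c(0.1, 0.9)),
                 lottery(c(3.85, 0.1), c(0.2, 0.8))),
    "same probability")
})

test_that("expected values reproduce the printed price-list table", {
  tab <- hl_table(hl_design(1))
  expect_equal(tab$ev_a, seq(1.640, 2.000, by = 0.040), tolerance = 1e-12)
  expect_equal(tab$ev_b, 0.475 + 0.375 * (0:9), tolerance = 1e-12)
  expect_equal(expected_value(lottery(2, 1)), 2)
  # the degenerate last row
  expect_equal(tab$ev_diff[10], -1.85)
})

test_that("crossovers are monotone in the row and invariant to payout scale", {
  c1 <- vapply(hl_design(1)$pairs, crra_crossover, numeric(1))
  c5 <- vapply(hl_design(5)$pairs, crra_crossover, numeric(1))
  expect_true(all(diff(c1[1:9]) > 0))
  expect_equal(c1[1:9], c5[1:9], tolerance = 1e-6)
  expect_identical(c1[10], Inf)
  expect_identical(c5[10], Inf)
})

test_that("crossover handles dominance and non-bracketing explicitly", {
  # option B dominates at every r: prizes strictly higher in every state
  dom <- lottery_pair(lottery(c(2, 1), c(0.5, 0.5)),
                      lottery(c(3, 1.5), c(0.5, 0.5)))
  expect_identical(crra_crossover(dom), Inf)
  # and the reverse
  dom2 <- lottery_pair(lottery(c(3, 1.5), c(0.5, 0.5)),
                       lottery(c(2, 1), c(0.5, 0.5)))
  expect_identical(crra_crossover(dom2), -Inf)
})

test_that("the summary table matches the printed interval layout", {
  tab <- hl_table()
  expect_identical(tab$rra_lower[1], -Inf)
  expect_identical(tab$rra_upper[10], Inf)
  expect_equal(tab$rra_lower[-1], tab$rra_upper[-10])
  # interval endpoints that the half-away-from-zero convention reproduces
  expect_equal(tab$rra_upper[c(1, 6, 7, 8)], c(-1.71, 0.41, 0.68, 0.97))
})

test_that("choice data validates records against the design registry", {
  rec <- data.frame(subject_id = "S1", task_id = "low", row_index = 1,
                    response = "A")
  expect_s3_class(choice_data(rec), "choice_data")
  expect_error(choice_data(transform(rec, response = "C")),
               "invalid response")
  expect_error(choice_data(transform(rec, task_id = "mid")),
               "not in the design registry")
  expect_error(choice_data(transform(rec, row_index = 11)),
               "out of range")
  expect_error(choice_data(rbind(rec, rec)), "duplicated")
  expect_error(choice_data(rec[, -4]), "missing required columns")
})

test_that("choice CSV round-trips losslessly and reports cluster structure", {
  sim <- simulate_choices(risk_truth(n_subjects = 84,
                                     indifference_rate = 0.05), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_choice_csv(sim, path)
  back <- read_choice_csv(path)
  expect_identical(back$records, sim$records)
  s <- summary(back)
  expect_equal(s$n_subjects, 84L)
  expect_true(all(s$cluster_sizes == 20L))

  # a corrupt response code is rejected with the offending line
  bad <- sim$records
  bad$response[3] <- "C"
  bad_path <- tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_choice_csv(bad_path), "line 4")
  hdr_path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), hdr_path)
  expect_error(read_choice_csv(hdr_path), "missing column")
})
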