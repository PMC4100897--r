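test_that("the maximum likelihood fit recovers a known generating process", {
  sim <- simulate_choices(risk_truth("EUT", "FP"), seed = 301)
  fit <- riskfit(sim, "EUT", "FP")
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["r"]] - 0.682), 4 * se[["r"]])
  expect_lt(abs(coef(fit)[["mu"]] - 0.428), 4 * se[["mu"]])
  # FitResult invariants
  expect_equal(fit$logLik, sum(fit$loglik_i), tolerance = 1e-8)
  expect_equal(fit$n_obs, 1680L)
  expect_equal(fit$n_clusters, 84L)
  expect_equal(fit$k, 2L)
  v <- vcov(fit)
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_true(all(eigen(v, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  expect_identical(fit$convergence$code, 0L)
})

test_that("probit and logit links agree up to the known scale factor", {
  sim <- simulate_choices(risk_truth("EUT", "FP"), seed = 302)
  fp <- riskfit(sim, "EUT", "FP")
  fl <- riskfit(sim, "EUT", "FL")
  expect_lt(abs(coef(fp)[["r"]] - coef(fl)[["r"]]), 0.05)
  expect_gt(coef(fp)[["mu"]] / coef(fl)[["mu"]], 1.5)
  expect_lt(coef(fp)[["mu"]] / coef(fl)[["mu"]], 1.9)
  expect_silent(compare_links(fp, fl))
})

test_that("degenerate response patterns are flagged, not silently estimated", {
  grid <- expand.grid(task_id = c("low", "high"), row_index = 1:10,
                      subject_id = sprintf("S%02d", 1:6),
                      stringsAsFactors = FALSE)
  grid$response <- "A"
  allA <- choice_data(grid)
  expect_warning(riskfit(allA, "EUT", "FP", compute_vcov = FALSE),
                 "boundary")
})

test_that("Wald tests reproduce the quadratic form and its reference distribution", {
  # single restriction: ((0.908 - 1) / 0.061)^2 against chi-squared(1)
  w <- wald_test(c(gamma = 0.908), c(gamma = 1),
                 vcov = matrix(0.061^2, dimnames = list("gamma", "gamma")))
  expect_equal(w$statistic, (0.092 / 0.061)^2, tolerance = 1e-10)
  expect_equal(w$p_value, pchisq((0.092 / 0.061)^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(w$p_value, 2), 0.13)
  # exactly satisfied restriction
  w0 <- wald_test(c(gamma = 1), c(gamma = 1),
                  vcov = matrix(0.05, dimnames = list("gamma", "gamma")))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # joint restriction has rank degrees of freedom
  est <- c(a = 0.2, b = 1.4)
  V <- diag(c(0.04, 0.09)); dimnames(V) <- list(names(est), names(est))
  wj <- wald_test(est, c(a = 0, b = 1), vcov = V)
  expect_equal(wj$df, 2L)
  expect_equal(wj$statistic, 0.2^2 / 0.04 + 0.4^2 / 0.09, tolerance = 1e-10)
})

test_that("constraints on parameters absent from the functional are rejected", {
  fit <- riskfit(tiny_dataset(n_subjects = 6), "EUT", "FP")
  expect_error(wald_test(fit, c(gamma = 1)), "absent from the EUT")
  # boundary restrictions are flagged as nonstandard
  expect_output(print(wald_test(c(pi_eut = 0.3), c(pi_eut = 0),
                                vcov = matrix(0.01, dimnames =
                                                list("pi_eut", "pi_eut")))),
                "nonstandard")
})

test_that("cluster sandwich scales correctly when clusters are duplicated", {
  sim <- tiny_dataset(n_subjects = 20, seed = 88)
  fit1 <- riskfit(sim, "EUT", "FP")
  rec2 <- sim$records
  rec2$subject_id <- paste0(rec2$subject_id, "dup")
  doubled <- choice_data(rbind(sim$records, rec2), sim$designs)
  fit2 <- riskfit(doubled, "EUT", "FP")
  # point estimates are unchanged; SEs shrink by about 1/sqrt(2)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-5)
  ratio <- sqrt(diag(vcov(fit2))) / sqrt(diag(vcov(fit1)))
  C <- fit1$n_clusters
  adj <- sqrt(0.5 * (2 * C / (2 * C - 1)) / (C / (C - 1)))
  expect_equal(unname(ratio), rep(adj, 2), tolerance = 0.02)
})

test_that("singleton clusters reduce the sandwich to the plain robust estimator", {
  sim <- tiny_dataset(n_subjects = 10, seed = 31)
  rec <- sim$records
  rec$subject_id <- sprintf("R%04d", seq_len(nrow(rec))) # one record per cluster
  singles <- choice_data(rec, sim$designs)
  fit <- riskfit(singles, "EUT", "FP")
  # independent recomputation: HC sandwich with factor n/(n-1)
  prep <- fit$prep
  negll <- riskmle:::make_negll(prep$pairs, "EUT", "FP", prep$counts)
  A <- riskmle:::fd_hessian(negll, fit$theta)
  S <- riskmle:::fd_scores(prep, "EUT", "FP", fit$theta)
  n <- nrow(S)
  V <- solve(A) %*% (crossprod(S) * n / (n - 1)) %*% solve(A)
  expect_equal(unname(fit$vcov_internal), unname(V), tolerance = 1e-10)
})

test_that("fit methods behave like standard modelling objects", {
  sim <- tiny_dataset(n_subjects = 10, seed = 77)
  fit <- riskfit(sim, "RDU", "CP")
  expect_named(coef(fit), c("r", "gamma", "mu"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 3L)
  expect_equal(AIC(fit), 2 * 3 - 2 * fit$logLik)
  expect_equal(BIC(fit), 3 * log(nobs(fit)) - 2 * fit$logLik)
  pb <- predict(fit)
  expect_length(pb, nobs(fit))
  expect_true(all(pb > 0 & pb < 1))
  res <- residuals(fit)
  expect_true(all(abs(res) <= 1))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "choice_data")
  expect_equal(nrow(sims[[1]]$records), nobs(fit))
  expect_output(print(fit), "RDU model")
  expect_output(print(summary(fit)), "gamma = 1")
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  plot(fit)
  plot(fit, which = "weighting")
  grDevices::dev.off()
  expect_true(file.exists(pdf_file))
})

test_that("adding indifferent records leaves the estimates unchanged", {
  truth <- risk_truth("EUT", "FP", n_subjects = 30, indifference_rate = 0.08)
  with_ind <- simulate_choices(truth, seed = 911)
  stripped <- choice_data(
    with_ind$records[with_ind$records$response != "INDIFFERENT", ],
    with_ind$designs)
  n_ind <- sum(with_ind$records$response == "INDIFFERENT")
  expect_gt(n_ind, 0)
  f1 <- riskfit(with_ind, "EUT", "FP", compute_vcov = FALSE)
  f2 <- riskfit(stripped, "EUT", "FP", compute_vcov = FALSE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(f1$logLik, f2$logLik + n_ind * log(0.5), tolerance = 1e-6)
})
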