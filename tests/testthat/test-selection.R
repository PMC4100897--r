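test_that("information criteria reproduce the printed table arithmetic", {
  # every printed log-likelihood / criterion combination of the emulated
  # study: EUT k=2, RDU k=3, mixture k=5, n = 1680 choice records
  rows <- rbind(
    data.frame(k = 2, ll = c(-748.614, -738.096, -723.632, -719.187, -748.115),
               aic = c(1501.227, 1480.192, 1451.263, 1442.374, 1500.230),
               bic = c(1512.080, 1491.045, 1462.117, 1453.228, 1511.083)),
    data.frame(k = 3, ll = c(-747.947, -737.252, -702.763, -705.638, -696.506),
               aic = c(1501.894, 1480.504, 1411.525, 1417.276, 1399.013),
               bic = c(1518.173, 1496.784, 1427.805, 1433.556, 1415.293)),
    data.frame(k = 5, ll = c(-713.872, -717.710, -693.940, -696.607, -695.669),
               aic = c(1437.744, 1445.420, 1397.880, 1403.214, 1401.337),
               bic = c(1464.876, 1472.553, 1425.013, 1430.346, 1428.470)))
  for (i in seq_len(nrow(rows))) {
    fit <- fake_fit(rows$ll[i], k = rows$k[i])
    fit$n_obs <- 1680L
    ic <- information_criteria(fit)
    # printed criteria regenerate from printed log-likelihoods up to the
    # rounding of the printed inputs
    expect_lt(abs(ic[["AIC"]] - rows$aic[i]), 0.002)
    expect_lt(abs(ic[["BIC"]] - rows$bic[i]), 0.002)
  }
})

test_that("the Vuong statistic equals its brute-force recomputation", {
  set.seed(402)
  n <- 500
  llf <- log(runif(n, 0.2, 0.9))
  llg <- log(runif(n, 0.2, 0.9))
  f <- fake_fit(llf); g <- fake_fit(llg)
  vt <- vuong_test(f, g)
  m <- llf - llg
  stat <- sum(m) / (sqrt(n) * sqrt(mean((m - mean(m))^2)))
  expect_equal(vt$statistic, stat, tolerance = 1e-12)
  expect_equal(vt$p_value, pnorm(stat, lower.tail = FALSE), tolerance = 1e-12)
  # antisymmetry under swapping the models
  expect_equal(vuong_test(g, f)$statistic, -stat, tolerance = 1e-12)
  # identical likelihood paths are a degenerate comparison
  expect_error(vuong_test(f, f), "degenerate")
  # unbiased-variance and clustered variants still brute-force check
  vt2 <- vuong_test(f, g, variance = "unbiased")
  expect_equal(vt2$statistic, sum(m) / (sqrt(n) * sd(m)), tolerance = 1e-12)
  vt3 <- vuong_test(f, g, cluster = TRUE)
  mc <- as.numeric(rowsum(m, f$prep$cluster_idx))
  expect_equal(vt3$statistic,
               sum(mc) / (sqrt(2) * sqrt(mean((mc - mean(mc))^2))),
               tolerance = 1e-12)
  # the dimension correction vanishes for equal k
  expect_equal(vuong_test(f, g, correction = "aic")$statistic, stat,
               tolerance = 1e-12)
})

test_that("Clarke p-values equal exact binomial tail sums", {
  set.seed(403)
  # 60 positive differences out of 100
  m <- c(runif(60, 0.01, 1), -runif(40, 0.01, 1))
  f <- fake_fit(cumsum(0 * m) + log(0.5) + m) # llf - llg = m by construction
  g <- fake_fit(rep(log(0.5), 100))
  ct <- clarke_test(f, g, "greater")
  expect_equal(ct$statistic, 60)
  expect_equal(ct$p_value, sum(choose(100, 60:100)) / 2^100,
               tolerance = 1e-12)
  expect_equal(round(ct$p_value, 4), 0.0284)
  ctl <- clarke_test(f, g, "less")
  expect_equal(ctl$p_value, sum(choose(100, 0:60)) / 2^100, tolerance = 1e-12)
  # all differences positive
  fp <- fake_fit(rep(log(0.5), 8) + 0.3)
  ct2 <- clarke_test(fp, fake_fit(rep(log(0.5), 8)), "greater")
  expect_equal(ct2$p_value, 0.5^8, tolerance = 1e-15)
  # an even split leaves the upper tail above one half
  ms <- rep(c(0.2, -0.2), 10)
  ct3 <- clarke_test(fake_fit(log(0.5) + ms), fake_fit(rep(log(0.5), 20)),
                     "greater")
  expect_gt(ct3$p_value, 0.5)
  # ties are dropped and reported
  mt <- c(rep(0, 5), rep(0.1, 4), rep(-0.1, 3))
  ct4 <- clarke_test(fake_fit(log(0.5) + mt), fake_fit(rep(log(0.5), 12)))
  expect_equal(ct4$n_effective, 7)
  expect_error(clarke_test(f, f), "ties")
})

test_that("tests refuse fits on different record sets", {
  f <- fake_fit(rep(log(0.5), 10))
  g <- fake_fit(rep(log(0.4), 12))
  expect_error(vuong_test(f, g), "identical record set")
  expect_error(clarke_test(f, g), "identical record set")
})

test_that("grouped cross-validation scores held-out subjects correctly", {
  # with every response indifferent the held-out likelihood is parameter-free
  d <- all_indifferent_dataset(n_subjects = 5)
  fit <- suppressWarnings(riskfit(d, "EUT", "FP", compute_vcov = FALSE))
  os <- osllf_cv(fit)
  expect_equal(os$total, nrow(d$records) * log(0.5), tolerance = 1e-10)
  expect_equal(nrow(os$per_cluster), 5L)
  expect_equal(sum(os$per_cluster$loglik), os$total, tolerance = 1e-10)
  expect_equal(os$n_failed, 0L)

  # on stochastic data the out-of-sample log-likelihood is negative and
  # cannot beat the in-sample one
  sim <- tiny_dataset(n_subjects = 12, seed = 55)
  fit2 <- riskfit(sim, "EUT", "FP", compute_vcov = FALSE)
  os2 <- osllf_cv(fit2)
  expect_lt(os2$total, 0)
  expect_lte(os2$total, fit2$logLik)
  expect_error(osllf_cv(riskfit(tiny_dataset(n_subjects = 2), "EUT", "FP",
                                compute_vcov = FALSE)), "3 clusters")
})

test_that("the battery assembles criteria, tests and best-model flags coherently", {
  sim <- simulate_choices(risk_truth("EUT", "CP", n_subjects = 16), seed = 61)
  rpt <- selection_battery(sim, functionals = "EUT",
                           errors = c("FP", "FL", "CP", "CL", "LUCE"),
                           osllf = FALSE, compute_vcov = FALSE)
  expect_equal(nrow(rpt$criteria), 5L)
  expect_equal(nrow(rpt$vuong), choose(5, 2))
  expect_equal(nrow(rpt$clarke), 2 * choose(5, 2))
  # equal k: AIC ordering must match the log-likelihood ordering
  expect_equal(order(rpt$criteria$AIC), order(-rpt$criteria$logLik))
  expect_equal(sum(rpt$criteria$best_within_AIC), 1L)
  expect_identical(
    rpt$criteria$error[rpt$criteria$best_within_AIC],
    rpt$criteria$error[which.min(rpt$criteria$AIC)])
  expect_output(print(rpt), "Vuong tests")
})

test_that("intransitive Clarke preference cycles are detected", {
  cl <- rbind(
    data.frame(functional = "EUT", model_f = "FP", model_g = "FL",
               direction = "greater", b = 9, n_effective = 10, p_value = 0.01),
    data.frame(functional = "EUT", model_f = "FL", model_g = "CP",
               direction = "greater", b = 9, n_effective = 10, p_value = 0.01),
    data.frame(functional = "EUT", model_f = "FP", model_g = "CP",
               direction = "less", b = 1, n_effective = 10, p_value = 0.01))
  cyc <- riskmle:::clarke_cycles(cl, alpha = 0.05)
  expect_false(is.null(cyc))
  expect_true(nrow(cyc) >= 1)
})
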