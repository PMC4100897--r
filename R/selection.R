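# In-sample and out-of-sample model judging: information criteria, the Vuong
# and Clarke non-nested tests, and grouped (leave-one-subject-out)
# cross-validated out-of-sample log-likelihood.

#' Information criteria of a fitted model
#'
#' \eqn{AIC = 2k - 2\,\mathrm{logL}} and
#' \eqn{BIC = k \ln(n) - 2\,\mathrm{logL}} with \eqn{n} the number of choice
#' records. Thin wrapper over \code{\link[stats]{AIC}} /
#' \code{\link[stats]{BIC}} on the \code{logLik} method.
#'
#' @param fit a \code{\link{riskfit}}.
#' @return Named vector \code{c(AIC, BIC)}.
#' @export
information_criteria <- function(fit) {
  ll <- stats::logLik(fit)
  c(AIC = stats::AIC(ll), BIC = stats::BIC(ll))
}

check_same_records <- function(fit_f, fit_g) {
  if (fit_f$n_obs != fit_g$n_obs ||
      !identical(fit_f$record_key, fit_g$record_key))
    stop("the two fits must be estimated on the identical record set")
}

#' Vuong test for non-nested models
#'
#' Tests the null that two non-nested models are equally close (in
#' Kullback-Leibler distance) to the truth, using the per-record
#' log-likelihood ratios \eqn{m_i = \ell_{f,i} - \ell_{g,i}}. The statistic
#' is \eqn{\sum_i m_i / (\sqrt{n}\, s_m)}; it is asymptotically standard
#' normal under the null, and the reported one-sided p-value is the upper
#' normal tail, so a large positive statistic (small p) favors the first
#' model. \code{variance = "ml"} (default) uses the maximum-likelihood
#' standard deviation of the \eqn{m_i}; \code{"unbiased"} divides by
#' \eqn{n-1}. With \code{cluster = TRUE} the ratios are first summed within
#' subject clusters and the statistic is computed over cluster sums (the
#' per-choice variant is the default). \code{correction} subtracts a
#' degrees-of-freedom penalty from the numerator for models of unequal
#' dimension (\code{"aic"}: \eqn{k_f - k_g}; \code{"bic"}:
#' \eqn{(k_f - k_g)\ln(n)/2}); it vanishes for equal-\eqn{k} comparisons.
#'
#' @param fit_f,fit_g \code{\link{riskfit}} objects on the identical record
#'   set.
#' @param correction \code{"none"} (default), \code{"aic"} or \code{"bic"}.
#' @param variance \code{"ml"} or \code{"unbiased"}.
#' @param cluster compute over within-subject sums instead of individual
#'   choices.
#' @return Object of class \code{"nonnested_test"}: statistic, one-sided
#'   p-value, favored model, effective sample size.
#' @export
vuong_test <- function(fit_f, fit_g, correction = c("none", "aic", "bic"),
                       variance = c("ml", "unbiased"), cluster = FALSE) {
  correction <- match.arg(correction)
  variance <- match.arg(variance)
  check_same_records(fit_f, fit_g)
  m <- fit_f$loglik_i - fit_g$loglik_i
  if (cluster) m <- as.numeric(rowsum(m, fit_f$prep$cluster_idx))
  n <- length(m)
  s2 <- sum((m - mean(m))^2) / if (variance == "ml") n else n - 1L
  if (s2 < 1e-24)
    stop("degenerate comparison: the two models have identical likelihood paths")
  num <- sum(m) - switch(correction,
                         none = 0,
                         aic = fit_f$k - fit_g$k,
                         bic = (fit_f$k - fit_g$k) * log(fit_f$n_obs) / 2)
  stat <- num / (sqrt(n) * sqrt(s2))
  structure(list(
    test = "vuong", statistic = stat,
    p_value = stats::pnorm(stat, lower.tail = FALSE),
    direction = if (stat > 0) "f" else "g",
    n_effective = n,
    model_f = paste(fit_f$functional, fit_f$error, sep = "-"),
    model_g = paste(fit_g$functional, fit_g$error, sep = "-")
  ), class = "nonnested_test")
}

#' Clarke paired sign test for non-nested models
#'
#' A distribution-free alternative to the Vuong test: under the null that
#' the two models are equally good, each per-record log-likelihood
#' difference \eqn{m_i} is positive with probability one half, so the number
#' of positive differences \eqn{B} is Binomial\eqn{(n, 1/2)}. Differences
#' that are zero to within \code{tie_tol} are dropped. The exact one-sided
#' binomial p-value is reported: \code{direction = "greater"} tests whether
#' the first model is better (\eqn{P(\mathrm{Bin} \ge B)}),
#' \code{"less"} the reverse tail.
#'
#' @inheritParams vuong_test
#' @param direction which one-sided alternative to test.
#' @param tie_tol absolute tolerance below which a difference counts as a
#'   tie.
#' @return Object of class \code{"nonnested_test"}.
#' @export
clarke_test <- function(fit_f, fit_g, direction = c("greater", "less"),
                        tie_tol = 1e-12) {
  direction <- match.arg(direction)
  check_same_records(fit_f, fit_g)
  m <- fit_f$loglik_i - fit_g$loglik_i
  m <- m[abs(m) > tie_tol]
  n <- length(m)
  if (n == 0L)
    stop("degenerate comparison: all per-record log-likelihood differences are ties")
  b <- sum(m > 0)
  p <- if (direction == "greater")
    stats::pbinom(b - 1L, n, 0.5, lower.tail = FALSE)
  else
    stats::pbinom(b, n, 0.5)
  structure(list(
    test = "clarke", statistic = b, p_value = p,
    direction = direction, n_effective = n,
    model_f = paste(fit_f$functional, fit_f$error, sep = "-"),
    model_g = paste(fit_g$functional, fit_g$error, sep = "-")
  ), class = "nonnested_test")
}

#' @export
print.nonnested_test <- function(x, ...) {
  if (x$test == "vuong")
    cat(sprintf("Vuong test %s vs %s: z = %.3f, one-sided p = %.4g (n = %d)\n",
                x$model_f, x$model_g, x$statistic, x$p_value, x$n_effective))
  else
    cat(sprintf("Clarke sign test %s vs %s (%s): B = %d of %d, exact p = %.4g\n",
                x$model_f, x$model_g, x$direction, x$statistic, x$n_effective,
                x$p_value))
  invisible(x)
}

#' Grouped cross-validated out-of-sample log-likelihood
#'
#' Leave-one-subject-out cross-validation: for each subject cluster, the
#' model is re-estimated on all remaining subjects (warm-started at the
#' full-sample estimate, with the multi-start schedule as fallback) and the
#' held-out subject's records are scored at that estimate. The OSLLF is the
#' sum of held-out log-likelihoods across subjects.
#'
#' @param fit a converged \code{\link{riskfit}} (at least 3 clusters).
#' @param fallback rerun the multi-start schedule when a warm-started refit
#'   fails.
#' @param include_failed include clusters whose refit did not converge in
#'   the total (they are always reported and flagged).
#' @param control optimizer control overrides for the refits.
#' @return Object of class \code{"osllf"}: \code{total}, per-cluster data
#'   frame, number of failed refits.
#' @export
osllf_cv <- function(fit, fallback = TRUE, include_failed = TRUE,
                     control = list()) {
  stopifnot(inherits(fit, "riskfit"))
  prep <- fit$prep
  if (prep$n_clusters < 3L) stop("grouped cross-validation needs >= 3 clusters")
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  cl_names <- levels(prep$cluster)
  out <- data.frame(cluster = cl_names,
                    n_records = NA_integer_, loglik = NA_real_,
                    converged = NA, stringsAsFactors = FALSE)
  for (c_i in seq_len(prep$n_clusters)) {
    cc <- prep$cluster_counts[, , c_i]
    counts_rest <- prep$counts - cc
    negll <- make_negll(prep$pairs, fit$functional, fit$error, counts_rest)
    run <- tryCatch(stats::optim(fit$theta, negll, method = "BFGS",
                                 control = ctrl),
                    error = function(e) NULL)
    if ((is.null(run) || run$convergence != 0L) && fallback) {
      sub <- choice_data(fit$data$records[prep$cluster_idx != c_i, ,
                                          drop = FALSE], fit$data$designs)
      refit <- tryCatch(riskfit(sub, fit$functional, fit$error,
                                compute_vcov = FALSE, control = control),
                        error = function(e) NULL)
      run <- if (is.null(refit)) NULL else
        list(par = refit$theta, convergence = refit$convergence$code)
    }
    if (is.null(run)) {
      out$converged[c_i] <- FALSE
      out$n_records[c_i] <- sum(cc)
      next
    }
    par_c <- to_natural(run$par, fit$functional, fit$error)
    M <- loglik_matrix(prep$pairs, fit$functional, fit$error, par_c)
    out$loglik[c_i] <- sum(cc * M)
    out$n_records[c_i] <- sum(cc)
    out$converged[c_i] <- run$convergence == 0L
  }
  failed <- which(!out$converged | is.na(out$loglik))
  keep <- if (include_failed) !is.na(out$loglik) else
    out$converged & !is.na(out$loglik)
  structure(list(total = sum(out$loglik[keep]), per_cluster = out,
                 n_failed = length(failed),
                 model = paste(fit$functional, fit$error, sep = "-")),
            class = "osllf")
}

#' @export
print.osllf <- function(x, ...) {
  cat(sprintf("Out-of-sample log-likelihood (%s), leave-one-subject-out: %.3f\n",
              x$model, x$total))
  if (x$n_failed > 0L)
    cat(sprintf("  %d cluster refit(s) flagged as non-converged\n", x$n_failed))
  invisible(x)
}

#' Run the full model-judging battery
#'
#' Fits every requested functional-by-error-specification combination, then
#' judges them: AIC/BIC (and optionally leave-one-subject-out OSLLF) per
#' model, and all pairwise Vuong and two-direction Clarke tests between
#' error specifications within each preference functional (error
#' specifications within a functional are non-nested in each other, whereas
#' EUT/RDU/mixture are nested by construction and are compared with Wald
#' tests instead). Within-functional and overall best models are flagged per
#' criterion, and intransitive Clarke preference cycles are reported when
#' present. Probit and logit Fechner fits of the same functional are
#' cross-checked for local-maximum symptoms (see
#' \code{\link{compare_links}}).
#'
#' @param data a \code{\link{choice_data}}.
#' @param functionals,errors model grid to fit.
#' @param osllf run the (expensive) grouped cross-validation.
#' @param alpha significance level used for the Clarke preference relation
#'   in the cycle report.
#' @param fits optional pre-computed named list of fits
#'   (\code{"EUT-FP"}, ...) to reuse.
#' @param ... passed to \code{\link{riskfit}}.
#' @return Object of class \code{"selection_report"} with components
#'   \code{fits}, \code{criteria}, \code{vuong}, \code{clarke},
#'   \code{cycles}.
#' @export
selection_battery <- function(data,
                              functionals = c("EUT", "RDU", "MIX"),
                              errors = c("FP", "FL", "CP", "CL", "LUCE"),
                              osllf = TRUE, alpha = 0.05, fits = NULL, ...) {
  functionals <- match.arg(functionals, FUNCTIONALS, several.ok = TRUE)
  errors <- vapply(errors, function(e) as.character(error_spec(e)), "")
  if (is.null(fits)) fits <- list()
  for (f in functionals) for (e in errors) {
    key <- paste(f, e, sep = "-")
    if (is.null(fits[[key]]))
      fits[[key]] <- riskfit(data, f, e, ...)
  }
  # probit/logit cross-check within each functional
  for (f in functionals)
    if (all(c("FP", "FL") %in% errors))
      compare_links(fits[[paste0(f, "-FP")]], fits[[paste0(f, "-FL")]])

  crit <- do.call(rbind, lapply(functionals, function(f)
    do.call(rbind, lapply(errors, function(e) {
      fit <- fits[[paste(f, e, sep = "-")]]
      ic <- information_criteria(fit)
      data.frame(functional = f, error = e, k = fit$k,
                 logLik = fit$logLik, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                 OSLLF = NA_real_, stringsAsFactors = FALSE)
    }))))
  if (osllf)
    crit$OSLLF <- vapply(seq_len(nrow(crit)), function(i)
      osllf_cv(fits[[paste(crit$functional[i], crit$error[i], sep = "-")]])$total,
      numeric(1))

  # best-model flags: minimal AIC/BIC, maximal OSLLF
  flag <- function(v, minimize) {
    if (all(is.na(v))) return(rep(FALSE, length(v)))
    if (minimize) v == min(v) else v == max(v)
  }
  for (cr in c("AIC", "BIC", "OSLLF")) {
    minimize <- cr != "OSLLF"
    crit[[paste0("best_within_", cr)]] <- unlist(lapply(
      split(crit[[cr]], crit$functional)[unique(crit$functional)],
      flag, minimize = minimize))
    crit[[paste0("best_overall_", cr)]] <- flag(crit[[cr]], minimize)
  }

  vuong <- list(); clarke <- list()
  if (length(errors) >= 2L) {
    pairs <- utils::combn(errors, 2L, simplify = FALSE)
    for (f in functionals) for (pr in pairs) {
      ff <- fits[[paste(f, pr[1L], sep = "-")]]
      fg <- fits[[paste(f, pr[2L], sep = "-")]]
      vt <- vuong_test(ff, fg)
      vuong[[length(vuong) + 1L]] <- data.frame(
        functional = f, model_f = pr[1L], model_g = pr[2L],
        statistic = vt$statistic, p_value = vt$p_value,
        stringsAsFactors = FALSE)
      for (dir in c("greater", "less")) {
        ct <- clarke_test(ff, fg, direction = dir)
        clarke[[length(clarke) + 1L]] <- data.frame(
          functional = f, model_f = pr[1L], model_g = pr[2L],
          direction = dir, b = ct$statistic, n_effective = ct$n_effective,
          p_value = ct$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  vuong <- if (length(vuong)) do.call(rbind, vuong) else NULL
  clarke <- if (length(clarke)) do.call(rbind, clarke) else NULL

  structure(list(fits = fits, criteria = crit, vuong = vuong, clarke = clarke,
                 cycles = clarke_cycles(clarke, alpha), alpha = alpha),
            class = "selection_report")
}

# detect intransitive strict-preference cycles in the Clarke relation
# within each functional: x beats y when the one-sided test of "x better
# than y" rejects at alpha
clarke_cycles <- function(clarke, alpha = 0.05) {
  if (is.null(clarke)) return(NULL)
  out <- list()
  for (f in unique(clarke$functional)) {
    cf <- clarke[clarke$functional == f & clarke$direction == "greater", ]
    cr <- clarke[clarke$functional == f & clarke$direction == "less", ]
    models <- unique(c(cf$model_f, cf$model_g))
    beats <- matrix(FALSE, length(models), length(models),
                    dimnames = list(models, models))
    for (i in seq_len(nrow(cf)))
      beats[cf$model_f[i], cf$model_g[i]] <- cf$p_value[i] < alpha
    for (i in seq_len(nrow(cr)))
      beats[cr$model_g[i], cr$model_f[i]] <- cr$p_value[i] < alpha
    for (a in models) for (b in models) for (d in models)
      if (beats[a, b] && beats[b, d] && beats[d, a])
        out[[length(out) + 1L]] <- data.frame(functional = f, a = a, b = b,
                                              c = d, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.selection_report <- function(x, digits = 3, ...) {
  cat("Model-judging battery\n=====================\n")
  crit <- x$criteria
  disp <- crit[c("functional", "error", "k", "logLik", "AIC", "BIC", "OSLLF")]
  mark <- function(v, w, o) paste0(formatC(v, format = "f", digits = digits),
                                  ifelse(w, "*", ""), ifelse(o, "*", ""))
  disp$AIC <- mark(crit$AIC, crit$best_within_AIC, crit$best_overall_AIC)
  disp$BIC <- mark(crit$BIC, crit$best_within_BIC, crit$best_overall_BIC)
  if (!all(is.na(crit$OSLLF)))
    disp$OSLLF <- mark(crit$OSLLF, crit$best_within_OSLLF,
                       crit$best_overall_OSLLF)
  print(disp, row.names = FALSE)
  cat("(* best within functional, ** best overall)\n")
  if (!is.null(x$vuong)) {
    cat("\nVuong tests (positive statistic favors model_f):\n")
    print(x$vuong, row.names = FALSE, digits = digits)
  }
  if (!is.null(x$clarke)) {
    cat("\nClarke sign tests (exact binomial, one-sided):\n")
    print(x$clarke, row.names = FALSE, digits = digits)
  }
  if (!is.null(x$cycles)) {
    cat("\nIntransitive Clarke preference cycles detected:\n")
    print(x$cycles, row.names = FALSE)
  }
  invisible(x)
}
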