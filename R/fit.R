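#' Fit a risky-choice model by maximum likelihood
#'
#' Estimates a preference functional (expected utility, rank-dependent
#' utility, or a choice-level EUT/RDU mixture) combined with one of five
#' stochastic error specifications (see \code{\link{error_spec}}) on a
#' lottery-choice dataset. The likelihood is maximized on an unconstrained
#' internal scale (\eqn{\mu = e^m}, \eqn{\gamma = e^g},
#' \eqn{\pi_{EUT} = \mathrm{logistic}(q)}, \eqn{r} free except
#' \eqn{r = 0.999 - e^s} under the Luce error) over a multi-start schedule:
#' every start on the grid is screened by its log-likelihood and the
#' \code{n_refine} most promising are polished with BFGS; the best local
#' optimum wins, with ties (within 1e-6) broken by the first start.
#' Cluster-robust (sandwich) standard errors, clustered on
#' \code{subject_id}, are mapped to the natural scale by the delta method.
#'
#' @param data a \code{\link{choice_data}}.
#' @param functional \code{"EUT"}, \code{"RDU"} or \code{"MIX"}.
#' @param error \code{"FP"}, \code{"FL"}, \code{"CP"}, \code{"CL"} or
#'   \code{"LUCE"}.
#' @param starts optional data frame / list of named natural-scale starting
#'   vectors; defaults to the built-in grid
#'   (\eqn{r \in \{-1,-.5,0,.5,.9\}}, \eqn{\gamma \in \{.5,1,2\}},
#'   \eqn{\mu \in \{.1,.5,1\}}, \eqn{\pi \in \{.2,.5,.8\}}, restricted to
#'   the functional's free parameters).
#' @param n_refine number of screened starts polished with BFGS (default 5
#'   for EUT, 10 for RDU, 32 for the mixture); refined starts are forced to
#'   be mutually distant on the internal scale so that several basins of
#'   attraction are explored. The defaults reproduce the optimum of
#'   refining every grid start on mixture test problems at a fraction of
#'   the cost.
#' @param control list merged into \code{\link[stats]{optim}} control
#'   (defaults: \code{maxit = 500}, \code{reltol = 1e-10}).
#' @param compute_vcov compute the cluster-robust covariance (disable for
#'   speed inside large Monte Carlo loops).
#' @return An object of class \code{"riskfit"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{logLik}, \code{nobs},
#'   \code{predict}, \code{residuals}, \code{simulate} and \code{plot}.
#' @examples
#' sim <- simulate_choices(risk_truth("EUT", "FP", n_subjects = 20), seed = 1)
#' fit <- riskfit(sim, "EUT", "FP")
#' coef(fit)
#' @export
riskfit <- function(data, functional = c("EUT", "RDU", "MIX"),
                    error = c("FP", "FL", "CP", "CL", "LUCE"),
                    starts = NULL, n_refine = NULL, control = list(),
                    compute_vcov = TRUE) {
  cl <- match.call()
  functional <- match.arg(functional)
  error <- as.character(error_spec(match.arg(error)))
  prep <- prep_choice_data(data)
  if (prep$n_clusters < 2L)
    stop("need at least 2 subject clusters for cluster-robust estimation")

  start_df <- if (is.null(starts)) default_starts(functional) else {
    as.data.frame(starts)
  }
  miss <- setdiff(par_names(functional), names(start_df))
  if (length(miss))
    stop("starts are missing parameter(s): ", paste(miss, collapse = ", "))
  theta0 <- lapply(seq_len(nrow(start_df)), function(i)
    to_internal(as.list(start_df[i, , drop = FALSE]), functional, error))

  negll <- make_negll(prep$pairs, functional, error, prep$counts)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  if (is.null(n_refine))
    n_refine <- switch(functional, EUT = 5L, RDU = 10L, MIX = 32L)

  # screen every grid start by its log-likelihood, then polish a
  # well-separated subset with BFGS: starts are taken in screening order but
  # a start too close (internal scale) to an already-selected one is skipped,
  # so the refined set covers distinct basins of attraction
  screen <- vapply(theta0, negll, numeric(1))
  ord <- order(screen)
  ord <- ord[is.finite(screen[ord]) & screen[ord] < 1e12]
  if (!length(ord))
    stop("no admissible starting value: likelihood not finite anywhere on the grid")
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) >= n_refine) break
    if (!length(keep) ||
        min(vapply(keep, function(j)
          sqrt(sum((theta0[[i]] - theta0[[j]])^2)), numeric(1))) > 0.75)
      keep <- c(keep, i)
  }

  runs <- lapply(keep, function(i) {
    tryCatch(stats::optim(theta0[[i]], negll, method = "BFGS", control = ctrl),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("optimization failed to converge from every refined start")
  vals <- vapply(runs[ok], `[[`, numeric(1), "value")
  # first start wins ties (within 1e-6)
  best <- which(ok)[which(vals <= min(vals) + 1e-6)[1L]]
  opt <- runs[[best]]
  # restart once from the winner: a fresh BFGS from the solution costs little
  # and polishes stalled line searches
  opt2 <- tryCatch(stats::optim(opt$par, negll, method = "BFGS", control = ctrl),
                   error = function(e) NULL)
  if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
  theta <- opt$par
  par_nat <- to_natural(theta, functional, error)

  llvec <- record_loglik_vec(prep, functional, error, par_nat)
  M <- loglik_matrix(prep$pairs, functional, error, par_nat)
  n_clipped <- attr(M, "n_clipped")

  boundary <- character(0)
  if (functional == "MIX" &&
      (par_nat[["pi_eut"]] < 1e-4 || par_nat[["pi_eut"]] > 1 - 1e-4))
    boundary <- c(boundary, "pi_eut")
  if (par_nat[["mu"]] < 1e-6 || par_nat[["mu"]] > 1e3)
    boundary <- c(boundary, "mu")
  r_vals <- par_nat[grep("^r", names(par_nat))]
  if (any(abs(r_vals) > 10) || (error == "LUCE" && any(r_vals > R_CAP - 1e-4)))
    boundary <- c(boundary, "r")
  if (length(boundary))
    warning("estimate at or near the parameter-space boundary (",
            paste(boundary, collapse = ", "),
            "); no interior optimum may exist for these data")

  fit <- structure(list(
    call = cl, functional = functional, error = error,
    coefficients = par_nat, theta = theta,
    logLik = sum(llvec), loglik_i = llvec,
    n_obs = prep$n_obs, n_clusters = prep$n_clusters,
    k = length(theta), prep = prep, data = data,
    record_key = paste(data$records$subject_id, data$records$task_id,
                       data$records$row_index, sep = "\r"),
    convergence = list(
      code = opt$convergence, n_starts = length(theta0),
      n_refined = length(keep), best_start = keep[best],
      counts = opt$counts, boundary = boundary, n_clipped = n_clipped)
  ), class = "riskfit")

  if (compute_vcov) {
    vc <- cluster_vcov(fit)
    fit$vcov <- vc$natural
    fit$vcov_internal <- vc$internal
    fit$hessian_condition <- vc$kappa
  }
  fit
}

default_starts <- function(functional) {
  r_grid <- c(-1, -0.5, 0, 0.5, 0.9)
  g_grid <- c(0.5, 1, 2)
  mu_grid <- c(0.1, 0.5, 1)
  pi_grid <- c(0.2, 0.5, 0.8)
  switch(functional,
         EUT = expand.grid(r = r_grid, mu = mu_grid),
         RDU = expand.grid(r = r_grid, gamma = g_grid, mu = mu_grid),
         MIX = expand.grid(r_eut = r_grid, r_rdu = r_grid, gamma = g_grid,
                           mu = mu_grid, pi_eut = pi_grid))
}

# ---- cluster-robust sandwich covariance ------------------------------------

fd_step <- function(theta) 1e-5 * (1 + abs(theta))

# central finite-difference Hessian
fd_hessian <- function(fn, theta) {
  k <- length(theta)
  h <- fd_step(theta)
  H <- matrix(0, k, k)
  f0 <- fn(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

# n x k matrix of per-record score contributions by central differences
fd_scores <- function(prep, functional, error, theta) {
  k <- length(theta)
  h <- fd_step(theta)
  S <- matrix(0, prep$n_obs, k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    up <- record_loglik_vec(prep, functional, error,
                            to_natural(theta + ei, functional, error))
    dn <- record_loglik_vec(prep, functional, error,
                            to_natural(theta - ei, functional, error))
    S[, i] <- (up - dn) / (2 * h[i])
  }
  S
}

#' Cluster-robust sandwich covariance of a fitted model
#'
#' Computes \eqn{A^{-1} B A^{-1}} where \eqn{A} is the observed information
#' (finite-difference Hessian of the negative log-likelihood at the MLE) and
#' \eqn{B} is the sum over subject clusters of outer products of within-
#' cluster score sums, scaled by the small-sample factor \eqn{C/(C-1)}
#' (\eqn{C} clusters). With singleton clusters this reduces to the ordinary
#' heteroskedasticity-robust sandwich with factor \eqn{n/(n-1)}. The
#' internal-scale covariance is mapped to the natural reporting scale by the
#' delta method.
#'
#' @param fit a \code{\link{riskfit}} object.
#' @return List with elements \code{natural} and \code{internal} (covariance
#'   matrices) and \code{kappa} (Hessian condition number).
#' @export
cluster_vcov <- function(fit) {
  stopifnot(inherits(fit, "riskfit"))
  prep <- fit$prep
  negll <- make_negll(prep$pairs, fit$functional, fit$error, prep$counts)
  A <- fd_hessian(negll, fit$theta)
  kappa_A <- kappa(A)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop(sprintf("singular Hessian at the optimum (condition number %.3g)", kappa_A)))
  S <- fd_scores(prep, fit$functional, fit$error, fit$theta)
  Sc <- rowsum(S, fit$prep$cluster_idx)
  C <- nrow(Sc)
  B <- crossprod(Sc) * C / (C - 1)
  Vint <- Ainv %*% B %*% Ainv
  Vint <- (Vint + t(Vint)) / 2
  J <- natural_jacobian(fit$theta, fit$functional, fit$error)
  Vnat <- J %*% Vint %*% t(J)
  dimnames(Vnat) <- list(names(fit$coefficients), names(fit$coefficients))
  list(natural = Vnat, internal = Vint, kappa = kappa_A)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
coef.riskfit <- function(object, ...) object$coefficients

#' @export
vcov.riskfit <- function(object, scale = c("natural", "internal"), ...) {
  scale <- match.arg(scale)
  v <- if (scale == "natural") object$vcov else object$vcov_internal
  if (is.null(v)) stop("fit was run with compute_vcov = FALSE")
  v
}

#' @export
logLik.riskfit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.riskfit <- function(object, ...) object$n_obs

#' @export
print.riskfit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model, %s error: %d records, %d subjects\n",
              x$functional, x$error, x$n_obs, x$n_clusters))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood %.3f (k = %d), AIC %.3f\n",
              x$logLik, x$k, 2 * x$k - 2 * x$logLik))
  if (length(x$convergence$boundary))
    cat("note: boundary estimate for",
        paste(x$convergence$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.riskfit <- function(object, level = 0.95, ...) {
  est <- object$coefficients
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else rep(NA_real_, length(est))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(estimate = est, std_error = se,
               ci_lower = est - z * se, ci_upper = est + z * se)
  wald <- list()
  if (object$functional %in% c("RDU", "MIX") && !is.null(object$vcov))
    wald$`gamma = 1` <- wald_test(object, c(gamma = 1))
  if (object$functional == "MIX" && !is.null(object$vcov)) {
    wald$`pi_eut = 1 (collapse to EUT)` <- wald_test(object, c(pi_eut = 1))
    wald$`pi_eut = 0 (collapse to RDU)` <- wald_test(object, c(pi_eut = 0))
    wald$`pi_eut = 0 & gamma = 1` <- wald_test(object, c(pi_eut = 0, gamma = 1))
  }
  structure(list(functional = object$functional, error = object$error,
                 coefficients = tab, logLik = object$logLik, k = object$k,
                 n_obs = object$n_obs, n_clusters = object$n_clusters,
                 wald = wald, convergence = object$convergence,
                 aic = 2 * object$k - 2 * object$logLik,
                 bic = object$k * log(object$n_obs) - 2 * object$logLik),
            class = "summary.riskfit")
}

#' @export
print.summary.riskfit <- function(x, digits = 4, ...) {
  cat(sprintf("%s preference functional with %s error\n", x$functional, x$error))
  cat(sprintf("%d records in %d subject clusters; cluster-robust SEs\n",
              x$n_obs, x$n_clusters))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood %.3f  AIC %.3f  BIC %.3f\n", x$logLik, x$aic, x$bic))
  if (length(x$wald)) {
    cat("Wald tests:\n")
    for (nm in names(x$wald))
      cat(sprintf("  %-28s W = %8.3f  df = %d  p = %.4f\n", nm,
                  x$wald[[nm]]$statistic, x$wald[[nm]]$df, x$wald[[nm]]$p_value))
  }
  invisible(x)
}

#' Predicted choice probabilities
#'
#' @param object a \code{\link{riskfit}}.
#' @param newdata optional \code{\link{choice_data}}; defaults to the fitting
#'   data.
#' @param type \code{"prob"} for per-record \eqn{P(B)} (marginal over the
#'   mixture for \code{"MIX"}), \code{"loglik"} for per-record
#'   log-likelihood contributions.
#' @param ... unused.
#' @return Numeric vector in record order.
#' @export
predict.riskfit <- function(object, newdata = NULL, type = c("prob", "loglik"),
                            ...) {
  type <- match.arg(type)
  prep <- if (is.null(newdata)) object$prep else prep_choice_data(newdata)
  if (type == "loglik")
    return(record_loglik_vec(prep, object$functional, object$error,
                             object$coefficients))
  L <- lik_matrix(prep$pairs, object$functional, object$error,
                  object$coefficients)
  L[prep$pair_idx, RESP_B]
}

#' @export
residuals.riskfit <- function(object, ...) {
  pb <- predict(object, type = "prob")
  y <- c(0, 1, 0.5)[object$prep$resp_idx]
  y - pb
}

#' Simulate datasets from a fitted model
#'
#' Draws new response sets for the fitted dataset's subjects and designs at
#' the estimated parameters (parametric bootstrap style).
#'
#' @param object a \code{\link{riskfit}}.
#' @param nsim number of datasets.
#' @param seed integer seed (optional).
#' @param ... unused.
#' @return A list of \code{\link{choice_data}} objects of length \code{nsim}.
#' @export
simulate.riskfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  truth <- risk_truth(functional = object$functional, error = object$error,
                      params = object$coefficients,
                      n_subjects = object$n_clusters,
                      designs = object$data$designs)
  lapply(seq_len(nsim), function(i) simulate_choices(truth))
}

#' Diagnostic plot of a fitted risky-choice model
#'
#' \code{which = "fit"} plots the empirical share of B choices per price-list
#' row (indifference counted as one half) against the fitted choice
#' probability, one panel curve per task. \code{which = "weighting"} draws
#' the estimated probability-weighting function against the identity
#' (meaningful for RDU and mixture fits).
#'
#' @param x a \code{\link{riskfit}}.
#' @param which \code{"fit"} or \code{"weighting"}.
#' @param ... passed to plotting primitives.
#' @export
plot.riskfit <- function(x, which = c("fit", "weighting"), ...) {
  which <- match.arg(which)
  if (which == "weighting") {
    if (x$functional == "EUT")
      stop("no probability weighting under EUT; use which = 'fit'")
    g <- x$coefficients[["gamma"]]
    p <- seq(0, 1, length.out = 201)
    graphics::plot(p, tk_weight(p, g), type = "l", xlab = "p",
                   ylab = "w(p)", main = sprintf("Weighting (gamma = %.3f)", g),
                   ...)
    graphics::abline(0, 1, lty = 2)
    return(invisible(x))
  }
  prep <- x$prep
  pb_hat <- lik_matrix(prep$pairs, x$functional, x$error,
                       x$coefficients)[, RESP_B]
  y <- c(0, 1, 0.5)[prep$resp_idx]
  emp <- rowsum(y, prep$pair_idx) / tabulate(prep$pair_idx, prep$n_pairs)
  info <- prep$pair_info
  graphics::plot(info$row_index, emp, pch = as.integer(factor(info$task_id)),
                 xlab = "price-list row", ylab = "share choosing B",
                 ylim = c(0, 1), main = sprintf("%s-%s fit", x$functional, x$error),
                 ...)
  for (tid in unique(info$task_id)) {
    sel <- info$task_id == tid
    graphics::lines(info$row_index[sel], pb_hat[sel], lty = 1)
  }
  invisible(x)
}

# ---- Wald tests ------------------------------------------------------------

#' Wald test of parameter restrictions
#'
#' Quadratic-form Wald test of point restrictions on natural-scale
#' parameters, referred to a chi-squared distribution with degrees of
#' freedom equal to the number of restrictions. For a fitted model pass the
#' restrictions as a named vector, e.g. \code{c(gamma = 1)} or
#' \code{c(pi_eut = 0, gamma = 1)}. When a mixture-probability restriction
#' sits on the boundary of the parameter space (\eqn{\pi = 0} or 1) the
#' chi-squared reference is nonstandard; the test is still reported in that
#' conventional form, flagged via the \code{boundary} field.
#'
#' @param object a \code{\link{riskfit}} or a named estimate vector.
#' @param hypothesis named numeric vector of hypothesized values.
#' @param vcov covariance matrix (only for the default method).
#' @param ... unused.
#' @return List of class \code{"wald_test"}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{hypothesis}, \code{boundary}.
#' @examples
#' wald_test(c(gamma = 0.908), c(gamma = 1),
#'           vcov = matrix(0.061^2, dimnames = list("gamma", "gamma")))
#' @export
wald_test <- function(object, hypothesis, ...) UseMethod("wald_test")

#' @rdname wald_test
#' @export
wald_test.riskfit <- function(object, hypothesis, ...) {
  bad <- setdiff(names(hypothesis), names(object$coefficients))
  if (length(bad))
    stop("constraint on parameter(s) absent from the ", object$functional,
         " functional: ", paste(bad, collapse = ", "))
  wald_test.default(object$coefficients, hypothesis, vcov = vcov(object))
}

#' @rdname wald_test
#' @export
wald_test.default <- function(object, hypothesis, vcov, ...) {
  if (is.null(names(hypothesis)) || is.null(names(object)))
    stop("`object` and `hypothesis` must be named")
  bad <- setdiff(names(hypothesis), names(object))
  if (length(bad))
    stop("constraint on parameter(s) absent from the estimates: ",
         paste(bad, collapse = ", "))
  nm <- names(hypothesis)
  d <- object[nm] - hypothesis
  V <- vcov[nm, nm, drop = FALSE]
  W <- drop(t(d) %*% solve(V) %*% d)
  df <- length(d)
  boundary <- any(nm == "pi_eut" & (hypothesis <= 0 | hypothesis >= 1))
  structure(list(statistic = W, df = df,
                 p_value = stats::pchisq(W, df, lower.tail = FALSE),
                 hypothesis = hypothesis, boundary = boundary),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald test of %s: W = %.4f, df = %d, p = %.4g\n",
              paste(names(x$hypothesis), "=", x$hypothesis, collapse = ", "),
              x$statistic, x$df, x$p_value))
  if (x$boundary)
    cat("note: restriction on the boundary of the parameter space;\n",
        "the chi-squared reference is nonstandard there\n")
  invisible(x)
}

#' Probit/logit cross-check of two Fechner fits
#'
#' Estimates from probit and logit links should agree up to the link scale;
#' strikingly different risk coefficients between the two are evidence that
#' a local maximum was found. Warns when the risk coefficients differ by
#' more than \code{tol}.
#'
#' @param fit_probit,fit_logit \code{\link{riskfit}} objects for the same
#'   functional with probit- and logit-link errors.
#' @param tol maximal acceptable difference in \eqn{r} (or \eqn{r_{EUT}}).
#' @return Invisibly, the absolute difference in the leading risk
#'   coefficient.
#' @export
compare_links <- function(fit_probit, fit_logit, tol = 0.1) {
  r1 <- coef(fit_probit)[[1L]]
  r2 <- coef(fit_logit)[[1L]]
  d <- abs(r1 - r2)
  if (is.finite(d) && d > tol)
    warning(sprintf(paste0("probit and logit links disagree in the risk ",
                           "coefficient (|%.3f - %.3f| > %.2f): possible ",
                           "local maximum"), r1, r2, tol))
  invisible(d)
}
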