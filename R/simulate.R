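# Forward simulation of lottery-choice datasets and Monte Carlo
# parameter-recovery studies.

# Published-style parameter presets for each functional x error spec
# combination: the estimates of the two-scale Holt-Laury experiment the
# package emulates, used as default simulation truths.
PRESET_PARAMS <- list(
  EUT = list(
    FP   = c(r = 0.682, mu = 0.428),
    FL   = c(r = 0.677, mu = 0.231),
    CP   = c(r = 0.580, mu = 0.242),
    CL   = c(r = 0.598, mu = 0.138),
    LUCE = c(r = 0.603, mu = 0.172)),
  RDU = list(
    FP   = c(r = 0.650, gamma = 0.908, mu = 0.378),
    FL   = c(r = 0.638, gamma = 0.900, mu = 0.199),
    CP   = c(r = -0.038, gamma = 3.345, mu = 0.274),
    CL   = c(r = -0.016, gamma = 3.275, mu = 0.163),
    LUCE = c(r = -0.500, gamma = 0.373, mu = 0.148)),
  MIX = list(
    FP   = c(r_eut = -0.633, r_rdu = 0.672, gamma = 0.881, mu = 0.229,
             pi_eut = 0.142),
    FL   = c(r_eut = -0.832, r_rdu = 0.650, gamma = 0.867, mu = 0.132,
             pi_eut = 0.124),
    CP   = c(r_eut = 0.409, r_rdu = -0.291, gamma = 0.391, mu = 0.106,
             pi_eut = 0.316),
    CL   = c(r_eut = 0.084, r_rdu = 0.059, gamma = 0.508, mu = 0.071,
             pi_eut = 0.064),
    LUCE = c(r_eut = 0.170, r_rdu = -0.806, gamma = 0.314, mu = 0.146,
             pi_eut = 0.186))
)

#' Preset simulation parameters
#'
#' Returns the built-in parameter vector for a functional / error
#' specification pair. The mixture contextual-probit preset
#' (\code{r_eut = 0.409, r_rdu = -0.291, gamma = 0.391, mu = 0.106,
#' pi_eut = 0.316}) is the package's default simulation truth.
#'
#' @param functional \code{"EUT"}, \code{"RDU"} or \code{"MIX"}.
#' @param error error specification code.
#' @return Named numeric parameter vector on the natural scale.
#' @export
preset_params <- function(functional = c("EUT", "RDU", "MIX"), error = "CP") {
  functional <- match.arg(functional)
  error <- as.character(error_spec(error))
  PRESET_PARAMS[[functional]][[error]]
}

#' Define a simulation truth
#'
#' Bundles everything the forward simulator needs: the generating model
#' (functional + error specification + parameters), the number of subjects,
#' the price-list designs, and an exogenous rate of expressed indifference.
#' Defaults emulate the study conditions the package targets: 84 subjects
#' facing the two-scale Holt-Laury lists (20 choices each), generated from
#' the mixture contextual-probit preset, with no indifference (an
#' indifferent response carries no parametric information in the likelihood,
#' so it is injected exogenously rather than modelled).
#'
#' @param functional,error generating model.
#' @param params named natural-scale parameter vector; \code{NULL} uses
#'   \code{\link{preset_params}}.
#' @param n_subjects number of simulated subjects (\eqn{\ge 2}).
#' @param designs design registry (task id to \code{\link{mpl_design}}).
#' @param indifference_rate probability, in \eqn{[0, 0.2]}, that a response
#'   is overwritten with \code{"INDIFFERENT"}.
#' @param subject_class diagnostic option for the mixture: draw the latent
#'   EUT/RDU class once per subject instead of once per choice. The default
#'   \code{FALSE} matches the choice-level mixture the estimator assumes.
#' @return Object of class \code{"risk_truth"}.
#' @export
risk_truth <- function(functional = c("MIX", "EUT", "RDU"), error = "CP",
                       params = NULL, n_subjects = 84,
                       designs = hl_registry(), indifference_rate = 0,
                       subject_class = FALSE) {
  functional <- match.arg(functional)
  error <- as.character(error_spec(error))
  if (is.null(params)) params <- preset_params(functional, error)
  check_par(params, functional)
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("`n_subjects` must be at least 2")
  if (indifference_rate < 0 || indifference_rate > 0.2)
    stop("`indifference_rate` must lie in [0, 0.2]")
  structure(list(functional = functional, error = error,
                 params = params[par_names(functional)],
                 n_subjects = as.integer(n_subjects), designs = designs,
                 indifference_rate = indifference_rate,
                 subject_class = isTRUE(subject_class)),
            class = "risk_truth")
}

#' @export
print.risk_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %s-%s, %d subjects x %d choices, indifference rate %g\n",
              x$functional, x$error, x$n_subjects,
              sum(vapply(x$designs, function(d) length(d$pairs), numeric(1))),
              x$indifference_rate))
  print(x$params)
  invisible(x)
}

#' Simulate a lottery-choice dataset
#'
#' Forward-simulates responses from a \code{\link{risk_truth}}: for every
#' subject and price-list row the generating choice probability
#' \eqn{P(B)} is computed under the truth (for the mixture, the record's
#' latent EUT/RDU class is first drawn with probability \eqn{\pi_{EUT}} per
#' choice), the response is drawn Bernoulli, and with probability
#' \code{indifference_rate} it is overwritten with \code{"INDIFFERENT"}.
#' Fully reproducible given \code{seed}.
#'
#' @param truth a \code{\link{risk_truth}}.
#' @param seed integer seed; \code{NULL} continues the current RNG stream.
#' @return A \code{\link{choice_data}} with the truth stored in
#'   \code{attr(, "truth")}.
#' @examples
#' sim <- simulate_choices(risk_truth("EUT", "FP", n_subjects = 10), seed = 1)
#' summary(sim)
#' @export
simulate_choices <- function(truth = risk_truth(), seed = NULL) {
  stopifnot(inherits(truth, "risk_truth"))
  if (!is.null(seed)) set.seed(seed)
  tasks <- names(truth$designs)
  grid <- do.call(rbind, lapply(tasks, function(tid)
    data.frame(task_id = tid,
               row_index = seq_along(truth$designs[[tid]]$pairs),
               stringsAsFactors = FALSE)))
  n_rows <- nrow(grid)
  subj <- sprintf("S%03d", seq_len(truth$n_subjects))

  # per-pair generating probabilities (identical across subjects)
  P <- pair_table_from_designs(truth$designs, grid)
  par <- truth$params
  if (truth$functional == "MIX") {
    pbE <- pair_prob_b(P, truth$error, par[["r_eut"]], 1, par[["mu"]])
    pbR <- pair_prob_b(P, truth$error, par[["r_rdu"]], par[["gamma"]],
                       par[["mu"]])
  } else {
    g <- if (truth$functional == "EUT") 1 else par[["gamma"]]
    pb <- pair_prob_b(P, truth$error, par[["r"]], g, par[["mu"]])
  }

  rec <- data.frame(
    subject_id = rep(subj, each = n_rows),
    task_id = rep(grid$task_id, truth$n_subjects),
    row_index = rep(grid$row_index, truth$n_subjects),
    stringsAsFactors = FALSE)
  n <- nrow(rec)
  pair_of <- rep(seq_len(n_rows), truth$n_subjects)

  if (truth$functional == "MIX") {
    is_eut <- if (truth$subject_class)
      rep(stats::runif(truth$n_subjects) < par[["pi_eut"]], each = n_rows)
    else stats::runif(n) < par[["pi_eut"]]
    p_b <- ifelse(is_eut, pbE[pair_of], pbR[pair_of])
  } else {
    p_b <- pb[pair_of]
  }
  resp <- ifelse(stats::runif(n) < p_b, "B", "A")
  if (truth$indifference_rate > 0)
    resp[stats::runif(n) < truth$indifference_rate] <- "INDIFFERENT"
  rec$response <- resp

  out <- choice_data(rec, truth$designs)
  attr(out, "truth") <- truth
  out
}

# build the likelihood pair table directly from a design registry
pair_table_from_designs <- function(designs, grid) {
  cols <- c("pa_best", "xa_best", "xa_worst", "pb_best", "xb_best", "xb_worst",
            "x_max", "x_min")
  P <- matrix(NA_real_, nrow(grid), length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_len(nrow(grid))) {
    pr <- designs[[grid$task_id[i]]]$pairs[[grid$row_index[i]]]
    oa <- order(pr$option_a$prizes, decreasing = TRUE)
    ob <- order(pr$option_b$prizes, decreasing = TRUE)
    prizes <- c(pr$option_a$prizes, pr$option_b$prizes)
    P[i, ] <- c(pr$option_a$probs[oa[1L]], pr$option_a$prizes[oa],
                pr$option_b$probs[ob[1L]], pr$option_b$prizes[ob],
                max(prizes), min(prizes))
  }
  P
}

#' Monte Carlo parameter-recovery study
#'
#' Repeatedly simulates datasets from a truth, refits the generating model,
#' and summarizes estimator performance per parameter: mean estimate, bias,
#' Monte Carlo standard error of the mean, RMSE, and coverage of the
#' cluster-robust 95\% confidence interval. Replication-level convergence
#' problems (optimizer failure, boundary estimates) are counted and
#' reported, never silently dropped from the report.
#'
#' @param truth a \code{\link{risk_truth}}.
#' @param n_reps number of replications (\eqn{\ge 1}; meaningful summaries
#'   need tens of replications).
#' @param seed integer seed; replication \eqn{j} uses \code{seed + j}.
#' @param level confidence level for the coverage column.
#' @param fit_args list of extra arguments to \code{\link{riskfit}}.
#' @return Object of class \code{"recovery_study"}: \code{summary} data
#'   frame, raw estimate and SE matrices, convergence bookkeeping.
#' @export
recovery_study <- function(truth, n_reps = 50, seed = 1L, level = 0.95,
                           fit_args = list()) {
  stopifnot(inherits(truth, "risk_truth"))
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be a positive integer")
  n_reps <- as.integer(n_reps)
  pn <- par_names(truth$functional)
  est <- se <- matrix(NA_real_, n_reps, length(pn), dimnames = list(NULL, pn))
  boundary <- failed <- logical(n_reps)
  for (j in seq_len(n_reps)) {
    sim <- simulate_choices(truth, seed = seed + j)
    fit <- tryCatch(
      withCallingHandlers(
        do.call(riskfit, c(list(data = sim, functional = truth$functional,
                                error = truth$error), fit_args)),
        warning = function(w) {
          boundary[j] <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) { failed[j] <- TRUE; next }
    est[j, ] <- coef(fit)[pn]
    if (!is.null(fit$vcov)) se[j, ] <- sqrt(diag(fit$vcov))[pn]
  }
  ok <- !failed
  z <- stats::qnorm(1 - (1 - level) / 2)
  smry <- do.call(rbind, lapply(pn, function(p) {
    e <- est[ok, p]; s <- se[ok, p]
    tr <- truth$params[[p]]
    data.frame(parameter = p, truth = tr, mean = mean(e),
               bias = mean(e) - tr, mcse = stats::sd(e) / sqrt(sum(ok)),
               rmse = sqrt(mean((e - tr)^2)),
               coverage = mean(abs(e - tr) <= z * s, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = smry, estimates = est, std_errors = se,
                 truth = truth, n_reps = n_reps,
                 n_failed = sum(failed), n_boundary = sum(boundary),
                 level = level, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery: %s-%s truth, %d replications (%d failed, %d boundary-flagged)\n",
              x$truth$functional, x$truth$error, x$n_reps, x$n_failed,
              x$n_boundary))
  print(cbind(x$summary[1], round(x$summary[-1], digits)), row.names = FALSE)
  invisible(x)
}
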