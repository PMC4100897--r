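# Orchestration entry points: simulate / fit / judge pipelines that write
# their artifacts (CSV / JSON / text report + a reproducibility manifest) to
# an output directory. These are the programmatic equivalents of a
# command-line workbench; each takes a flat configuration list or the path
# to a DCF ("Key: value") configuration file.

#' Load a flat run configuration
#'
#' Reads a Debian-control-format (\code{Key: value}) text file into a named
#' list. Values \code{"true"}/\code{"false"} become logicals and purely
#' numeric values become numbers; everything else stays character.
#'
#' @param path configuration file path.
#' @return Named list.
#' @export
load_run_config <- function(path) {
  m <- read.dcf(path)
  cfg <- as.list(m[1L, ])
  lapply(cfg, function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", v)) return(as.numeric(v))
    v
  })
}

as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) load_run_config(config)
  else as.list(config)
}

write_manifest <- function(out_dir, command, config, seed, t0) {
  manifest <- list(
    command = command,
    config = config[!vapply(config, is.object, logical(1))],
    seed = seed,
    package = "riskmle",
    version = as.character(utils::packageVersion("riskmle")),
    r_version = R.version.string,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

parse_model_keys <- function(models) {
  if (is.null(models)) models <- "MIX-CP"
  if (length(models) == 1L) models <- strsplit(models, "[,;[:space:]]+")[[1L]]
  models <- models[nzchar(models)]
  valid <- as.vector(outer(FUNCTIONALS, ERROR_CODES, paste, sep = "-"))
  bad <- setdiff(toupper(models), valid)
  if (length(bad))
    stop("invalid model specification(s) ", paste(bad, collapse = ", "),
         "; valid combinations: ", paste(valid, collapse = ", "))
  toupper(models)
}

#' Simulate a dataset and write it to disk
#'
#' Writes \code{choices.csv} (the standard choice CSV), \code{truth.json}
#' (the generating model, parameters and seed, for recovery scoring) and
#' \code{manifest.json} to \code{config$out_dir}.
#'
#' @param config list or DCF file path with entries \code{out_dir},
#'   \code{seed}, and optionally \code{functional}, \code{error},
#'   \code{n_subjects}, \code{indifference_rate}.
#' @return Invisibly, the paths written.
#' @export
cmd_simulate <- function(config) {
  t0 <- Sys.time()
  cfg <- as_config(config)
  out_dir <- cfg$out_dir %||% stop("config must name an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  truth <- risk_truth(
    functional = cfg$functional %||% "MIX",
    error = cfg$error %||% "CP",
    n_subjects = cfg$n_subjects %||% 84,
    indifference_rate = cfg$indifference_rate %||% 0
  )
  sim <- simulate_choices(truth, seed = seed)
  csv <- file.path(out_dir, "choices.csv")
  write_choice_csv(sim, csv)
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(functional = truth$functional, error = truth$error,
         params = as.list(truth$params), n_subjects = truth$n_subjects,
         indifference_rate = truth$indifference_rate, seed = seed),
    truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate", cfg, seed, t0)
  invisible(c(choices = csv, truth = truth_json))
}

#' Fit models and write estimate reports
#'
#' Fits the requested functional-error combinations and writes
#' \code{fits.json} (estimates, cluster-robust SEs, covariance,
#' log-likelihood, diagnostics), \code{estimates.csv} (the combined
#' coefficient table with 95\% CIs) including the Wald-test panel
#' (\eqn{\gamma = 1} for every RDU/mixture fit, mixture-probability
#' constraints for mixtures), and \code{manifest.json}.
#'
#' @param config list or DCF file path with entries \code{data} (choice CSV
#'   path) or \code{out_dir} of a previous \code{\link{cmd_simulate}} run,
#'   \code{models} (comma-separated \code{"EUT-FP"}-style keys), and
#'   \code{out_dir}.
#' @return Invisibly, the named list of fits.
#' @export
cmd_fit <- function(config) {
  t0 <- Sys.time()
  cfg <- as_config(config)
  out_dir <- cfg$out_dir %||% stop("config must name an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  data_path <- cfg$data %||% file.path(out_dir, "choices.csv")
  data <- read_choice_csv(data_path)
  models <- parse_model_keys(cfg$models)

  fits <- list(); rows <- list(); wald_rows <- list(); json <- list()
  for (key in models) {
    parts <- strsplit(key, "-")[[1L]]
    fit <- riskfit(data, parts[1L], parts[2L])
    fits[[key]] <- fit
    s <- summary(fit)
    tab <- as.data.frame(s$coefficients)
    tab <- cbind(model = key, parameter = rownames(tab), tab,
                 logLik = fit$logLik, row.names = NULL)
    rows[[key]] <- tab
    for (nm in names(s$wald))
      wald_rows[[paste(key, nm)]] <- data.frame(
        model = key, hypothesis = nm,
        statistic = s$wald[[nm]]$statistic, df = s$wald[[nm]]$df,
        p_value = s$wald[[nm]]$p_value, stringsAsFactors = FALSE)
    json[[key]] <- list(
      functional = fit$functional, error = fit$error,
      estimates = as.list(coef(fit)),
      std_errors = as.list(sqrt(diag(vcov(fit)))),
      vcov = vcov(fit), logLik = fit$logLik,
      n_obs = fit$n_obs, n_clusters = fit$n_clusters, k = fit$k,
      convergence = fit$convergence[c("code", "n_starts", "n_refined",
                                      "boundary", "n_clipped")])
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  if (length(wald_rows))
    utils::write.csv(do.call(rbind, wald_rows),
                     file.path(out_dir, "wald_tests.csv"), row.names = FALSE)
  jsonlite::write_json(json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "fit", cfg, seed, t0)
  invisible(fits)
}

#' Run the judging battery and write its reports
#'
#' Runs \code{\link{selection_battery}} over the requested grid and writes
#' \code{criteria.csv} (AIC/BIC/OSLLF with best-model flags),
#' \code{vuong.csv}, \code{clarke.csv}, a human-readable \code{report.txt},
#' and \code{manifest.json}.
#'
#' @param config list or DCF file path; entries as in \code{\link{cmd_fit}}
#'   plus \code{functionals}, \code{errors} (comma-separated), and
#'   \code{osllf} (logical, default \code{TRUE}).
#' @return Invisibly, the \code{selection_report}.
#' @export
cmd_judge <- function(config) {
  t0 <- Sys.time()
  cfg <- as_config(config)
  out_dir <- cfg$out_dir %||% stop("config must name an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  data_path <- cfg$data %||% file.path(out_dir, "choices.csv")
  data <- read_choice_csv(data_path)
  split_keys <- function(v, default) {
    if (is.null(v)) return(default)
    toupper(strsplit(v, "[,;[:space:]]+")[[1L]])
  }
  report <- selection_battery(
    data,
    functionals = split_keys(cfg$functionals, c("EUT", "RDU", "MIX")),
    errors = split_keys(cfg$errors, ERROR_CODES),
    osllf = isTRUE(cfg$osllf %||% TRUE))
  utils::write.csv(report$criteria, file.path(out_dir, "criteria.csv"),
                   row.names = FALSE)
  if (!is.null(report$vuong))
    utils::write.csv(report$vuong, file.path(out_dir, "vuong.csv"),
                     row.names = FALSE)
  if (!is.null(report$clarke))
    utils::write.csv(report$clarke, file.path(out_dir, "clarke.csv"),
                     row.names = FALSE)
  txt <- file.path(out_dir, "report.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  print(report)
  sink(); on.exit()
  write_manifest(out_dir, "judge", cfg, seed, t0)
  invisible(report)
}
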