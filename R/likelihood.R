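# Vectorized likelihood machinery.
#
# A choice dataset over two-outcome price-list pairs has only
# (number of distinct pairs) x (3 responses) distinct record likelihoods, so
# the dataset log-likelihood is computed as counts * log-likelihood-matrix.
# Per-record vectors (needed for Vuong/Clarke tests and cluster scores) are
# recovered by indexing the same matrix.

RESP_A <- 1L
RESP_B <- 2L
RESP_I <- 3L

# Decompose a choice_data object into flat structures:
#   pairs: per distinct (task, row) pair, the best/worst prize and the
#          probability of the best outcome of each option, plus the pooled
#          prize extremes for the contextual range
#   counts: n_pairs x 3 response-count matrix
#   records: pair_idx / resp_idx / cluster_idx per record (original order)
#   cluster_counts: n_pairs x 3 x n_clusters count array (for grouped CV)
prep_choice_data <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  rec <- data$records
  if (nrow(rec) == 0L) stop("empty dataset")
  pkey <- paste(rec$task_id, rec$row_index, sep = "\r")
  upairs <- unique(data.frame(task_id = rec$task_id, row_index = rec$row_index,
                              key = pkey, stringsAsFactors = FALSE))
  upairs <- upairs[order(upairs$task_id, upairs$row_index), ]
  np <- nrow(upairs)

  cols <- c("pa_best", "xa_best", "xa_worst", "pb_best", "xb_best", "xb_worst",
            "x_max", "x_min")
  P <- matrix(NA_real_, np, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(np)) {
    pr <- data$designs[[upairs$task_id[i]]]$pairs[[upairs$row_index[i]]]
    if (length(pr$option_a$prizes) != 2L || length(pr$option_b$prizes) != 2L)
      stop("the likelihood machinery supports two-outcome price-list pairs only")
    oa <- order(pr$option_a$prizes, decreasing = TRUE)
    ob <- order(pr$option_b$prizes, decreasing = TRUE)
    prizes <- c(pr$option_a$prizes, pr$option_b$prizes)
    P[i, ] <- c(pr$option_a$probs[oa[1L]], pr$option_a$prizes[oa],
                pr$option_b$probs[ob[1L]], pr$option_b$prizes[ob],
                max(prizes), min(prizes))
  }

  pair_idx <- match(pkey, upairs$key)
  resp_idx <- match(rec$response, RESPONSE_LEVELS)
  cluster <- factor(rec$subject_id)
  counts <- matrix(0, np, 3L)
  cc <- array(0, dim = c(np, 3L, nlevels(cluster)),
              dimnames = list(NULL, NULL, levels(cluster)))
  ci <- as.integer(cluster)
  for (j in seq_along(pair_idx))
    cc[pair_idx[j], resp_idx[j], ci[j]] <- cc[pair_idx[j], resp_idx[j], ci[j]] + 1
  counts <- rowSums(cc, dims = 2L)

  list(pairs = P, n_pairs = np, pair_info = upairs[c("task_id", "row_index")],
       counts = counts, cluster_counts = cc,
       pair_idx = pair_idx, resp_idx = resp_idx,
       cluster = cluster, cluster_idx = ci,
       n_obs = nrow(rec), n_clusters = nlevels(cluster))
}

# P(choose B) for every pair row, one functional component (EUT: gamma = 1).
# Returns a vector of clipped probabilities; attribute "n_clipped" counts
# probabilities that hit the clipping guard.
pair_prob_b <- function(P, error, r, gamma, mu) {
  if (error == "LUCE") {
    if (r >= 0.999)
      stop("the Luce strict-utility error requires r < 1 so option values stay positive")
    e <- 1 - r
    ua_b <- P[, "xa_best"]^e; ua_w <- P[, "xa_worst"]^e
    ub_b <- P[, "xb_best"]^e; ub_w <- P[, "xb_worst"]^e
    wa <- tk_weight(P[, "pa_best"], gamma)
    wb <- tk_weight(P[, "pb_best"], gamma)
    va <- wa * ua_b + (1 - wa) * ua_w
    vb <- wb * ub_b + (1 - wb) * ub_w
    pb <- stats::plogis((log(vb) - log(va)) / mu)
  } else {
    r <- clamp_r_band(r)
    e <- 1 - r
    ua_b <- P[, "xa_best"]^e / e; ua_w <- P[, "xa_worst"]^e / e
    ub_b <- P[, "xb_best"]^e / e; ub_w <- P[, "xb_worst"]^e / e
    wa <- tk_weight(P[, "pa_best"], gamma)
    wb <- tk_weight(P[, "pb_best"], gamma)
    index <- (wb * ub_b + (1 - wb) * ub_w - wa * ua_b - (1 - wa) * ua_w) / mu
    if (error %in% c("CP", "CL"))
      index <- index / (P[, "x_max"]^e / e - P[, "x_min"]^e / e)
    pb <- if (error %in% c("FP", "CP")) stats::pnorm(index) else stats::plogis(index)
  }
  out <- clip_prob(pb)
  attr(out, "n_clipped") <- sum(out != pb)
  out
}

# n_pairs x 3 likelihood matrix (columns: response A, B, INDIFFERENT) on the
# probability scale; an indifferent response is the 50/50 mixture of the two
# choice likelihoods, hence exactly 0.5
lik_matrix <- function(P, functional, error, par) {
  if (functional == "MIX") {
    pbE <- pair_prob_b(P, error, par[["r_eut"]], 1, par[["mu"]])
    pbR <- pair_prob_b(P, error, par[["r_rdu"]], par[["gamma"]], par[["mu"]])
    pi_e <- par[["pi_eut"]]
    L <- pi_e * cbind(1 - pbE, pbE, 0.5) + (1 - pi_e) * cbind(1 - pbR, pbR, 0.5)
    attr(L, "n_clipped") <- attr(pbE, "n_clipped") + attr(pbR, "n_clipped")
  } else {
    g <- if (functional == "EUT") 1 else par[["gamma"]]
    pb <- pair_prob_b(P, error, par[["r"]], g, par[["mu"]])
    L <- cbind(1 - pb, pb, 0.5)
    attr(L, "n_clipped") <- attr(pb, "n_clipped")
  }
  L
}

loglik_matrix <- function(P, functional, error, par) {
  L <- lik_matrix(P, functional, error, par)
  out <- log(L)
  attr(out, "n_clipped") <- attr(L, "n_clipped")
  out
}

# ---- parameter transforms -------------------------------------------------
# Internal (unconstrained) scale used by the optimizer:
#   mu = exp(m), gamma = exp(g), pi_eut = plogis(q), r free, except under the
#   Luce error where r = R_CAP - exp(s) keeps option values positive.
R_CAP <- 0.999

par_names <- function(functional) {
  switch(functional,
         EUT = c("r", "mu"),
         RDU = c("r", "gamma", "mu"),
         MIX = c("r_eut", "r_rdu", "gamma", "mu", "pi_eut"),
         stop("unknown functional '", functional, "'"))
}

r_to_internal <- function(r, error) {
  if (error == "LUCE") log(R_CAP - pmin(r, R_CAP - 1e-6)) else r
}
r_to_natural <- function(s, error) {
  if (error == "LUCE") R_CAP - exp(s) else s
}

to_internal <- function(par, functional, error) {
  switch(functional,
         EUT = c(r_to_internal(par[["r"]], error), log(par[["mu"]])),
         RDU = c(r_to_internal(par[["r"]], error), log(par[["gamma"]]),
                 log(par[["mu"]])),
         MIX = c(r_to_internal(par[["r_eut"]], error),
                 r_to_internal(par[["r_rdu"]], error),
                 log(par[["gamma"]]), log(par[["mu"]]),
                 stats::qlogis(par[["pi_eut"]])))
}

to_natural <- function(theta, functional, error) {
  out <- switch(functional,
                EUT = c(r = r_to_natural(theta[1L], error), mu = exp(theta[2L])),
                RDU = c(r = r_to_natural(theta[1L], error),
                        gamma = exp(theta[2L]), mu = exp(theta[3L])),
                MIX = c(r_eut = r_to_natural(theta[1L], error),
                        r_rdu = r_to_natural(theta[2L], error),
                        gamma = exp(theta[3L]), mu = exp(theta[4L]),
                        pi_eut = stats::plogis(theta[5L])))
  names(out) <- par_names(functional)
  out
}

# diagonal Jacobian d(natural)/d(internal), for the delta method
natural_jacobian <- function(theta, functional, error) {
  nat <- to_natural(theta, functional, error)
  dr <- function(s) if (error == "LUCE") -exp(s) else 1
  j <- switch(functional,
              EUT = c(dr(theta[1L]), nat[["mu"]]),
              RDU = c(dr(theta[1L]), nat[["gamma"]], nat[["mu"]]),
              MIX = c(dr(theta[1L]), dr(theta[2L]), nat[["gamma"]], nat[["mu"]],
                      nat[["pi_eut"]] * (1 - nat[["pi_eut"]])))
  diag(j, nrow = length(j))
}

# negative log-likelihood on the internal scale against a count matrix
make_negll <- function(P, functional, error, counts) {
  force(P); force(counts)
  function(theta) {
    par <- to_natural(theta, functional, error)
    M <- loglik_matrix(P, functional, error, par)
    v <- -sum(counts * M)
    if (!is.finite(v)) return(1e12)
    v
  }
}

# per-record log-likelihood vector at natural-scale parameters
record_loglik_vec <- function(prep, functional, error, par) {
  M <- loglik_matrix(prep$pairs, functional, error, par)
  M[cbind(prep$pair_idx, prep$resp_idx)]
}

#' Log-likelihood of a choice dataset under a model specification
#'
#' Evaluates the choice-model log-likelihood at given parameter values: each
#' record contributes \eqn{\ln P(B)} for a B choice, \eqn{\ln P(A)} for an A
#' choice, and \eqn{\ln(0.5 P(A) + 0.5 P(B)) = \ln 0.5} for an expressed
#' indifference. Under the \code{"MIX"} functional the record-level
#' likelihood is the probability-weighted combination
#' \eqn{\pi_{EUT} L_{EUT} + (1 - \pi_{EUT}) L_{RDU}}, mixed before taking
#' the log (a choice-level mixture).
#'
#' @param data a \code{\link{choice_data}}.
#' @param functional \code{"EUT"}, \code{"RDU"}, or \code{"MIX"}.
#' @param error error specification code (see \code{\link{error_spec}}).
#' @param par named parameter vector on the natural scale: \code{r, mu}
#'   (EUT); \code{r, gamma, mu} (RDU); \code{r_eut, r_rdu, gamma, mu,
#'   pi_eut} (MIX).
#' @return The total log-likelihood, with attribute \code{"per_record"}
#'   holding the per-record vector in dataset order.
#' @examples
#' sim <- simulate_choices(risk_truth("EUT", "FP", n_subjects = 5), seed = 1)
#' choice_loglik(sim, "EUT", "FP", c(r = 0.68, mu = 0.43))
#' @export
choice_loglik <- function(data, functional = c("EUT", "RDU", "MIX"), error,
                          par) {
  functional <- match.arg(functional)
  error <- as.character(error_spec(error))
  check_par(par, functional)
  prep <- prep_choice_data(data)
  v <- record_loglik_vec(prep, functional, error, par)
  structure(sum(v), per_record = v)
}

check_par <- function(par, functional) {
  need <- par_names(functional)
  if (is.null(names(par)) || !all(need %in% names(par)))
    stop("`par` must be a named vector with elements ",
         paste(need, collapse = ", "))
  if (par[["mu"]] <= 0) stop("`mu` must be strictly positive")
  if ("gamma" %in% need && par[["gamma"]] <= 0)
    stop("`gamma` must be strictly positive")
  if ("pi_eut" %in% need &&
      (par[["pi_eut"]] < 0 || par[["pi_eut"]] > 1))
    stop("`pi_eut` must lie in [0, 1]")
  invisible(par)
}
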