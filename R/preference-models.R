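#' CRRA utility
#'
#' Constant relative risk aversion utility of a money amount:
#' \eqn{u(x) = x^{1-r}/(1-r)}, with \eqn{r} the relative risk aversion
#' coefficient (\eqn{r = 0} risk neutral, \eqn{r > 0} risk averse,
#' \eqn{r < 0} risk loving). Within a \code{1e-6} neighborhood of
#' \eqn{r = 1} the function returns \eqn{\ln x}, the continuity limit of the
#' normalized form. With \code{normalized = TRUE} the affinely shifted
#' variant \eqn{(x^{1-r}-1)/(1-r)} is returned instead; it induces the same
#' preferences and is continuous through \eqn{r = 1}, which matters for
#' root-finding across \eqn{r} (see \code{\link{crra_crossover}}).
#'
#' @param x strictly positive money amount(s).
#' @param r relative risk aversion coefficient (scalar).
#' @param normalized use the shifted form that is continuous at \eqn{r = 1}.
#' @return Utility value(s), same length as \code{x}.
#' @examples
#' crra_utility(2, r = 0)       # 2: risk neutrality is linear utility
#' crra_utility(1, r = 0.5)     # 2
#' @export
crra_utility <- function(x, r, normalized = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("CRRA utility requires strictly positive, finite amounts")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("`r` must be a finite scalar")
  if (abs(1 - r) <= 1e-6) return(log(x))
  if (normalized) (x^(1 - r) - 1) / (1 - r) else x^(1 - r) / (1 - r)
}

#' Inverse-S probability weighting function
#'
#' The one-parameter weighting form of Tversky and Kahneman,
#' \eqn{w(p) = p^\gamma / (p^\gamma + (1-p)^\gamma)^{1/\gamma}}. At
#' \eqn{\gamma = 1} it is the identity, so rank-dependent utility collapses
#' to expected utility; testing \eqn{\gamma = 1} is the test of no
#' probability weighting. \eqn{\gamma < 1} over-weights small and
#' under-weights large probabilities; large \eqn{\gamma} under-weights
#' essentially all probabilities.
#'
#' @param p probability (or vector of probabilities) in \eqn{[0, 1]}.
#' @param gamma curvature parameter, strictly positive.
#' @return Decision weight(s) in \eqn{[0, 1]}; \eqn{w(0)=0}, \eqn{w(1)=1}.
#' @examples
#' tk_weight(0.1, 0.61)
#' tk_weight(c(0, 0.5, 1), 2)
#' @export
tk_weight <- function(p, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a strictly positive scalar")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pg <- p^gamma
  qg <- (1 - p)^gamma
  pg / (pg + qg)^(1 / gamma)
}

# internal utility kinds used by the likelihood machinery:
#  "literal"   x^(1-r)/(1-r)        (the estimation form)
#  "normalized" (x^(1-r)-1)/(1-r)   (continuous through r = 1)
#  "positive"  x^(1-r), r < 1       (Luce strict utility needs positive values)
u_eval <- function(x, r, kind = "literal") {
  switch(kind,
         literal = {
           r <- clamp_r_band(r)
           x^(1 - r) / (1 - r)
         },
         normalized = crra_utility(x, r, normalized = TRUE),
         positive = {
           if (r >= 1) stop("positive-utility evaluation requires r < 1")
           x^(1 - r)
         },
         stop("unknown utility kind"))
}

# value of a lottery under EUT (gamma = 1) or RDU, any number of outcomes;
# ties in prizes are merged before ranking so an equal-prize option is
# treated as degenerate. User-facing variants go through crra_utility (with
# its ln limit at r = 1) so eut_value and rdu_value agree exactly at gamma = 1.
lottery_value <- function(l, r, gamma = 1, kind = "literal") {
  ux <- sort(unique(l$prizes), decreasing = TRUE)
  if (length(ux) == length(l$prizes)) {
    p <- l$probs[order(l$prizes, decreasing = TRUE)]
  } else {
    p <- vapply(ux, function(z) sum(l$probs[l$prizes == z]), numeric(1))
  }
  dw <- if (gamma == 1) p else diff(c(0, tk_weight(cumsum(p), gamma)))
  u <- switch(kind,
              literal = crra_utility(ux, r),
              normalized = crra_utility(ux, r, normalized = TRUE),
              positive = u_eval(ux, r, "positive"),
              stop("unknown utility kind"))
  sum(dw * u)
}

#' Expected utility of a lottery
#'
#' \eqn{EU = \sum_i p_i u(x_i)} under CRRA utility.
#'
#' @param lottery a \code{\link{lottery}}.
#' @param r relative risk aversion coefficient.
#' @param normalized evaluate with the normalized CRRA form (continuous at
#'   \eqn{r = 1}) rather than the literal one.
#' @return Scalar utility value.
#' @examples
#' eut_value(lottery(c(2, 1.6), c(0.1, 0.9)), r = 0) # 1.64, the EV
#' @export
eut_value <- function(lottery, r, normalized = FALSE) {
  stopifnot(inherits(lottery, "lottery"))
  sum(lottery$probs * crra_utility(lottery$prizes, r, normalized = normalized))
}

#' Rank-dependent utility of a lottery
#'
#' Replaces the outcome probabilities of expected utility with decision
#' weights derived from the \code{\link{tk_weight}} weighting function
#' applied to the decumulative distribution: with outcomes ranked from best
#' to worst, the weight on the \eqn{j}-th best outcome is
#' \eqn{w(p_1 + \dots + p_j) - w(p_1 + \dots + p_{j-1})}. For a two-outcome
#' lottery this is \eqn{w(p_{best}) u(x_{best}) + (1 - w(p_{best}))
#' u(x_{worst})}. At \eqn{\gamma = 1} it equals \code{\link{eut_value}}.
#'
#' @inheritParams eut_value
#' @param gamma probability-weighting curvature, strictly positive.
#' @return Scalar utility value.
#' @examples
#' l <- lottery(c(3.85, 0.1), c(0.1, 0.9))
#' rdu_value(l, r = 0, gamma = 0.5)
#' @export
rdu_value <- function(lottery, r, gamma = 1, normalized = FALSE) {
  stopifnot(inherits(lottery, "lottery"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a strictly positive scalar")
  lottery_value(lottery, r, gamma,
                kind = if (normalized) "normalized" else "literal")
}
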