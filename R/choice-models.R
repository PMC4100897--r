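#' Stochastic error specifications
#'
#' The five admissible error specifications linking deterministic lottery
#' values to choice probabilities:
#' \describe{
#'   \item{FP / FL}{Fechner (strong utility) error: the latent index
#'     \eqn{(V_B - V_A)/\mu} is passed through a standard normal (probit) or
#'     standard logistic (logit) link.}
#'   \item{CP / CL}{Contextual utility (moderate utility): the Fechner index
#'     is additionally divided by \eqn{\nu}, the utility range of the pair's
#'     prizes, which accommodates lottery-pair-specific heteroskedasticity.}
#'   \item{LUCE}{Luce (strict utility) error:
#'     \eqn{P(B) = V_B^{1/\mu} / (V_A^{1/\mu} + V_B^{1/\mu})}, defined for
#'     strictly positive option values; algebraically a logit on the
#'     log-value difference.}
#' }
#'
#' @param code one of \code{"FP"}, \code{"FL"}, \code{"CP"}, \code{"CL"},
#'   \code{"LUCE"}.
#' @return The canonical code, with attributes \code{family} and
#'   \code{link}.
#' @export
error_spec <- function(code) {
  code <- toupper(as.character(code))
  specs <- list(
    FP   = c(family = "FECHNER",     link = "PROBIT"),
    FL   = c(family = "FECHNER",     link = "LOGIT"),
    CP   = c(family = "CONTEXTUAL",  link = "PROBIT"),
    CL   = c(family = "CONTEXTUAL",  link = "LOGIT"),
    LUCE = c(family = "LUCE_STRICT", link = "NONE")
  )
  if (length(code) != 1L || !code %in% names(specs))
    stop("unknown error specification '", code, "'; admissible: ",
         paste(names(specs), collapse = ", "))
  structure(code, family = specs[[code]][["family"]],
            link = specs[[code]][["link"]])
}

ERROR_CODES <- c("FP", "FL", "CP", "CL", "LUCE")
FUNCTIONALS <- c("EUT", "RDU", "MIX")

#' Latent Fechner index of a lottery pair
#'
#' \eqn{(V_B - V_A) / \mu}, where \eqn{V} is the expected utility (EUT) or
#' rank-dependent utility (RDU) of each option and \eqn{\mu > 0} is the noise
#' scale.
#'
#' @param pair a \code{\link{lottery_pair}}.
#' @param functional \code{"EUT"} or \code{"RDU"}.
#' @param r relative risk aversion coefficient.
#' @param gamma probability-weighting curvature (ignored under EUT).
#' @param mu noise scale, strictly positive.
#' @return Scalar index; positive values favor option B.
#' @export
latent_index <- function(pair, functional = c("EUT", "RDU"), r, gamma = 1, mu) {
  stopifnot(inherits(pair, "lottery_pair"))
  functional <- match.arg(functional)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("`mu` must be a strictly positive scalar")
  g <- if (functional == "EUT") 1 else gamma
  (lottery_value(pair$option_b, r, g) - lottery_value(pair$option_a, r, g)) / mu
}

#' Contextual utility range of a lottery pair
#'
#' \eqn{\nu}: the utility of the largest prize appearing anywhere in the pair
#' minus the utility of the smallest, under the current risk coefficient.
#' Prizes are pooled across both options and probability weighting does not
#' enter. \eqn{\nu} changes from pair to pair, hence "contextual".
#'
#' @param pair a \code{\link{lottery_pair}}.
#' @param r relative risk aversion coefficient.
#' @return Strictly positive scalar.
#' @export
contextual_range <- function(pair, r) {
  stopifnot(inherits(pair, "lottery_pair"))
  prizes <- c(pair$option_a$prizes, pair$option_b$prizes)
  if (max(prizes) - min(prizes) <= 0)
    stop("degenerate pair: all prizes equal, utility range is zero")
  crra_utility(max(prizes), r) - crra_utility(min(prizes), r)
}

#' Probability of choosing option B
#'
#' Maps a lottery pair, a preference functional, and preference/noise
#' parameters to \eqn{P(\mathrm{choose\ B})} under one of the five error
#' specifications (see \code{\link{error_spec}}). Under \code{"LUCE"} option
#' values must be strictly positive; the package therefore evaluates the
#' strict-utility ratio with the positive CRRA kernel \eqn{u(x) = x^{1-r}}
#' (the \eqn{1/(1-r)} factor cancels in the ratio for \eqn{r < 1}) and
#' requires \eqn{r < 1}.
#'
#' @inheritParams latent_index
#' @param error error specification code.
#' @return \eqn{P(B) \in (0, 1)}.
#' @examples
#' p <- hl_design()$pairs[[1]]
#' choice_prob(p, "EUT", error = "FP", r = 0.5, mu = 0.3)
#' @export
choice_prob <- function(pair, functional = c("EUT", "RDU"), error, r,
                        gamma = 1, mu) {
  stopifnot(inherits(pair, "lottery_pair"))
  functional <- match.arg(functional)
  spec <- error_spec(error)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("`mu` must be a strictly positive scalar")
  g <- if (functional == "EUT") 1 else gamma

  if (attr(spec, "family") == "LUCE_STRICT") {
    if (r >= 1)
      stop("the Luce strict-utility error requires r < 1 so option values stay positive")
    va <- lottery_value(pair$option_a, r, g, kind = "positive")
    vb <- lottery_value(pair$option_b, r, g, kind = "positive")
    if (va <= 0 || vb <= 0)
      stop("the Luce strict-utility error requires strictly positive option values")
    return(stats::plogis((log(vb) - log(va)) / mu))
  }

  va <- lottery_value(pair$option_a, r, g)
  vb <- lottery_value(pair$option_b, r, g)
  index <- (vb - va) / mu
  if (attr(spec, "family") == "CONTEXTUAL")
    index <- index / contextual_range(pair, r)
  if (attr(spec, "link") == "PROBIT") stats::pnorm(index) else stats::plogis(index)
}
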