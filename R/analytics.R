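#' Equilibrium repertoire size of an isolated population
#'
#' At equilibrium the expected number of tools established per step,
#' `P_inv * beta * N`, balances the expected number lost, which is the
#' per-tool loss probability times the repertoire size `x`. Under the
#' default scaled loss model (per-tool probability `p_loss / N`) this gives
#' the closed form `x = P_inv * beta * N^2 / P_loss`; under the
#' independent-individuals model (per-tool probability `p_ind ^ N`) it
#' gives `x = P_inv * beta * N / p_ind^N`, which grows exponentially in
#' `N`. The value is the mean of the stochastic equilibrium, not an
#' integer.
#'
#' @param n Census size (vectorised, non-negative).
#' @param params A [sim_params()] object.
#' @return Expected equilibrium repertoire size(s).
#' @examples
#' equilibrium_repertoire(200) # 40 under the default rates
#' equilibrium_repertoire(400) # 160
#' @export
equilibrium_repertoire <- function(n, params = sim_params()) {
  stopifnot(is.numeric(n), all(n >= 0))
  if (params$loss_model == "scaled") {
    if (params$p_loss <= 0)
      stop("p_loss = 0: repertoire size grows without bound, no finite ",
           "equilibrium", call. = FALSE)
    params$p_inv * params$beta * n^2 / params$p_loss
  } else {
    if (params$p_ind <= 0 || params$p_ind >= 1)
      stop("independent-individuals equilibrium requires 0 < p_ind < 1",
           call. = FALSE)
    params$p_inv * params$beta * n / params$p_ind^n
  }
}

#' Effective cultural population size
#'
#' The census size at which an isolated population would be expected to
#' hold a repertoire of the observed size: the exact inverse of
#' [equilibrium_repertoire()]. Under the scaled loss model this is
#' `sqrt(x * p_loss / (p_inv * beta))`; under the independent-individuals
#' model the inverse has no closed form and is found numerically (the
#' equilibrium is strictly increasing in `N`).
#'
#' @param x Observed (time-averaged) repertoire size(s), non-negative.
#' @param params A [sim_params()] object.
#' @return Effective population size(s), real-valued.
#' @examples
#' effective_population_size(40)  # 200 under the default rates
#' effective_population_size(135) # about 367
#' @export
effective_population_size <- function(x, params = sim_params()) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("`x` must be a non-negative repertoire size", call. = FALSE)
  if (params$loss_model == "scaled") {
    if (params$p_loss <= 0)
      stop("p_loss = 0: effective size undefined", call. = FALSE)
    sqrt(x * params$p_loss / (params$p_inv * params$beta))
  } else {
    vapply(x, function(xi) {
      if (xi == 0) return(0)
      f <- function(m) equilibrium_repertoire(m, params) - xi
      hi <- 1
      while (f(hi) < 0) hi <- hi * 2
      stats::uniroot(f, c(0, hi), tol = 1e-9)$root
    }, numeric(1))
  }
}

#' Expected migration events per time step
#'
#' With a per-individual migration probability `p_mig`, a population of
#' `n` individuals produces on average `n * p_mig` migration events per
#' step. At the default scales (sizes 200-2000, rates 1e-6 to 1e-5) this
#' spans 0.0002 to 0.02 events per step, i.e. migration is rare.
#'
#' @param n Census size (vectorised).
#' @param p_mig Per-individual, per-step migration probability.
#' @return Expected events per step.
#' @examples
#' expected_migration_events(200, 1e-6)  # 2e-04
#' expected_migration_events(2000, 1e-5) # 0.02
#' @export
expected_migration_events <- function(n, p_mig) {
  stopifnot(is.numeric(n), all(n >= 0), is.numeric(p_mig),
            all(p_mig >= 0), all(p_mig <= 1))
  n * p_mig
}

#' Cultural-rescue loss arithmetic
#'
#' Compares the per-step probability that a tool is lost from a single
#' merged population of size `2n` (which is `p_loss / (2n)` under the
#' scaled loss model) with the probability of simultaneous loss in two
#' fully connected populations of size `n` each (`(p_loss / n)^2`). Their
#' ratio, `n / (2 * p_loss)`, exceeds 1 whenever `n > 2 * p_loss` — i.e.
#' for any realistic census size — which is why tightly coupled
#' populations can hold a larger repertoire than a merged population of
#' the same total census size ("cultural rescue").
#'
#' @param n Census size of each of the two populations.
#' @param p_loss Loss-rate constant.
#' @return A list with `merged_loss_prob`, `simultaneous_loss_prob`,
#'   `ratio`, and `rescue_regime` (`TRUE` when merged loss is the more
#'   likely event).
#' @examples
#' rescue_loss_comparison(200, 0.1)
#' @export
rescue_loss_comparison <- function(n, p_loss = 0.1) {
  stopifnot(is.numeric(n), all(n >= 1), is.numeric(p_loss),
            all(p_loss > 0), all(p_loss <= 1))
  merged <- p_loss / (2 * n)
  simultaneous <- (p_loss / n)^2
  list(merged_loss_prob = merged,
       simultaneous_loss_prob = simultaneous,
       ratio = n / (2 * p_loss),
       rescue_regime = merged >= simultaneous)
}

#' Per-tool loss probability under the independent-individuals model
#'
#' If a tool disappears from a population only when every one of its `n`
#' individuals independently fails to retain it (each with probability
#' `p_ind` per step), the per-tool per-step loss probability is
#' `p_ind ^ n` — exponentially decreasing in census size, in contrast to
#' the default `p_loss / n` scaling. Under this mechanism tightly coupled
#' populations gain no rescue effect: their pooled effective size
#' approaches, but does not exceed, the sum of their census sizes.
#'
#' @param n Census size (vectorised).
#' @param p_ind Per-individual retention-failure probability in \[0, 1\].
#' @return Loss probability `p_ind ^ n`.
#' @examples
#' alternative_loss_prob(10, 0.5) # 0.5^10
#' @export
alternative_loss_prob <- function(n, p_ind) {
  stopifnot(is.numeric(n), all(n >= 0), is.numeric(p_ind),
            all(p_ind >= 0), all(p_ind <= 1))
  p_ind ^ n
}

#' Calibrate the independent-individuals loss model to the scaled model
#'
#' Chooses `p_ind` so that an isolated population of size `n` has the same
#' per-tool loss probability — and hence the same equilibrium repertoire —
#' under both loss models: `p_ind = (p_loss / n)^(1/n)`. Used by the
#' rescue experiment so that the two mechanisms differ only in how loss
#' scales away from the calibration size.
#'
#' @param n Calibration census size.
#' @param p_loss Loss-rate constant of the scaled model.
#' @return The matched `p_ind`.
#' @export
calibrate_p_ind <- function(n, p_loss = 0.1) {
  stopifnot(n >= 1, p_loss > 0, p_loss / n <= 1)
  (p_loss / n)^(1 / n)
}
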