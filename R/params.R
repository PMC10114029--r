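#' Simulation parameters
#'
#' Bundle of all model rates and protocol settings. The defaults are the
#' proof-of-principle values used throughout: a per-individual innovation
#' probability of 0.001, a mean selection coefficient of 0.1, a loss-rate
#' constant of 0.1 (divided by census size to give the per-tool per-step
#' loss probability), migrants carrying the whole source repertoire
#' (`f = 1`), a horizon of 200 000 steps, and equilibrium averaging over
#' steps 100 000-200 000 with unique-tool counts sampled every 100 steps.
#'
#' @param p_inv Per-individual, per-step probability of inventing a new tool.
#' @param beta Mean of the exponential distribution from which each new
#'   tool's selection coefficient `s` is drawn (`E(s) = beta`). Draws are
#'   clamped to at most 1 because `s` is used as a probability.
#' @param p_loss Loss-rate constant. Under the default `loss_model =
#'   "scaled"` each established tool is lost, independently per step, with
#'   probability `p_loss / N` in a population of census size `N`.
#' @param p_mig Default per-individual, per-step migration probability,
#'   used when a metapopulation is built without an explicit rate.
#' @param f Fraction of the source repertoire carried by each migrant when
#'   `payload_mode = "fraction"`; each tool is included independently with
#'   probability `f`, so `f = 1` carries the whole repertoire.
#' @param payload_mode `"fraction"` (default) or `"fixed_count"`: whether a
#'   migrant carries a fraction `f` of the source repertoire or a uniform
#'   random subset of fixed size `payload_k`.
#' @param payload_k Number of tools carried per migrant when
#'   `payload_mode = "fixed_count"`; truncated to the repertoire size.
#' @param loss_model `"scaled"` (per-tool loss probability `p_loss / N`,
#'   the default) or `"independent_individuals"` (loss requires independent
#'   retention failure by every individual, probability `p_ind ^ N`).
#' @param p_ind Per-individual retention-failure probability, required when
#'   `loss_model = "independent_individuals"`. No default: the model is an
#'   alternative loss mechanism, not the baseline.
#' @param t_max Total number of time steps to simulate.
#' @param window_start,window_end Averaging window for equilibrium
#'   summaries; inclusive start, exclusive end, i.e. steps
#'   `[window_start, window_end)`.
#' @param unique_sample_every Sampling cadence (in steps) for unique-tool
#'   and overlap counts within the averaging window.
#'
#' @return An object of class `"sim_params"` (a validated list).
#' @examples
#' p <- sim_params()
#' p$p_inv
#' # reduced-scale protocol for quick runs
#' sim_params(t_max = 40000, window_start = 20000, window_end = 40000)
#' @export
sim_params <- function(p_inv = 0.001, beta = 0.1, p_loss = 0.1,
                       p_mig = 0, f = 1,
                       payload_mode = c("fraction", "fixed_count"),
                       payload_k = NULL,
                       loss_model = c("scaled", "independent_individuals"),
                       p_ind = NULL,
                       t_max = 200000L,
                       window_start = 100000L, window_end = 200000L,
                       unique_sample_every = 100L) {
  payload_mode <- match.arg(payload_mode)
  loss_model <- match.arg(loss_model)

  check_prob(p_inv, "p_inv")
  check_prob(p_loss, "p_loss")
  check_prob(p_mig, "p_mig")
  check_prob(f, "f")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number, got ", format(beta),
         call. = FALSE)
  if (payload_mode == "fixed_count") {
    if (is.null(payload_k) || !is.numeric(payload_k) || length(payload_k) != 1L ||
        payload_k < 0 || payload_k != round(payload_k))
      stop("`payload_k` must be a single non-negative integer when ",
           "payload_mode = \"fixed_count\"", call. = FALSE)
    payload_k <- as.integer(payload_k)
  }
  if (loss_model == "independent_individuals") {
    if (is.null(p_ind))
      stop("`p_ind` must be supplied when loss_model = ",
           "\"independent_individuals\"", call. = FALSE)
    check_prob(p_ind, "p_ind")
  }
  for (nm in c("t_max", "window_start", "window_end", "unique_sample_every")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop("`", nm, "` must be a single non-negative integer", call. = FALSE)
  }
  t_max <- as.integer(t_max)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  unique_sample_every <- as.integer(unique_sample_every)
  if (t_max > 0L) {
    if (!(window_start < window_end && window_end <= t_max))
      stop("averaging window must satisfy 0 <= window_start < window_end ",
           "<= t_max (got [", window_start, ", ", window_end, ") with t_max = ",
           t_max, ")", call. = FALSE)
  }
  if (unique_sample_every < 1L) unique_sample_every <- 1L

  structure(list(
    p_inv = p_inv, beta = beta, p_loss = p_loss, p_mig = p_mig, f = f,
    payload_mode = payload_mode, payload_k = payload_k,
    loss_model = loss_model, p_ind = p_ind,
    t_max = t_max, window_start = window_start, window_end = window_end,
    unique_sample_every = unique_sample_every
  ), class = "sim_params")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single probability in [0, 1], got ",
         paste(format(x), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  innovation   p_inv = %g, beta = %g\n", x$p_inv, x$beta))
  if (x$loss_model == "scaled") {
    cat(sprintf("  loss         p_loss = %g (per-tool probability p_loss/N)\n",
                x$p_loss))
  } else {
    cat(sprintf("  loss         independent individuals, p_ind = %g (per-tool probability p_ind^N)\n",
                x$p_ind))
  }
  if (x$payload_mode == "fraction") {
    cat(sprintf("  migration    default p_mig = %g, payload fraction f = %g\n",
                x$p_mig, x$f))
  } else {
    cat(sprintf("  migration    default p_mig = %g, fixed payload of %d tools\n",
                x$p_mig, x$payload_k))
  }
  cat(sprintf("  protocol     t_max = %d, window = [%d, %d), unique sample every %d steps\n",
              x$t_max, x$window_start, x$window_end, x$unique_sample_every))
  invisible(x)
}

#' Reduced-scale protocol preset
#'
#' Convenience wrapper producing the same model rates with a shorter
#' horizon (40 000 steps, window steps 20 000-40 000). Intended for test
#' suites and quick exploration; the relaxation time of an isolated
#' population is roughly `N / p_loss` steps, so the reduced window is
#' comfortably stationary for census sizes up to about 2000 under the
#' default rates.
#'
#' @param ... Passed on to [sim_params()].
#' @return A `"sim_params"` object.
#' @export
sim_params_reduced <- function(...) {
  sim_params(t_max = 40000L, window_start = 20000L, window_end = 40000L, ...)
}
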