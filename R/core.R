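#' Draw selection coefficients for newly invented tools
#'
#' Selection coefficients are drawn from an exponential distribution with
#' mean `beta` and clamped to at most 1, because `s` is reused as an
#' establishment probability both at invention and whenever the tool is
#' carried to another population. The clamp matters only in the extreme
#' tail: with `beta = 0.1` a raw draw exceeds 1 with probability
#' `exp(-10)`, about 4.5e-5.
#'
#' @param n Number of draws.
#' @param params A [sim_params()] object (only `beta` is used).
#' @return Numeric vector of `n` values in (0, 1].
#' @examples
#' set.seed(1)
#' mean(draw_selection_coefficient(1e5, sim_params()))
#' @export
draw_selection_coefficient <- function(n = 1L, params = sim_params()) {
  pmin(stats::rexp(n, rate = 1 / params$beta), 1)
}

# per-tool per-step loss probability for each population under the
# configured loss model
tool_loss_prob <- function(sizes, params) {
  if (params$loss_model == "scaled") {
    p <- params$p_loss / sizes
    if (any(p > 1))
      stop("p_loss / N exceeds 1 for a population of size ",
           sizes[which.max(p)], "; reduce p_loss or enlarge the population",
           call. = FALSE)
    p
  } else {
    params$p_ind ^ sizes
  }
}

# --- single-population step pieces -------------------------------------
# These are the primitive moves of one time step. Repertoires are plain
# integer vectors of tool ids; the registry environment is mutated in
# place. RNG draw order within each piece is fixed and documented in the
# run_simulation() help page.

# innovation: Binomial(n, p_inv) attempts, each with a fresh s; only
# attempts that establish (probability s) are registered and retained
innovate_pop <- function(rep_ids, n, params, reg, pop, t) {
  k <- stats::rbinom(1L, n, params$p_inv)
  if (k == 0L) return(list(rep = rep_ids, new = integer(0)))
  s <- pmin(stats::rexp(k, rate = 1 / params$beta), 1)
  est <- stats::runif(k) < s
  if (!any(est)) return(list(rep = rep_ids, new = integer(0)))
  ids <- reg_add(reg, s[est], pop, t)
  list(rep = c(rep_ids, ids), new = ids)
}

# loss: each established tool removed independently with probability
# p_tool; implemented as a binomial count plus a uniform subset, which is
# distributionally identical to per-tool Bernoulli trials
lose_pop <- function(rep_ids, p_tool) {
  x <- length(rep_ids)
  if (x == 0L || p_tool <= 0) return(list(rep = rep_ids, removed = integer(0)))
  d <- stats::rbinom(1L, x, p_tool)
  if (d == 0L) return(list(rep = rep_ids, removed = integer(0)))
  idx <- sample.int(x, d)
  list(rep = rep_ids[-idx], removed = rep_ids[idx])
}

# payload carried by one migrant: independent per-tool inclusion with
# probability f (deterministically the whole repertoire when f = 1), or a
# uniform subset of fixed size payload_k truncated to the repertoire
select_payload <- function(rep_ids, params) {
  x <- length(rep_ids)
  if (x == 0L) return(integer(0))
  if (params$payload_mode == "fraction") {
    if (params$f >= 1) return(rep_ids)
    if (params$f <= 0) return(integer(0))
    rep_ids[stats::runif(x) < params$f]
  } else {
    k <- min(params$payload_k, x)
    if (k == 0L) return(integer(0))
    if (k == x) return(rep_ids)
    rep_ids[sample.int(x, k)]
  }
}

# establishment of a carried payload in the target population: each tool
# not already present establishes with its original selection coefficient;
# tools already present are no-ops; the source repertoire is untouched
# (migration copies knowledge, it does not move it)
transfer_payload <- function(payload, target_ids, reg) {
  if (length(payload) == 0L) return(integer(0))
  if (any(payload > reg$n))
    stop("payload refers to tool ids absent from the registry", call. = FALSE)
  cand <- payload[!(payload %in% target_ids)]
  if (length(cand) == 0L) return(integer(0))
  cand[stats::runif(length(cand)) < reg$s[cand]]
}

# --- simulation state ---------------------------------------------------

#' Create a simulation state
#'
#' Builds the mutable state advanced by [sim_step()] and [run_simulation()]:
#' empty repertoires, an empty tool registry, and precomputed per-tool
#' loss probabilities. Exposed mainly for step-by-step inspection and
#' testing; most users call [run_simulation()].
#'
#' @param meta A [metapopulation()] object.
#' @param params A [sim_params()] object.
#' @return An environment of class `"culture_state"` with elements
#'   `sizes`, `p_mig`, `reps` (list of integer id vectors), `registry`,
#'   `params`, and `t` (steps completed so far).
#' @export
culture_state <- function(meta, params = sim_params()) {
  stopifnot(inherits(meta, "metapopulation"), inherits(params, "sim_params"))
  st <- new.env(parent = emptyenv())
  st$sizes <- meta$sizes
  st$p_mig <- meta$p_mig
  st$p_row <- rowSums(meta$p_mig)
  st$p_tool <- tool_loss_prob(meta$sizes, params)
  st$reps <- rep(list(integer(0)), length(meta$sizes))
  st$registry <- new_registry()
  st$params <- params
  st$t <- 0L
  class(st) <- "culture_state"
  st
}

#' @export
print.culture_state <- function(x, ...) {
  cat(sprintf("Simulation state after %d step%s\n", x$t,
              if (x$t == 1L) "" else "s"))
  cat("  repertoire sizes:", paste(lengths(x$reps), collapse = ", "), "\n")
  cat("  tools ever established:", reg_size(x$registry), "\n")
  invisible(x)
}

# one full step, mutating st; any_mig avoids the migration block when all
# off-diagonal rates are zero
step_core <- function(st, any_mig) {
  params <- st$params
  sizes <- st$sizes
  npop <- length(sizes)
  t <- st$t + 1L

  # 1. innovation, in population order
  for (i in seq_len(npop)) {
    out <- innovate_pop(st$reps[[i]], sizes[i], params, st$registry, i, t)
    st$reps[[i]] <- out$rep
  }

  # 2. migration: emigrant counts per source in population order, events
  # processed sequentially; each payload is a snapshot of the source
  # repertoire at processing time
  if (any_mig) {
    for (i in seq_len(npop)) {
      p_tot <- st$p_row[i]
      if (p_tot <= 0) next
      m <- stats::rbinom(1L, sizes[i], p_tot)
      if (m == 0L) next
      if (npop == 2L) {
        targets <- rep.int(if (i == 1L) 2L else 1L, m)
      } else {
        targets <- sample.int(npop, m, replace = TRUE,
                              prob = st$p_mig[i, ] / p_tot)
      }
      for (j in targets) {
        payload <- select_payload(st$reps[[i]], params)
        est <- transfer_payload(payload, st$reps[[j]], st$registry)
        if (length(est)) st$reps[[j]] <- c(st$reps[[j]], est)
      }
    }
  }

  # 3. loss, in population order (a tool established earlier in this same
  # step is already exposed to loss)
  for (i in seq_len(npop)) {
    out <- lose_pop(st$reps[[i]], st$p_tool[i])
    st$reps[[i]] <- out$rep
  }

  st$t <- t
  invisible(st)
}

#' Advance a simulation state by one time step
#'
#' Applies, in fixed order, innovation in every population, then all
#' migration events, then loss in every population. The order is a model
#' convention: at the default rates the three processes interact far below
#' Monte-Carlo noise, but a fixed order makes runs exactly reproducible.
#' Note the ordering implies a tool invented (or received) in a step is
#' exposed to loss in that same step.
#'
#' @param state A [culture_state()] environment; modified in place.
#' @return The state, invisibly.
#' @export
sim_step <- function(state) {
  stopifnot(inherits(state, "culture_state"))
  step_core(state, any(state$p_row > 0))
}
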