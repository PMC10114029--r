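# shared protocol presets: the full protocol is 200 000 steps; most tests
# use the reduced protocol (same rates, shorter horizon) or a tiny one.
# Relaxation time of an isolated population is ~N/p_loss steps, so the
# reduced window [20k, 40k) is stationary for the census sizes used here.
reduced_params <- function(...) {
  sim_params(t_max = 40000L, window_start = 20000L, window_end = 40000L, ...)
}

tiny_params <- function(...) {
  sim_params(t_max = 2000L, window_start = 1000L, window_end = 2000L, ...)
}

# mean of the clamped selection coefficient min(Exp(beta), 1):
# beta * (1 - exp(-1/beta))
clamped_mean_s <- function(beta) beta * (1 - exp(-1 / beta))

# hand-built trajectory object for summary() unit tests
fake_sim <- function(sizes, params, unique_times = integer(0),
                     unique = NULL, shared = NULL, union_size = NULL,
                     census = rep(200L, ncol(sizes))) {
  structure(list(
    meta = metapopulation(census),
    params = params,
    seed = NA_integer_,
    sizes = sizes,
    unique_times = unique_times,
    unique = if (is.null(unique))
      matrix(0L, length(unique_times), ncol(sizes)) else unique,
    shared = if (is.null(shared))
      matrix(0L, length(unique_times), 1L) else shared,
    union_size = if (is.null(union_size))
      integer(length(unique_times)) else union_size,
    repertoires = rep(list(integer(0)), ncol(sizes)),
    registry = culturesim:::new_registry()
  ), class = "culture_sim")
}
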