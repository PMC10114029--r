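#' Run a cultural-repertoire simulation
#'
#' Iterates the three-phase step (innovation, migration, loss) for
#' `params$t_max` steps from empty repertoires, recording every
#' population's repertoire size after each step and, at every
#' `unique_sample_every`-th step inside the averaging window, the count of
#' tools unique to each population, the pairwise shared-tool counts, and
#' the size of the metapopulation-wide union repertoire.
#'
#' All randomness is consumed from R's global generator in a fixed,
#' documented order, so a given `(meta, params, seed)` triple reproduces a
#' run bit for bit. Within a step the order is: for each population in
#' index order, an invention-attempt count `Binomial(N, p_inv)`, then the
#' attempts' selection coefficients, then their establishment trials; next,
#' for each source population in index order, an emigrant count
#' `Binomial(N, total p_mig)`, then per event (in draw order) the payload
#' inclusion draws followed by the establishment trials in the target;
#' finally, for each population in index order, a loss count
#' `Binomial(x, per-tool loss probability)` and the uniform choice of which
#' tools go.
#'
#' @param meta A [metapopulation()] object (a single integer census size is
#'   also accepted and treated as an isolated population).
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the run; `NULL` continues from the current
#'   RNG state.
#' @param record_unique Record unique/shared/union samples inside the
#'   window (default `TRUE`; they cost a set operation per sample).
#' @param progress Print a progress line every 10 000 steps.
#' @return An object of class `"culture_sim"`: a list with `sizes` (a
#'   `t_max` x npop integer matrix of repertoire sizes after each step),
#'   `unique_times`, `unique`, `shared`, `union_size` (window samples),
#'   `repertoires` (final tool-id sets), `registry` (every tool that ever
#'   established), plus `meta`, `params`, and `seed`. Summarise with
#'   [summary.culture_sim()], plot with [plot.culture_sim()].
#' @examples
#' p <- sim_params(t_max = 2000, window_start = 1000, window_end = 2000)
#' sim <- run_simulation(metapopulation(200), p, seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(meta, params = sim_params(), seed = NULL,
                           record_unique = TRUE, progress = FALSE) {
  if (is.numeric(meta) && !inherits(meta, "metapopulation"))
    meta <- metapopulation(meta, p_mig = params$p_mig)
  stopifnot(inherits(meta, "metapopulation"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)

  st <- culture_state(meta, params)
  t_max <- params$t_max
  npop <- length(st$sizes)
  any_mig <- any(st$p_row > 0)
  npair <- npop * (npop - 1L) %/% 2L

  sizes_rec <- matrix(0L, nrow = t_max, ncol = npop)

  ws <- params$window_start
  we <- params$window_end
  every <- params$unique_sample_every
  if (record_unique && t_max > 0L) {
    first <- max(ws, every) # never sample the (empty) pre-run state at t = 0
    first <- as.integer(ceiling(first / every)) * every
    ut <- if (first < we) seq.int(first, we - 1L, by = every) else integer(0)
  } else {
    ut <- integer(0)
  }
  un_rec <- matrix(0L, nrow = length(ut), ncol = npop)
  sh_rec <- matrix(0L, nrow = length(ut), ncol = max(npair, 1L))
  union_rec <- integer(length(ut))
  ui <- 1L
  n_ut <- length(ut)

  for (t in seq_len(t_max)) {
    step_core(st, any_mig)
    sizes_rec[t, ] <- lengths(st$reps)
    if (ui <= n_ut && t == ut[ui]) {
      if (npop == 1L) {
        un_rec[ui, 1L] <- length(st$reps[[1L]])
        union_rec[ui] <- un_rec[ui, 1L]
      } else {
        all_ids <- unlist(st$reps, use.names = FALSE)
        tab <- tabulate(all_ids, nbins = reg_size(st$registry))
        union_rec[ui] <- sum(tab > 0L)
        k <- 1L
        for (i in seq_len(npop)) {
          ids <- st$reps[[i]]
          un_rec[ui, i] <- sum(tab[ids] == 1L)
        }
        for (i in seq_len(npop - 1L)) for (j in seq.int(i + 1L, npop)) {
          sh_rec[ui, k] <- sum(st$reps[[i]] %in% st$reps[[j]])
          k <- k + 1L
        }
      }
      ui <- ui + 1L
    }
    if (progress && t %% 10000L == 0L)
      message(sprintf("step %d / %d: repertoire sizes %s", t, t_max,
                      paste(lengths(st$reps), collapse = ", ")))
  }

  structure(list(
    meta = meta, params = params, seed = seed,
    sizes = sizes_rec,
    unique_times = ut, unique = un_rec, shared = sh_rec,
    union_size = union_rec,
    repertoires = st$reps,
    registry = st$registry
  ), class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  npop <- length(x$meta$sizes)
  cat(sprintf("Cultural repertoire simulation: %d population%s, %d step%s\n",
              npop, if (npop == 1L) "" else "s",
              x$params$t_max, if (x$params$t_max == 1L) "" else "s"))
  cat("  census sizes:   ", paste(x$meta$sizes, collapse = ", "), "\n")
  if (nrow(x$sizes) > 0L)
    cat("  final repertoires:", paste(x$sizes[nrow(x$sizes), ], collapse = ", "),
        "\n")
  cat("  tools ever established:", reg_size(x$registry), "\n")
  invisible(x)
}

#' Plot a repertoire-size trajectory
#'
#' Repertoire size of every population against time, with the averaging
#' window shaded; the standard accumulation-timeline view of a run.
#'
#' @param x A `"culture_sim"` object.
#' @param thin Plot every `thin`-th step (default keeps about 2000 points).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.culture_sim <- function(x, thin = max(1L, nrow(x$sizes) %/% 2000L), ...) {
  if (nrow(x$sizes) == 0L) stop("empty trajectory: t_max = 0", call. = FALSE)
  idx <- seq.int(1L, nrow(x$sizes), by = thin)
  graphics::matplot(idx, x$sizes[idx, , drop = FALSE], type = "l", lty = 1,
                    xlab = "time step", ylab = "repertoire size", ...)
  graphics::abline(v = c(x$params$window_start, x$params$window_end),
                   lty = 3, col = "grey40")
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_along(x$meta$sizes),
                   legend = paste0("N = ", x$meta$sizes))
  invisible(x)
}
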