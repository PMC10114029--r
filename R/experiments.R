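# Deterministic replicate seeds: replicate r of cell c under base seed b
# maps to (b mod 20000) * 100000 + (c mod 1000) * 100 + (r mod 100).
# Cells and replicates therefore get distinct streams, partial reruns are
# possible, and the value stays far below 2^31.
derive_seed <- function(base, cell = 0L, rep = 1L) {
  (as.integer(base) %% 20000L) * 100000L +
    (as.integer(cell) %% 1000L) * 100L + (as.integer(rep) %% 100L)
}

#' Specify a connectivity parameter sweep
#'
#' Describes the two-population grid experiment: a focal population of
#' fixed size connected to a neighbour whose census size and
#' per-individual migration probability vary over a grid. The default grid
#' spans neighbour sizes 200-2000 and migration rates 1e-6 to 1e-5, the
#' region where migration events are rare (0.0002-0.02 per step) yet still
#' reshape the focal repertoire.
#'
#' @param neighbour_sizes Census sizes of the neighbour population.
#' @param migration_probs Per-individual migration probabilities.
#' @param focal_size Census size of the focal population.
#' @param replicates Replicate runs per grid cell.
#' @param base_params A [sim_params()] object for rates and protocol.
#' @param variant `"fraction_payload"` (migrants carry a fraction `f` of
#'   the source repertoire) or `"fixed_count_payload"` (a constant number
#'   `payload_k` of tools regardless of repertoire size).
#' @param payload_k Payload size for the fixed-count variant.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(neighbour_sizes = seq(200L, 2000L, by = 200L),
                       migration_probs = seq(1e-6, 1e-5, by = 1e-6),
                       focal_size = 200L,
                       replicates = 10L,
                       base_params = sim_params(),
                       variant = c("fraction_payload", "fixed_count_payload"),
                       payload_k = NULL) {
  variant <- match.arg(variant)
  stopifnot(length(neighbour_sizes) >= 1L, length(migration_probs) >= 1L,
            replicates >= 1L, inherits(base_params, "sim_params"))
  if (variant == "fixed_count_payload") {
    if (is.null(payload_k)) payload_k <- base_params$payload_k
    if (is.null(payload_k))
      stop("`payload_k` required for the fixed_count_payload variant",
           call. = FALSE)
  }
  structure(list(neighbour_sizes = as.integer(neighbour_sizes),
                 migration_probs = migration_probs,
                 focal_size = as.integer(focal_size),
                 replicates = as.integer(replicates),
                 base_params = base_params,
                 variant = variant, payload_k = payload_k),
            class = "sweep_spec")
}

# params for one sweep cell under a spec
cell_params <- function(spec, p_mig) {
  bp <- spec$base_params
  if (spec$variant == "fixed_count_payload") {
    sim_params(p_inv = bp$p_inv, beta = bp$beta, p_loss = bp$p_loss,
               p_mig = p_mig, payload_mode = "fixed_count",
               payload_k = spec$payload_k, loss_model = bp$loss_model,
               p_ind = bp$p_ind, t_max = bp$t_max,
               window_start = bp$window_start, window_end = bp$window_end,
               unique_sample_every = bp$unique_sample_every)
  } else {
    sim_params(p_inv = bp$p_inv, beta = bp$beta, p_loss = bp$p_loss,
               p_mig = p_mig, f = bp$f, loss_model = bp$loss_model,
               p_ind = bp$p_ind, t_max = bp$t_max,
               window_start = bp$window_start, window_end = bp$window_end,
               unique_sample_every = bp$unique_sample_every)
  }
}

#' Run the connectivity heat-map sweep
#'
#' For every (neighbour size, migration probability) cell of a
#' [sweep_spec()], simulates the two-population system for each replicate
#' and summarises the focal and neighbour populations over the averaging
#' window. Replicate seeds derive deterministically from `seed` and the
#' cell index, so identical calls reproduce identical tables.
#'
#' @param spec A [sweep_spec()].
#' @param seed Base seed.
#' @param progress Print one line per completed cell.
#' @return An object of class `"culture_sweep"`: `records` has one row per
#'   population per replicate per cell (columns `neighbour_size`, `p_mig`,
#'   `replicate`, `seed`, `population`, `census`, `mean_repertoire`,
#'   `n_eff`, `mean_unique`, `mean_shared`, `jaccard`); `cells` aggregates
#'   the focal population per cell (replicate mean and standard error).
#' @export
run_heatmap <- function(spec, seed = 1L, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(neighbour_size = spec$neighbour_sizes,
                      p_mig = spec$migration_probs,
                      KEEP.OUT.ATTRS = FALSE)
  recs <- vector("list", nrow(grid) * spec$replicates)
  idx <- 1L
  for (c_i in seq_len(nrow(grid))) {
    nb <- grid$neighbour_size[c_i]
    pm <- grid$p_mig[c_i]
    params <- cell_params(spec, pm)
    meta <- metapopulation(c(spec$focal_size, nb), p_mig = pm)
    for (r in seq_len(spec$replicates)) {
      sd_r <- derive_seed(seed, c_i, r)
      sm <- summary(run_simulation(meta, params, seed = sd_r))
      recs[[idx]] <- data.frame(
        neighbour_size = nb, p_mig = pm, replicate = r, seed = sd_r,
        population = c("focal", "neighbour"),
        census = sm$census,
        mean_repertoire = sm$mean_repertoire,
        n_eff = sm$n_eff,
        mean_unique = sm$mean_unique,
        mean_shared = rep(sm$mean_shared[1], 2),
        jaccard = rep(sm$jaccard[1], 2))
      idx <- idx + 1L
    }
    if (progress)
      message(sprintf("cell %d/%d (neighbour %d, p_mig %g) done",
                      c_i, nrow(grid), nb, pm))
  }
  records <- do.call(rbind, recs)
  focal <- records[records$population == "focal", ]
  agg_mean <- stats::aggregate(
    focal[c("mean_repertoire", "n_eff", "mean_unique")],
    by = focal[c("neighbour_size", "p_mig")], FUN = mean)
  agg_se <- stats::aggregate(
    focal[c("mean_repertoire", "n_eff", "mean_unique")],
    by = focal[c("neighbour_size", "p_mig")],
    FUN = function(v) stats::sd(v) / sqrt(length(v)))
  names(agg_se)[3:5] <- paste0("se_", names(agg_se)[3:5])
  cells <- merge(agg_mean, agg_se, by = c("neighbour_size", "p_mig"))
  cells <- cells[order(cells$neighbour_size, cells$p_mig), ]
  rownames(cells) <- NULL

  structure(list(spec = spec, seed = seed, records = records, cells = cells),
            class = "culture_sweep")
}

#' @export
print.culture_sweep <- function(x, ...) {
  cat(sprintf("Connectivity sweep: focal %d, %d x %d grid, %d replicates/cell (%s)\n",
              x$spec$focal_size, length(x$spec$neighbour_sizes),
              length(x$spec$migration_probs), x$spec$replicates,
              x$spec$variant))
  print(utils::head(x$cells, 10), row.names = FALSE)
  if (nrow(x$cells) > 10) cat("  ...", nrow(x$cells), "cells in total\n")
  invisible(x)
}

#' Pivot a sweep into a heat-map matrix
#'
#' @param x A `"culture_sweep"`.
#' @param value Cell statistic to pivot (`"mean_repertoire"`, `"n_eff"`,
#'   or `"mean_unique"`).
#' @return Matrix with one row per neighbour size and one column per
#'   migration probability.
#' @export
pivot_grid <- function(x, value = c("mean_repertoire", "n_eff",
                                    "mean_unique")) {
  stopifnot(inherits(x, "culture_sweep"))
  value <- match.arg(value)
  ns <- sort(unique(x$cells$neighbour_size))
  pm <- sort(unique(x$cells$p_mig))
  m <- matrix(NA_real_, length(ns), length(pm),
              dimnames = list(neighbour_size = ns, p_mig = signif(pm, 3)))
  for (i in seq_len(nrow(x$cells)))
    m[as.character(x$cells$neighbour_size[i]),
      as.character(signif(x$cells$p_mig[i], 3))] <- x$cells[[value]][i]
  m
}

#' @export
plot.culture_sweep <- function(x, value = "n_eff", ...) {
  m <- pivot_grid(x, value)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  axes = FALSE, xlab = "migration probability",
                  ylab = "neighbour census size", main = value, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    graphics::text(j, i, round(m[i, j], 1), cex = 0.8)
  invisible(m)
}

#' Focal repertoire and unique-tool counts for the two-population scenario
#'
#' Reproduces the highlighted scenario: a focal population of 200
#' connected to a neighbour of 400 with per-individual migration
#' probability 5e-6 and full-repertoire payloads. Reports the focal
#' population's replicate-aggregated mean repertoire size and mean count
#' of tools unique to it.
#'
#' @param focal_size,neighbour_size Census sizes.
#' @param p_mig Per-individual migration probability.
#' @param params A [sim_params()] object.
#' @param replicates Number of replicate runs.
#' @param seed Base seed.
#' @return A list of class `"unique_tools_result"` with per-replicate
#'   vectors `repertoire` and `unique`, their means, and standard errors.
#' @export
run_unique_tools_experiment <- function(focal_size = 200L,
                                        neighbour_size = 400L,
                                        p_mig = 5e-6,
                                        params = sim_params(),
                                        replicates = 10L,
                                        seed = 1L) {
  meta <- metapopulation(c(focal_size, neighbour_size), p_mig = p_mig)
  rep_means <- numeric(replicates)
  rep_unique <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sm <- summary(run_simulation(meta, params, seed = derive_seed(seed, 0L, r)))
    rep_means[r] <- sm$mean_repertoire[1]
    rep_unique[r] <- sm$mean_unique[1]
  }
  structure(list(
    focal_size = focal_size, neighbour_size = neighbour_size, p_mig = p_mig,
    replicates = replicates, seed = seed,
    repertoire = rep_means, unique = rep_unique,
    mean_repertoire = mean(rep_means),
    se_repertoire = stats::sd(rep_means) / sqrt(replicates),
    mean_unique = mean(rep_unique),
    se_unique = stats::sd(rep_unique) / sqrt(replicates)
  ), class = "unique_tools_result")
}

#' @export
print.unique_tools_result <- function(x, ...) {
  cat(sprintf("Focal %d + neighbour %d, p_mig = %g, %d replicates\n",
              x$focal_size, x$neighbour_size, x$p_mig, x$replicates))
  cat(sprintf("  focal mean repertoire: %.2f (SE %.2f)\n",
              x$mean_repertoire, x$se_repertoire))
  cat(sprintf("  focal mean unique tools: %.2f (SE %.2f)\n",
              x$mean_unique, x$se_unique))
  invisible(x)
}

#' Cultural-rescue scan over migration rates
#'
#' For two equal populations and each migration probability, reports the
#' pooled effective size of the metapopulation (computed from the mean
#' union repertoire) under both loss mechanisms: the default scaled model
#' (per-tool loss `p_loss / N`) and the independent-individuals model
#' calibrated so an isolated population of size `n` behaves identically
#' (`p_ind = (p_loss / n)^(1/n)`). Under the scaled model high
#' connectivity drives the pooled effective size beyond the census sum
#' (`2n`) — cultural rescue; under the independent model it can only
#' approach the sum.
#'
#' @param n Census size of each population.
#' @param p_mig_values Migration probabilities to scan.
#' @param params A [sim_params()] object (scaled-model rates).
#' @param replicates Replicates per migration rate and loss model.
#' @param seed Base seed.
#' @return A data frame of class `"rescue_result"` with one row per
#'   migration rate per loss model: `pooled_repertoire`, `pooled_n_eff`,
#'   standard errors, and `exceeds_census_sum`.
#' @export
run_rescue_experiment <- function(n = 200L,
                                  p_mig_values = c(1e-5, 1e-4, 1e-3),
                                  params = sim_params(),
                                  replicates = 5L,
                                  seed = 1L) {
  p_ind <- calibrate_p_ind(n, params$p_loss)
  params_ind <- sim_params(
    p_inv = params$p_inv, beta = params$beta, p_loss = params$p_loss,
    f = params$f, loss_model = "independent_individuals", p_ind = p_ind,
    t_max = params$t_max, window_start = params$window_start,
    window_end = params$window_end,
    unique_sample_every = params$unique_sample_every)

  rows <- list()
  cell <- 0L
  for (model in c("scaled", "independent_individuals")) {
    pp <- if (model == "scaled") params else params_ind
    for (pm in p_mig_values) {
      cell <- cell + 1L
      meta <- metapopulation(c(n, n), p_mig = pm)
      pooled <- numeric(replicates)
      neff <- numeric(replicates)
      for (r in seq_len(replicates)) {
        sm <- summary(run_simulation(meta, pp, seed = derive_seed(seed, cell, r)))
        pooled[r] <- sm$pooled_repertoire
        neff[r] <- sm$pooled_n_eff
      }
      rows[[length(rows) + 1L]] <- data.frame(
        loss_model = model, p_mig = pm, n = n,
        pooled_repertoire = mean(pooled),
        se_pooled_repertoire = stats::sd(pooled) / sqrt(replicates),
        pooled_n_eff = mean(neff),
        se_pooled_n_eff = stats::sd(neff) / sqrt(replicates),
        exceeds_census_sum = mean(neff) > 2 * n)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_ind") <- p_ind
  attr(out, "seed") <- seed
  class(out) <- c("rescue_result", "data.frame")
  out
}

#' Connectivity-repertoire curve
#'
#' Scans the focal population's window-mean repertoire across migration
#' probabilities spanning several orders of magnitude. The relationship is
#' sigmoid on a log scale: at very low rates the repertoire relaxes back
#' to the isolation equilibrium between migration events (flat low
#' plateau); at very high rates almost all tools are already shared, so
#' additional migrants add little (flat high plateau).
#'
#' @param p_mig_grid Ascending migration probabilities (ideally spanning
#'   at least five decades).
#' @param focal_size,neighbour_size Census sizes.
#' @param params A [sim_params()] object.
#' @param replicates Replicates per grid point.
#' @param seed Base seed.
#' @return A list of class `"connectivity_curve"`: `curve` (data frame of
#'   `p_mig`, replicate `mean`, `se`), the isolation equilibrium, and the
#'   detected shape flags `flat_low`, `rising`, `flat_high` (first/last
#'   increments below 15% of the total range, interior rise above 50%).
#' @export
run_connectivity_curve <- function(p_mig_grid = 10^seq(-8, -3),
                                   focal_size = 200L,
                                   neighbour_size = 400L,
                                   params = sim_params(),
                                   replicates = 5L,
                                   seed = 1L) {
  stopifnot(!is.unsorted(p_mig_grid))
  means <- numeric(length(p_mig_grid))
  ses <- numeric(length(p_mig_grid))
  for (g in seq_along(p_mig_grid)) {
    meta <- metapopulation(c(focal_size, neighbour_size),
                           p_mig = p_mig_grid[g])
    v <- numeric(replicates)
    for (r in seq_len(replicates))
      v[r] <- summary(run_simulation(meta, params,
                                     seed = derive_seed(seed, g, r),
                                     record_unique = FALSE))$mean_repertoire[1]
    means[g] <- mean(v)
    ses[g] <- stats::sd(v) / sqrt(replicates)
  }
  rng <- max(means) - min(means)
  k <- length(means)
  structure(list(
    curve = data.frame(p_mig = p_mig_grid, mean = means, se = ses),
    isolation_equilibrium = equilibrium_repertoire(focal_size, params),
    flat_low = k >= 3 && (means[2] - means[1]) < 0.15 * rng + 2 *
      sqrt(ses[1]^2 + ses[2]^2),
    rising = k >= 3 && rng > 0 &&
      (max(means) - means[1]) > 0.5 * rng,
    flat_high = k >= 3 && (means[k] - means[k - 1]) < 0.15 * rng + 2 *
      sqrt(ses[k]^2 + ses[k - 1]^2),
    seed = seed
  ), class = "connectivity_curve")
}

#' @export
print.connectivity_curve <- function(x, ...) {
  cat("Connectivity-repertoire curve\n")
  print(transform(x$curve, mean = round(mean, 2), se = round(se, 2)),
        row.names = FALSE)
  cat(sprintf("  isolation equilibrium: %.1f\n", x$isolation_equilibrium))
  cat(sprintf("  shape: flat_low = %s, rising = %s, flat_high = %s\n",
              x$flat_low, x$rising, x$flat_high))
  invisible(x)
}

#' @export
plot.connectivity_curve <- function(x, ...) {
  graphics::plot(log10(x$curve$p_mig), x$curve$mean, type = "b", pch = 16,
                 xlab = "log10 migration probability",
                 ylab = "focal mean repertoire", ...)
  graphics::arrows(log10(x$curve$p_mig), x$curve$mean - 2 * x$curve$se,
                   log10(x$curve$p_mig), x$curve$mean + 2 * x$curve$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = x$isolation_equilibrium, lty = 3)
  invisible(x)
}

#' Accumulation timeline
#'
#' Runs one simulation and returns a thinned per-step repertoire-size
#' series suitable for the standard accumulation plot (rise from an empty
#' repertoire to a fluctuating plateau).
#'
#' @param meta A [metapopulation()] object or vector of census sizes.
#' @param params A [sim_params()] object.
#' @param seed Seed.
#' @param thin Keep every `thin`-th step (default 100).
#' @return A data frame with columns `t`, `population`, `repertoire_size`.
#' @export
run_timeline <- function(meta, params = sim_params(), seed = 1L,
                         thin = 100L) {
  sim <- run_simulation(meta, params, seed = seed, record_unique = FALSE)
  idx <- seq.int(thin, params$t_max, by = thin)
  if (params$t_max < thin) idx <- seq_len(params$t_max)
  npop <- ncol(sim$sizes)
  data.frame(
    t = rep(idx, npop),
    population = rep(seq_len(npop), each = length(idx)),
    repertoire_size = as.vector(sim$sizes[idx, ])
  )
}
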