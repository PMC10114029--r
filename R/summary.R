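#' Summarise a simulation over the averaging window
#'
#' Computes the equilibrium summary statistics of a run: the time-averaged
#' repertoire size of every population over the window steps
#' `[window_start, window_end)`, the time-averaged count of tools unique
#' to each population (present there and in no other population at the
#' sampling instant, sampled every `unique_sample_every` steps), the
#' effective cultural population size implied by each mean repertoire, the
#' mean pairwise shared-tool counts and Jaccard indices over the same
#' samples, and the pooled statistics of the metapopulation-wide union
#' repertoire.
#'
#' @param object A `"culture_sim"` object from [run_simulation()].
#' @param ... Unused.
#' @return An object of class `"summary.culture_sim"`: a list with
#'   `mean_repertoire`, `mean_unique`, `n_eff` (per population),
#'   `mean_shared`, `jaccard` (per population pair, `NA` for a single
#'   population), `pooled_repertoire`, `pooled_n_eff`, `n_samples`, and
#'   the window bounds.
#' @export
summary.culture_sim <- function(object, ...) {
  params <- object$params
  ws <- params$window_start
  we <- params$window_end
  if (nrow(object$sizes) < we || ws >= we)
    stop("trajectory does not cover the averaging window [", ws, ", ", we,
         ")", call. = FALSE)
  win <- seq.int(max(ws, 1L), we - 1L)
  mean_rep <- colMeans(object$sizes[win, , drop = FALSE])

  npop <- ncol(object$sizes)
  nsamp <- length(object$unique_times)
  if (nsamp > 0L) {
    mean_unique <- colMeans(object$unique[seq_len(nsamp), , drop = FALSE])
    pooled <- mean(object$union_size)
    if (npop > 1L) {
      mean_shared <- colMeans(object$shared[seq_len(nsamp), , drop = FALSE])
      # per-sample pairwise Jaccard, then time-averaged
      jac <- matrix(NA_real_, nsamp, ncol(object$shared))
      k <- 1L
      szs <- object$sizes[object$unique_times, , drop = FALSE]
      for (i in seq_len(npop - 1L)) for (j in seq.int(i + 1L, npop)) {
        uni <- szs[, i] + szs[, j] - object$shared[, k]
        jac[, k] <- ifelse(uni > 0, object$shared[, k] / uni, NA_real_)
        k <- k + 1L
      }
      jaccard <- colMeans(jac, na.rm = TRUE)
    } else {
      mean_shared <- NA_real_
      jaccard <- NA_real_
    }
  } else {
    mean_unique <- rep(NA_real_, npop)
    mean_shared <- NA_real_
    jaccard <- NA_real_
    pooled <- NA_real_
  }

  structure(list(
    mean_repertoire = unname(mean_rep),
    mean_unique = unname(mean_unique),
    n_eff = unname(effective_population_size(unname(mean_rep), params)),
    mean_shared = unname(mean_shared),
    jaccard = unname(jaccard),
    pooled_repertoire = pooled,
    pooled_n_eff = if (is.na(pooled)) NA_real_ else
      effective_population_size(pooled, params),
    census = object$meta$sizes,
    n_samples = nsamp,
    window = c(ws, we)
  ), class = "summary.culture_sim")
}

#' @export
print.summary.culture_sim <- function(x, ...) {
  cat(sprintf("Equilibrium summary over window steps [%d, %d)\n",
              x$window[1], x$window[2]))
  df <- data.frame(census = x$census,
                   mean_repertoire = round(x$mean_repertoire, 2),
                   mean_unique = round(x$mean_unique, 2),
                   n_eff = round(x$n_eff, 1))
  print(df, row.names = FALSE)
  if (length(x$census) > 1L && !all(is.na(x$mean_shared))) {
    cat(sprintf("  mean shared tools: %s | mean Jaccard: %s\n",
                paste(round(x$mean_shared, 2), collapse = ", "),
                paste(round(x$jaccard, 3), collapse = ", ")))
    cat(sprintf("  pooled union repertoire: %.2f (pooled n_eff %.1f, census sum %d)\n",
                x$pooled_repertoire, x$pooled_n_eff, sum(x$census)))
  }
  invisible(x)
}
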