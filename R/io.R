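# configuration keys understood by load_config(); anything else is an error
config_param_keys <- c("p_inv", "beta", "p_loss", "p_mig", "f",
                       "payload_mode", "payload_k", "loss_model", "p_ind",
                       "t_max", "window_start", "window_end",
                       "unique_sample_every")
names2 <- function(x) if (is.null(names(x))) character(length(x)) else names(x)

config_top_keys <- c("params", "populations", "p_mig", "seed", "replicates",
                     "experiment", "focal_size", "neighbour_size",
                     "neighbour_sizes", "migration_probs", "variant",
                     "payload_k", "n", "p_mig_values", "p_mig_grid", "out")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, validates every key, applies the model
#' defaults for anything omitted, and returns the fully resolved
#' configuration. An empty document resolves to the standard protocol
#' (p_inv 0.001, beta 0.1, p_loss 0.1, f 1, 200 000 steps) for a single
#' isolated population of 200. Unknown keys — at the top level or inside
#' `params` — are rejected by name, so typos never silently fall back to a
#' default.
#'
#' An annotated example ships with the package:
#' `system.file("extdata", "example-config.json", package = "culturesim")`.
#' Keys starting with `_` are treated as comments and ignored.
#'
#' @param path Path to a JSON file. The document may contain: `params` (a
#'   mapping of [sim_params()] arguments), `populations` (census sizes),
#'   `p_mig` (scalar or matrix), `seed`, `replicates`, `experiment` (one
#'   of `run`, `sweep`, `unique`, `rescue`, `curve`, `timeline`), the
#'   experiment-specific fields (`focal_size`, `neighbour_size`,
#'   `neighbour_sizes`, `migration_probs`, `variant`, `payload_k`, `n`,
#'   `p_mig_values`, `p_mig_grid`), and `out`.
#' @return A list of class `"run_config"` with resolved `params` (a
#'   `sim_params` object), `meta` (a `metapopulation`), and the remaining
#'   fields with defaults applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("failed to parse configuration ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) raw <- list()
  if (!is.list(raw)) stop("configuration must be a JSON object", call. = FALSE)

  # keys starting with "_" are comments (JSON has no comment syntax)
  raw <- raw[!startsWith(names2(raw), "_")]
  if (!is.null(raw$params))
    raw$params <- raw$params[!startsWith(names2(raw$params), "_")]

  unknown <- setdiff(names(raw), config_top_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pl <- raw$params
  if (is.null(pl)) pl <- list()
  unknown <- setdiff(names(pl), config_param_keys)
  if (length(unknown))
    stop("unknown key(s) under params: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- tryCatch(do.call(sim_params, pl), error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))

  populations <- if (is.null(raw$populations)) 200L else raw$populations
  p_mig <- if (is.null(raw$p_mig)) params$p_mig else raw$p_mig
  if (is.list(p_mig)) p_mig <- do.call(rbind, lapply(p_mig, as.numeric))
  if (is.numeric(p_mig) && !is.matrix(p_mig) && length(p_mig) > 1L)
    p_mig <- matrix(p_mig, nrow = sqrt(length(p_mig)))
  meta <- tryCatch(metapopulation(populations, p_mig = p_mig),
                   error = function(e)
                     stop("invalid configuration: ", conditionMessage(e),
                          call. = FALSE))

  experiment <- if (is.null(raw$experiment)) "run" else raw$experiment
  experiment <- match.arg(experiment,
                          c("run", "sweep", "unique", "rescue", "curve",
                            "timeline"))

  cfg <- list(
    params = params,
    meta = meta,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    replicates = if (is.null(raw$replicates)) 10L else
      as.integer(raw$replicates),
    experiment = experiment,
    focal_size = if (is.null(raw$focal_size)) 200L else
      as.integer(raw$focal_size),
    neighbour_size = if (is.null(raw$neighbour_size)) 400L else
      as.integer(raw$neighbour_size),
    neighbour_sizes = if (is.null(raw$neighbour_sizes))
      seq(200L, 2000L, by = 200L) else as.integer(raw$neighbour_sizes),
    migration_probs = if (is.null(raw$migration_probs))
      seq(1e-6, 1e-5, by = 1e-6) else as.numeric(raw$migration_probs),
    variant = if (is.null(raw$variant)) "fraction_payload" else raw$variant,
    payload_k = raw$payload_k,
    n = if (is.null(raw$n)) 200L else as.integer(raw$n),
    p_mig_values = if (is.null(raw$p_mig_values)) c(1e-5, 1e-4, 1e-3) else
      as.numeric(raw$p_mig_values),
    p_mig_grid = if (is.null(raw$p_mig_grid)) 10^seq(-8, -3) else
      as.numeric(raw$p_mig_grid),
    out = raw$out
  )
  if (cfg$replicates < 1L)
    stop("invalid configuration: `replicates` must be >= 1", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration back to disk
#'
#' Serialises a [load_config()] result to JSON with every default made
#' explicit; reloading the written file reproduces the configuration
#' exactly, which is the provenance contract of the output sidecars.
#'
#' @param config A `"run_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  doc <- list(
    params = Filter(Negate(is.null), unclass(config$params)),
    populations = config$meta$sizes,
    p_mig = config$meta$p_mig,
    seed = config$seed,
    replicates = config$replicates,
    experiment = config$experiment,
    focal_size = config$focal_size,
    neighbour_size = config$neighbour_size,
    neighbour_sizes = config$neighbour_sizes,
    migration_probs = config$migration_probs,
    variant = config$variant,
    payload_k = config$payload_k,
    n = config$n,
    p_mig_values = config$p_mig_values,
    p_mig_grid = config$p_mig_grid,
    out = config$out
  )
  doc <- Filter(Negate(is.null), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# flatten any supported result object into the tidy long table written to
# disk: one row per population per replicate per cell where that applies
result_table <- function(result) {
  if (inherits(result, "culture_sweep")) return(result$records)
  if (inherits(result, "rescue_result")) return(as.data.frame(result))
  if (inherits(result, "connectivity_curve")) return(result$curve)
  if (inherits(result, "unique_tools_result")) {
    return(data.frame(replicate = seq_len(result$replicates),
                      population = "focal",
                      census = result$focal_size,
                      mean_repertoire = result$repertoire,
                      mean_unique = result$unique))
  }
  if (inherits(result, "culture_sim")) result <- summary(result)
  if (inherits(result, "summary.culture_sim")) {
    npop <- length(result$census)
    return(data.frame(population = seq_len(npop),
                      census = result$census,
                      mean_repertoire = result$mean_repertoire,
                      n_eff = result$n_eff,
                      mean_unique = result$mean_unique))
  }
  if (is.data.frame(result)) return(result)
  stop("don't know how to tabulate an object of class ",
       paste(class(result), collapse = "/"), call. = FALSE)
}

#' Write simulation results and a metadata sidecar
#'
#' Writes any result object of this package (`culture_sweep`,
#' `unique_tools_result`, `rescue_result`, `connectivity_curve`,
#' `culture_sim`/its summary, or a plain data frame such as a timeline) as
#' a tidy CSV, plus a JSON sidecar at `<path>.meta.json` carrying the
#' resolved configuration, seed, package version, and timestamp. The data
#' table depends only on the result, so re-running the same configuration
#' and seed yields a byte-identical CSV; everything volatile lives in the
#' sidecar.
#'
#' @param result A result object.
#' @param path Output CSV path.
#' @param config Optional `"run_config"` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, config = NULL) {
  tab <- result_table(result)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  meta <- list(
    package = "culturesim",
    version = as.character(utils::packageVersion("culturesim")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    result_class = class(result)[1],
    rows = nrow(tab),
    seed = if (!is.null(result$seed)) result$seed else
      attr(result, "seed", exact = TRUE)
  )
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    save_config(config, tmp)
    meta$config <- jsonlite::read_json(tmp, simplifyVector = TRUE)
    unlink(tmp)
  }
  jsonlite::write_json(Filter(Negate(is.null), meta),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
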