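#' Define a metapopulation
#'
#' A metapopulation is an ordered set of populations with fixed census
#' sizes and a pairwise per-individual migration probability matrix.
#' Census sizes never change: migration moves knowledge, not people.
#'
#' @param sizes Integer vector of census sizes (one per population, each
#'   at least 1).
#' @param p_mig Either a single per-individual, per-step migration
#'   probability applied to every ordered pair of distinct populations, or
#'   a square matrix whose `[i, j]` entry is the per-individual probability
#'   that an individual of population `i` migrates to population `j` in one
#'   step. The diagonal must be zero.
#'
#' @return An object of class `"metapopulation"` with elements `sizes` and
#'   `p_mig` (always stored as a matrix).
#' @examples
#' metapopulation(c(200, 400), p_mig = 5e-6)
#' @export
metapopulation <- function(sizes, p_mig = 0) {
  if (!is.numeric(sizes) || length(sizes) < 1L || any(!is.finite(sizes)) ||
      any(sizes < 1) || any(sizes != round(sizes)))
    stop("`sizes` must be a vector of census sizes (integers >= 1)",
         call. = FALSE)
  sizes <- as.integer(sizes)
  npop <- length(sizes)

  if (is.matrix(p_mig)) {
    if (nrow(p_mig) != npop || ncol(p_mig) != npop)
      stop("`p_mig` matrix must be ", npop, " x ", npop, call. = FALSE)
    pmat <- p_mig
  } else {
    if (!is.numeric(p_mig) || length(p_mig) != 1L)
      stop("`p_mig` must be a single probability or a square matrix",
           call. = FALSE)
    pmat <- matrix(p_mig, npop, npop)
  }
  diag(pmat) <- 0
  if (any(!is.finite(pmat)) || any(pmat < 0) || any(pmat > 1))
    stop("migration probabilities must lie in [0, 1]", call. = FALSE)
  if (any(rowSums(pmat) > 1))
    stop("total per-individual emigration probability exceeds 1 for at ",
         "least one population", call. = FALSE)

  structure(list(sizes = sizes, p_mig = pmat), class = "metapopulation")
}

#' @export
print.metapopulation <- function(x, ...) {
  npop <- length(x$sizes)
  cat(sprintf("Metapopulation of %d population%s\n", npop,
              if (npop == 1L) "" else "s"))
  cat("  census sizes:", paste(x$sizes, collapse = ", "), "\n")
  off <- x$p_mig[row(x$p_mig) != col(x$p_mig)]
  if (npop > 1L) {
    if (length(unique(off)) == 1L) {
      cat(sprintf("  per-individual migration probability: %g\n", off[1]))
    } else {
      cat("  migration matrix:\n")
      print(x$p_mig)
    }
  }
  invisible(x)
}
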