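# Independent brute-force implementation of one population's dynamics:
# an explicit loop over individuals (innovation) and over tools (loss),
# exactly as the model is defined, with none of the binomial-count
# shortcuts the production engine uses. Used only as an oracle.
oracle_run_final_size <- function(n, p_inv, beta, p_loss, t_max) {
  rep_s <- numeric(0)
  p_tool <- p_loss / n
  for (t in seq_len(t_max)) {
    for (ind in seq_len(n)) {
      if (stats::runif(1) < p_inv) {
        s <- min(stats::rexp(1, rate = 1 / beta), 1)
        if (stats::runif(1) < s) rep_s <- c(rep_s, s)
      }
    }
    if (length(rep_s)) {
      keep <- stats::runif(length(rep_s)) >= p_tool
      rep_s <- rep_s[keep]
    }
  }
  length(rep_s)
}
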