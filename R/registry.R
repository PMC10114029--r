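# Tool registry: append-only store of every tool that ever established
# anywhere. Tool ids are consecutive positive integers and double as the
# index into the backing vectors, so lookups are O(1). Ids are never
# reused, even after a tool is lost everywhere, which keeps lost-and-
# retransferred tools recognisable for unique-tool and overlap statistics.

new_registry <- function(init = 1024L) {
  reg <- new.env(parent = emptyenv())
  reg$s <- numeric(init)
  reg$origin <- integer(init)
  reg$t_inv <- integer(init)
  reg$n <- 0L
  class(reg) <- "tool_registry"
  reg
}

# register k tools sharing one origin population and invention step;
# returns their new ids
reg_add <- function(reg, s, origin, t) {
  k <- length(s)
  if (k == 0L) return(integer(0))
  n <- reg$n
  cap <- length(reg$s)
  if (n + k > cap) {
    newcap <- max(2L * cap, n + k)
    length(reg$s) <- newcap
    length(reg$origin) <- newcap
    length(reg$t_inv) <- newcap
  }
  ids <- seq.int(n + 1L, n + k)
  reg$s[ids] <- s
  reg$origin[ids] <- origin
  reg$t_inv[ids] <- t
  reg$n <- n + k
  ids
}

reg_size <- function(reg) reg$n

reg_s <- function(reg, ids) reg$s[ids]

#' @export
as.data.frame.tool_registry <- function(x, ...) {
  n <- x$n
  data.frame(id = seq_len(n), s = x$s[seq_len(n)],
             origin_pop = x$origin[seq_len(n)],
             t_invented = x$t_inv[seq_len(n)])
}

#' @export
print.tool_registry <- function(x, ...) {
  cat(sprintf("Tool registry: %d established tool%s\n", x$n,
              if (x$n == 1L) "" else "s"))
  invisible(x)
}
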