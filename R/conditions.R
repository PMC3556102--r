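# Typed conditions so callers can distinguish bad arguments from degenerate
# classifier training (which bootstrap callers handle by redrawing) and from
# rejection-sampling exhaustion.

stop_argument <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cvbias_argument_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cvbias_degenerate_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_exhausted <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cvbias_exhausted_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' Derive a child seed from a master seed
#'
#' One master seed spawns independent child seeds per (run, scheme, ...)
#' so any single table cell can be regenerated in isolation. Lehmer-style
#' mixing mod 2^31 - 1; multipliers are small enough that every intermediate
#' product stays below 2^53 and is exact in double arithmetic.
#'
#' @param master Master integer seed.
#' @param ... Further integer identifiers (run index, scheme index, ...).
#' @return An integer seed in \[0, 2^31 - 1).
#' @export
derive_seed <- function(master, ...) {
  ids <- c(master, ...)
  h <- 17
  for (v in ids) {
    h <- (h * 69621 + (as.numeric(v) %% 2147483647) + 97531) %% 2147483647
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
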