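## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

# Deterministic sub-seed per pipeline stage. Offsets keep stage streams
# distinct while staying inside 32-bit integer range.
sub_seed <- function(seed, stage) {
  offsets <- c(expression = 0L, clinical = 1L, outcomes = 2L,
               clustering = 3L, reference = 4L)
  if (!stage %in% names(offsets)) stop_domain("unknown seed stage: ", stage)
  s <- as.integer(seed) + offsets[[stage]]
  if (s >= .Machine$integer.max) s <- s - .Machine$integer.max + 1L
  s
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_domain(name, " must contain probabilities in [0, 1]")
  }
  invisible(x)
}

# Largest-remainder apportionment of n units to proportions p (sums to n
# exactly; deterministic, ties broken toward lower index).
largest_remainder <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# right-continuous step-function evaluation of (time, value) pairs with
# value v0 before the first time
step_eval <- function(time, value, at, v0) {
  idx <- findInterval(at, time)
  c(v0, value)[idx + 1L]
}
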