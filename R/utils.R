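# Internal helpers: classed errors, seed handling, interval arithmetic.

hb_stop <- function(msg, class) {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "hoofbeat_error", "error", "condition")
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive an independent RNG stream seed from a master seed and integer
# indices (recording, channel, band, ...). The scheme is a fixed-multiplier
# polynomial hash modulo a prime below 2^31, so any sub-stream is
# reproducible on its own: derive_seed(seed, i, j) depends only on (seed, i, j).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  primes <- c(100003, 10007, 1009, 101, 7919)
  s <- as.double(seed) %% 2147483629
  for (i in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[[i]]) * primes[[((i - 1L) %% 5L) + 1L]]) %% 2147483629
  }
  as.integer(s) + 1L
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Merge possibly-overlapping half-open intervals given as a 2-column matrix
# (start, end), after optional symmetric padding, clipped to [lo, hi].
merge_intervals <- function(intervals, pad = 0, lo = 0, hi = Inf) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- cbind(pmax(intervals[, 1] - pad, lo), pmin(intervals[, 2] + pad, hi))
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
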