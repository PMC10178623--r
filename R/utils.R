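#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. Every stochastic generator in the package funnels through
# this so that no function ever draws from unseeded global state.
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` is required (reproducibility contract)", call. = FALSE)
  }
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a deterministic child seed from a master seed and a label, kept
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- digest_string(parts)
  as.integer(h %% 2147483647)
}

# Small string hash (FNV-1a over bytes, folded to double) -- avoids a
# dependency for seed derivation only; not cryptographic.
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  h
}

# stopifnot() with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# half-open window [lo, hi) selector on a time axis in ms
window_index <- function(time_ms, window_ms) {
  which(time_ms >= window_ms[1] & time_ms < window_ms[2])
}

mean_square <- function(x) mean(x^2)
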