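#' Clip values to the unit interval
#'
#' Belief components and construct aggregates live on \[0, 1\]; every update
#' is clipped back into that range.
#'
#' @param x Numeric vector.
#' @return `x` with every element forced into \[0, 1\].
#' @export
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible child seed from a master seed and labels
#'
#' Combines a master seed with an arbitrary sequence of labels (condition
#' ids, replication indices, ...) into a 31-bit seed using the FNV-1a hash
#' over the string `"<seed>|<label>|<label>..."`. The scheme is stable
#' across platforms and R sessions, so every replication of every condition
#' gets an independent, reproducible random stream.
#'
#' @param master_seed Integer master seed.
#' @param ... Further labels (coerced to character) to mix in.
#' @return A single integer in \[0, 2^31 - 2\], usable with [set.seed()].
#' @examples
#' seed_combine(42, "M1", 3)
#' @export
seed_combine <- function(master_seed, ...) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed))
  key <- paste(c(format(as.integer(master_seed)), vapply(list(...), function(p)
    paste(format(p), collapse = ","), character(1))), collapse = "|")
  fnv1a32(key) %% 2147483647L
}

# FNV-1a 32-bit hash of a string, computed in doubles with 16-bit splits so
# the multiplication never leaves the exact-integer range of a double.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- (h %% 65536) * prime
    hi <- ((h %/% 65536) * prime) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

# XOR for nonnegative doubles < 2^32 (bitwXor only takes 32-bit signed ints).
bitwXor32 <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

# Round half away from zero (counts are nonnegative here, so half-up),
# matching how replicate-averaged evacuation counts are reported.
round_half_up <- function(x) floor(x + 0.5)

# Validate that a probability vector sums to 1.
check_marginal <- function(p, what) {
  if (any(p < 0 | p > 1)) {
    stop(sprintf("probabilities in '%s' must lie in [0, 1]", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("probabilities in '%s' must sum to 1 (got %.12f)", what, sum(p)),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
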