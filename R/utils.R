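# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child random seed from a master seed
#'
#' All stochastic generators draw their randomness from one integer master
#' seed through this splitting scheme: each generator call receives its own
#' child stream so that adding or reordering calls does not perturb the
#' others. The mix is a fixed affine map modulo 2^31 - 1, exact in double
#' precision.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index (small non-negative integer).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L)
  m <- 2147483647
  s <- (abs(seed) %% m)
  as.integer(((s * 69069) %% m + (stream * 1234567) %% m) %% m)
}

# Maximal runs of TRUE in a logical vector, as an integer matrix with
# columns start, end (1-based, inclusive). Zero-row matrix if none.
find_runs <- function(flag) {
  n <- length(flag)
  if (n == 0L || !any(flag)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Jaccard index of two inclusive integer intervals.
interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}

# 32-bit xor on doubles holding values in [0, 2^32).
xor32 <- function(a, b) {
  a_lo <- a %% 2^16; a_hi <- (a - a_lo) / 2^16
  b_lo <- b %% 2^16; b_hi <- (b - b_lo) / 2^16
  bitwXor(as.integer(a_lo), as.integer(b_lo)) +
    bitwXor(as.integer(a_hi), as.integer(b_hi)) * 2^16
}

# FNV-1a hash of a character scalar, returned as 8 hex digits; used for
# provenance stamping of configurations. 32-bit multiply done in two 16-bit
# halves so every step is exact in double precision.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- ((lo * 16777619) %% 2^32 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  lo <- h %% 2^16
  sprintf("%04x%04x", as.integer((h - lo) / 2^16), as.integer(lo))
}

# Fixed-format numeric for deterministic text output; full float precision.
fmt_full <- function(x) sprintf("%.17g", x)
fmt_ms <- function(x) sprintf("%.6f", x)

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
warn_msg <- function(...) warning(sprintf(...), call. = FALSE)

check_finite <- function(x, what, rows = seq_along(x)) {
  bad <- !is.finite(x)
  if (any(bad)) {
    stop_bad("non-finite %s at row %d", what, rows[which(bad)[1]])
  }
  invisible(x)
}
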