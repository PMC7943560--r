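# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stepnet_log <- function(fmt, ...) {
  message(sprintf(paste0("[stepnet] ", fmt), ...))
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp reports with a configuration fingerprint; stable across
# platforms because all arithmetic stays below 2^32 via double precision.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    if (h < 0) h <- h + 2^32
    # multiply by the FNV prime 16777619 mod 2^32 without overflow:
    # split h into high/low 16-bit halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# All permutations of 1..n as an n! x n integer matrix (lexicographic-ish
# order, deterministic). Only sensible for n <= 9.
all_perms <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[((i - 1L) * m + 1L):(i * m), ] <-
      cbind(rep.int(i, m), matrix(rest[sub], m, n - 1L))
  }
  out
}

# Deterministic child seed, kept well below .Machine$integer.max so a small
# caller-supplied seed never overflows.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483629)
}
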