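# Internal numeric and hashing helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    # all -Inf (no admissible path) stays -Inf; +Inf propagates
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic.
# R has no 64-bit integers; the multiply is split so intermediates stay
# below 2^53.
#' @noRd
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  h
}

# Keyed 64-bit-equivalent digest: two independent FNV-1a passes with
# domain-separated inputs, rendered as 16 hex characters.
#' @noRd
keyed_digest <- function(key, value) {
  h1 <- fnv1a32(paste0("a\x01", key, "\x02", value))
  h2 <- fnv1a32(paste0("b\x01", value, "\x02", key))
  # doubles may exceed .Machine$integer.max, so format in 16-bit halves
  hex8 <- function(h) {
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }
  paste0(hex8(h1), hex8(h2))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (config, seed).
#' @noRd
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_nmu <- function(..., class) {
  stop(structure(
    class = c(class, "nmutext_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
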