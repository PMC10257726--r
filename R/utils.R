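# Internal helpers: seeded RNG scoping, stable hashing for per-cell
# substreams, half-up rounding, and classed error conditions.

FRAME_INTERVAL_MIN <- 3
FWHM_CONST <- 2 * sqrt(2 * log(2))  # FWHM = 2.3548 * sigma for a Gaussian

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 31-bit polynomial hash of strings; used to derive independent per-cell
# RNG substreams so adding a cell never perturbs another cell's trace.
str_hash <- function(...) {
  s <- paste(..., sep = "\r")
  codes <- utf8ToInt(s)
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% m
  h
}

derive_seed <- function(seed, ...) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + str_hash(...)) %% m)
}

# round-half-up, so 62.5 -> 63 (matches conventional reporting, unlike
# base round()'s round-half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_format <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("erkpulse_format_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_config <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("erkpulse_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_invalid <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("erkpulse_invalid_error", "error", "condition"),
                 list(message = msg, call = call)))
}
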