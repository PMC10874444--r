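#' @useDynLib palscale, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median optimize plogis pnorm predict pt quantile
#'   rbinom rnorm runif sd var
#' @importFrom utils combn read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomized operations in the package funnel through this so that a
# seed argument fully determines their output without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive `n` child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used to stamp output files with the configuration that produced them.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor touches only the low byte
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 2^32
  }
  # h is a double in [0, 2^32); render as 8 hex digits
  hex <- "0123456789abcdef"
  out <- character(8)
  for (i in 8:1) {
    out[i] <- substr(hex, h %% 16 + 1, h %% 16 + 1)
    h <- h %/% 16
  }
  paste(out, collapse = "")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
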