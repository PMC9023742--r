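`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so that seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a hash of a deparsed R object; stamps a configuration
# fingerprint into pipeline outputs without external dependencies.  The
# multiply is split into 16-bit halves to stay exact in double precision.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits only (byte-sized input), keeping h a double
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice; used for Shrake-Rupley style surface
#' sampling so SASA values are reproducible bit-for-bit.
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Internal: stop() with sprintf-style formatting, no call in the message.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal: one frame row (length 3N, x1 y1 z1 x2 ...) <-> N x 3 matrix.
vec2mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
mat2vec <- function(m) as.numeric(t(m))
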