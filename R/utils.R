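#' Wrap phase angles to (-pi, pi]
#'
#' @param x Numeric vector or array of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic extension of a real series by zeroing
#' negative frequencies in the DFT. The series is mirror-padded (point
#' reflection is not needed here; plain mirroring suffices for envelope and
#' phase) by `pad` samples at both ends before the transform and trimmed
#' afterwards, which tames the edge artifacts that otherwise contaminate the
#' first and last few tens of milliseconds of a 1 s epoch.
#'
#' @param x Finite real numeric vector, length >= 4.
#' @param pad Number of mirror-padding samples per edge; default
#'   `min(256, floor(length(x) / 4))`.
#' @return An object of class `analytic_trace`: a list with `amplitude`
#'   (non-negative envelope), `phase` (instantaneous phase in (-pi, pi]) and
#'   `z` (the complex analytic series), all of the input length.
#' @examples
#' tr <- analytic(cos(2 * pi * 8 * (0:1023) / 1024))
#' range(tr$amplitude[100:900])
#' @export
analytic <- function(x, pad = NULL) {
  if (!is.numeric(x) || length(x) < 4L) {
    stop("analytic() needs a numeric series of length >= 4")
  }
  if (!all(is.finite(x))) stop("analytic() requires finite input")
  n <- length(x)
  if (is.null(pad)) pad <- min(256L, n %/% 4L)
  z <- hilbert_mat(matrix(x, ncol = 1L), pad = pad)[, 1L]
  structure(
    list(amplitude = Mod(z), phase = Arg(z), z = z),
    class = "analytic_trace"
  )
}

# Analytic signal of every column of a matrix (samples x series), mirror-padded.
# Vectorised across columns with mvfft; the workhorse behind analytic() and
# the PAC chain.
hilbert_mat <- function(X, pad = NULL) {
  n <- nrow(X)
  if (is.null(pad)) pad <- min(256L, n %/% 4L)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    top <- X[(pad + 1L):2L, , drop = FALSE]
    bot <- X[(n - 1L):(n - pad), , drop = FALSE]
    Xp <- rbind(top, X, bot)
  } else {
    Xp <- X
  }
  np <- nrow(Xp)
  h <- numeric(np)
  if (np %% 2L == 0L) {
    h[1L] <- 1
    h[np / 2L + 1L] <- 1
    h[2L:(np / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((np + 1L) / 2L)] <- 2
  }
  Z <- stats::mvfft(stats::mvfft(Xp) * h, inverse = TRUE) / np
  Z[(pad + 1L):(pad + n), , drop = FALSE]
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards. Keeps every stochastic entry point
# reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, staying well inside
# 32-bit integer range.
child_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000003L) * 1009L + seq_len(n) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
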