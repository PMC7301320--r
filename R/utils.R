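# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with integer indices (subject, drug, block, ...) into
#' a single positive 32-bit integer, so that every randomised stage of the
#' pipeline draws from its own deterministic stream.
#'
#' @param seed master seed (positive integer).
#' @param ... integer indices identifying the sub-stream.
#' @return a positive integer < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(seed) %% m
  primes <- c(1299709, 15485863, 32452843, 49979687, 67867967, 86028121)
  for (i in seq_along(idx)) {
    p <- primes[((i - 1L) %% length(primes)) + 1L]
    h <- (h * 31 + (as.numeric(idx[i]) + 1) * p) %% m
  }
  as.integer(h + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# ex-Gaussian RT sampler (normal + exponential), all parameters in ms
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}
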