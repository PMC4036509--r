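# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulators never clobber user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Deterministic sub-stream seed derived from a single user-facing seed.
# Lehmer-style mixing; exact in doubles (operands < 2^53), result < 2^31.
sub_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 48271 + k * 2654435) %% 2147483647)
}

# Multiplicative lognormal noise factors with unit mean and coefficient of
# variation `cv` (cv = 0 returns exact ones).
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdl^2 / 2, sd = sdl))
}

# Trapezoidal integral of y(t) sampled at (strictly increasing) times t.
trapezoid <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-n] + y[-1]) / 2)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}

# Full-precision numeric formatting for bit-exact TSV round trips.
format_full <- function(x) {
  sprintf("%.17g", x)
}
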