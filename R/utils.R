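# Internal helpers: seed derivation, circular sampling, colored noise.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a string tag, so that stages can be re-run independently and the
#' whole pipeline is reproducible from one integer. The derivation is a
#' multiplicative hash of the tag folded into the master seed, reduced
#' modulo 2^31 - 2 (R's set.seed accepts any 32-bit integer; we stay
#' strictly positive).
#'
#' @param master integer master seed.
#' @param ... tags (strings or integers) identifying the sub-stream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(7, "simulate", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647  # 2^31 - 1, prime
  h <- (abs(master) %% m)
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.numeric(tag)
    for (cc in codes) {
      # 31-bit multiplicative mix; doubles are exact below 2^53 so split the
      # multiplication to keep intermediates < 2^53
      h <- (h * 69069 + cc + 1) %% m
      h <- (h * 31 + 17) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for per-epoch phase-lag jitter of
#' planted couplings: lag ~ vonMises(mu, kappa), with kappa = 0 giving a
#' uniform phase (no coupling) and kappa = Inf a deterministic lag.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); `Inf` returns `mu` exactly.
#' @return angles wrapped to (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(wrap_angle(rep(mu, n)))
  if (kappa == 0) return(runif(n, -pi, pi))
  if (kappa > 1e4) {
    # wrapped-normal limit; error O(1/kappa) is far below sampling noise here
    return(wrap_angle(rnorm(n, mu, 1 / sqrt(kappa))))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  w <- atan2(sin(x), cos(x))
  w[w == -pi] <- pi
  w
}

# 1/f ("pink", power slope -1) Gaussian noise, unit variance, length n.
# Spectral shaping: white-noise FFT scaled by f^(-1/2) in amplitude.
pink_noise <- function(n, slope = -1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up; bin index as frequency
  f <- pmin(f, n - f + 1)            # symmetric (two-sided) frequency index
  g <- f^(slope / 2)
  g[1] <- 0                          # remove DC
  x <- Re(fft(W * g, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# clip numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# z-score columns of x using training-side statistics; returns list with
# transformed train/test. Zero-variance columns are centered only.
standardize_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(
    train = sweep(sweep(xtr, 2, mu, "-"), 2, sg, "/"),
    test  = sweep(sweep(xte, 2, mu, "-"), 2, sg, "/")
  )
}

# half-open window [w[1], w[2]) membership on a time axis
in_window <- function(times, w) times >= w[1] & times < w[2]

`%||%` <- function(a, b) if (is.null(a)) b else a
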