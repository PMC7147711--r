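# Random-number helpers shared by the simulators.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded simulator calls do not disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

#' Draw von Mises circular variates
#'
#' Best-Fisher rejection sampler for the von Mises distribution with mean
#' direction `mu` and concentration `kappa`. `kappa = 0` reduces to the
#' uniform distribution on the circle; large `kappa` concentrates tightly
#' around `mu`. Used to give synthetic oscillatory bursts a controlled
#' across-trial phase concentration, whose population resultant length is
#' the Bessel ratio I1(kappa)/I0(kappa).
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, `>= 0`.
#' @return Numeric vector of angles wrapped to (-pi, pi].
#' @examples
#' set.seed(1)
#' th <- rvonmises(1000, 0, 2)
#' Mod(mean(exp(1i * th)))  # near besselI(2, 1) / besselI(2, 0)
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  wrap_angle(mu + out)
}

#' Draw ex-Gaussian variates
#'
#' Sum of a Gaussian and an independent exponential; the standard
#' parameterization of go-process finishing times in race models of the
#' stop-signal task (mean `mu + tau`).
#'
#' @param n Number of draws.
#' @param mu,sigma Gaussian mean and standard deviation (ms).
#' @param tau Mean of the exponential tail (ms); `tau = 0` gives a pure
#'   Gaussian.
#' @return Numeric vector, ms.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma >= 0, tau >= 0)
  x <- stats::rnorm(n, mu, sigma)
  if (tau > 0) x <- x + stats::rexp(n, rate = 1 / tau)
  x
}

#' Wrap angles to (-pi, pi]
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
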