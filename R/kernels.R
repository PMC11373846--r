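#' Draw turn angles from a von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler.
#' `kappa = 0` (and numerically tiny kappa) falls back to the circular
#' uniform. Angles are returned in `(-pi, pi]` shifted by `mu`.
#'
#' @param n Number of draws.
#' @param kappa Concentration parameter (>= 0).
#' @param mu Mean direction in radians (default 0).
#' @return Numeric vector of angles in radians.
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) {
    theta <- runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(0)
    while (length(theta) < n) {
      m <- n - length(theta)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      if (any(keep)) {
        ang <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
        theta <- c(theta, ang)
      }
    }
    theta <- theta[seq_len(n)]
  }
  if (mu != 0) theta <- (theta + mu + pi) %% (2 * pi) - pi
  theta
}
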