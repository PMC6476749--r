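# numerically stable helpers shared by the likelihood and simulation code

# elementwise log(exp(a) + exp(b)); tolerates -Inf in either argument
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

# Dirichlet draws via normalised gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler on the circle; used by the diel-activity
#' generator and the smoothed bootstrap for the overlap coefficient.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
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
    nk <- sum(ok)
    if (nk > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  (out + mu) %% (2 * pi)
}

# maximum-likelihood von Mises concentration from the mean resultant length,
# via the standard Best-Fisher series/continued-fraction approximation
a1inv <- function(r) {
  if (r < 0) r <- 0
  if (r >= 1) return(Inf)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
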