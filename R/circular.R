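# Circular statistics for theta phase locking. Phases are in radians
# internally; user-facing preferred phase mu is reported in degrees in
# [-180, 180) with 0 deg at the theta peak.

#' Rayleigh test for circular uniformity
#'
#' Tests the null of a uniform phase distribution against a unimodal
#' alternative, using the standard large-sample approximation for the
#' p-value of the resultant length.
#'
#' @param phases numeric vector of phases (radians).
#' @return list with `r_bar` (mean resultant length), `n`, and `p`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("rayleigh_test: need at least 2 phases")
  C <- mean(cos(phases)); S <- mean(sin(phases))
  r_bar <- sqrt(C^2 + S^2)
  R <- n * r_bar
  z <- R^2 / n
  # Zar (1999) approximation
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, n = n, p = min(max(p, 0), 1))
}

#' Maximum-likelihood von Mises fit
#'
#' `mu` is the circular mean; `kappa` is recovered by inverting
#' A(kappa) = I1(kappa)/I0(kappa) at the mean resultant length, using the
#' Best-Fisher three-regime approximation followed by a few Newton steps on
#' the exact Bessel ratio. `kappa` is capped (degenerate samples).
#'
#' @param phases numeric vector of phases (radians).
#' @param kappa_max cap on the concentration estimate.
#' @return list with `mu` (radians, in `[-pi, pi)`), `kappa`.
#' @export
vonmises_mle <- function(phases, kappa_max = 50) {
  C <- mean(cos(phases)); S <- mean(sin(phases))
  mu <- atan2(S, C)
  r <- sqrt(C^2 + S^2)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  if (!is.finite(k) || k > kappa_max) k <- kappa_max
  if (k > 0 && k < kappa_max) {
    for (i in 1:5) {
      A <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
      dA <- 1 - A^2 - A / k
      step <- (A - r) / dA
      k <- k - step
      if (!is.finite(k) || k <= 0) { k <- 1e-8; break }
      if (k > kappa_max) { k <- kappa_max; break }
      if (abs(step) < 1e-10) break
    }
  }
  list(mu = atan2(sin(mu), cos(mu)), kappa = max(k, 0))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; reduces to uniform at `kappa = 0`.
#'
#' @param n number of samples.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return phases in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-9) {
    th <- runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      th <- sign(u3 - 0.5) * acos(f)
      out[i] <- th + mu
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

#' Convert radians to the reporting convention (degrees in [-180, 180))
#' @param rad phases in radians.
#' @export
phase_deg <- function(rad) {
  d <- (rad * 180 / pi) %% 360
  ifelse(d >= 180, d - 360, d)
}
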