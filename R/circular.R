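# Circular-statistics helpers for the heading model. Internal.

# Mean resultant length A1(kappa) = I1(kappa)/I0(kappa) of a von Mises
# distribution; exponentially scaled Bessel ratios keep this stable for
# large kappa.
.vm_rho <- function(kappa) {
  ifelse(kappa < 1e-8, kappa / 2,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Inverse of .vm_rho: concentration giving mean resultant length rho.
.vm_kappa <- function(rho) {
  stopifnot(rho >= 0, rho < 1)
  if (rho < 1e-8) return(0)
  f <- function(k) .vm_rho(k) - rho
  # rho < 1 - 1/(2*kappa) approx; upper bound comfortably above the root
  upper <- max(10, 2 / (1 - rho))
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-10, upper), tol = 1e-10)$root
}

# Wrap angles to (-pi, pi].
.wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# One heading update for n walkers. phi: current headings (radians, from +x).
# kappa_p: persistence concentration (pull toward the current heading);
# kappa_a: axial concentration (pull toward the nearer of +/- groove axis,
# i.e. +/- pi/2). The new heading is a wrapped-normal draw about the
# resultant direction, with spread matched to the resultant concentration so
# that E[cos(phi' - mu)] equals the von Mises mean resultant length.
.step_heading <- function(phi, kappa_p, kappa_a) {
  n <- length(phi)
  mu_axis <- ifelse(sin(phi) >= 0, pi / 2, -pi / 2)
  vx <- kappa_p * cos(phi) + kappa_a * cos(mu_axis)
  vy <- kappa_p * sin(phi) + kappa_a * sin(mu_axis)
  keff <- sqrt(vx^2 + vy^2)
  out <- numeric(n)
  flat <- keff < 1e-6
  if (any(flat)) out[flat] <- stats::runif(sum(flat), -pi, pi)
  if (any(!flat)) {
    mu <- atan2(vy[!flat], vx[!flat])
    sigma <- sqrt(-2 * log(.vm_rho(keff[!flat])))
    out[!flat] <- .wrap_angle(mu + sigma * stats::rnorm(sum(!flat)))
  }
  out
}

# Evaluate code with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls are reproducible without side effects.
.with_seed <- function(seed, code) {
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
  force(code)
}
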