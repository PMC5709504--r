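# Independent oracles used to cross-check the package implementation.

# Brute-force EME density: direct quadrature of the Erlang*exponential
# convolution written from the defining integral (independent of the
# package's own convolution helper, which integrates the mirrored kernel).
oracle_eme_conv <- function(t, k, lam1, lam2) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    f <- function(u) {
      # u is the exponential stage time; the Erlang part took ti - u
      dexp(u, rate = lam2) * dgamma(ti - u, shape = k, rate = lam1)
    }
    integrate(f, 0, ti, rel.tol = 1e-11)$value
  }, numeric(1))
}

# Closed-form k = 4 equal-rate stage means (hyperbolic/trigonometric form).
oracle_k4_stage_means <- function(t, C) {
  a <- 2^(9 / 4) * t / C
  e <- exp(-4 * t / C)
  cbind(M1 = e / 2 * (cosh(a) + cos(a)),
        M2 = e / 2^(5 / 4) * (sinh(a) + sin(a)),
        M3 = e / 2^(3 / 2) * (cosh(a) - cos(a)),
        M4 = e / 2^(7 / 4) * (sinh(a) - sin(a)))
}

# Plain-R direct-method SSA for the three-reaction exponential (k = 1)
# stem-cell model: S -> 2S (rho r1), S -> S + P (rho r2), S -> 2P (rho r3).
# Returns the stem count at t_end for one realization.
oracle_stemcell_k1 <- function(rho, r1, r3, s0, t_end) {
  s <- s0
  t <- 0
  repeat {
    if (s == 0) return(0L)
    t <- t + rexp(1, rate = rho * s)
    if (t > t_end) return(s)
    u <- runif(1)
    if (u < r1) s <- s + 1L
    else if (u < 1 - r3) s <- s  # asymmetric: stem count unchanged
    else s <- s - 1L
  }
}

# Monte-Carlo standard error of a sample variance, from the fourth moment.
se_of_variance <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  s2 <- var(x)
  sqrt((m4 - s2^2 * (n - 3) / (n - 1)) / n)
}
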