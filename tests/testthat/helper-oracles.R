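# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (double loops, direct order statistics,
# polynomial roots) and share no code with R/.

# Passing-Bablok by literal enumeration: explicit double loop over pairs,
# explicit shifted order statistics, no vectorized shortcuts.
pb_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0) next          # vertical or identical point
      s <- dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  ns <- length(slopes)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  if (ns %% 2 == 1) {
    b <- slopes[(ns + 1) / 2 + K]
  } else {
    b <- (slopes[ns / 2 + K] + slopes[ns / 2 + 1 + K]) / 2
  }
  C <- qnorm((1 + conf_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- floor((ns - C) / 2 + 0.5)
  M2 <- ns - M1 + 1
  clamp <- function(i) min(max(i, 1), ns)
  list(slope = b,
       slope_lo = slopes[clamp(M1 + K)],
       slope_hi = slopes[clamp(M2 + K)],
       intercept = median(y - b * x),
       slopes = slopes)
}

# Free-T4 equilibrium by clearing denominators: total = F + sum_i
# P_i Ka_i F / (1 + Ka_i F) becomes a degree-4 polynomial in F whose
# admissible root lies in (0, total].  Coefficients are expanded
# symbolically for the three-binder case.
equilibrium_poly_oracle <- function(total, p, ka) {
  stopifnot(length(p) == 3, length(ka) == 3)
  # multiply through by prod(1 + ka_i F); collect powers of F
  # (F - total) * prod(1 + ka_i F) + sum_i p_i ka_i F * prod_{j != i} (1 + ka_j F) = 0
  e1 <- sum(ka)
  e2 <- ka[1] * ka[2] + ka[1] * ka[3] + ka[2] * ka[3]
  e3 <- ka[1] * ka[2] * ka[3]
  # (F - total)(1 + e1 F + e2 F^2 + e3 F^3)
  c0 <- -total
  c1 <- 1 - total * e1
  c2 <- e1 - total * e2
  c3 <- e2 - total * e3
  c4 <- e3
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    s1 <- ka[others[1]] + ka[others[2]]
    s2 <- ka[others[1]] * ka[others[2]]
    # p_i ka_i F (1 + s1 F + s2 F^2)
    c1 <- c1 + p[i] * ka[i]
    c2 <- c2 + p[i] * ka[i] * s1
    c3 <- c3 + p[i] * ka[i] * s2
  }
  roots <- polyroot(c(c0, c1, c2, c3, c4))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * max(1, abs(Re(roots)))])
  cand <- real[real > 0 & real <= total * (1 + 1e-12)]
  stopifnot(length(cand) >= 1)
  min(cand)
}

# Exact Mann-Whitney two-sided p by full enumeration (used as a second,
# independently coded route at tiny n).
mw_brute_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  all_u <- apply(combn(n, na), 2, u_of)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

default_constants <- calibrate_binding_constants()

# A well-spread noiseless reference series for exact-line checks.
x_spread <- c(10, 11.5, 13, 14.2, 16, 17.5, 19, 21, 23.5, 26, 28, 30)
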