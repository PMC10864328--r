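# Independent oracles: deliberately naive implementations used only to
# cross-check the production code paths.

# Brute-force P2 autocorrelation: explicit double loop over all ordered
# (origin, origin + lag) frame pairs. O(n^2); for tiny inputs only.
oracle_p2_loop <- function(v, L) {
  n <- nrow(v)
  out <- numeric(L + 1)
  for (l in 0:L) {
    acc <- 0
    for (t0 in 1:(n - l)) {
      ct <- sum(v[t0, ] * v[t0 + l, ])
      acc <- acc + 1.5 * ct^2 - 0.5
    }
    out[l + 1] <- acc / (n - l)
  }
  out
}

# Textbook mono-exponential (rigid rotor) 15N relaxation with Lorentzian
# Lipari-Szabo spectral density j(w) = (2/5) tau / (1 + (w tau)^2).
oracle_relax_15N <- function(tau_s, mhz, r_A = 1.02, dsig_ppm = -170) {
  gH <- 2.6752218744e8; gN <- -2.7126e7; hbar <- 1.054571817e-34
  wH <- 2 * pi * mhz * 1e6; wN <- wH * abs(gN / gH)
  j <- function(w) 0.4 * tau_s / (1 + (w * tau_s)^2)
  d <- 1e-7 * hbar * gH * abs(gN) / (r_A * 1e-10)^3
  cc <- wN * dsig_ppm * 1e-6 / sqrt(3)
  R1 <- d^2 / 4 * (j(wH - wN) + 3 * j(wN) + 6 * j(wH + wN)) + cc^2 * j(wN)
  R2 <- d^2 / 8 * (4 * j(0) + j(wH - wN) + 3 * j(wN) + 6 * j(wH) + 6 * j(wH + wN)) +
    cc^2 / 6 * (4 * j(0) + 3 * j(wN))
  T1 <- 1 / R1
  list(T1 = T1, T2 = 1 / R2,
       hetNOE = 1 + (gH / gN) * (d^2 / 4) * (6 * j(wH + wN) - j(wH - wN)) * T1)
}

# Textbook mono-exponential quadrupolar (2H) relaxation, axial EFG.
oracle_relax_2H <- function(tau_s, mhz, chi_kHz = 167) {
  gH <- 2.6752218744e8; gD <- 4.10663e7
  wD <- 2 * pi * mhz * 1e6 * gD / gH
  j <- function(w) 0.4 * tau_s / (1 + (w * tau_s)^2)
  chi <- chi_kHz * 1e3
  R1 <- (3 * pi^2 / 10) * chi^2 * (j(wD) + 4 * j(2 * wD))
  R2 <- (3 * pi^2 / 20) * chi^2 * (3 * j(0) + 5 * j(wD) + 2 * j(2 * wD))
  list(T1 = 1 / R1, T2 = 1 / R2)
}

# From-scratch Pearson r and two-sided t-test p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Random unit vectors for property tests.
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# A rotation matrix about an arbitrary axis.
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Mono-exponential expfit at an exact timescale (weight 1 on tau_ps).
mono_fit <- function(tau_ps) {
  spinscape::expfit(c(1, 0), spinscape::timescale_grid(2, tau_ps, tau_ps * 10))
}
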