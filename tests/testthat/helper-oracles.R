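# Independent brute-force oracles and shared fixtures, written against the
# textbook definitions rather than the package internals.

# Angular-momentum matrices assembled directly from the ladder-operator
# definition (independent of s2epr::spin_operators).
oracle_spin_matrices <- function(S) {
  m <- seq(S, -S)
  n <- length(m)
  Sz <- diag(m) + 0i
  Sp <- matrix(0 + 0i, n, n)
  for (i in seq_len(n - 1)) {
    Sp[i, i + 1] <- sqrt(S * (S + 1) - m[i + 1] * (m[i + 1] + 1))
  }
  Sm <- Conj(t(Sp))
  list(Sx = (Sp + Sm) / 2, Sy = (Sp - Sm) / (2i), Sz = Sz)
}

# Eigenvalues of the bare ZFS Hamiltonian D(Sz^2 - S(S+1)/3) + E(Sx^2-Sy^2),
# by direct diagonalization of the hand-assembled matrix.
oracle_zfs_eigvals <- function(S, D, E) {
  op <- oracle_spin_matrices(S)
  n <- 2 * S + 1
  H <- D * (op$Sz %*% op$Sz - S * (S + 1) / 3 * diag(n)) +
    E * (op$Sx %*% op$Sx - op$Sy %*% op$Sy)
  sort(Re(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
}

# CODATA constants for closed-form checks, restated independently.
ORACLE <- list(
  beta_cmG = 9.2740100783e-24 * 1e-4 / (6.62607015e-34 * 2.99792458e10),
  ghz_to_cm = 1e9 / 2.99792458e10,
  mhz_to_cm = 1e6 / 2.99792458e10
)

# A symmetric Gaussian first-derivative line for signal-location tests.
gaussian_derivative_line <- function(axis, center, sigma, amplitude = 1) {
  u <- (axis - center) / sigma
  -amplitude * u * exp(-u^2 / 2)
}

# Small, fast synthetic configuration used across the analysis tests:
# electron-only g4.1 species and a modest orientation grid.
fast_synth_cfg <- function(...) {
  synth_config(g41_system = g41_spin52(hyperfine = FALSE),
               g41_n_orientations = 100, ...)
}
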