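# Spin-Hamiltonian assembly in the product basis
# |m_S> (x) |m_I1> (x) |m_I2> ..., energies in cm^-1, fields in Gauss.

# Angular-momentum operator matrices for spin j in the |m = j..-j> basis.
spin_operators <- function(j) {
  m <- seq(j, -j)
  n <- length(m)
  Sz <- diag(m) + 0i
  Sp <- matrix(0 + 0i, n, n)
  if (n > 1) {
    for (i in 2:n) Sp[i - 1, i] <- sqrt(j * (j + 1) - m[i] * (m[i] + 1))
  }
  Sm <- Conj(t(Sp))
  list(x = (Sp + Sm) / 2, y = (Sp - Sm) / (2i), z = Sz)
}

# Embed an operator acting on subspace `which` of the product space whose
# factor dimensions are `dims` (electron first, then nuclei in order).
.embed <- function(op, dims, which) {
  out <- if (which == 1) op else diag(dims[1]) + 0i
  if (length(dims) > 1) {
    for (k in 2:length(dims)) {
      fac <- if (k == which) op else diag(dims[k]) + 0i
      out <- kronecker(out, fac)
    }
  }
  out
}

# Field-independent part H0 (ZFS + cubic + hyperfine) and the per-Gauss
# Zeeman derivative operators Gx, Gy, Gz = beta * g_a * (S_a (x) 1), all in
# cm^-1 (per Gauss for G*).  The G operators double as the B1 transition
# moment operators (g-squared intensity convention).
ham_parts <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  dims <- c(2 * sys$S + 1, vapply(sys$nuclei, function(n) 2 * n$I + 1,
                                  numeric(1)))
  dims <- as.integer(round(dims))
  dim_tot <- prod(dims)
  Sop <- spin_operators(sys$S)
  Sx <- .embed(Sop$x, dims, 1L)
  Sy <- .embed(Sop$y, dims, 1L)
  Sz <- .embed(Sop$z, dims, 1L)
  Id <- diag(dim_tot) + 0i

  S <- sys$S
  H0 <- sys$D_cm1 * (Sz %*% Sz - S * (S + 1) / 3 * Id) +
    sys$E_cm1 * (Sx %*% Sx - Sy %*% Sy)
  if (sys$a_cubic_cm1 != 0) {
    S4 <- Sx %*% Sx %*% Sx %*% Sx + Sy %*% Sy %*% Sy %*% Sy +
      Sz %*% Sz %*% Sz %*% Sz
    off <- S * (S + 1) * (3 * S^2 + 3 * S - 1) / 5
    H0 <- H0 + sys$a_cubic_cm1 / 6 * (S4 - off * Id)
  }
  if (length(sys$nuclei)) {
    for (k in seq_along(sys$nuclei)) {
      nuc <- sys$nuclei[[k]]
      Iop <- spin_operators(nuc$I)
      A <- nuc$A_MHz * .mhz_to_cm
      H0 <- H0 +
        A[1] * Sx %*% .embed(Iop$x, dims, k + 1L) +
        A[2] * Sy %*% .embed(Iop$y, dims, k + 1L) +
        A[3] * Sz %*% .embed(Iop$z, dims, k + 1L)
    }
  }
  list(H0 = H0,
       Gx = .beta_cmG * sys$g[1] * Sx,
       Gy = .beta_cmG * sys$g[2] * Sy,
       Gz = .beta_cmG * sys$g[3] * Sz)
}

#' Build the spin Hamiltonian at a given magnetic field
#'
#' Assembles the electron Zeeman, zero-field-splitting, cubic
#' fine-structure, and 55Mn hyperfine terms of a [spin_system()] in the
#' electron-nuclear product basis.  Energies are in cm^-1, the field in
#' Gauss.
#'
#' @param sys a [spin_system()].
#' @param field_gauss magnetic field 3-vector in Gauss.
#' @return a Hermitian complex matrix of dimension [hilbert_dim()].
#' @examples
#' H <- build_hamiltonian(spin_system(3/2, D_cm1 = 0.3), c(0, 0, 0))
#' Re(diag(H))  # zero-field doublets split by 2D = 0.6 cm^-1
#' @export
build_hamiltonian <- function(sys, field_gauss) {
  stopifnot(length(field_gauss) == 3, all(is.finite(field_gauss)))
  p <- ham_parts(sys)
  p$H0 + field_gauss[1] * p$Gx + field_gauss[2] * p$Gy + field_gauss[3] * p$Gz
}

#' Diagonalize a spin Hamiltonian
#'
#' @param H Hermitian matrix in cm^-1 (e.g. from [build_hamiltonian()]).
#' @param field_gauss the field 3-vector at which `H` was built (stored for
#'   provenance; default `c(0, 0, 0)`).
#' @param tol relative Hermiticity tolerance.
#' @return an object of class `eigensystem`: `energies` (ascending, cm^-1),
#'   `states` (unitary eigenvector matrix, columns match `energies`), and
#'   `field`.
#' @export
eigensystem <- function(H, field_gauss = c(0, 0, 0), tol = 1e-10) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("`H` must be square")
  nrm <- max(abs(H), 1e-300)
  if (max(abs(H - Conj(t(H)))) > tol * nrm) {
    stop("`H` is not Hermitian to within tolerance")
  }
  e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  structure(list(energies = rev(e$values) * 1.0,
                 states = e$vectors[, rev(seq_len(ncol(H))), drop = FALSE],
                 field = field_gauss),
            class = "eigensystem")
}

#' @export
print.eigensystem <- function(x, ...) {
  cat(sprintf("<eigensystem> %d levels at B = (%g, %g, %g) G\n",
              length(x$energies), x$field[1], x$field[2], x$field[3]))
  print(x$energies)
  invisible(x)
}

#' Zero-field level structure (Kramers doublet ladder)
#'
#' Diagonalizes the field-free Hamiltonian and clusters the energies into
#' degenerate groups.  For half-integer spins every zero-field level is at
#' least doubly degenerate (Kramers theorem); a rhombic S = 5/2 system
#' yields exactly three doublets.
#'
#' @param sys a [spin_system()].
#' @param tol energy tolerance (cm^-1) for clustering degenerate levels.
#' @return a data frame with columns `energy_cm1` (relative to the lowest
#'   level, ascending) and `degeneracy`.
#' @examples
#' zero_field_levels(spin_system(3/2, D_cm1 = 0.45, E_over_D = 0.25))
#' # two doublets separated by 2 * sqrt(D^2 + 3 E^2)
#' @export
zero_field_levels <- function(sys, tol = 1e-8) {
  es <- eigensystem(build_hamiltonian(sys, c(0, 0, 0)))
  e <- es$energies - min(es$energies)
  groups <- cumsum(c(TRUE, diff(e) > tol))
  data.frame(energy_cm1 = as.numeric(tapply(e, groups, mean)),
             degeneracy = as.integer(table(groups)))
}
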