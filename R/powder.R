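# Powder CW-EPR simulation: orientation averaging of the eigenfield
# resonance search, Gaussian lineshape convolution, field derivative.

#' Deterministic orientation grid over one octant
#'
#' Igloo (ring) grid of field orientations.  With collinear orthorhombic
#' tensors the powder average only requires one octant of the unit sphere;
#' `n_orientations` is the nominal hemisphere count, of which ~n/4 knots are
#' placed in the octant and weighted by solid angle.
#'
#' @param n_orientations nominal hemisphere orientation count (>= 50).
#' @return list with `vectors` (m x 3 unit rows) and `weights` (sum 1).
#' @export
orientation_grid <- function(n_orientations) {
  if (n_orientations < 50) stop("`n_orientations` must be >= 50")
  n_oct <- max(4L, as.integer(round(n_orientations / 4)))
  K <- max(2L, as.integer(round(sqrt(2 * n_oct))))
  theta <- (seq_len(K) - 0.5) * (pi / 2) / K
  m_ring <- pmax(1L, as.integer(round(n_oct * sin(theta) / sum(sin(theta)))))
  vecs <- matrix(0, sum(m_ring), 3)
  wts <- numeric(sum(m_ring))
  r <- 0L
  for (k in seq_len(K)) {
    m <- m_ring[k]
    phi <- (seq_len(m) - 0.5) * (pi / 2) / m
    idx <- r + seq_len(m)
    vecs[idx, ] <- cbind(sin(theta[k]) * cos(phi), sin(theta[k]) * sin(phi),
                         rep(cos(theta[k]), m))
    wts[idx] <- sin(theta[k]) / m
    r <- r + m
  }
  list(vectors = vecs, weights = wts / sum(wts))
}

#' Resonance fields for one orientation
#'
#' Scans the level differences of the spin Hamiltonian along a field ladder
#' in the search window, brackets the roots of `dE(B) - h nu` for every
#' ordered level pair, and refines each root with a safeguarded secant to
#' `refine_tol_G`.  The intensity of each transition is the squared
#' magnetic-dipole transition moment for B1 perpendicular to the static
#' field (g-tensor folded in), times the Boltzmann population difference at
#' `sys$temperature_K`, times the frequency-to-field factor
#' `1/|d(dE)/dB|`.
#'
#' @param sys a [spin_system()].
#' @param orientation static-field direction (3-vector, normalized
#'   internally) in the molecular frame.
#' @param frequency_GHz microwave frequency in GHz.
#' @param field_window_G two-vector search window in Gauss (positive,
#'   finite).
#' @param ladder_points number of ladder knots across the window.
#' @param refine_tol_G root refinement tolerance in Gauss; at the default
#'   1e-3 G every reported field satisfies `|dE - h nu| <= 1e-6 h nu`.
#' @return a `transition_set`: data frame with columns
#'   `resonance_field_G`, `amplitude`, `lower`, `upper` (level indices),
#'   `dEdB_cm1_per_G`; the orientation is kept as an attribute.  An empty
#'   frame (no transitions in the window) is not an error.
#' @export
resonance_search <- function(sys, orientation, frequency_GHz, field_window_G,
                             ladder_points = 64, refine_tol_G = 1e-3) {
  stopifnot(inherits(sys, "spin_system"), length(orientation) == 3)
  nrm <- sqrt(sum(orientation^2))
  if (!is.finite(nrm) || nrm == 0) stop("`orientation` must be a nonzero vector")
  orientation <- orientation / nrm
  if (length(field_window_G) != 2 || any(!is.finite(field_window_G)) ||
      any(field_window_G < 0) || diff(range(field_window_G)) <= 0) {
    stop("`field_window_G` must be a finite nonnegative interval")
  }
  ladder <- seq(min(field_window_G), max(field_window_G),
                length.out = max(8, ladder_points))
  p <- ham_parts(sys)
  m <- .resonances_cpp(p$H0, p$Gx, p$Gy, p$Gz, orientation, ladder,
                       frequency_GHz * .ghz_to_cm, sys$temperature_K,
                       refine_tol_G)
  out <- data.frame(resonance_field_G = m[, 1], amplitude = m[, 2],
                    lower = as.integer(m[, 3]), upper = as.integer(m[, 4]),
                    dEdB_cm1_per_G = m[, 5])
  out <- out[order(out$resonance_field_G), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  class(out) <- c("transition_set", class(out))
  out
}

# Bin resonance sticks (B, amplitude) onto a uniform axis with linear
# splitting between the two neighbouring bins.
.bin_sticks <- function(B, amp, axis) {
  n <- length(axis)
  dx <- axis[2] - axis[1]
  acc <- numeric(n)
  pos <- (B - axis[1]) / dx
  keep <- pos > -1 & pos < n
  pos <- pos[keep]
  amp <- amp[keep]
  i0 <- floor(pos)
  frac <- pos - i0
  lo <- i0 + 1L
  hi <- lo + 1L
  w_lo <- amp * (1 - frac)
  w_hi <- amp * frac
  ok <- lo >= 1 & lo <= n
  if (any(ok)) {
    s <- rowsum(w_lo[ok], lo[ok])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  ok <- hi >= 1 & hi <= n
  if (any(ok)) {
    s <- rowsum(w_hi[ok], hi[ok])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  acc
}

# Convolve a binned absorption with a unit-sum Gaussian whose
# peak-to-peak first-derivative width is `linewidth_G`, then (optionally)
# differentiate with respect to field (central differences).
.broaden <- function(acc, dx, linewidth_G, derivative = TRUE) {
  sigma <- linewidth_G / 2
  half <- max(3L, ceiling(5 * sigma / dx))
  kern <- stats::dnorm(seq(-half, half) * dx, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(acc)
  padded <- c(numeric(half), acc, numeric(half))
  conv <- stats::convolve(padded, rev(kern), type = "open")
  y <- conv[(2 * half + 1):(2 * half + n)]
  if (derivative) {
    d <- numeric(n)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dx)
    d[1] <- (y[2] - y[1]) / dx
    d[n] <- (y[n] - y[n - 1]) / dx
    d
  } else {
    y
  }
}

#' Powder first-derivative CW-EPR spectrum
#'
#' Orientation-averaged field-swept spectrum: eigenfield resonance search
#' over a deterministic octant grid ([orientation_grid()]), sticks
#' accumulated in field, convolved with a Gaussian of peak-to-peak
#' derivative width `linewidth_G`, and differentiated once with respect to
#' field.  Fully deterministic (no randomness anywhere).
#'
#' The ladder spans the field axis extended by four linewidths on both
#' sides, so lines just outside the window contribute their tails.
#' Resonance fields between ladder knots are obtained by linear
#' interpolation of the level differences; with the default 32-knot ladder
#' the positional error is a small fraction of any realistic linewidth
#' (set `refine_tol_G > 0` to force secant refinement of every root).
#'
#' @param sys a [spin_system()]; `sys$temperature_K` sets the Boltzmann
#'   weights.
#' @param frequency_GHz microwave frequency in GHz.
#' @param field_axis uniform ascending field axis in Gauss.
#' @param n_orientations nominal hemisphere orientation count (default
#'   3000; 300 is adequate for coarse work).
#' @param linewidth_G Gaussian peak-to-peak linewidth in Gauss (> 0).
#' @param ladder_points knots of the field ladder per orientation.
#' @param refine_tol_G per-root refinement tolerance in Gauss (0 = linear
#'   interpolation only, the default).
#' @param vec_stride eigenvectors (for transition moments and populations)
#'   are computed at every `vec_stride`-th ladder knot.
#' @return an [epr_spectrum()] on `field_axis`.
#' @examples
#' \donttest{
#' axis <- seq(400, 2900, length.out = 1250)
#' spec <- powder_spectrum(g41_spin52(hyperfine = FALSE), 9.369115, axis,
#'                         n_orientations = 300, linewidth_G = 140)
#' effective_g(locate_signal_center(spec, c(1200, 2200)), 9.369115)
#' }
#' @export
powder_spectrum <- function(sys, frequency_GHz, field_axis,
                            n_orientations = 3000, linewidth_G,
                            ladder_points = 32, refine_tol_G = 0,
                            vec_stride = 4) {
  stopifnot(inherits(sys, "spin_system"))
  if (linewidth_G <= 0) stop("`linewidth_G` must be > 0")
  dx <- .check_uniform(field_axis)
  pad <- ceiling(4 * linewidth_G / dx)
  ext <- c(seq(field_axis[1] - pad * dx, by = dx, length.out = pad),
           field_axis,
           seq(field_axis[length(field_axis)] + dx, by = dx,
               length.out = pad))
  ladder <- seq(max(min(ext), 0), max(ext), length.out = max(8, ladder_points))
  grid <- orientation_grid(n_orientations)
  p <- ham_parts(sys)
  sticks <- .powder_sticks_cpp(p$H0, p$Gx, p$Gy, p$Gz, grid$vectors,
                               grid$weights, ladder,
                               frequency_GHz * .ghz_to_cm,
                               sys$temperature_K, as.integer(vec_stride),
                               refine_tol_G)
  acc <- .bin_sticks(sticks[, 1], sticks[, 2], ext)
  y <- .broaden(acc, dx, linewidth_G, derivative = TRUE)
  keep <- (pad + 1):(pad + length(field_axis))
  epr_spectrum(field_axis, y[keep], frequency_GHz = frequency_GHz,
               temperature_K = sys$temperature_K,
               metadata = list(simulated = "powder derivative",
                               n_orientations = n_orientations,
                               linewidth_G = linewidth_G))
}

#' Effective g-values of a Kramers doublet
#'
#' Intradoublet effective g along each principal axis in the weak-field
#' limit, `g_eff = lim_{B -> 0} dE_doublet / (beta B)`, computed by exact
#' diagonalization at a probe field of 0.1 G.  Valid in the high-D regime
#' where the microwave quantum does not mix the doublets; a warning is
#' issued when `|D| < 5 h nu` at X-band.  In the fully rhombic S = 5/2
#' limit (E/D = 1/3, intrinsic g = 2.00) the middle doublet is isotropic
#' with g = 30/7 = 4.286 and the outer doublets give the principal set
#' {9.678, 0.857, 0.607}; the axial S = 3/2 +/-1/2 doublet gives (4, 4, 2).
#'
#' Nuclei, if present, are dropped for this electron-doublet calculation.
#'
#' @param sys a [spin_system()].
#' @param doublet_index 1-based doublet index, ascending in energy: 1..3
#'   for S = 5/2, 1..2 for S = 3/2.
#' @param frequency_GHz frequency used only for the high-D regime check.
#' @return named numeric `c(gx_eff, gy_eff, gz_eff)`.
#' @export
doublet_effective_g <- function(sys, doublet_index, frequency_GHz = 9.369115) {
  stopifnot(inherits(sys, "spin_system"))
  sys <- drop_nuclei(sys)
  n_doub <- (2 * sys$S + 1) / 2
  if (!doublet_index %in% seq_len(n_doub)) {
    stop("`doublet_index` must be in 1..", n_doub)
  }
  nu_cm <- frequency_GHz * .ghz_to_cm
  if (abs(sys$D_cm1) < 5 * nu_cm && sys$S > 1/2) {
    warning("|D| < 5 h nu: doublet effective g-values assume the high-D limit")
  }
  B <- 0.1 # Gauss; linear regime, splitting still >> eigensolver noise
  out <- vapply(list(c(B, 0, 0), c(0, B, 0), c(0, 0, B)), function(fv) {
    e <- eigensystem(build_hamiltonian(sys, fv), fv)$energies
    pair <- e[c(2 * doublet_index - 1, 2 * doublet_index)]
    (pair[2] - pair[1]) / (.beta_cmG * B)
  }, numeric(1))
  names(out) <- c("gx_eff", "gy_eff", "gz_eff")
  out
}

#' Locate the center of the dominant derivative feature
#'
#' Finds the zero crossing of the first-derivative feature with the largest
#' peak-to-peak amplitude inside a field window: the crossing between the
#' window's extremal maximum and minimum, linearly interpolated between
#' samples.  Used to read an effective g off a simulated or measured
#' spectrum (e.g. the g4.1 feature "centered near g = 4.1").
#'
#' @param spec an [epr_spectrum()].
#' @param window_G two-vector window in Gauss, inside the field axis.
#' @return the crossing field in Gauss.
#' @export
locate_signal_center <- function(spec, window_G) {
  stopifnot(inherits(spec, "epr_spectrum"))
  idx <- .window_idx(spec, window_G)
  x <- spec$field_G[idx]
  y <- spec$intensity[idx]
  i_max <- which.max(y)
  i_min <- which.min(y)
  lo <- min(i_max, i_min)
  hi <- max(i_max, i_min)
  if (lo == hi) stop("no derivative feature found in window")
  seg <- lo:hi
  sgn <- sign(y[seg])
  cross <- which(sgn[-length(sgn)] * sgn[-1] <= 0 & sgn[-length(sgn)] != 0)
  if (!length(cross)) stop("no zero crossing found in window")
  k <- seg[cross[1]]
  x[k] + (0 - y[k]) * (x[k + 1] - x[k]) / (y[k + 1] - y[k])
}
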