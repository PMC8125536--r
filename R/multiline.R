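# First-order model of the S2 multiline (ML) signal: spin-projected 55Mn
# hyperfine couplings, spectral width, and stick spectra.
#
# In the exchange-coupled Mn4 cluster the effective hyperfine coupling of
# ion i within the total-spin S_T = 1/2 manifold is A_i = rho_i * A_i^ion,
# with dimensionless spin-projection coefficients rho_i that sum to 1 over
# the cluster.  To first order the ML width is 5 * sum(|A_i_eff|) (each
# I = 5/2 nucleus spans 2I = 5 splittings).

#' Spin-projection set for the Mn4 cluster
#'
#' @param rho four dimensionless spin-projection coefficients; their sum
#'   should be ~1 for the whole cluster (a deviation beyond 0.1 warns, the
#'   published values being approximate: rho1 ~ 2, rho2 ~ -1.2,
#'   rho3 + rho4 ~ 0.2, split equally here by convention).
#' @param A_ion_MHz four intrinsic ('isolated-ion') hyperfine values, MHz.
#' @return an object of class `projection_set`.
#' @export
projection_set <- function(rho = c(2, -1.2, 0.1, 0.1),
                           A_ion_MHz = c(165, 165, 165, 165)) {
  stopifnot(length(rho) == 4, length(A_ion_MHz) == 4,
            all(is.finite(rho)), all(is.finite(A_ion_MHz)))
  if (abs(sum(rho) - 1) > 0.1) {
    warning(sprintf("sum(rho) = %.3g deviates from 1 by more than 0.1",
                    sum(rho)))
  }
  structure(list(rho = as.numeric(rho), A_ion_MHz = as.numeric(A_ion_MHz)),
            class = "projection_set")
}

#' Spin-projected effective hyperfine couplings
#'
#' `A_i_eff = rho_i * A_i^ion`, sign retained.  The dominant Mn(III)
#' coupling comes out roughly twice the Mn(IV) one for the published
#' projections.
#'
#' @param p a [projection_set()].
#' @return four effective couplings in MHz.
#' @export
spin_projected_couplings <- function(p) {
  stopifnot(inherits(p, "projection_set"))
  p$rho * p$A_ion_MHz
}

#' First-order multiline width
#'
#' `width = 5 * sum(|A_i_eff|)` for four I = 5/2 nuclei, in whatever unit
#' the couplings are given (commonly Gauss after [mhz_to_gauss()]).  A set
#' summing to 360 G gives the observed ~1800 G ML width.
#'
#' @param A_eff exactly four effective coupling magnitudes.
#' @return the first-order spectral width, same unit as the input.
#' @export
ml_width_first_order <- function(A_eff) {
  if (length(A_eff) != 4) stop("exactly four couplings are required")
  stopifnot(all(is.finite(A_eff)))
  5 * sum(abs(A_eff))
}

#' First-order multiline stick spectrum
#'
#' Enumerates all nuclear projection combinations m_i in {-I..I} (6^n for
#' n I = 5/2 nuclei) and places sticks at
#' `B = B0 - sum_i m_i dB_i`, `B0 = h nu / (g beta)`,
#' `dB_i = mhz_to_gauss(A_i, g)`, accumulating multiplicities of
#' coincident positions.  The total stick intensity is 6^n and the extent
#' `max - min` equals `5 * sum(|dB_i|)` (for four nuclei: the first-order
#' width).
#'
#' @param A_eff_MHz effective couplings in MHz (1 to 4 nuclei; the S2 ML
#'   signal uses four).
#' @param g_center g-value of the ML center (~1.98).
#' @param frequency_GHz microwave frequency in GHz.
#' @param I nuclear spin (5/2 for 55Mn).
#' @return data frame with `resonance_field_G` (sorted ascending) and
#'   `amplitude` (multiplicities), class `transition_set`.
#' @export
ml_stick_spectrum <- function(A_eff_MHz, g_center = 1.98,
                              frequency_GHz = 9.369126, I = 5/2) {
  stopifnot(length(A_eff_MHz) >= 1, length(A_eff_MHz) <= 4,
            all(is.finite(A_eff_MHz)))
  B0 <- field_for_g(g_center, frequency_GHz)
  dB <- mhz_to_gauss(A_eff_MHz, g_center)
  m_vals <- seq(-I, I)
  combos <- do.call(expand.grid, rep(list(m_vals), length(dB)))
  B <- B0 - as.numeric(as.matrix(combos) %*% dB)
  key <- round(B, 6)
  tab <- rowsum(rep(1, length(B)), key)
  out <- data.frame(resonance_field_G = as.numeric(rownames(tab)),
                    amplitude = tab[, 1])
  out <- out[order(out$resonance_field_G), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transition_set", class(out))
  out
}

#' Broaden a stick spectrum into a first-derivative line spectrum
#'
#' Bins sticks on a uniform field axis, convolves with a unit-area
#' Gaussian of peak-to-peak width `linewidth_G`, and differentiates once
#' (set `derivative = FALSE` for the absorption).
#'
#' @param sticks data frame with `resonance_field_G` and `amplitude`
#'   (e.g. from [ml_stick_spectrum()]).
#' @param field_axis uniform ascending axis in Gauss.
#' @param linewidth_G Gaussian peak-to-peak width in Gauss.
#' @param frequency_GHz stored in the resulting spectrum.
#' @param derivative return the first derivative (default) or absorption.
#' @return an [epr_spectrum()].
#' @export
broaden_sticks <- function(sticks, field_axis, linewidth_G,
                           frequency_GHz = 9.369126, derivative = TRUE) {
  stopifnot(is.data.frame(sticks),
            all(c("resonance_field_G", "amplitude") %in% names(sticks)))
  dx <- .check_uniform(field_axis)
  pad <- ceiling(4 * linewidth_G / dx)
  ext <- c(seq(field_axis[1] - pad * dx, by = dx, length.out = pad),
           field_axis,
           seq(field_axis[length(field_axis)] + dx, by = dx,
               length.out = pad))
  acc <- .bin_sticks(sticks$resonance_field_G, sticks$amplitude, ext)
  y <- .broaden(acc, dx, linewidth_G, derivative = derivative)
  keep <- (pad + 1):(pad + length(field_axis))
  epr_spectrum(field_axis, y[keep], frequency_GHz = frequency_GHz,
               metadata = list(simulated = "broadened stick spectrum",
                               linewidth_G = linewidth_G))
}

#' Count resolved extrema of a derivative spectrum
#'
#' Number of local maxima of the derivative trace above a noise floor,
#' used to verify that a simulated ML pattern resolves the observed
#' \\eqn{>20} hyperfine lines.
#'
#' @param spec an [epr_spectrum()].
#' @param frac minimum prominence as a fraction of the global maximum.
#' @param kind `"maxima"` counts local maxima only (one per absorption
#'   line); `"extrema"` also counts local minima, appropriate for
#'   first-derivative traces where each line contributes a maximum and a
#'   minimum.
#' @return integer count of resolved extrema.
#' @export
count_resolved_peaks <- function(spec, frac = 0.01,
                                 kind = c("maxima", "extrema")) {
  kind <- match.arg(kind)
  y <- spec$intensity
  n <- length(y)
  thr <- frac * max(abs(y))
  i <- 2:(n - 1)
  up <- sum(y[i] > y[i - 1] & y[i] >= y[i + 1] & abs(y[i]) > thr)
  if (kind == "maxima") return(up)
  dn <- sum(y[i] < y[i - 1] & y[i] <= y[i + 1] & abs(y[i]) > thr)
  up + dn
}
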