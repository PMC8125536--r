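# Seeded generator of synthetic experiment sets with the statistical
# structure the decomposition assumes: an annealed S1 background (baseline
# drift + tyrosine radical), a ~240 K green-illuminated spectrum carrying
# the S2 multiline signal, and a ~140 K NIR-illuminated spectrum in which a
# fraction of multiline centers has interconverted to the g4.1 species.

#' Field axis of an acquisition grid
#'
#' @param center_G center field in Gauss.
#' @param sweep_G sweep width in Gauss.
#' @param points number of points (>= 2).
#' @return uniform ascending axis of length `points`.
#' @export
grid_axis <- function(center_G, sweep_G, points) {
  if (points < 2) stop("`points` must be >= 2")
  seq(center_G - sweep_G / 2, center_G + sweep_G / 2, length.out = points)
}

#' Configuration of a synthetic experiment
#'
#' Defaults emulate the emulated acquisition: multiline window grid
#' (center 3400 G, sweep 2500 G, 2500 points), X-band frequency, 6 K,
#' 15 G modulation, conversion fraction 0.35, and the published spin-5/2
#' candidate as the g4.1 species.  The multiline template is an
#' illustrative four-coupling first-order comb (equal 250 MHz couplings at
#' g = 1.98, 20 G broadening) chosen to match the observed ~90 G dominant
#' spacing, ~1800 G width and >20 resolved lines; the tyrosine radical
#' defaults to g = 2.0046, 8 G width (a convention, not a measured value).
#' Noise is additive white Gaussian on the derivative signal.  Templates
#' are peak-to-peak normalized; with the default multiline template the
#' peak amplitude is ~0.55, so a target signal-to-noise ratio S (peak
#' amplitude over noise standard deviation, the usual spectroscopic
#' convention) corresponds to `noise_sd ~ 0.55 / S`.
#'
#' @param conversion_fraction fraction of multiline centers interconverted
#'   by the NIR illumination (0..1; default 0.35).
#' @param ml_couplings_MHz four effective multiline couplings in MHz.
#' @param ml_g_center multiline center g-value.
#' @param ml_linewidth_G broadening of the multiline sticks in Gauss.
#' @param g41_system [spin_system()] of the g4.1 species (Table of
#'   published parameters by default, hyperfine included).
#' @param g41_linewidth_G powder linewidth of the g4.1 simulation in Gauss.
#' @param g41_amplitude peak amplitude of the g4.1 component relative to
#'   the (unit peak-to-peak) multiline template.
#' @param g41_n_orientations orientation count for the g4.1 powder template.
#' @param radical list with `g`, `width_G`, `amplitude` for the Y_D line.
#' @param noise_sd Gaussian noise standard deviation in units of the
#'   multiline peak-to-peak amplitude (default 0.01, i.e. SNR 100).
#' @param baseline polynomial baseline coefficients in the reduced field
#'   u in [-1, 1] (constant, linear, quadratic, ...), same units.
#' @param grid list with `center_G`, `sweep_G`, `points`.
#' @param frequency_GHz microwave frequency in GHz.
#' @param temperature_K acquisition temperature label in K.
#' @param modulation_amplitude_G modulation amplitude metadata in G.
#' @param seed integer seed making the experiment bit-reproducible.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(conversion_fraction = 0.35,
                         ml_couplings_MHz = c(250, 250, 250, 250),
                         ml_g_center = 1.98,
                         ml_linewidth_G = 20,
                         g41_system = g41_spin52(),
                         g41_linewidth_G = 140,
                         g41_amplitude = 1,
                         g41_n_orientations = 300,
                         radical = list(g = 2.0046, width_G = 8,
                                        amplitude = 3),
                         noise_sd = 0.01,
                         baseline = c(0.02, 0.05, 0.03),
                         grid = list(center_G = 3400, sweep_G = 2500,
                                     points = 2500),
                         frequency_GHz = 9.369126,
                         temperature_K = 6,
                         modulation_amplitude_G = 15,
                         seed = 1) {
  if (conversion_fraction < 0 || conversion_fraction > 1) {
    stop("`conversion_fraction` must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(grid$points) || grid$points < 2) stop("invalid grid")
  stopifnot(inherits(g41_system, "spin_system"), length(ml_couplings_MHz) == 4)
  structure(list(conversion_fraction = conversion_fraction,
                 ml_couplings_MHz = ml_couplings_MHz,
                 ml_g_center = ml_g_center, ml_linewidth_G = ml_linewidth_G,
                 g41_system = g41_system, g41_linewidth_G = g41_linewidth_G,
                 g41_amplitude = g41_amplitude,
                 g41_n_orientations = g41_n_orientations,
                 radical = radical, noise_sd = noise_sd, baseline = baseline,
                 grid = grid, frequency_GHz = frequency_GHz,
                 temperature_K = temperature_K,
                 modulation_amplitude_G = modulation_amplitude_G,
                 seed = seed),
            class = "synth_config")
}

#' Synthetic tyrosine-radical line
#'
#' Gaussian first-derivative line of peak-to-peak width `width_G` and
#' peak-to-peak amplitude `amplitude`, centered at `h nu / (g_pos beta)`.
#'
#' @param g_pos g-value of the line center.
#' @param width_G peak-to-peak width in Gauss (> 0).
#' @param amplitude peak-to-peak amplitude (a.u.).
#' @param field_axis uniform ascending axis in Gauss.
#' @param frequency_GHz microwave frequency in GHz.
#' @return an [epr_spectrum()].
#' @export
generate_radical <- function(g_pos, width_G, amplitude, field_axis,
                             frequency_GHz) {
  if (width_G <= 0) stop("`width_G` must be > 0")
  B0 <- field_for_g(g_pos, frequency_GHz)
  sigma <- width_G / 2
  u <- (field_axis - B0) / sigma
  y <- -amplitude / 2 * exp(0.5) * u * exp(-u^2 / 2)
  epr_spectrum(field_axis, y, frequency_GHz = frequency_GHz,
               metadata = list(simulated = "radical line", g = g_pos))
}

# Noiseless, seed-independent components of a synthetic experiment on the
# configured grid.  Computing these once and passing them to
# generate_experiment() amortizes the powder simulation over many seeds.
#' @rdname generate_experiment
#' @export
synth_templates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  axis <- grid_axis(cfg$grid$center_G, cfg$grid$sweep_G, cfg$grid$points)
  u <- 2 * (axis - mean(axis)) / diff(range(axis))
  base <- rep(0, length(axis))
  for (k in seq_along(cfg$baseline)) base <- base + cfg$baseline[k] * u^(k - 1)

  radical <- generate_radical(cfg$radical$g, cfg$radical$width_G,
                              cfg$radical$amplitude, axis,
                              cfg$frequency_GHz)$intensity

  sticks <- ml_stick_spectrum(cfg$ml_couplings_MHz, cfg$ml_g_center,
                              cfg$frequency_GHz)
  ml <- broaden_sticks(sticks, axis, cfg$ml_linewidth_G,
                       cfg$frequency_GHz)$intensity
  pp <- diff(range(ml))
  if (pp > 0) ml <- ml / pp

  # g4.1 powder component, simulated on an axis that always covers its
  # core region so the normalization does not depend on the window chosen
  dx <- axis[2] - axis[1]
  lo <- min(axis[1], 400)
  hi <- max(axis[length(axis)], 2900)
  wide <- seq(lo, hi, by = dx)
  g41_wide <- powder_spectrum(cfg$g41_system, cfg$frequency_GHz, wide,
                              n_orientations = cfg$g41_n_orientations,
                              linewidth_G = cfg$g41_linewidth_G)$intensity
  ppg <- diff(range(g41_wide))
  if (ppg > 0) g41_wide <- g41_wide / ppg * cfg$g41_amplitude
  g41 <- stats::approx(wide, g41_wide, xout = axis, rule = 2)$y

  list(field_axis = axis, baseline = base, radical = radical, ml = ml,
       g41 = g41)
}

# evaluate code with a private, restored RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic experiment set
#'
#' Assembles the three labelled spectra of the illumination protocol on
#' the configured grid:
#' `annealed = baseline + radical + noise`,
#' `illuminated_240K = annealed parts + multiline + noise`,
#' `illuminated_140K_NIR = annealed parts + (1 - f) multiline +
#'  f * amplitude * g4.1 powder + noise`,
#' with `f = conversion_fraction` and three independent Gaussian noise
#' draws.  Identical seeds give bit-identical sets, and every ground-truth
#' component (including the noise draws) is stored so oracle tests can
#' reassemble each spectrum exactly.
#'
#' @param cfg a [synth_config()].
#' @param templates optional precomputed [synth_templates()] for `cfg`
#'   (recomputed when `NULL`).
#' @return an object of class `experiment_set`: spectra `annealed`,
#'   `illuminated_240K`, `illuminated_140K_NIR`, the named analysis
#'   `windows`, and the ground `truth` components.
#' @export
generate_experiment <- function(cfg, templates = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(templates)) templates <- synth_templates(cfg)
  axis <- templates$field_axis
  n <- length(axis)
  f <- cfg$conversion_fraction

  det <- list(
    annealed = templates$baseline + templates$radical,
    illuminated_240K = templates$baseline + templates$radical + templates$ml,
    illuminated_140K_NIR = templates$baseline + templates$radical +
      (1 - f) * templates$ml + f * templates$g41
  )
  noise <- .with_seed(cfg$seed, list(
    annealed = stats::rnorm(n, 0, cfg$noise_sd),
    illuminated_240K = stats::rnorm(n, 0, cfg$noise_sd),
    illuminated_140K_NIR = stats::rnorm(n, 0, cfg$noise_sd)
  ))

  mk <- function(label) {
    epr_spectrum(axis, det[[label]] + noise[[label]],
                 frequency_GHz = cfg$frequency_GHz,
                 temperature_K = cfg$temperature_K,
                 modulation_amplitude_G = cfg$modulation_amplitude_G,
                 metadata = list(label = label, seed = cfg$seed))
  }
  B_rad <- field_for_g(cfg$radical$g, cfg$frequency_GHz)
  structure(list(
    annealed = mk("annealed"),
    illuminated_240K = mk("illuminated_240K"),
    illuminated_140K_NIR = mk("illuminated_140K_NIR"),
    windows = list(ml = c(2400, 4400), g41 = c(600, 2700),
                   radical = c(B_rad - 30, B_rad + 30)),
    truth = list(conversion_fraction = f, deterministic = det,
                 noise = noise, templates = templates,
                 noise_sd = cfg$noise_sd)
  ), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("<experiment_set>\n")
  for (nm in c("annealed", "illuminated_240K", "illuminated_140K_NIR")) {
    cat(" ", nm, ": ", sep = "")
    print(x[[nm]])
  }
  cat(sprintf("  truth conversion fraction: %.3f\n",
              x$truth$conversion_fraction))
  invisible(x)
}
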