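---
title: "Spin-state analysis of the S2-state g4.1 EPR signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-state analysis of the S2-state g4.1 EPR signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s2epr)
```

## The scientific problem

Low-temperature illumination traps the oxygen-evolving complex (OEC) of
photosystem II in its S2 state, which shows two characteristic CW-EPR
signatures of the Mn4CaO5 cluster: the 55Mn hyperfine-structured
*multiline* (ML) signal of the total-spin-1/2 ground state near g = 2, and
the broad *g4.1* signal near effective g = 4.1 that grows at the expense of
the ML signal under near-infrared (NIR) illumination at about 140 K.  The
package implements the quantitative machinery needed to ask what spin state
produces the g4.1 signal: exact spin-Hamiltonian powder simulation,
closed-form and numerical Kramers-doublet effective g-values, a first-order
model of the ML signal, the illumination-difference / scaled-subtraction
decomposition with conversion-fraction estimation, bounded least-squares
fitting of zero-field-splitting (ZFS) parameters, and a seeded synthetic
spectrometer standing in for instrument data (none are publicly deposited
for this system).

## The spin Hamiltonian

All energies are handled internally in cm^-1, fields in Gauss, hyperfine
couplings in MHz, microwave frequencies in GHz, with CODATA constants.  A
`spin_system()` carries electronic spin $S \in \{1/2, 3/2, 5/2\}$ and the
terms

$$
H = \beta\, \mathbf{B}\cdot \mathbf{g} \cdot \hat{\mathbf S}
  + D\left[\hat S_z^2 - \tfrac{S(S+1)}{3}\right]
  + E\left[\hat S_x^2 - \hat S_y^2\right]
  + \frac{a}{6}\left[\hat S_x^4 + \hat S_y^4 + \hat S_z^4 - c_S\right]
  + \sum_k \hat{\mathbf S}\cdot \mathbf A_k \cdot \hat{\mathbf I}_k ,
$$

with $c_S = S(S+1)(3S^2+3S-1)/5$ making the cubic term traceless, and
diagonal (collinear) 55Mn hyperfine tensors $\mathbf A_k$ in the
electron-nuclear product basis.  Design choices a user should know:

* **ZFS canonicalization.**  Any $(D, E)$ input is re-expressed with the
  principal axes ordered so that $0 \le E/D \le 1/3$; g-values and
  hyperfine tensors are permuted along.  $E$ carries the sign of $D$, and
  both signs of $D$ are physically meaningful (the sign for the g4.1
  species is not established, so the fitting layer explores both).
* **Nuclear terms.**  Nuclear Zeeman energy (about 5 MHz for 55Mn at
  1600 G, versus a 140 G = 390 MHz lineshape) is omitted.  Quadrupole
  coupling is structurally present in the type but must be zero: no
  quadrupole magnitudes are established for this system, and silently
  guessing them would be worse than refusing.
* **Kramers degeneracy.**  For half-integer electronic spin every
  zero-field level is doubly degenerate.  With nuclei the protection
  depends on the *total* angular-momentum parity: two I = 5/2 nuclei keep
  it (and the test suite checks degeneracy in the full 216-dimensional
  space), a single I = 5/2 nucleus would not.

## Effective g-values and the Kramers-doublet limits

The apparent position of an intradoublet transition is described by
$g_\mathrm{eff} = h\nu/(\beta B)$.  `doublet_effective_g()` computes
$g_\mathrm{eff}$ along each principal axis from the intradoublet splitting
at a 0.1 G probe field (safely inside the linear regime for any
$|D| \gtrsim 0.1$ cm^-1, yet far above eigensolver noise).  Two classical
limits anchor the implementation and are exercised by the tests:

```{r}
doublet_effective_g(spin_system(5/2, g = 2, D_cm1 = 2, E_over_D = 1/3), 2)
doublet_effective_g(spin_system(3/2, g = 2, D_cm1 = 2), 1)
```

The fully rhombic S = 5/2 middle doublet is isotropic at $g = 30/7 =
4.286$ — the reason a rhombic S = 5/2 species shows a prominent,
quasi-isotropic resonance near g = 4.2–4.3 while its outer doublets
(principal set 9.678 / 0.857 / 0.607) spread over the whole field range —
and the axial S = 3/2 ±1/2 doublet gives (4, 4, 2).

## Powder simulation numerics

`powder_spectrum()` is a deterministic field-swept simulation:

1. **Orientation grid.**  A ring ("igloo") grid restricted to one octant
   (valid for collinear orthorhombic tensors), weighted by solid angle.
   `n_orientations` counts nominal hemisphere orientations; about n/4
   knots are evaluated.  The default is 3000 for production figures and
   300 for coarse work and tests.  Convergence is O(1/n) without
   orientational interpolation: for the g4.1-type system the
   doubling-change falls below 1% of the peak-to-peak range at about
   n = 6000, and the dominant-feature position is stable to well under a
   Gauss from n = 300 upward.
2. **Eigenfield search.**  For each orientation the Hamiltonian is linear
   in the field magnitude, $H(B) = H_0 + B H_1$.  Eigenvalues are computed
   on a 32-knot field ladder (LAPACK divide-and-conquer through
   RcppArmadillo) and every ordered level pair whose gap crosses $h\nu$
   within a ladder segment yields a resonance, located by linear
   interpolation of the gap.  The interpolation error on the default
   ladder is a few Gauss at worst — far below any realistic linewidth —
   and `refine_tol_G` switches on a safeguarded secant refinement
   (used by `resonance_search()`, default 1e-3 G, which brings every
   root to $|\Delta E - h\nu| \le 10^{-6} h\nu$) when exact eigenfields
   are wanted.  Sorted-pair tracking keeps gaps continuous through
   avoided crossings.
3. **Intensities.**  Squared magnetic-dipole moment for the microwave
   field perpendicular to B (g-tensor folded in, averaged over two
   perpendicular B1 directions), times the Boltzmann population
   difference at the sample temperature (populations are evaluated at the
   nearest eigenvector knot; `temperature_K = Inf` gives equal
   populations), times the frequency-to-field conversion
   $1/|d\Delta E/dB|$.  Resonator and modulation transfer functions are
   not modelled — intensities are arbitrary units, as in the figures the
   package reproduces.
4. **Lineshape.**  Resonances are accumulated on the field axis (extended
   by four linewidths so edge lines contribute their tails), convolved
   with a unit-area Gaussian parameterized by its peak-to-peak
   first-derivative width (σ = width/2), and differentiated once.  The
   15 G modulation amplitude of the emulated acquisitions is carried as
   metadata only — it is small against the 140 G linewidth and is not
   convolved in.

## The published g4.1 parameter sets

`g41_spin52()` and `g41_spin32()` hold the two candidate descriptions of
the g4.1 species (S = 5/2: D = 0.45 cm^-1, E/D = 0.25; S = 3/2: D = 0.3,
E/D = 0.3; principal g 2.18/2.16/1.98; two 55Mn couplings 194.2 and
45.2 MHz; 140 G companion linewidth).  Two interpretation decisions were
genuinely open and are resolved as follows:

* **Axis assignment of the g-values.**  The published table does not say
  which ZFS principal axis each g-value belongs to.  In the canonical
  frame used here the assignment $g_z = 2.18, g_y = 2.16, g_x = 1.98$
  reproduces the reported dominant feature at effective g = 4.10 for the
  electron parameters (the naive gx-first reading lands at ~4.36); all
  six assignments were scanned and the reproducing one adopted.
* **Hyperfine treatment.**  With the two tabulated couplings taken as
  intrinsic tensors in the exact 216-dimensional product space, the
  hyperfine envelope (±5(A1+A2)/2 ≈ ±430 MHz, amplified within the
  doublet) broadens the powder pattern asymmetrically and moves the
  dominant zero crossing from 4.10 (electron-only) to about 4.27; an
  emulated first-order (symmetric, position-preserving) hyperfine
  treatment lands in between (~4.18).  The package deliberately keeps
  the exact treatment — it is the defensible physics — and reports the
  resulting position as computed.  The tension between the tabulated
  couplings and the reported band position is documented rather than
  hidden: a reader comparing against the printed 4.10 should be aware
  that that number is consistent only with a treatment in which the
  hyperfine interaction does not reshape the envelope.

## First-order multiline model

Within the strongly exchange-coupled cluster the effective coupling of Mn
ion $i$ is the spin-projected $A_i = \rho_i A_i^{\mathrm{ion}}$
(`spin_projected_couplings()`), with projections summing to 1 over the
cluster; the accepted values ($\rho_1 \approx 2$, $\rho_2 \approx -1.2$,
$\rho_3+\rho_4 \approx 0.2$) make the Mn(III) coupling roughly twice the
Mn(IV) one.  Only the sum $\rho_3+\rho_4$ is constrained; the default
splits it equally, a flagged convention.  To first order, four I = 5/2
nuclei spread the spectrum over $5\sum_i |A_i|$ (`ml_width_first_order()`),
and `ml_stick_spectrum()` enumerates all $6^4$ nuclear projections.  No
coupling set is tabulated for the ML simulation, so the synthetic default
is deliberately minimal and labelled illustrative: four equal couplings of
250 MHz at g = 1.98 with 20 G broadening, which reproduce the observed
~90 G dominant spacing, the ~1800 G (~5 GHz) first-order width, and 21
resolved lines.  Second-order shifts and hyperfine anisotropy are outside
the first-order model; the exact product-space route in the powder module
exists for cross-checks.

## Difference-spectrum decomposition

The decomposition mirrors the illumination protocol: subtract the annealed
S1 background from each illuminated spectrum (`difference_spectrum()`),
remove the narrow tyrosine-radical line near g = 2.0046
(`remove_radical()`; default is a fitted Gaussian-derivative subtraction,
with an edge-interpolation mode whose contract is that it also removes any
overlapped ML intensity), then estimate the fraction of ML centers lost to
NIR interconversion as the ordinary-least-squares scalar $s$ minimizing
$\lVert d_{140\mathrm{NIR}} - s\, d_{240} \rVert^2$ over the ML comparison
window (default 2400–4400 G excluding the 3250–3450 G radical region;
`fraction_lost = 1 - s`).  OLS on the derivative spectra matches the
visual scaled-subtraction practice and is robust at 2500 points; note that
because the reference difference spectrum itself carries noise (and shares
the annealed background), the estimator has a small positive bias of order
$N\sigma^2/\lVert \mathrm{ML} \rVert^2$ — negligible at the
signal-to-noise ratios of interest (the tests verify recovery within
±0.02 at SNR 50 and bias below 0.005 at SNR 200).  The pure NIR-generated
g4.1 spectrum is then the scaled subtraction
$d_{140\mathrm{NIR}} - s\, d_{240}$ evaluated in the g4.1 window.

**Quantification.**  `double_integral()` integrates a derivative spectrum
twice after subtracting a linear baseline fitted to 5% edge margins
(point-anchoring is available but fragile).  A caveat the simulations make
explicit: the spin-5/2 candidate carries a weak secondary branch up-field
of the main g4.1 feature (effective g ~ 2.4–2.8), so the double integral
is stable only at the tens-of-percent level against ±10% window changes —
window positions are reported alongside any quantification for that
reason.

## Fitting and model comparison

`fit_spectrum()` minimizes the pointwise residual between a powder
simulation and a (difference) spectrum over a chosen parameter subset
(default D, E/D, linewidth), with amplitude and a linear baseline profiled
out exactly at every evaluation.  The optimizer is bounded
Levenberg–Marquardt with 8 seed-derived multistarts by default,
alternating the sign of D.  Identical seeds give identical results, and
the best-so-far objective trace is recorded (non-increasing by
construction).  Simulations inside the loop use a reduced grid (default
300 orientations) with a final residual evaluation at 3000.  Two practical
notes: (i) with hyperfine nuclei included the forward model is
216-dimensional and every evaluation costs seconds — fits conventionally
drop the nuclei (`drop_nuclei()`), whose unresolved ~70 G structure is
subsumed by the 140 G lineshape, and hold the tabulated couplings fixed
rather than floating them; (ii) in self-consistency (parameter-recovery)
exercises the target and the fit must share the orientation grid, because
at reduced grids the O(1/n) powder ripple between two different grids
exceeds a SNR-30 noise floor.  `compare_models()` runs identical-budget
fits for candidate spin states and ranks them by residual RMS — the
comparison that pits the spin-5/2 description of the g4.1 signal against
the spin-3/2 alternative (which the tests show is correctly identified in
at least 19 of 20 noisy replicates in either direction).

## The synthetic spectrometer

`generate_experiment()` emulates the three-spectrum experiment on the
acquisition grids of the emulated instrument (2500 points, 2500 G sweep,
centered at 3400 G for ML work and 1650 G for g4.1 work; X-band
frequencies; 6 K label; 15 G modulation):

* annealed = polynomial baseline drift + tyrosine-radical line + noise;
* 240 K illuminated = the same deterministic background + the ML template;
* 140 K NIR illuminated = background + (1 − f)·ML + f·g4.1 powder
  spectrum, with conversion fraction f = 0.35 by default.

Noise is additive white Gaussian on the derivative signal with three
independent draws (default sd = 1% of the ML peak-to-peak amplitude); the
radical defaults (g = 2.0046, 8 G) are a stated convention.  Every
deterministic component and noise draw is stored in the returned object,
so oracle tests can reassemble each spectrum exactly, and identical seeds
give bit-identical sets without disturbing the caller's RNG stream.  What
the generator does **not** emulate — and what passing tests therefore do
not establish about real data — includes microwave power saturation,
non-Curie temperature dependence of signal amplitudes, field offsets
between acquisitions, cavity background artifacts, and any inhomogeneity
of the ML species beyond the single template.

## Problem sizes used by the shipped tests

The test suite runs the full product-space g4.1 simulation at 300
orientations on the 2500-point grid, the fraction-recovery study at 100
seeds, the ZFS parameter-recovery study at 20 noisy spectra (SNR 30,
electron-only forward model at 400 orientations), and the model
discrimination at 2 × 20 seeds; the acceptance script runs the production
3000-orientation simulation.  These sizes are the package's choice of a
thorough desk-scale study; all of them scale up by changing the
corresponding arguments.

## Known limitations

Non-Kramers (integer-spin) systems, explicit exchange-coupled multi-site
Hamiltonians, Euler-angle-rotated (non-collinear) tensor frames, nuclear
quadrupole interactions, pulsed-EPR observables, frequency-swept spectra,
and saturation/relaxation modelling are out of scope.  Orientation
averaging uses no interpolation, so very sharp powder patterns (large D,
small linewidth) need large `n_orientations`; and double-integral
quantification inherits the usual baseline fragility of CW-EPR practice.
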