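---
title: "Resolving tryptophan microenvironments: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving tryptophan microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpmicro)
```

# The problem

A protein with several tryptophans emits a superposition of bands whose
maxima range from ~308 nm (deeply buried indoles) to ~350 nm (fully
solvent-exposed ones).  Steady-state spectra alone cannot separate the
contributors.  `trpmicro` implements the three measurement models that
together can — corrected steady-state spectra, trilinear decomposition
of multi-dimensional fluorescence, and multi-exponential lifetime
analysis — plus the structural descriptors that explain *why* a given
tryptophan emits where it does.  The driving application is mouse
thymidylate synthase (mTS), whose emission resolves into a blue
component near 330 nm (most tryptophans) and an unusually red component
near 362 nm attributable to a single residue, Trp103, whose local
electrostatic potential *decreases* from the benzene toward the pyrrole
ring — the opposite of every other tryptophan in the protein.

# Steady-state processing

Spectra are corrected as `(raw − blank) · G` with the inner-filter
factor `G = 10^((ΔA_ex + ΔA_em)/2)`, then normalised to unit maximum.
Corrected intensities are clipped at zero: after blank subtraction,
small negative residuals are measurement noise with no physical
meaning.  We correct first and normalise second; normalising first
would make the inner-filter factor wavelength-dependent through the
normalisation constant, which contradicts its definition from
absorbances.

Band location works on Savitzky–Golay-smoothed derivatives.  Maxima
are + to − sign changes of the first derivative.  For shoulders the
operational rule is: an interior local *minimum* of |dI/dλ| at which
the derivative stays bounded away from zero.  Such a point is a
second-derivative zero-crossing on a monotone flank — the signature of
a partially merged minor band — whereas the two plain inflection
points that any single Gaussian band possesses are local *maxima* of
|dI/dλ| and are correctly rejected.  The `shoulder_sensitivity`
parameter (default 0.8) sets how deep the slope dip must be relative
to the surrounding flank.  Note that the detectable dip of a merged
doublet sits between the minor band's centre and the main peak, so a
335 nm satellite under a 347 nm band reports a shoulder near 337–339
nm; tests assert location within a few nm for this reason.

# TSFS, the t-EEM layout and PARAFAC

TSFS scans emission at fixed offsets Δλ from the excitation, so a
datum at (λ_exc, Δλ) belongs at emission wavelength λ_exc + Δλ.  The
default grids are λ_exc 260–320 nm and Δλ 20–160 nm, both in 2 nm
steps (a 31 × 71 plane per sample; emission support 280–480 nm).  The
transform interpolates each excitation row onto a common emission axis
and flags unmeasured cells in a missing mask — the t-EEM wedge.

PARAFAC is fitted by weighted alternating least squares: masked cells
carry zero weight in every update, rather than being pre-imputed.
(Interpolation over the wedge is available as an optional
pre-processing step, but the fit itself never uses imputed values; a
test verifies that perturbing masked cells leaves the model
bit-identical.)  Updates are hierarchical (columnwise) with
nonnegative projection; each row of each factor has its own weighted
normal equations, assembled with a handful of matrix products per
sweep.  Scale and permutation indeterminacy are fixed by peak-
normalising the excitation and emission loadings, absorbing magnitude
into the sample scores, and ordering components by ascending emission
maximum.  Initialisation is random nonnegative with `n_starts`
(default 10) restarts; convergence is declared when the observed
residual fraction changes by less than `tol` (default 1e-8) between
sweeps, with a 2000-iteration cap.

Two numerical points deserve emphasis:

* **Edge coverage.**  The extreme emission wavelengths of a t-EEM
  wedge are observed under only one or two excitation rows.  A
  component can fit pure noise there and, after peak normalisation,
  report a nonsense maximum.  `parafac_fit` therefore drops emission
  columns observed in less than `min_coverage` (default 25 %) of the
  (sample, excitation) rows; the model's emission grid reflects the
  trimmed axis.
* **Convergence versus CONCORDIA.**  The two mTS-like components have
  nearly collinear excitation loadings (282/284 nm, congruence ≈ 0.99).
  The core-consistency diagnostic — `100·(1 − ‖G − T‖²/‖T‖²)` with G
  the least-squares Tucker core and T the superdiagonal target —
  amplifies any residual misconvergence through the pseudo-inverses of
  the nearly collinear factors.  Loosely converged fits can read 85–93 %
  on a genuinely rank-2 cube whose tightly converged fit reads > 99.5 %.
  The validation studies therefore run the fit to `tol = 1e-9` with up
  to 3000 sweeps.

Component count selection accepts the largest K whose core consistency
stays above a threshold (default 90 %) and whose residual improves by
at least 2 % relative; a cube whose one-component model explains less
than half the observed variance is flagged structureless.

# TCSPC decay analysis

The decay model is `Σ_n α_n exp(−t/τ_n)` convolved with a unit-sum IRF
plus a constant background.  The convolution integrand is causal — it
jumps at the point where excitation instant meets observation time —
so the quadrature gives the bin containing the jump half weight; this
makes the discrete sum track the continuous reconvolution to < 0.1 %
of peak at 1024 bins, verified against a 10×-oversampled direct
numerical convolution with exact endpoints.  A single-bin IRF is the
ideal (unbroadened) limit and returns the pure shifted decay exactly.

Fits are Levenberg–Marquardt with Neyman weights `1/max(counts, 1)`,
lifetimes and amplitudes on a log scale, background constrained
nonnegative, and multi-start initialisation from log-spaced lifetime
guesses.  The fit window opens where the rising edge first reaches 1 %
of peak.  Degenerate outcomes are flagged rather than reported as
fits: two lifetimes collapsing within 1 % (refitted with one component
fewer), a decaying part below 1 % of the background (a flat curve),
or a lifetime exceeding three observation windows (indistinguishable
from a constant).

Model selection adds components while the reduced χ² improves by more
than 10 % (no published numeric threshold exists for the visual
residual inspection it replaces; 10 % is this package's default).
Intensity fractions follow the SPCImage convention
`a_n = α_n τ_n / Σ α_m τ_m`, and `τ_av = Σ (a_n/100) τ_n`.  When
printed-style fractions are supplied directly they are *not*
renormalised to exactly 100: this reproduces published τ_av arithmetic
(e.g. 0.86·1.32 + 0.145·5.5 = 1.93 ns).  A few published rows are
internally inconsistent under any convention (their printed τ_av
differs from Σ(a_n/100)τ_n by more than the printed precision); the
package reproduces the arithmetic, not those rows.

The synthetic decay generator defaults to 1024 bins over 33.3 ns —
one repetition period of a 30 MHz pulsed source, which is what bounds
the observation window on a TCSPC instrument — a 0.5 ns FWHM Gaussian
IRF (a measured instrument response can be substituted), ~20k counts
in the peak bin, and per-bin Poisson sampling with no afterpulsing or
dark background by default.  Under these conditions the Neyman-weighted
reduced χ² of correct models falls in ≈ 0.95–1.2; appending a long
empty tail (a window much longer than the repetition period allows)
would bias it visibly below 1, because `1/max(counts,1)` under-weights
near-empty bins.

# Electrostatics and structural descriptors

Synthetic potential grids use screened-Coulomb superposition,
`φ = Σ_i q_i l_B e^{−κ r_i}/r_i` in kT/e, with the Bjerrum length
`l_B ≈ 7.1 Å` (water, 298.15 K) and `κ` from the ionic strength
(Debye length ≈ 7.9 Å at 0.15 M).  This is a deliberate
single-dielectric model: it provides smooth, physically scaled test
fields with superposition and symmetry properties that tests can
verify exactly.  It does not reproduce the two-dielectric
Poisson–Boltzmann solution of a finite-difference solver — those
results enter through the OpenDX reader (`read_dx`, APBS dialect,
z-fastest data order), and all descriptor code is agnostic to which
source produced the grid.

Per tryptophan, the benzene centroid averages CD2, CE2, CE3, CZ2, CZ3,
CH2 and the pyrrole centroid CG, CD1, NE1, CE2, CD2 — the fused-bond
atoms belong to both rings.  The potential is read at the centroids by
trilinear interpolation (no out-of-plane offset; the rings' π faces
are not singled out) and `Δ = φ_pyrrole − φ_benzene`.  Den2 counts
heavy atoms, excluding the tryptophan's own residue and (by default)
waters, whose nearest-ring-atom distance is below 7.5 Å;
"distance to the ring" is taken as distance to the nearest of the nine
ring atoms, the least convention-dependent choice.  Acc is the
residue's rolling-probe (Shrake–Rupley, 256-point golden-spiral) SASA
relative to the isolated residue, ×100, divided by 1.5 — the published
empirical factor mapping GETAREA-style ratios onto the classification
scale.

The class thresholds (Acc: S < 2.0 ≤ I < 7.4 ≤ I/II < 10.0 ≤ II
< 20.0 ≤ III; Den2: S ≥ 140 > I ≥ 125 > I/II ≥ 121 > II) are
calibrated so that every one of the 60 published mTS labels is
reproduced; the A and III boundaries are extrapolations beyond the
calibration data and are flagged on output.  The bundled reference
tables (`mts_reference_descriptors()`, `mts_reference_lifetimes()`)
carry those published values for calibration and worked-example tests.

# The toy-structure generator

Toy tryptophans are ideal fused rings — a regular hexagon and regular
pentagon sharing a 1.40 Å edge, giving a centroid separation of
2.18 Å — randomly rotated and placed on a 15 Å lattice, with decoy
carbon atoms scattered at ≥ 2 Å clearance.  This geometry is exact for
what the descriptors measure (centroids, axis, distances) and makes
Den2 and Δ analytically checkable; it makes no attempt at force-field
realism beyond the indole moiety, so SASA values for toy structures
are only meaningful relatively (burial limit ≈ 0, isolated limit
= 100/1.5).

# What the synthetic studies do and do not show

The generators emulate band shapes (Gaussian by default, log-normal
optionally), instrument scatter (a second-order ridge at
λ_em ≈ 2 λ_exc), Poisson photon statistics, and IRF broadening — the
features the algorithms must be robust to.  They do not emulate
detector afterpulsing, wavelength-dependent instrument response,
polarisation effects, conformational heterogeneity, or real blank
spectra; passing the recovery suites therefore demonstrates
correctness of the estimators under the stated noise models, not
instrument-grade validation.  Problem sizes in the validation studies
— 20-sample cubes on the full grids with 10 seeds for PARAFAC, 20
seeds of 1024-bin decays for TCSPC, 50 random structures for the Den2
oracle — were chosen so each study characterises seed-to-seed spread
while the whole suite runs in minutes on a single core.

# Known limitations

* PARAFAC assumes trilinearity; shifting spectra (solvent relaxation
  during acquisition) would need PARAFAC2, which is out of scope.
* The screened-Coulomb grids ignore the low-dielectric protein
  interior; quantitative Δ values for real proteins should come from a
  Poisson–Boltzmann solver via `read_dx`.
* Lifetime analysis is per-channel; global (linked-lifetime) analysis
  across channels and lifetime-distribution models are not
  implemented.
* The Acc/1.5 rescaling is an empirical bridge, not a physical model;
  class labels near threshold boundaries are sensitive to the SASA
  method used upstream.
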