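---
title: "Helix orientation and insertion analysis at lipid interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix orientation and insertion analysis at lipid interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interfilm)
```

`interfilm` analyses three model-membrane experiments that together
characterise how a helical peripheral protein binds and inserts into a lipid
interface: polarized infrared reflection–absorption spectroscopy (IRRAS) of
protein/lipid monolayers, Langmuir-trough adsorption at controlled surface
pressure, and QCM-D adsorption onto supported lipid bilayers. This vignette
documents the models behind each analysis, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
demonstrate.

## The forward optical model

An IRRA spectrum is the reflection–absorbance
RA(ν) = −log₁₀(R_film(ν)/R₀(ν)) of a film-covered liquid surface relative to
the bare surface. We model the film as a single homogeneous, uniaxially
anisotropic layer (optical axis along the surface normal) of thickness *d*
between a non-absorbing incident medium (air, n = 1) and a semi-infinite
absorbing subphase, and solve the three-phase reflection exactly with a 2×2
characteristic-matrix formalism. For s-polarization only the in-plane
permittivity ε_x enters; for p-polarization the layer's normal-component
wavevector is k_z,f = k₀√(ε_x(1 − sin²φ/ε_z)), so the out-of-plane ε_z is
probed as well — this polarization contrast is what carries the orientation
information. An exact solution (rather than the classical first-order
thin-film expansion) keeps the model valid at all angles, including near the
Brewster angle where the p-polarized reference reflectance is small and RA
changes sign. The first-order expansion is retained in the test suite as an
independent oracle; the two agree to better than 1 % for the film
thicknesses and extinctions treated here.

**Dielectric construction.** Each vibrational band contributes a Lorentzian
(default) or Gaussian extinction line with integrated area `strength`.
Orientation enters through the azimuthally averaged second moment of the
transition dipole with respect to the surface normal,

M(α, γ) = cos²α·sin²γ + ½·sin²α·cos²γ,

for a dipole at angle α from a helix axis inclined γ from the film plane.
The principal extinctions are k_z = 3M·k_iso and k_x = k_y = 3/2(1−M)·k_iso,
which preserves the isotropic sum rule k_x + k_y + k_z = 3k_iso pointwise.
Bands flagged `isotropic` (unordered structure, lipid ester C=O) contribute
equally to all axes. The complex permittivity is ε = (n_inf + i·k)²; no
Kramers–Kronig correction of the real part is applied, which is adequate for
the weak bands (k ≲ 0.3) of a monolayer.

**Parameters and defaults.**

| parameter | default | meaning |
|---|---|---|
| `thickness_nm` | 2.5 nm | monolayer + adsorbed helix layer; a nuisance parameter held fixed during fitting |
| `n_inf` | 1.41 | non-resonant film refractive index |
| `dipole_angle` | 38° | amide I transition dipole from the helix axis (standard α-helix literature value) |
| grid | 1590–1790 cm⁻¹, 2 cm⁻¹ | covers amide I′ (~1640 cm⁻¹) and lipid ν(C=O) (~1730 cm⁻¹) |
| subphase | D₂O | amide I′ measurements use a heavy-water subphase |

The default band set (`default_film()`) — an oriented helical amide I′
component at 1640 cm⁻¹, an isotropic unordered component at 1662 cm⁻¹ and the
isotropic lipid carbonyl at 1730 cm⁻¹ — is a configurable placeholder with
typical positions and widths for a coiled-coil protein at a phospholipid
monolayer, not a fitted parameter set for any specific protein.

Subphase optical constants for D₂O and H₂O are generated from a
Lorentz-oscillator parameterization (O-D/O-H stretch, bend, association and
libration bands) chosen to approximate published mid-infrared dispersion
data; they reproduce the features that matter here — n ≈ 1.3–1.45 and weak
D₂O absorption across the amide I′ window — and user-supplied tables are
accepted wherever a subphase argument appears.

## Inclination fitting

`fit_orientation()` profiles the inclination: for each γ on a grid (default
0–90° in 2.5° steps, matching the resolution at which such estimates are
usually quoted) the band strengths are refit to the full multi-angle,
dual-polarization set by nonnegative least squares on the exact forward
model, and the residual SSD is recorded. Only strengths are refit; band
positions, widths, thickness and n_inf stay fixed, which keeps the γ profile
identifiable. Both polarizations are fitted jointly with equal weight. The
fit window defaults to the amide I′ region (1600–1700 cm⁻¹) so the
orientation-insensitive lipid carbonyl cannot dominate the residual.

The solver initialises with a linear NNLS solve on unit-strength basis
spectra and polishes with damped Gauss–Newton steps whose linearized
subproblems are again solved under s ≥ 0. Because RA is nearly linear in the
strengths at monolayer optical densities, a handful of iterations reaches
machine precision; noiseless self-fits recover SSD ≈ 10⁻²⁸. Ties in the
profile minimum break toward smaller γ, making the output deterministic.

The 95 % confidence interval is a profile-likelihood F-test on the SSD
ratio: CI = {γ : SSD(γ) ≤ SSD_min(1 + F(1, n−p; 0.95)/(n−p))}, with the
threshold crossing located by linear interpolation between grid points, n
the number of fitted residuals and p the number of fitted parameters
(strengths + γ). A profile that never exceeds the threshold is returned as
the full grid range and flagged `unconstrained`; a minimum on the grid
boundary is flagged and warned about. In 200-replicate simulations at
realistic noise (RA noise of 1/50 of the maximum band) the empirical
coverage of the true inclination is ~98 %, inside the expected 90–99 % band
for a grid-discretised profile interval.

One convention deserves note: simulated RA spectra include the smooth
baseline contributed by the band-free film (thickness × index contrast).
Because the same baseline appears in the fitted model, it cancels from the
residual whenever data and model describe the same film — but a fit to
spectra that are exactly zero will report the (small) baseline SSD rather
than zero unless the template's thickness is also negligible.

## From helix inclination to bundle inclination

IRRAS senses the *second moment* of the helix orientation distribution, so
for an intact coiled-coil bundle the quantity comparable across experiments
is the effective individual-helix inclination γ_eff defined by

sin²γ_eff = cos²δ·sin²β + ½·sin²δ·cos²β,

where β is the bundle-axis inclination from the film plane and δ the fixed
helix-to-bundle angle, averaged over rotation of the bundle about its own
axis. We adopt this second-moment convention (rather than the arithmetic
mean of inclinations) because it is the quantity the spectroscopy actually
constrains; for small δ the two differ by well under a degree. The map is
nonlinear: a flat-lying bundle (β = 0) still shows
γ_eff = arcsin(sin δ/√2) > 0, and the inverse map is only defined above that
geometric minimum — requests below it raise an error that reports the
minimum, and `fit_orientation()` maps such values to β = 0.

δ is measured from structure: per-chain helix axes by the rotational-fit
method (local axis points from sliding windows of four Cα atoms via the
bisector construction, then the principal component of those points,
oriented N→C), and the bundle axis as the principal direction of the
sign-aligned helix directions. N→C alignment before the bundle-axis
computation avoids antiparallel cancellation. The helical residue range
defaults to the longest residue run resolved in *all* chains, with an
explicit override. For an ideal trimer built at δ = 17° — the geometry of
the HR1-type trimeric coiled coil used throughout the examples — the three
anchor values of the map are: minimum effective helix inclination 12°
(β = 0), and trimer inclinations of 20° and 23° for effective helix
inclinations of 22.5° and 25°.

## Langmuir monolayer insertion

Adsorption curves π(t) at initial pressure π₀ are read out as
Δπ = π(t_read) − π₀ with t_read 20 min after injection (mean over ±0.5 min);
the Δπ(π₀) points are regressed by OLS. The synergy factor is a = slope + 1
(a > 0: attractive protein–lipid interactions) and the maximum insertion
pressure is the x-intercept, MIP = −intercept/slope, defined only for
negative slopes. The MIP SD is propagated from the OLS covariance of
(intercept, slope) by the delta method — an equivalent-in-spirit choice
where published analyses cite an external error formula. Classification as
membrane-inserting uses a strict inequality against the monolayer–bilayer
equivalence pressure (30 mN·m⁻¹ by default): "above" means above.

## QCM-D

Traces are stored long (time × overtone) with event markers. Shifts are
event-referenced: the mean F and D over a 30 s window *ending* at the event,
minus the same statistic at a baseline event (the window length is an
instrumentally reasonable choice, configurable, as the original acquisition
convention is not standardised). Only the third overtone is analysed by
default; all recorded overtones are parsed and retained. Layer softness is
ΔD/(−ΔF), defined only for ΔF < 0. Desorption analysis fits an OLS line to
the post-rinse frequency decay and reports the deviation of any later
segment from the extrapolated line in units of the residual SD — segments
continuing the same trend sit within ~2 SD, a threefold-accelerated
desorption exceeds 5 SD. No Sauerbrey or viscoelastic mass modelling is
applied by default; a Sauerbrey helper with the standard 5 MHz crystal
constant is provided for rigid films.

## Spectral statistics

Band-integral ratios use trapezoidal integration with an optional linear
endpoint baseline per window; defaults are amide I′ 1600–1700 cm⁻¹ and
ν(C=O) 1700–1760 cm⁻¹, around the ~1640 and ~1730 cm⁻¹ band maxima. PCA of
the carbonyl region operates on mean-centred covariance (the spectra share
units), and each loading is oriented so its largest-magnitude element is
positive, making signs deterministic. The CD analysis reads θ₂₂₂ and θ₂₀₈ by
linear interpolation and reports their ratio; a ratio above 1 indicates
increased hydrophobicity of the helix environment (membrane burial or
oligomerisation).

## Synthetic data: what it shows and what it does not

Every input class has a generator with known ground truth
(`simulate_irras_set()`, `simulate_coiled_coil()`, `simulate_adsorption()`,
`simulate_qcmd()`, `simulate_cd()`), deterministic under a fixed seed. The
noise model is i.i.d. Gaussian throughout, with defaults chosen as visually
realistic fractions of signal: RA noise of 1/50 of the maximum band,
0.2 mN·m⁻¹ on surface pressure, 0.3 Hz on frequency. Generator defaults
reproduce the canonical experiment designs (10 angles × 2 polarizations
between 25° and 70°; π₀ between 15 and 30 mN·m⁻¹; an SLB run with vesicle
overshoot, rupture, protein adsorption and rinse).

Round-trip recovery of generator parameters through the analysis modules
demonstrates *internal consistency*: the fitting machinery inverts the
forward models correctly at realistic noise. It does not demonstrate that
the forward models capture every feature of real instruments — correlated
baseline drift, imperfect polarization, film heterogeneity, vesicle-rupture
kinetics and instrument-specific windowing conventions are all outside the
noise model, so real-data uncertainties will be somewhat larger than the
simulated ones.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use an ideal 3 × 60-residue
trimer, 10-angle × 2-polarization spectra on a 101-point grid, a 37-point
inclination grid (2.5° steps, narrowed to the informative range inside
replicate loops), 200-replicate coverage simulations and 100-seed bias
checks — sizes chosen so the entire validation runs in a few minutes on one
CPU while leaving Monte-Carlo error well below the tolerances being checked.
Degenerate inputs are handled explicitly: collinear Cα traces fall back to
the line direction; near-identical bands trigger an ill-conditioning warning
and return a pseudo-solution; flat SSD profiles are flagged rather than
silently producing a spurious interval; exact Brewster-angle references on a
non-absorbing subphase raise a singularity error with advice.

## Limitations

- Single uniaxial layer only: no biaxial films, multilayer stacks or
  roughness corrections.
- Band positions and widths are never fitted; a misassigned band set biases
  the inclination estimate.
- The helix↔bundle map assumes a rigid bundle with one δ; partially
  uncoiled or heterogeneous assemblies need per-helix treatment.
- QCM-D softness is a ratio, not a viscoelastic model; no Voigt fitting.
- Subphase optical constants are an oscillator-model approximation; users
  with tabulated literature data should supply them via
  `read_optical_constants()`.
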