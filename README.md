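# interfilm

Quantitative biophysics of peripheral membrane-protein films at lipid
interfaces, in R.

Peripheral proteins such as the caveolar coat protein Cavin1 bind lipid
membranes through a trimeric coiled coil and insert between the lipid head
groups. Three classical model-membrane experiments quantify this process,
and `interfilm` implements the full analysis stack for each of them, plus
synthetic-data generators with known ground truth so every stage can be
validated end to end:

- **Polarized IRRAS orientation analysis.** Infrared reflection–absorption
  spectra, RA(ν) = −log₁₀(R/R₀), of a protein/lipid monolayer on a D₂O
  subphase are measured at several angles of incidence with p- and
  s-polarized light. The amide I′ dichroism encodes the helix inclination
  angle γ (from the film plane). `interfilm` simulates RA spectra with an
  exact characteristic-matrix solution for a uniaxially anisotropic film
  between air and an absorbing subphase, and fits γ by profiling: at each
  candidate γ the band strengths are refit (nonnegative least squares on the
  exact forward model) and the sum of squared deviations (SSD) is recorded;
  the 95 % CI comes from a profile-likelihood F-test,
  SSD(γ) ≤ SSD_min·(1 + F(1, n−p; 0.95)/(n−p)).
  The orientational weight of each band is the azimuthally averaged second
  moment M = ⟨cos²θ⟩ = cos²α·sin²γ + ½·sin²α·cos²γ for a transition dipole
  at angle α from the helix axis, giving k_z = 3M·k_iso and
  k_x = k_y = 3/2·(1−M)·k_iso.

- **Coiled-coil bundle geometry.** For an intact bundle whose axis is
  inclined β from the film plane, with helices at the fixed angle δ from the
  bundle axis, the spectroscopically effective individual-helix inclination
  follows the second-moment average over bundle rotation:
  sin²γ_eff = cos²δ·sin²β + ½·sin²δ·cos²β — a nonlinear map whose minimum
  γ_eff(β=0) = arcsin(sin δ/√2) is the smallest helix inclination an intact
  bundle can show. `bundle_angles()` measures δ from any PDB structure
  (helix axes by a rotational/bisector fit of the Cα trace), and
  `trimer_inclination()` inverts the map.

- **Langmuir monolayer insertion.** Regressing the protein-induced pressure
  change Δπ on the initial pressure π₀ yields the synergy factor
  a = slope + 1 and the maximum insertion pressure MIP = −intercept/slope
  (x-intercept), with the MIP SD propagated from the OLS covariance.
  MIP above the monolayer–bilayer equivalence pressure (~30 mN·m⁻¹)
  classifies a protein as membrane-inserting.

- **QCM-D adsorption traces.** Event-referenced ΔF/ΔD shifts (third
  overtone), layer softness ΔD/(−ΔF), the classic two-phase supported-lipid-
  bilayer formation signature, and extrapolation of post-rinse desorption
  baselines to test whether later treatments release extra protein.

- **Spectral statistics.** Amide I′/ν(C=O) band-integral ratios (adsorbed
  protein per lipid), covariance PCA of the carbonyl region (carbonyl
  hydration), and the CD ellipticity ratio [θ₂₂₂]/[θ₂₀₈].

Everything is tidyverse-native: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate a full polarized multi-angle acquisition from a film whose helices
are inclined 22.5° from the interface, refit the inclination, and map it to
the inclination of an intact trimer with helix-to-bundle angle δ = 17°:

```r
library(interfilm)

geom <- bundle_angles(simulate_coiled_coil(delta = 17, n_res = 60))
glance(geom)
#> # A tibble: 1 × 6
#>   n_helices delta_mean delta_min delta_max res_first res_last
#>       <int>      <dbl>     <dbl>     <dbl>     <int>    <int>
#> 1         3       17.0      17.0      17.0         1       60

spectra <- simulate_irras_set(gamma_true = 22.5, angles = seq(25, 70, 5),
                              noise_sigma = 0, seed = 1)
fit <- fit_orientation(spectra, default_film(),
                       gamma_grid = seq(0, 90, 2.5), structure = geom)
fit
#> <orientation_fit> gamma = 22.50 deg (95% CI 22.50-22.50), SSD_min = 3.6e-28, 1020 residuals
#>   bundle inclination beta = 20.18 deg (delta = 17.00 deg, CI 20.18-20.18)
```

The fitted helix inclination of 22.5° corresponds to a trimer inclination of
20° (the map is nonlinear: a flat-lying intact trimer, β = 0, still shows an
effective helix inclination of ~12° because of the fixed helix-to-bundle
angle). With noiseless input the CI collapses onto the best grid cell; with
realistic noise it widens to a few degrees.

Monolayer insertion analysis from a Δπ/π₀ table:

```r
ia <- mip_synergy(tibble::tibble(pi0 = c(20, 25, 30),
                                 delta_pi = c(9.50, 6.55, 3.60)))
ia
#> <insertion_analysis> n = 3: slope = -0.5900, synergy a = 0.4100
#>   MIP = 36.10 +- 0.00 mN/m (R^2 = 1.0000)
classify_insertion(ia$mip)
#> [1] "inserting"
```

A positive synergy factor indicates attractive protein–lipid interactions;
a MIP of 36.1 mN·m⁻¹ exceeds the ~30 mN·m⁻¹ bilayer-equivalence pressure,
so this protein inserts spontaneously into bilayer membranes.

## Package layout

- `R/optics.R`, `R/orientation.R` — forward optical model and inclination fit
- `R/geometry.R` — helix axes, bundle angles, inclination mapping
- `R/langmuir.R`, `R/qcmd.R`, `R/spectra-stats.R` — companion analyses
- `R/simulate.R` — ground-truth generators for every input class
- `R/pipeline.R` — end-to-end `run_pipeline()` (simulate → fit → map → report)
- `vignettes/orientation-analysis.Rmd` — models, assumptions, parameter
  choices and limitations
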