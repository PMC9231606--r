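#' Band components and film models
#'
#' `band_component()` describes one vibrational band of the film: a
#' Lorentzian or Gaussian line with integrated isotropic extinction
#' `strength`, centred at `position`, and a transition dipole at angle
#' `dipole_angle` from the helix axis. `film_model()` assembles bands into
#' the uniaxial monolayer description consumed by the forward optical
#' simulator.
#'
#' @param position Band-centre wavenumber (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param strength Integrated isotropic extinction (dimensionless * cm^-1),
#'   >= 0.
#' @param dipole_angle Angle between transition dipole moment and helix axis
#'   (degrees, 0-90). The amide I default of 38 degrees is the standard
#'   alpha-helix literature value.
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#' @param isotropic If `TRUE` the band is orientation-insensitive (e.g.
#'   unordered structure, lipid carbonyl treated isotropically).
#' @param assignment Free-text band assignment.
#' @return One-row tibble describing the band.
#' @export
band_component <- function(position, fwhm, strength, dipole_angle = 38,
                           shape = c("lorentzian", "gaussian"),
                           isotropic = FALSE, assignment = "") {
  shape <- match.arg(shape)
  assert_number(fwhm, "fwhm", lower = 0, closed_lower = FALSE)
  assert_number(strength, "strength", lower = 0)
  assert_number(dipole_angle, "dipole_angle", 0, 90)
  tibble(position = position, fwhm = fwhm, strength = strength,
         dipole_angle = dipole_angle, shape = shape,
         isotropic = isotropic, assignment = assignment)
}

#' @rdname band_component
#' @param thickness_nm Film thickness (nm), > 0. Held fixed (nuisance) during
#'   orientation fitting; default 2.5 nm for a lipid monolayer with an
#'   adsorbed helix layer.
#' @param n_inf Non-resonant real refractive index of the film.
#' @param bands Tibble of band components (rows from [band_component()]).
#' @param gamma_helix Helix inclination angle from the film plane (degrees;
#'   0 = parallel to the interface, 90 = normal).
#' @return For `film_model()`: a list of class `film_model`.
#' @export
film_model <- function(bands, gamma_helix = 0, thickness_nm = 2.5, n_inf = 1.41) {
  assert_number(thickness_nm, "thickness_nm", lower = 0, closed_lower = FALSE)
  assert_number(gamma_helix, "gamma_helix", 0, 90)
  assert_number(n_inf, "n_inf", lower = 0, closed_lower = FALSE)
  if (nrow(bands) > 0) {
    assert_number(bands$strength, "strength", lower = 0)
    assert_number(bands$fwhm, "fwhm", lower = 0, closed_lower = FALSE)
    assert_number(bands$dipole_angle, "dipole_angle", 0, 90)
  }
  structure(list(thickness_nm = thickness_nm, n_inf = n_inf,
                 bands = as_tibble(bands), gamma_helix = gamma_helix),
            class = "film_model")
}

#' @export
print.film_model <- function(x, ...) {
  cat(sprintf("<film_model> d = %.2f nm, n_inf = %.3f, gamma_helix = %.1f deg\n",
              x$thickness_nm, x$n_inf, x$gamma_helix))
  print(x$bands)
  invisible(x)
}

#' Default three-band film template
#'
#' A configurable placeholder amide I' + lipid carbonyl model: an oriented
#' helical component, an isotropic unordered component and the isotropic
#' lipid ester C=O band. Positions and widths are typical values for a
#' coiled-coil protein at a phospholipid monolayer, not a fitted set.
#'
#' @inheritParams film_model
#' @param strengths Length-3 numeric: helix, unordered, lipid C=O strengths.
#' @return A `film_model`.
#' @export
default_film <- function(gamma_helix = 0, strengths = c(12, 5, 8),
                         thickness_nm = 2.5, n_inf = 1.41) {
  bands <- dplyr::bind_rows(
    band_component(1640, 25, strengths[1], dipole_angle = 38,
                   assignment = "amide I' helix"),
    band_component(1662, 35, strengths[2], isotropic = TRUE,
                   assignment = "amide I' unordered"),
    band_component(1730, 30, strengths[3], isotropic = TRUE,
                   assignment = "lipid C=O")
  )
  film_model(bands, gamma_helix = gamma_helix,
             thickness_nm = thickness_nm, n_inf = n_inf)
}

#' Orientation second moment of a transition dipole
#'
#' Azimuthally averaged squared cosine M = <cos^2 theta> of the angle between
#' a transition dipole and the surface normal, for a dipole fixed at angle
#' `alpha` from a helix axis inclined `gamma_helix` from the surface plane,
#' with uniaxial symmetry about the normal:
#' M = cos^2(alpha) sin^2(gamma) + 1/2 sin^2(alpha) cos^2(gamma).
#' M = 1/3 at the magic angle (54.7356 deg) for any gamma.
#'
#' @param alpha Dipole-to-helix-axis angle (degrees, 0-90).
#' @param gamma_helix Helix inclination from the film plane (degrees, 0-90).
#' @return M in \[0, 1\].
#' @examples
#' dipole_second_moment(0, 90)        # 1
#' dipole_second_moment(54.7356, 20)  # 1/3
#' @export
dipole_second_moment <- function(alpha, gamma_helix) {
  assert_number(alpha, "alpha", 0, 90)
  assert_number(gamma_helix, "gamma_helix", 0, 90)
  a <- deg2rad(alpha); g <- deg2rad(gamma_helix)
  cos(a)^2 * sin(g)^2 + 0.5 * sin(a)^2 * cos(g)^2
}

# isotropic lineshape with unit *integrated* area times `strength`
band_kiso <- function(position, fwhm, strength, shape, grid) {
  if (shape == "lorentzian") {
    hw <- fwhm / 2
    strength / pi * hw / ((grid - position)^2 + hw^2)
  } else {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    strength / (s * sqrt(2 * pi)) * exp(-(grid - position)^2 / (2 * s^2))
  }
}

#' Anisotropic extinction spectra of an oriented film
#'
#' Distributes each band's isotropic extinction over the principal axes of a
#' uniaxial film (optical axis along the surface normal z). For an oriented
#' band with second moment M (from [dipole_second_moment()]):
#' k_z = 3 M k_iso and k_x = k_y = 3/2 (1 - M) k_iso. Isotropic-flagged bands
#' contribute k_iso to all three axes. The sum rule
#' k_x + k_y + k_z = 3 sum(k_iso) holds pointwise.
#'
#' @param bands Band tibble (rows from [band_component()]).
#' @param gamma_helix Helix inclination (degrees).
#' @param grid Wavenumbers (cm^-1). Should cover band centres +- 3 fwhm for
#'   quantitative work.
#' @return Tibble with columns `wavenumber`, `k_x`, `k_y`, `k_z`.
#' @export
anisotropic_extinction <- function(bands, gamma_helix, grid) {
  kx <- kz <- kiso_tot <- numeric(length(grid))
  if (nrow(bands) > 0) {
    assert_number(bands$strength, "strength", lower = 0)
    for (i in seq_len(nrow(bands))) {
      b <- bands[i, ]
      kiso <- band_kiso(b$position, b$fwhm, b$strength, b$shape, grid)
      kiso_tot <- kiso_tot + kiso
      if (isTRUE(b$isotropic)) {
        kx <- kx + kiso
        kz <- kz + kiso
      } else {
        M <- dipole_second_moment(b$dipole_angle, gamma_helix)
        kz <- kz + 3 * M * kiso
        kx <- kx + 1.5 * (1 - M) * kiso
      }
    }
  }
  tibble(wavenumber = grid, k_x = kx, k_y = kx, k_z = kz)
}

# complex kz and polarization admittance in an isotropic half-space
iso_q <- function(eps, kx2, pol) {
  kz <- sqrt(eps - kx2)
  if (pol == "s") kz else kz / eps
}

# Exact reflection amplitude of air / uniaxial film / substrate, vectorized
# over the grid. eps_x, eps_z, eps_sub are complex vectors; nu in cm^-1,
# d in cm. Characteristic-matrix (Abeles) solution; for p-polarization the
# uniaxial layer has kz_f^2 = eps_x (k0^2 - kx^2/eps_z) and TM admittance
# kz_f / eps_x.
uniaxial_r <- function(nu, eps_x, eps_z, d_cm, eps_sub, phi_deg, pol) {
  k0 <- 2 * pi * nu
  kx2 <- sin(deg2rad(phi_deg))^2  # in units of k0^2 (incident medium n = 1)
  q1 <- iso_q(1 + 0i, kx2, pol)
  q3 <- iso_q(eps_sub, kx2, pol)
  if (pol == "s") {
    kzf <- sqrt(eps_x - kx2)
    qf <- kzf
  } else {
    kzf <- sqrt(eps_x * (1 - kx2 / eps_z))
    qf <- kzf / eps_x
  }
  beta <- k0 * d_cm * kzf
  B <- cos(beta) + 1i * sin(beta) * q3 / qf
  C <- 1i * qf * sin(beta) + q3 * cos(beta)
  (q1 * B - C) / (q1 * B + C)
}

#' Reflectance of the three-phase system air / uniaxial film / subphase
#'
#' Exact characteristic-matrix solution for an anisotropic uniaxial layer
#' (in-plane permittivity from k_x, out-of-plane from k_z, optical axis along
#' the surface normal) of thickness `thickness_nm` on a semi-infinite
#' absorbing subphase. s-polarized light probes only in-plane components;
#' p-polarized light mixes in-plane and out-of-plane. Reduces continuously to
#' the two-phase Fresnel reflectance as thickness goes to 0.
#'
#' @param film A [film_model()].
#' @param phi Angle of incidence (degrees), in (0, 90).
#' @param polarization `"p"` or `"s"`.
#' @param subphase Optical-constants tibble for the subphase; interpolated
#'   onto `grid`.
#' @param grid Wavenumbers (cm^-1).
#' @return Tibble with columns `wavenumber`, `reflectance` (in \[0, 1\]).
#' @export
reflectance_three_phase <- function(film, phi, polarization = c("p", "s"),
                                    subphase = subphase_optical_constants("D2O", grid),
                                    grid = default_grid()) {
  polarization <- match.arg(polarization)
  assert_number(phi, "phi", 0, 90, closed_lower = FALSE, closed_upper = FALSE)
  sub <- interp_constants(subphase, grid)
  if (any(!is.finite(sub$n)) || any(!is.finite(sub$k))) {
    abort("non-finite subphase optical constants.", class = "interfilm_data_error")
  }
  kk <- anisotropic_extinction(film$bands, film$gamma_helix, grid)
  eps_x <- (film$n_inf + 1i * kk$k_x)^2
  eps_z <- (film$n_inf + 1i * kk$k_z)^2
  eps_sub <- (sub$n + 1i * sub$k)^2
  r <- uniaxial_r(grid, eps_x, eps_z, film$thickness_nm * 1e-7, eps_sub,
                  phi, polarization)
  tibble(wavenumber = grid, reflectance = Mod(r)^2)
}

#' Two-phase (bare-surface) Fresnel reflectance
#'
#' Reflectance of the film-free air/subphase interface, used as the
#' reference R0 in reflection-absorbance spectra.
#'
#' @inheritParams reflectance_three_phase
#' @return Tibble with columns `wavenumber`, `reflectance`.
#' @export
two_phase_reflectance <- function(phi, polarization = c("p", "s"),
                                  subphase = subphase_optical_constants("D2O", grid),
                                  grid = default_grid()) {
  polarization <- match.arg(polarization)
  assert_number(phi, "phi", 0, 90, closed_lower = FALSE, closed_upper = FALSE)
  sub <- interp_constants(subphase, grid)
  kx2 <- sin(deg2rad(phi))^2
  q1 <- iso_q(1 + 0i, kx2, polarization)
  q3 <- iso_q((sub$n + 1i * sub$k)^2, kx2, polarization)
  r <- (q1 - q3) / (q1 + q3)
  tibble(wavenumber = grid, reflectance = Mod(r)^2)
}

#' Simulate an IRRA spectrum
#'
#' Forward-simulates the reflection-absorbance spectrum
#' RA(nu) = -log10(R_film / R_bare) of an oriented film on an aqueous
#' subphase, where R_bare is the film-free two-phase reflectance of the same
#' subphase.
#'
#' @inheritParams reflectance_three_phase
#' @param label Label carried in the output spectrum.
#' @return A spectra tibble (one spectrum) with `phi` and `polarization`
#'   metadata.
#' @examples
#' film <- default_film(gamma_helix = 22.5)
#' sp <- simulate_irra_spectrum(film, phi = 40, polarization = "p")
#' @export
simulate_irra_spectrum <- function(film, phi, polarization = c("p", "s"),
                                   subphase = subphase_optical_constants("D2O", grid),
                                   grid = default_grid(), label = "simulated") {
  polarization <- match.arg(polarization)
  r_film <- reflectance_three_phase(film, phi, polarization, subphase, grid)
  r_bare <- two_phase_reflectance(phi, polarization, subphase, grid)
  if (any(r_bare$reflectance <= 1e-12)) {
    abort(paste0(
      "bare-surface reflectance vanishes at this angle (Brewster angle of a ",
      "non-absorbing subphase): RA is singular. Use an absorbing subphase or ",
      "a different angle of incidence."
    ), class = "interfilm_singularity_error")
  }
  spectra_tbl(grid, -log10(r_film$reflectance / r_bare$reflectance),
              angle_deg = phi, polarization = polarization, label = label)
}
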