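test_that("dipole second moment matches closed form, magic angle and numerical integration", {
  # vertical helix, dipole along the axis
  expect_equal(dipole_second_moment(0, 90), 1.0)
  # magic angle is isotropic irrespective of inclination
  for (g in c(0, 20, 45, 90)) {
    expect_equal(dipole_second_moment(54.7356, g), 1 / 3, tolerance = 1e-6)
  }
  # flat helix with the amide I dipole angle: M = sin^2(alpha)/2
  expect_equal(dipole_second_moment(38, 0), 0.5 * sin(38 * pi / 180)^2,
               tolerance = 1e-12)
  expect_equal(dipole_second_moment(38, 0), 0.18952, tolerance = 1e-4)
  # numerical azimuthal integration oracle over assorted geometries
  for (al in c(10, 38, 70)) {
    for (g in c(0, 22.5, 60)) {
      expect_equal(dipole_second_moment(al, g), num_second_moment(al, g),
                   tolerance = 1e-7)
    }
  }
  expect_error(dipole_second_moment(-1, 10), class = "interfilm_domain_error")
  expect_error(dipole_second_moment(10, 91), class = "interfilm_domain_error")
})

test_that("anisotropic extinction obeys the sum rule and isotropic limits", {
  grid <- default_grid()
  bands <- dplyr::bind_rows(
    band_component(1640, 25, 12, dipole_angle = 38),
    band_component(1662, 35, 5, isotropic = TRUE),
    band_component(1730, 30, 8, dipole_angle = 75),
    band_component(1615, 18, 3, dipole_angle = 0, shape = "gaussian")
  )
  for (g in c(0, 22.5, 67)) {
    kk <- anisotropic_extinction(bands, g, grid)
    kiso <- Reduce(`+`, lapply(seq_len(nrow(bands)), function(j) {
      interfilm:::band_kiso(bands$position[j], bands$fwhm[j], bands$strength[j],
                            bands$shape[j], grid)
    }))
    expect_lt(max(abs(kk$k_x + kk$k_y + kk$k_z - 3 * kiso)), 1e-12)
  }
  # magic-angle band is isotropic: all axes equal the isotropic lineshape
  b_magic <- band_component(1640, 25, 10, dipole_angle = 54.7356)
  kk <- anisotropic_extinction(b_magic, 20, grid)
  kiso <- interfilm:::band_kiso(1640, 25, 10, "lorentzian", grid)
  expect_equal(kk$k_x, kiso, tolerance = 1e-6)
  expect_equal(kk$k_z, kiso, tolerance = 1e-6)
  # peak scaling at M = sin^2(38 deg)/2 for a flat helix
  M <- dipole_second_moment(38, 0)
  b <- band_component(1640, 25, 0.1 * pi * 25 / 2, dipole_angle = 38) # peak k_iso = 0.1
  kk <- anisotropic_extinction(b, 0, grid)
  i <- which(grid == 1640)
  expect_equal(kk$k_z[i], 3 * M * 0.1, tolerance = 1e-4)   # 0.0569
  expect_equal(kk$k_x[i], 1.5 * (1 - M) * 0.1, tolerance = 1e-4) # 0.1216
  # empty band list is a valid zero film
  kk0 <- anisotropic_extinction(bands[0, ], 10, grid)
  expect_true(all(kk0$k_x == 0 & kk0$k_z == 0))
  bneg <- bands
  bneg$strength[1] <- -1
  expect_error(anisotropic_extinction(bneg, 10, grid),
               class = "interfilm_domain_error")
})

test_that("three-phase reflectance reduces to two-phase Fresnel as thickness vanishes", {
  grid <- seq(1600, 1700, 50)
  film0 <- film_model(default_film()$bands[0, ], gamma_helix = 0,
                      thickness_nm = 1e-9)
  # non-absorbing and absorbing subphases, both polarizations, 5-85 deg
  for (nk in list(c(1.33, 0), c(1.32, 0.05))) {
    sub <- flat_subphase(grid, nk[1], nk[2])
    n2 <- complex(real = nk[1], imaginary = nk[2])
    for (pol in c("p", "s")) {
      for (phi in seq(5, 85, by = 5)) {
        R <- reflectance_three_phase(film0, phi, pol, sub, grid)$reflectance
        expect_equal(R, rep(fresnel_R(phi, pol, n2), length(grid)),
                     tolerance = 1e-10)
      }
    }
  }
  # near-normal incidence closed form
  sub <- flat_subphase(grid)
  R0 <- reflectance_three_phase(film0, 0.001, "p", sub, grid)$reflectance[1]
  expect_equal(R0, ((1.33 - 1) / (1.33 + 1))^2, tolerance = 1e-6)
  # Brewster angle zero for p polarization on a non-absorbing subphase
  Rb <- reflectance_three_phase(film0, atan(1.33) * 180 / pi, "p", sub,
                                grid)$reflectance
  expect_lt(max(Rb), 1e-20)
  expect_error(reflectance_three_phase(film0, 0, "p", sub, grid),
               class = "interfilm_domain_error")
  expect_error(reflectance_three_phase(film0, 90, "p", sub, grid),
               class = "interfilm_domain_error")
})

test_that("exact reflection-absorbance agrees with the first-order thin-film oracle", {
  grid <- default_grid()
  sub <- subphase_optical_constants("D2O", grid)
  film <- default_film(gamma_helix = 25, thickness_nm = 3)
  kk <- anisotropic_extinction(film$bands, 25, grid)
  film$bands$strength <- film$bands$strength * 0.1 / max(kk$k_x) # peak k = 0.1
  kk <- anisotropic_extinction(film$bands, 25, grid)
  eps_x <- (film$n_inf + 1i * kk$k_x)^2
  eps_z <- (film$n_inf + 1i * kk$k_z)^2
  eps_sub <- (sub$n + 1i * sub$k)^2
  for (pol in c("p", "s")) {
    for (phi in c(30, 50, 68)) {
      exact <- simulate_irra_spectrum(film, phi, pol, sub, grid)$ra
      appr <- ra_first_order(grid, eps_x, eps_z, 3e-7, eps_sub, phi, pol)
      i <- which.max(abs(exact))
      expect_lt(abs(appr[i] - exact[i]) / abs(exact[i]), 0.05)
    }
  }
})

test_that("s-polarized spectra are blind to out-of-plane extinction", {
  grid <- default_grid()
  sub <- subphase_optical_constants("D2O", grid)
  # same in-plane extinction, different out-of-plane: isotropic band with
  # strength s versus fully in-plane band (dipole perpendicular to a vertical
  # helix, M = 0) with strength s / 1.5
  s <- 9
  f_iso <- film_model(band_component(1640, 25, s, isotropic = TRUE))
  f_ip <- film_model(band_component(1640, 25, s / 1.5, dipole_angle = 90),
                     gamma_helix = 90)
  k_iso <- anisotropic_extinction(f_iso$bands, 0, grid)
  k_ip <- anisotropic_extinction(f_ip$bands, 90, grid)
  expect_equal(k_iso$k_x, k_ip$k_x, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(k_iso$k_z, k_ip$k_z)))
  for (phi in c(30, 60)) {
    ra1 <- simulate_irra_spectrum(f_iso, phi, "s", sub, grid)$ra
    ra2 <- simulate_irra_spectrum(f_ip, phi, "s", sub, grid)$ra
    expect_lt(max(abs(ra1 - ra2)), 1e-12)
    # p-polarization does see the difference
    rp1 <- simulate_irra_spectrum(f_iso, phi, "p", sub, grid)$ra
    rp2 <- simulate_irra_spectrum(f_ip, phi, "p", sub, grid)$ra
    expect_gt(max(abs(rp1 - rp2)), 1e-6)
  }
})

test_that("magic-angle films give inclination-independent spectra", {
  grid <- default_grid()
  sub <- subphase_optical_constants("D2O", grid)
  bands <- band_component(1645, 30, 10,
                          dipole_angle = acos(1 / sqrt(3)) * 180 / pi)
  ra <- lapply(c(0, 35, 90), function(g) {
    simulate_irra_spectrum(film_model(bands, gamma_helix = g), 40, "p", sub, grid)$ra
  })
  expect_lt(max(abs(ra[[1]] - ra[[2]])), 1e-10)
  expect_lt(max(abs(ra[[1]] - ra[[3]])), 1e-10)
})

test_that("thin weak-absorber RA scales linearly in thickness and strength", {
  grid <- default_grid()
  sub <- subphase_optical_constants("D2O", grid)
  mk <- function(d, s) {
    film_model(band_component(1640, 25, s, dipole_angle = 38),
               gamma_helix = 20, thickness_nm = d)
  }
  band_amp <- function(film) {
    ra <- simulate_irra_spectrum(film, 40, "p", sub, grid)$ra
    base <- simulate_irra_spectrum(
      film_model(film$bands[0, ], gamma_helix = 20,
                 thickness_nm = film$thickness_nm), 40, "p", sub, grid)$ra
    max(abs(ra - base))
  }
  s_weak <- 0.05 * pi * 25 / 2 # peak k_iso = 0.05
  expect_equal(band_amp(mk(2, s_weak)) / band_amp(mk(1, s_weak)), 2,
               tolerance = 0.02)
  expect_equal(band_amp(mk(3, 2 * s_weak)) / band_amp(mk(3, s_weak)), 2,
               tolerance = 0.03)
})

test_that("RA vanishes for a vanishing film and is singular at Brewster on a clear subphase", {
  grid <- seq(1600, 1700, 10)
  sub <- flat_subphase(grid)
  film0 <- film_model(default_film()$bands[0, ], thickness_nm = 1e-12)
  ra <- simulate_irra_spectrum(film0, 40, "p", sub, grid)$ra
  expect_lt(max(abs(ra)), 1e-10)
  expect_error(
    simulate_irra_spectrum(default_film(), atan(1.33) * 180 / pi, "p", sub, grid),
    class = "interfilm_singularity_error"
  )
})
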