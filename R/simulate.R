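#' Synthetic multi-angle IRRA dataset
#'
#' Forward-simulates a full acquisition series (several angles of incidence,
#' both polarizations) at a known helix inclination `gamma_true` and adds
#' i.i.d. Gaussian noise. The default angles mirror a 25-70 degree series;
#' the default noise is 1/50 of the maximum band amplitude, a visually
#' realistic level for accumulated FT-IR scans.
#'
#' @param gamma_true True helix inclination (degrees).
#' @param angles Angles of incidence (degrees).
#' @param polarizations Subset of `c("p", "s")`.
#' @param film A [film_model()]; its `gamma_helix` is replaced by
#'   `gamma_true`.
#' @param noise_sigma Gaussian noise SD on RA; `NULL` = max|RA|/50; `0` =
#'   noiseless.
#' @param seed Integer seed (required when `noise_sigma > 0` for
#'   reproducibility).
#' @param subphase,grid Passed to [simulate_irra_spectrum()].
#' @param label Label prefix for the generated spectra.
#' @return A spectra tibble with one spectrum per (angle, polarization).
#' @export
simulate_irras_set <- function(gamma_true, angles = seq(25, 70, by = 5),
                               polarizations = c("p", "s"),
                               film = default_film(),
                               noise_sigma = NULL, seed = NULL,
                               subphase = subphase_optical_constants("D2O", grid),
                               grid = default_grid(), label = "synthetic") {
  assert_number(gamma_true, "gamma_true", 0, 90)
  film$gamma_helix <- gamma_true
  combos <- tidyr::expand_grid(angle = angles, pol = polarizations)
  out <- purrr::pmap(combos, function(angle, pol) {
    simulate_irra_spectrum(film, angle, pol, subphase, grid, label = label)
  }) |> purrr::list_rbind()
  sigma <- noise_sigma %||% (max(abs(out$ra)) / 50)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    out$ra <- out$ra + stats::rnorm(nrow(out), 0, sigma)
  }
  out
}

# rotation taking the z axis onto unit vector v
rot_z_to <- function(v) {
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3], z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * K %*% K
}

#' Ideal coiled-coil coordinates with known helix-to-bundle angle
#'
#' Builds `n_helices` ideal alpha-helices (C-alpha only) whose straight axes
#' make the angle `delta` with a common bundle axis (z), at equal azimuthal
#' spacing on a circle of radius `bundle_radius`. Each axis is tilted
#' *tangentially* (supercoil-like), so the helices stay separated instead of
#' converging. [bundle_angles()] on the output recovers `delta` within 0.5
#' degrees. This synthetic construction stands in for a real coiled-coil
#' trimer crystal structure when one is not at hand.
#'
#' @param delta Helix-to-bundle angle (degrees, 0 <= delta < 30).
#' @param n_helices Number of helices (default 3).
#' @param n_res Residues per helix (>= 15).
#' @param rise Rise per residue along the helix axis (Angstrom, default 1.5).
#' @param radius Helix radius of the C-alpha trace (Angstrom, default 2.3).
#' @param bundle_radius Distance of each helix axis from the bundle axis
#'   (Angstrom, default 7).
#' @param twist Helical twist per residue (degrees, default 100).
#' @return Tibble of C-alpha coordinates with columns `chain`, `resno`,
#'   `x`, `y`, `z` (chains "A", "B", ...).
#' @examples
#' cc <- simulate_coiled_coil(delta = 17, n_res = 30)
#' bundle_angles(cc)$delta_mean
#' @export
simulate_coiled_coil <- function(delta, n_helices = 3, n_res = 60, rise = 1.5,
                                 radius = 2.3, bundle_radius = 7, twist = 100) {
  assert_number(delta, "delta", 0, 30, closed_upper = FALSE)
  if (n_res < 15) abort("n_res must be >= 15.", class = "interfilm_domain_error")
  if (n_helices > 1) {
    chord <- 2 * bundle_radius * sin(pi / n_helices)
    if (chord < 2 * radius) {
      abort("helices overlap at these radii; increase bundle_radius.",
            class = "interfilm_domain_error")
    }
  }
  t_res <- deg2rad(twist) * (seq_len(n_res) - 1)
  z_res <- rise * (seq_len(n_res) - 1)
  local <- cbind(radius * cos(t_res), radius * sin(t_res), z_res)
  local <- sweep(local, 2, c(0, 0, mean(z_res)))  # centre along the axis
  out <- purrr::map(seq_len(n_helices), function(i) {
    phi <- 2 * pi * (i - 1) / n_helices
    origin <- bundle_radius * c(cos(phi), sin(phi), 0)
    tangent <- c(-sin(phi), cos(phi), 0)
    dir <- cos(deg2rad(delta)) * c(0, 0, 1) + sin(deg2rad(delta)) * tangent
    R <- rot_z_to(dir)
    xyz <- t(R %*% t(local)) + matrix(origin, n_res, 3, byrow = TRUE)
    tibble(chain = LETTERS[i], resno = seq_len(n_res),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }) |> purrr::list_rbind()
  # hard safety check against actual steric overlap of the generated traces
  if (n_helices > 1) {
    a <- out[out$chain == "A", c("x", "y", "z")]
    b <- out[out$chain == "B", c("x", "y", "z")]
    dmin <- min(pracma::distmat(as.matrix(a), as.matrix(b)))
    if (dmin < 2) abort("generated helices collide; increase bundle_radius.",
                        class = "interfilm_domain_error")
  }
  out
}

#' Write C-alpha coordinates as a PDB file
#'
#' @param ca Tibble with columns `chain`, `resno`, `x`, `y`, `z` (e.g. from
#'   [simulate_coiled_coil()]).
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_ca_pdb <- function(ca, path) {
  xyz <- as.vector(t(as.matrix(ca[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(ca)),
    resno = ca$resno, chain = ca$chain,
    resid = rep("ALA", nrow(ca)), elety = rep("CA", nrow(ca))
  )
  invisible(path)
}

#' Synthetic monolayer adsorption experiment
#'
#' Generates adsorption kinetics pi(t) = pi0 + delta_pi (1 - exp(-t/tau)) at
#' several initial pressures, where the equilibrium responses lie exactly on
#' the line delta_pi = slope * pi0 + intercept with `slope = synergy_true - 1`
#' and x-intercept `mip_true`. Gaussian noise of SD `noise_sigma` is added to
#' the recorded pressures; the returned table carries the exact equilibrium
#' values.
#'
#' @param mip_true True maximum insertion pressure (mN/m).
#' @param synergy_true True synergy factor (< 1, so the slope is negative).
#' @param pi0 Initial surface pressures (mN/m), all below `mip_true`.
#' @param tau_min Adsorption time constant (minutes).
#' @param noise_sigma Pressure noise SD (mN/m, default 0.2).
#' @param seed Integer seed.
#' @param t_max,dt Record length and sampling interval (minutes).
#' @param injection_time Injection time (minutes into each record).
#' @return List with `curves` (tibble: pi0, time_min, pressure) and `table`
#'   (tibble: pi0, delta_pi - the exact equilibrium line).
#' @export
simulate_adsorption <- function(mip_true = 36.1, synergy_true = 0.41,
                                pi0 = c(20, 25, 30), tau_min = 3,
                                noise_sigma = 0.2, seed = NULL,
                                t_max = 30, dt = 0.1, injection_time = 0) {
  if (synergy_true >= 1) {
    abort("synergy_true must be < 1 (negative regression slope).",
          class = "interfilm_domain_error")
  }
  slope <- synergy_true - 1
  intercept <- -slope * mip_true
  delta_pi <- slope * pi0 + intercept
  if (any(delta_pi <= 0)) {
    warn("some pi0 >= MIP: generated delta_pi <= 0 for those curves.")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_max, by = dt)
  curves <- purrr::map2(pi0, delta_pi, function(p0, dp) {
    t_after <- pmax(times - injection_time, 0)
    pres <- p0 + dp * (1 - exp(-t_after / tau_min))
    if (noise_sigma > 0) pres <- pres + stats::rnorm(length(pres), 0, noise_sigma)
    tibble(pi0 = p0, time_min = times, pressure = pres)
  }) |> purrr::list_rbind()
  list(curves = curves, table = tibble(pi0 = pi0, delta_pi = delta_pi))
}

#' Synthetic QCM-D trace with SLB formation and protein adsorption
#'
#' Builds the canonical supported-lipid-bilayer experiment: vesicle
#' adsorption overshoot followed by rupture to the final bilayer frequency
#' (the classic two-phase SLB signature), a stable baseline, protein
#' adsorption as a saturating exponential to (`protein_df`, `protein_dd`),
#' and linear desorption after the buffer rinse. Event markers are embedded:
#' `vesicle_injection`, `slb_formed`, `protein_injection`, `equilibrium`,
#' `rinse`, `record_end`.
#'
#' @param slb_final_f Final bilayer frequency shift (Hz, < 0).
#' @param protein_df,protein_dd Protein-induced equilibrium shifts (Hz < 0;
#'   dissipation x 1e-6).
#' @param adsorption_tau Protein adsorption time constant (minutes).
#' @param desorption_rate Post-rinse frequency recovery rate (Hz/min, >= 0).
#' @param noise_sigma Frequency noise SD (Hz, default 0.3; dissipation noise
#'   is scaled to 1/10 of it).
#' @param seed Integer seed.
#' @param overtones Overtone numbers to emit (identical normalized signal).
#' @param overshoot_f Vesicle-phase frequency minimum (Hz).
#' @param dt Sampling interval (minutes).
#' @param t_slb,t_protein,t_equil,t_rinse,t_end Event times (minutes).
#' @return A [qcmd_trace()].
#' @export
simulate_qcmd <- function(slb_final_f = -25, protein_df = -25.1, protein_dd = 2.0,
                          adsorption_tau = 2, desorption_rate = 0.05,
                          noise_sigma = 0.3, seed = NULL,
                          overtones = c(1, 3, 5, 7, 9, 11),
                          overshoot_f = -60, dt = 1 / 30,
                          t_slb = 10, t_protein = 20, t_equil = 45,
                          t_rinse = 50, t_end = 80) {
  if (slb_final_f >= 0) abort("slb_final_f must be < 0.", class = "interfilm_domain_error")
  ev_t <- c(2, t_slb, t_protein, t_equil, t_rinse, t_end)
  if (any(diff(ev_t) <= 0)) {
    abort("event times must be ordered: vesicle < slb < protein < equilibrium < rinse < end.",
          class = "interfilm_domain_error")
  }
  times <- seq(0, t_end, by = dt)
  f <- numeric(length(times)); d <- numeric(length(times))
  # vesicle adsorption overshoot, then rupture to the bilayer value; the
  # plateau is established 2 min before the slb_formed marker so that a
  # pre-event averaging window sees only the finished bilayer
  t_plateau <- t_slb - 2
  ves <- times >= 2 & times < t_plateau
  tmid <- 2 + 0.4 * (t_plateau - 2)
  f[ves] <- ifelse(times[ves] < tmid,
                   overshoot_f * (times[ves] - 2) / (tmid - 2),
                   overshoot_f + (slb_final_f - overshoot_f) *
                     (times[ves] - tmid) / (t_plateau - tmid))
  d[ves] <- -f[ves] / 10  # vesicles are soft: dissipation tracks the overshoot
  slb <- times >= t_plateau
  f[slb] <- slb_final_f
  d[slb] <- 0.3
  # protein adsorption: saturating exponential between injection and rinse
  ads <- times >= t_protein & times < t_rinse
  gr <- 1 - exp(-(times[ads] - t_protein) / adsorption_tau)
  f[ads] <- f[ads] + protein_df * gr
  d[ads] <- d[ads] + protein_dd * gr
  # post-rinse linear desorption
  rin <- times >= t_rinse
  g_r <- 1 - exp(-(t_rinse - t_protein) / adsorption_tau)
  f[rin] <- slb_final_f + protein_df * g_r + desorption_rate * (times[rin] - t_rinse)
  d[rin] <- 0.3 + protein_dd * g_r * pmax(1 - desorption_rate *
                                            (times[rin] - t_rinse) / abs(protein_df), 0)
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(overtones, function(n) {
    fn <- f; dn <- d
    if (noise_sigma > 0) {
      fn <- fn + stats::rnorm(length(f), 0, noise_sigma)
      dn <- dn + stats::rnorm(length(d), 0, noise_sigma / 10)
    }
    tibble(time_min = times, overtone = n, delta_f = fn, delta_d = dn)
  }) |> purrr::list_rbind()
  qcmd_trace(out, tibble(
    time_min = ev_t,
    label = c("vesicle_injection", "slb_formed", "protein_injection",
              "equilibrium", "rinse", "record_end")
  ))
}

#' Detect the final bilayer frequency of an SLB-formation signature
#'
#' Locates the vesicle-adsorption frequency minimum and reads the stable
#' plateau after rupture (median over a window before `slb_formed`, or before
#' `t_after` when given).
#'
#' @param trace A [qcmd_trace()].
#' @param overtone Overtone number (default 3).
#' @param window_min Plateau read window length (minutes, default 2).
#' @return One-row tibble with `overshoot_f` and `slb_f` (Hz).
#' @export
slb_signature <- function(trace, overtone = 3, window_min = 2) {
  stopifnot(inherits(trace, "qcmd_trace"))
  t1 <- event_time(trace, "slb_formed")
  dd <- trace[trace$overtone == overtone & trace$time_min <= t1, ]
  plate <- dd$delta_f[dd$time_min > t1 - window_min]
  tibble(overshoot_f = min(dd$delta_f), slb_f = stats::median(plate))
}

#' Synthetic CD spectrum of an alpha-helical protein
#'
#' Two-Gaussian model of the 208 and 222 nm minima with adjustable depth
#' ratio, for testing [cd_ratio()].
#'
#' @param ratio_222_208 Desired theta_222/theta_208 ratio.
#' @param theta_208 Depth at 208 nm (mdeg, negative).
#' @param wavelengths Wavelength grid (nm).
#' @param noise_sigma Ellipticity noise SD (mdeg).
#' @param seed Integer seed.
#' @return Tibble with `wavelength`, `ellipticity`.
#' @export
simulate_cd <- function(ratio_222_208 = 0.9, theta_208 = -10,
                        wavelengths = seq(195, 255, by = 0.5),
                        noise_sigma = 0, seed = NULL) {
  th222 <- theta_208 * ratio_222_208
  # solve 2x2 for Gaussian amplitudes so the curve passes exactly through
  # the two target ellipticities
  g1 <- function(w) exp(-(w - 208)^2 / (2 * 6^2))
  g2 <- function(w) exp(-(w - 222)^2 / (2 * 7^2))
  A <- matrix(c(g1(208), g2(208), g1(222), g2(222)), 2, 2, byrow = TRUE)
  amp <- solve(A, c(theta_208, th222))
  ell <- amp[1] * g1(wavelengths) + amp[2] * g2(wavelengths)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    ell <- ell + stats::rnorm(length(ell), 0, noise_sigma)
  }
  tibble(wavelength = wavelengths, ellipticity = ell)
}
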