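#' Optical-constants tibbles
#'
#' A table of complex refractive index n + ik per wavenumber for a bulk
#' phase. The incident medium defaults to non-absorbing air (n = 1, k = 0).
#'
#' @param wavenumber Wavenumbers (cm^-1), strictly increasing.
#' @param n Real refractive index (> 0).
#' @param k Extinction coefficient (>= 0).
#' @return Tibble with columns `wavenumber`, `n`, `k`.
#' @export
optical_constants <- function(wavenumber, n, k) {
  if (any(diff(wavenumber) <= 0)) {
    abort("`wavenumber` must be strictly increasing.", class = "interfilm_domain_error")
  }
  assert_number(n, "n", lower = 0, closed_lower = FALSE)
  assert_number(k, "k", lower = 0)
  tibble(wavenumber = wavenumber, n = n, k = k)
}

# Lorentz-oscillator dielectric model: eps(nu) = eps_inf + sum_j S_j nu_j^2 /
# (nu_j^2 - nu^2 - i G_j nu). Parameters chosen to approximate the published
# mid-infrared dispersion of liquid H2O and D2O (O-H/O-D stretch, bend and
# association bands); they are an analytic approximation, not literature
# tables.
lorentz_nk <- function(nu, eps_inf, osc) {
  eps <- rep(complex(real = eps_inf, imaginary = 0), length(nu))
  for (o in osc) {
    eps <- eps + o$S * o$nu0^2 / (o$nu0^2 - nu^2 - 1i * o$G * nu)
  }
  m <- sqrt(eps)
  list(n = Re(m), k = Im(m))
}

subphase_params <- list(
  H2O = list(
    eps_inf = 1.70,
    osc = list(
      list(nu0 = 3400, S = 0.070, G = 280), # O-H stretch
      list(nu0 = 1643, S = 0.013, G = 85),  # H-O-H bend
      list(nu0 = 2120, S = 0.0025, G = 200),# association/combination
      list(nu0 = 600,  S = 0.400, G = 350)  # libration tail
    )
  ),
  D2O = list(
    eps_inf = 1.70,
    osc = list(
      list(nu0 = 2500, S = 0.100, G = 280), # O-D stretch
      list(nu0 = 1209, S = 0.024, G = 90),  # D-O-D bend
      list(nu0 = 1555, S = 0.0051, G = 150),# association band
      list(nu0 = 450,  S = 0.400, G = 300)  # libration tail
    )
  )
)

#' Subphase optical constants for H2O or D2O
#'
#' Returns n(nu), k(nu) for a liquid water or heavy-water subphase on the
#' requested grid (valid roughly over 1000-4000 cm^-1). Values come from a
#' Lorentz-oscillator parameterization approximating published dispersion
#' data for the two liquids; they reproduce the qualitative features that
#' matter for reflection-absorption modelling (n near 1.3-1.45, weak
#' absorption of D2O across the amide I' window, strong H2O bend absorption
#' near 1643 cm^-1).
#'
#' @param medium `"D2O"` (default; amide I' measurements use a D2O subphase)
#'   or `"H2O"`.
#' @param grid Wavenumbers (cm^-1).
#' @return An optical-constants tibble.
#' @examples
#' subphase_optical_constants("D2O", seq(1600, 1700, 10))
#' @export
subphase_optical_constants <- function(medium = c("D2O", "H2O"), grid = default_grid()) {
  medium <- match.arg(medium)
  p <- subphase_params[[medium]]
  nk <- lorentz_nk(grid, p$eps_inf, p$osc)
  optical_constants(grid, nk$n, nk$k)
}

#' Read an optical-constants table
#'
#' Three delimited columns: wavenumber (cm^-1), n, k. `#` header lines are
#' ignored.
#'
#' @param path File path.
#' @return An optical-constants tibble.
#' @export
read_optical_constants <- function(path) {
  p <- read_delimited_columns(path, 3)
  optical_constants(p$data[, 1], p$data[, 2], p$data[, 3])
}

# interpolate optical constants onto a working grid
interp_constants <- function(oc, grid) {
  if (min(grid) < min(oc$wavenumber) || max(grid) > max(oc$wavenumber)) {
    abort("working grid extends beyond the optical-constants table.",
          class = "interfilm_data_error")
  }
  tibble(
    wavenumber = grid,
    n = stats::approx(oc$wavenumber, oc$n, xout = grid)$y,
    k = stats::approx(oc$wavenumber, oc$k, xout = grid)$y
  )
}
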