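# Independent oracles used across the optics and geometry tests.

# First-order (thin-film) reflection-absorbance of a uniaxial layer on an
# absorbing half-space, incident medium n = 1. Closed form obtained by
# expanding the boundary-value solution of the three-phase system to first
# order in thickness; kept deliberately separate from the package's exact
# characteristic-matrix implementation.
ra_first_order <- function(nu, eps_x, eps_z, d_cm, eps_sub, phi_deg, pol) {
  k0 <- 2 * pi * nu
  kx2 <- sin(phi_deg * pi / 180)^2
  q1 <- sqrt(1 - kx2)
  e3 <- eps_sub
  ratio <- if (pol == "s") {
    2i * k0 * q1 * (e3 - eps_x) / (1 - e3)
  } else {
    2i * k0 * q1 * (e3^2 * eps_z - e3^2 * kx2 - e3 * eps_x * eps_z + eps_x * eps_z * kx2) /
      (eps_z * (e3 - kx2 - e3^2 + e3^2 * kx2))
  }
  -log10(1 + 2 * Re(ratio) * d_cm)
}

# Fresnel reflectance of a bare interface (complex-index capable)
fresnel_R <- function(phi_deg, pol, n2_complex) {
  th1 <- phi_deg * pi / 180
  c1 <- cos(th1)
  c2 <- sqrt(1 - (sin(th1) / n2_complex)^2)
  r <- if (pol == "s") {
    (c1 - n2_complex * c2) / (c1 + n2_complex * c2)
  } else {
    (n2_complex * c1 - c2) / (n2_complex * c1 + c2)
  }
  Mod(r)^2
}

# numerical azimuthal average of the squared z-component of a unit vector at
# fixed angle `alpha_deg` from an axis inclined `gamma_deg` from the xy plane
num_second_moment <- function(alpha_deg, gamma_deg, n_az = 20000) {
  a <- alpha_deg * pi / 180
  g <- gamma_deg * pi / 180
  axis <- c(cos(g), 0, sin(g))
  e1 <- c(-sin(g), 0, cos(g)) # perpendicular to axis, in xz plane
  e2 <- c(0, 1, 0)
  psi <- seq(0, 2 * pi, length.out = n_az + 1)[-1]
  uz <- cos(a) * axis[3] + sin(a) * (cos(psi) * e1[3] + sin(psi) * e2[3])
  mean(uz^2)
}

# flat non-absorbing reference subphase over a grid
flat_subphase <- function(grid, n = 1.33, k = 0) {
  optical_constants(grid, rep(n, length(grid)), rep(k, length(grid)))
}

# analytically constructed ideal alpha-helix C-alpha trace about the z axis
ideal_helix <- function(n_res = 30, radius = 2.3, rise = 1.5, twist_deg = 100) {
  t <- (seq_len(n_res) - 1) * twist_deg * pi / 180
  cbind(x = radius * cos(t), y = radius * sin(t), z = rise * (seq_len(n_res) - 1))
}

rot_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
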