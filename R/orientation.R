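#' Orientation fitting of multi-angle polarized IRRA spectra
#'
#' The helix inclination angle gamma is inferred by profiling: for each
#' candidate gamma, the band strengths (the only nuisance parameters; band
#' positions, widths, film thickness and refractive index stay fixed) are
#' refit by nonnegative least squares against the experimental spectra, and
#' the residual sum of squared deviations (SSD) is recorded. The gamma with
#' minimal SSD is the estimate; a profile-likelihood F-test on the SSD ratio
#' gives the 95% confidence interval.
#'
#' @name orientation_fit
NULL

# Precompute everything gamma- and strength-independent for a spectra set:
# per spectrum the window grid, experimental values, unit-strength isotropic
# lineshape matrix, subphase permittivity and bare-surface reflectance.
prepare_fit_data <- function(spectra, film, subphase, window) {
  spectra <- spectrum_ids(validate_spectra(spectra))
  groups <- spectra |>
    filter(.data$wavenumber >= window[1], .data$wavenumber <= window[2]) |>
    group_by(.data$.spectrum, .data$label, .data$angle_deg, .data$polarization) |>
    group_split()
  if (length(groups) == 0) {
    abort("no spectral points inside the fit window.", class = "interfilm_data_error")
  }
  n_angles <- length(unique(vapply(groups, function(g) g$angle_deg[1], 0)))
  if (length(groups) < 2 || n_angles < 2) {
    abort("orientation fitting needs >= 2 spectra spanning >= 2 angles of incidence.",
          class = "interfilm_domain_error")
  }
  bands <- film$bands
  # all spectra share the window grid after simulation/resampling; the
  # forward model is then vectorized grid x spectra per polarization batch
  grids <- lapply(groups, function(g) g$wavenumber)
  if (!all(vapply(grids, identical, TRUE, grids[[1]]))) {
    abort("spectra must share a common grid inside the fit window; use resample_spectra().",
          class = "interfilm_data_error")
  }
  grid <- grids[[1]]
  sub <- interp_constants(subphase, grid)
  Kiso <- vapply(seq_len(nrow(bands)), function(j) {
    band_kiso(bands$position[j], bands$fwhm[j], 1, bands$shape[j], grid)
  }, numeric(length(grid)))
  eps_sub <- (sub$n + 1i * sub$k)^2
  batches <- lapply(c("s", "p"), function(pol) {
    gs <- groups[vapply(groups, function(g) g$polarization[1] == pol, TRUE)]
    if (length(gs) == 0) return(NULL)
    phis <- vapply(gs, function(g) g$angle_deg[1], 0)
    n <- length(grid); S <- length(phis)
    KX2 <- matrix(sin(deg2rad(phis))^2, n, S, byrow = TRUE)
    ES <- matrix(eps_sub, n, S)
    list(
      pol = pol, phis = phis, KX2 = KX2,
      q1 = sqrt(1 - KX2),
      q3 = if (pol == "s") sqrt(ES - KX2) else sqrt(ES - KX2) / ES,
      y = vapply(gs, function(g) g$ra, numeric(length(grid))),
      r_bare = vapply(phis, function(phi) {
        two_phase_reflectance(phi, pol, sub, grid)$reflectance
      }, numeric(length(grid)))
    )
  })
  batches <- batches[!vapply(batches, is.null, TRUE)]
  list(batches = batches, film = film, bands = bands, grid = grid,
       Kiso = matrix(Kiso, nrow = length(grid)),
       eps_sub = (sub$n + 1i * sub$k)^2,
       y = unlist(lapply(batches, function(b) as.vector(b$y)), use.names = FALSE),
       n_points = length(grid) * sum(vapply(batches, function(b) length(b$phis), 0L)))
}

# batched exact reflectance for one polarization batch with cached
# strength-independent pieces (q1, q3, KX2): grid x spectra matrix
uniaxial_r_cached <- function(k0, eps_x, eps_z, d_cm, batch) {
  n <- length(k0); S <- length(batch$phis)
  EX <- matrix(eps_x, n, S)
  if (batch$pol == "s") {
    kzf <- sqrt(EX - batch$KX2)
    qf <- kzf
  } else {
    kzf <- sqrt(EX * (1 - batch$KX2 / matrix(eps_z, n, S)))
    qf <- kzf / EX
  }
  beta <- (k0 * d_cm) * kzf
  cb <- cos(beta); sb <- sin(beta)
  B <- cb + 1i * sb * batch$q3 / qf
  C <- 1i * qf * sb + batch$q3 * cb
  r <- (batch$q1 * B - C) / (batch$q1 * B + C)
  Mod(r)^2
}

# forward-simulate the window RA of every prepared spectrum at given
# strengths and gamma, returning one concatenated vector (same order as
# prep$y)
forward_ra <- function(prep, strengths, gamma) {
  bands <- prep$bands
  film <- prep$film
  g <- deg2rad(gamma); a <- deg2rad(bands$dipole_angle)
  M <- cos(a)^2 * sin(g)^2 + 0.5 * sin(a)^2 * cos(g)^2
  cx <- ifelse(bands$isotropic, 1, 1.5 * (1 - M))
  cz <- ifelse(bands$isotropic, 1, 3 * M)
  k_x <- as.vector(prep$Kiso %*% (cx * strengths))
  k_z <- as.vector(prep$Kiso %*% (cz * strengths))
  eps_x <- (film$n_inf + 1i * k_x)^2
  eps_z <- (film$n_inf + 1i * k_z)^2
  k0 <- 2 * pi * prep$grid
  d_cm <- film$thickness_nm * 1e-7
  unlist(lapply(prep$batches, function(b) {
    R <- uniaxial_r_cached(k0, eps_x, eps_z, d_cm, b)
    as.vector(-log10(R / b$r_bare))
  }), use.names = FALSE)
}

# nonnegative least squares on the exact forward model: NNLS on the
# linearized design as initialization, then damped Gauss-Newton steps with
# the nonnegativity handled by re-solving the linearized subproblem under
# s >= 0 (the model is almost linear in the strengths, so this converges in
# a handful of iterations even to zero-residual solutions)
fit_strengths_prepared <- function(prep, gamma, max_iter = 30) {
  nb <- nrow(prep$bands)
  y <- prep$y
  jac <- function(s) {
    f0 <- forward_ra(prep, s, gamma)
    h <- pmax(abs(s), 1) * 1e-6
    A <- vapply(seq_len(nb), function(j) {
      sj <- s; sj[j] <- sj[j] + h[j]
      (forward_ra(prep, sj, gamma) - f0) / h[j]
    }, numeric(length(y)))
    list(f0 = f0, A = matrix(A, nrow = length(y)))
  }
  base <- jac(rep(0, nb))
  sv <- svd(base$A, nu = 0, nv = 0)$d
  if (sv[1] / max(sv[length(sv)], .Machine$double.eps) > 1e10) {
    warn("band design is ill-conditioned (near-identical bands); strengths are a pseudo-solution.")
  }
  s <- tryCatch(pracma::lsqnonneg(base$A, y - base$f0)$x, error = function(e) rep(0, nb))
  ssd <- sum((y - forward_ra(prep, s, gamma))^2)
  for (it in seq_len(max_iter)) {
    J <- jac(s)
    r <- y - J$f0
    s_new <- tryCatch(pracma::lsqnonneg(J$A, r + as.vector(J$A %*% s))$x,
                      error = function(e) s)
    step <- s_new - s
    ssd_new <- sum((y - forward_ra(prep, s_new, gamma))^2)
    damp <- 1
    while (ssd_new > ssd && damp > 1e-4) {   # halve the step if it overshoots
      damp <- damp / 2
      s_new <- pmax(s + damp * step, 0)
      ssd_new <- sum((y - forward_ra(prep, s_new, gamma))^2)
    }
    done <- ssd - ssd_new <= 1e-14 * (1 + ssd)
    if (ssd_new <= ssd) {
      s <- s_new
      ssd <- ssd_new
    }
    if (done) break
  }
  list(strengths = stats::setNames(s, prep$bands$assignment),
       ssd = ssd, n_points = length(y))
}

#' Fit band strengths at a fixed helix inclination
#'
#' Nonnegative least-squares fit of the band strengths of `film_template` to
#' a set of experimental spectra, with band positions, widths, film thickness
#' and refractive index held fixed, at the given inclination `gamma`.
#' Initialized by a linearized nonnegative solve and polished by
#' Levenberg-Marquardt on the exact forward model.
#'
#' @param spectra A spectra tibble with at least two spectra spanning at
#'   least two angles of incidence.
#' @param film_template A [film_model()]; its strengths are ignored.
#' @param gamma Helix inclination (degrees).
#' @param window Fit window in cm^-1 (default the amide I' region
#'   1600-1700, avoiding the lipid carbonyl).
#' @param subphase Subphase optical constants.
#' @return List with `strengths` (named, >= 0), `ssd` and `n_points`.
#' @export
fit_band_strengths <- function(spectra, film_template, gamma,
                               window = c(1600, 1700),
                               subphase = subphase_optical_constants("D2O", default_grid())) {
  assert_number(gamma, "gamma", 0, 90)
  prep <- prepare_fit_data(spectra, film_template, subphase, window)
  fit_strengths_prepared(prep, gamma)
}

#' Sum-square-deviation profile over candidate inclinations
#'
#' Calls [fit_band_strengths()] at every gamma in `gamma_grid` and records
#' the residual SSD. Ties in the minimum break toward the smaller gamma.
#'
#' @inheritParams fit_band_strengths
#' @param gamma_grid Candidate inclinations (degrees), e.g. `seq(0, 90, 2.5)`.
#' @return An `orientation_fit` object (without a confidence interval yet):
#'   list with `profile` (tibble gamma, ssd, strengths), `gamma_best`,
#'   `ssd_min`, `n_points`, `n_params`.
#' @export
ssd_profile <- function(spectra, film_template, gamma_grid = seq(0, 90, by = 2.5),
                        window = c(1600, 1700),
                        subphase = subphase_optical_constants("D2O", default_grid())) {
  if (length(gamma_grid) == 0) {
    abort("`gamma_grid` is empty.", class = "interfilm_domain_error")
  }
  assert_number(gamma_grid, "gamma_grid", 0, 90)
  gamma_grid <- sort(gamma_grid)
  prep <- prepare_fit_data(spectra, film_template, subphase, window)
  fits <- purrr::map(gamma_grid, function(g) fit_strengths_prepared(prep, g))
  profile <- tibble(
    gamma = gamma_grid,
    ssd = vapply(fits, function(f) f$ssd, 0),
    strengths = purrr::map(fits, "strengths")
  )
  i_best <- which(profile$ssd == min(profile$ssd))[1]  # ties -> smaller gamma
  structure(list(
    profile = profile,
    gamma_best = profile$gamma[i_best],
    ssd_min = profile$ssd[i_best],
    strengths_best = profile$strengths[[i_best]],
    n_points = fits[[1]]$n_points,
    n_params = nrow(film_template$bands) + 1L,
    boundary = i_best %in% c(1L, nrow(profile)),
    ci_95 = NULL, unconstrained = NA
  ), class = "orientation_fit")
}

#' Profile-likelihood confidence interval for the inclination
#'
#' The 95% CI is the set of gamma whose profile SSD satisfies
#' `SSD(gamma) <= SSD_min * (1 + F(1, n - p; 0.95) / (n - p))`
#' (F-test on the SSD ratio), with boundary crossings located by linear
#' interpolation between grid points. A flat profile (information-free data)
#' yields the full grid range, flagged `unconstrained`.
#'
#' @param result An `orientation_fit` from [ssd_profile()].
#' @param n_points Number of fitted residuals (defaults to the value stored
#'   in `result`).
#' @param n_params Number of fitted parameters (strengths + gamma).
#' @param level Confidence level (default 0.95).
#' @return `result` with `ci_95` (length-2 numeric) and `unconstrained` set.
#' @export
confidence_interval <- function(result, n_points = result$n_points,
                                n_params = result$n_params, level = 0.95) {
  stopifnot(inherits(result, "orientation_fit"))
  if (n_points <= n_params) {
    abort("need more residuals than parameters for a CI.",
          class = "interfilm_domain_error")
  }
  prof <- result$profile
  ssd_min <- result$ssd_min
  if (!is.finite(ssd_min)) abort("SSD profile has no finite minimum.",
                                 class = "interfilm_domain_error")
  dfree <- n_points - n_params
  fcrit <- stats::qf(level, 1, dfree)
  thr <- ssd_min * (1 + fcrit / dfree)
  if (max(prof$ssd) <= thr) {
    result$ci_95 <- range(prof$gamma)
    result$unconstrained <- TRUE
    return(result)
  }
  inside <- prof$ssd <= thr
  i_best <- which(prof$gamma == result$gamma_best)
  cross <- function(i0, i1) {
    # linear interpolation of the threshold crossing between grid points
    g0 <- prof$gamma[i0]; g1 <- prof$gamma[i1]
    s0 <- prof$ssd[i0]; s1 <- prof$ssd[i1]
    g0 + (thr - s0) / (s1 - s0) * (g1 - g0)
  }
  lo <- prof$gamma[1]
  i <- i_best
  while (i > 1 && inside[i - 1]) i <- i - 1
  if (i > 1) lo <- cross(i, i - 1)
  hi <- prof$gamma[nrow(prof)]
  i <- i_best
  while (i < nrow(prof) && inside[i + 1]) i <- i + 1
  if (i < nrow(prof)) hi <- cross(i, i + 1)
  result$ci_95 <- c(lo, hi)
  result$unconstrained <- FALSE
  result
}

#' Fit the helix inclination angle to polarized IRRA spectra
#'
#' Full pipeline: SSD profile over `gamma_grid` ([ssd_profile()]) followed by
#' the profile-likelihood confidence interval ([confidence_interval()]).
#' If a helix-to-bundle angle `delta` (degrees) or a [bundle_angles()] result
#' is supplied, the fitted helix inclination and its CI are also mapped to
#' the corresponding bundle (trimer) inclination via [trimer_inclination()];
#' helix inclinations below the geometric minimum for an intact bundle map
#' to a bundle inclination of 0.
#'
#' @inheritParams ssd_profile
#' @param structure Optional: a `bundle_geometry` object or a numeric
#'   helix-to-bundle angle delta (degrees) used to map helix inclination to
#'   bundle inclination.
#' @return An `orientation_fit` object: list with elements `profile`
#'   (tibble of gamma, ssd, strengths), `gamma_best`, `ci_95`, `ssd_min`,
#'   `strengths_best`, `boundary`, `unconstrained`, and (when `structure` is
#'   given) `trimer` (list with `delta`, `beta_best`, `ci_95`).
#' @examples
#' \donttest{
#' sp <- simulate_irras_set(gamma_true = 22.5, angles = c(30, 50, 70),
#'                          noise_sigma = 0, seed = 1)
#' fit <- fit_orientation(sp, default_film(), gamma_grid = seq(0, 90, 10))
#' fit$gamma_best
#' }
#' @export
fit_orientation <- function(spectra, film_template,
                            gamma_grid = seq(0, 90, by = 2.5),
                            window = c(1600, 1700),
                            subphase = subphase_optical_constants("D2O", default_grid()),
                            structure = NULL) {
  res <- ssd_profile(spectra, film_template, gamma_grid, window, subphase)
  res <- confidence_interval(res)
  if (res$boundary) {
    warn(sprintf("best-fit gamma = %g deg lies on the grid boundary; the estimate is censored.",
                 res$gamma_best))
  }
  if (!is.null(structure)) {
    delta <- if (inherits(structure, "bundle_geometry")) structure$delta_mean else structure
    map_beta <- function(g) {
      gmin <- min_effective_inclination(delta)
      if (g < gmin) 0 else trimer_inclination(g, delta)
    }
    res$trimer <- list(
      delta = delta,
      beta_best = map_beta(res$gamma_best),
      ci_95 = vapply(res$ci_95, map_beta, 0)
    )
  }
  res
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("<orientation_fit> gamma = %.2f deg", x$gamma_best))
  if (!is.null(x$ci_95)) cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_95[1], x$ci_95[2]))
  cat(sprintf(", SSD_min = %.3g, %d residuals\n", x$ssd_min, x$n_points))
  if (isTRUE(x$unconstrained)) cat("  profile is flat: inclination unconstrained\n")
  if (isTRUE(x$boundary)) cat("  minimum on grid boundary\n")
  if (!is.null(x$trimer)) {
    cat(sprintf("  bundle inclination beta = %.2f deg (delta = %.2f deg, CI %.2f-%.2f)\n",
                x$trimer$beta_best, x$trimer$delta,
                x$trimer$ci_95[1], x$trimer$ci_95[2]))
  }
  invisible(x)
}

#' @export
tidy.orientation_fit <- function(x, ...) {
  x$profile |> select("gamma", "ssd")
}

#' @export
glance.orientation_fit <- function(x, ...) {
  tibble(
    gamma_best = x$gamma_best,
    ci_low = x$ci_95[1] %||% NA_real_,
    ci_high = x$ci_95[2] %||% NA_real_,
    ssd_min = x$ssd_min,
    n_points = x$n_points,
    n_params = x$n_params,
    boundary = x$boundary,
    unconstrained = x$unconstrained,
    beta_trimer = if (!is.null(x$trimer)) x$trimer$beta_best else NA_real_
  )
}

#' Serialize an orientation fit to JSON
#'
#' Writes the full SSD profile, the estimate, CI and any mapped bundle
#' inclination as structured JSON for re-plotting or downstream use.
#'
#' @param x An `orientation_fit`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_orientation_fit <- function(x, path) {
  out <- list(
    gamma_best = x$gamma_best, ci_95 = x$ci_95, ssd_min = x$ssd_min,
    n_points = x$n_points, n_params = x$n_params,
    boundary = x$boundary, unconstrained = x$unconstrained,
    strengths_best = as.list(x$strengths_best),
    profile = list(gamma = x$profile$gamma, ssd = x$profile$ssd),
    trimer = x$trimer
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
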