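make_set <- function(gamma, angles = seq(25, 70, by = 9), sigma = 0, seed = NULL,
                     strengths = c(12, 5, 8)) {
  simulate_irras_set(gamma, angles = angles, film = default_film(strengths = strengths),
                     noise_sigma = sigma, seed = seed)
}

test_that("noiseless self-fit recovers the generating strengths exactly", {
  sp <- make_set(30, strengths = c(12, 5, 8))
  fit <- fit_band_strengths(sp, default_film(), gamma = 30)
  expect_equal(unname(fit$strengths), c(12, 5, 8), tolerance = 1e-8)
  expect_lt(fit$ssd, 1e-18)
})

test_that("a zero-strength band stays on the nonnegativity boundary", {
  sp <- make_set(25, strengths = c(12, 0, 8))
  fit <- fit_band_strengths(sp, default_film(), gamma = 25)
  expect_equal(unname(fit$strengths[2]), 0)
  expect_equal(unname(fit$strengths[c(1, 3)]), c(12, 8), tolerance = 1e-8)
})

test_that("noisy strength estimates are unbiased within Monte-Carlo error", {
  est <- t(vapply(1:60, function(s) {
    sp <- make_set(20, angles = c(30, 50, 70), sigma = 1e-4, seed = s,
                   strengths = c(10, 5, 8))
    unname(fit_band_strengths(sp, default_film(), gamma = 20)$strengths[1:2])
  }, numeric(2)))
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 10), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 5), 3 * se[2])
})

test_that("SSD profile recovers the generating inclination on the grid", {
  sp <- make_set(30)
  prof <- ssd_profile(sp, default_film(), gamma_grid = seq(0, 90, by = 2.5))
  expect_equal(prof$gamma_best, 30)
  expect_lt(prof$ssd_min, 1e-18)
  expect_true(all(is.finite(prof$profile$ssd)))
  expect_true(all(prof$profile$ssd >= 0))
  expect_error(ssd_profile(sp, default_film(), gamma_grid = numeric(0)),
               class = "interfilm_domain_error")
})

test_that("profile is invariant under re-ordering of the input rows", {
  sp <- make_set(40, angles = c(30, 50, 70))
  # permute the order of whole spectra within the set
  sp_shuffled <- sp |>
    dplyr::arrange(dplyr::desc(.data$angle_deg), .data$polarization, .data$wavenumber)
  g <- seq(20, 60, by = 10)
  p1 <- ssd_profile(sp, default_film(), g)
  p2 <- ssd_profile(sp_shuffled, default_film(), g)
  expect_equal(p1$profile$ssd, p2$profile$ssd, tolerance = 1e-10)
})

test_that("noiseless recovery is exact across the inclination range", {
  for (g_true in c(0, 10, 22.5, 45, 80)) {
    sp <- make_set(g_true, angles = c(25, 40, 55, 70))
    prof <- ssd_profile(sp, default_film(), gamma_grid = seq(0, 90, by = 2.5))
    expect_equal(prof$gamma_best, g_true)
  }
})

test_that("an exactly-fitting extra spectrum does not raise the minimum SSD", {
  sp <- make_set(22.5, angles = c(30, 50))
  extra <- make_set(22.5, angles = 65)
  g <- seq(15, 30, by = 2.5)
  p1 <- ssd_profile(sp, default_film(), g)
  p2 <- ssd_profile(dplyr::bind_rows(sp, extra), default_film(), g)
  expect_lte(p2$ssd_min, p1$ssd_min + 1e-18)
})

test_that("confidence interval matches the analytic parabola oracle", {
  gamma <- seq(0, 40, by = 0.01)
  fake <- structure(list(
    profile = tibble::tibble(gamma = gamma, ssd = 1 + (gamma - 20)^2,
                             strengths = vector("list", length(gamma))),
    gamma_best = 20, ssd_min = 1, n_points = 1000, n_params = 3,
    boundary = FALSE, ci_95 = NULL, unconstrained = NA
  ), class = "orientation_fit")
  res <- confidence_interval(fake)
  half <- sqrt(stats::qf(0.95, 1, 997) * 1 / 997) # SSD = 1 + (g-20)^2 crosses
  expect_equal(res$ci_95[1], 20 - half, tolerance = 1e-3)
  expect_equal(res$ci_95[2], 20 + half, tolerance = 1e-3)
  expect_false(res$unconstrained)
})

test_that("noiseless CI collapses onto the best grid cell; flat profiles are flagged", {
  sp <- make_set(22.5, angles = c(25, 40, 55, 70))
  fit <- fit_orientation(sp, default_film(), gamma_grid = seq(10, 35, by = 2.5))
  expect_equal(fit$gamma_best, 22.5)
  expect_lte(fit$ci_95[2] - fit$ci_95[1], 5)
  expect_true(fit$ci_95[1] <= fit$gamma_best && fit$gamma_best <= fit$ci_95[2])
  flat <- structure(list(
    profile = tibble::tibble(gamma = seq(0, 90, 10), ssd = rep(1, 10),
                             strengths = vector("list", 10)),
    gamma_best = 0, ssd_min = 1, n_points = 500, n_params = 4,
    boundary = TRUE, ci_95 = NULL, unconstrained = NA
  ), class = "orientation_fit")
  res <- confidence_interval(flat)
  expect_true(res$unconstrained)
  expect_equal(res$ci_95, c(0, 90))
})

test_that("a grid that excludes the truth censors the estimate at the boundary", {
  sp <- make_set(20, angles = c(30, 50, 70))
  expect_warning(
    fit <- fit_orientation(sp, default_film(), gamma_grid = seq(40, 90, by = 5)),
    "boundary"
  )
  expect_equal(fit$gamma_best, 40)
  expect_true(fit$boundary)
})

test_that("CI width grows with noise and shrinks with more spectra", {
  width <- function(n_angles, sigma_scale, seed) {
    angles <- seq(25, 70, length.out = n_angles)
    sp0 <- make_set(22.5, angles = angles)
    sigma <- max(abs(sp0$ra)) / 50 * sigma_scale
    sp <- make_set(22.5, angles = angles, sigma = sigma, seed = seed)
    fit <- fit_orientation(sp, default_film(), gamma_grid = seq(5, 40, by = 2.5))
    diff(fit$ci_95)
  }
  seeds <- 1:15
  w_lo <- vapply(seeds, function(s) width(4, 1, s), 0)
  w_hi <- vapply(seeds, function(s) width(4, 2, s), 0)
  expect_gte(stats::median(w_hi), stats::median(w_lo))
  # 2 angles x 2 polarizations versus 10 x 2: less information, wider CI
  w_few <- vapply(seeds, function(s) width(2, 1, s), 0)
  w_many <- vapply(seeds, function(s) width(10, 1, s), 0)
  expect_gte(stats::median(w_few - w_many), 0)
})

test_that("the fitted inclination maps onto the bundle inclination when a structure is given", {
  sp <- make_set(22.5, angles = c(25, 40, 55, 70))
  geom <- bundle_angles(simulate_coiled_coil(delta = 17, n_res = 60))
  fit <- fit_orientation(sp, default_film(), gamma_grid = seq(0, 90, by = 2.5),
                         structure = geom)
  expect_equal(round(fit$trimer$beta_best), 20)
  expect_equal(fit$trimer$delta, geom$delta_mean)
  # numeric delta works the same way
  fit2 <- fit_orientation(sp, default_film(), gamma_grid = seq(20, 25, by = 2.5),
                          structure = 17)
  expect_equal(round(fit2$trimer$beta_best), 20)
})

test_that("tidy, glance and JSON serialization expose the profile", {
  sp <- make_set(30, angles = c(30, 60))
  fit <- fit_orientation(sp, default_film(), gamma_grid = seq(20, 40, by = 5))
  td <- tidy(fit)
  expect_named(td, c("gamma", "ssd"))
  gl <- glance(fit)
  expect_equal(gl$gamma_best, 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_orientation_fit(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$gamma_best, 30)
  expect_length(parsed$profile$gamma, 5)
})
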