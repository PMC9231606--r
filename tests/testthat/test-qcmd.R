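step_trace <- function(step_f = -25.1, step_d = 2.0, t_step = 10, t_end = 30,
                       sigma = 0, seed = NULL, dt = 1 / 60) {
  t <- seq(0, t_end, by = dt)
  f <- ifelse(t < t_step, 0, step_f)
  d <- ifelse(t < t_step, 0, step_d)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(t), 0, sigma)
  }
  qcmd_trace(tibble::tibble(time_min = t, overtone = 3, delta_f = f, delta_d = d),
             tibble::tibble(time_min = c(t_step, t_end - 1),
                            label = c("injection", "rinse")))
}

test_that("event-referenced shifts read constructed steps", {
  tr <- step_trace()
  s <- shift_at_event(tr, "rinse")
  expect_equal(s$delta_f, -25.1, tolerance = 1e-12)
  expect_equal(s$delta_d, 2.0, tolerance = 1e-12)
  # identical event and baseline: zero by construction
  s0 <- shift_at_event(tr, "rinse", baseline_event = "rinse")
  expect_equal(c(s0$delta_f, s0$delta_d), c(0, 0))
  expect_error(shift_at_event(tr, "no-such-event"), "available",
               class = "interfilm_data_error")
  expect_error(shift_at_event(tr, "rinse", overtone = 5),
               class = "interfilm_data_error")
})

test_that("shifts are additive across consecutive events on clean traces", {
  tr <- simulate_qcmd(noise_sigma = 0)
  ab <- shift_at_event(tr, "slb_formed")
  bc <- shift_at_event(tr, "equilibrium", baseline_event = "slb_formed")
  ac <- shift_at_event(tr, "equilibrium")
  expect_equal(ab$delta_f + bc$delta_f, ac$delta_f, tolerance = 1e-10)
  expect_equal(ab$delta_d + bc$delta_d, ac$delta_d, tolerance = 1e-10)
})

test_that("window averaging suppresses white noise", {
  sigma <- 0.5
  est <- vapply(1:100, function(s) {
    shift_at_event(step_trace(sigma = sigma, seed = s), "rinse")$delta_f
  }, 0)
  n_window <- 30 # 30 s window at 1 s sampling
  expect_lt(stats::sd(est), 2 * sigma * sqrt(2) / sqrt(n_window))
  expect_lt(stats::sd(est), sigma)
})

test_that("softness is the dissipation-to-frequency ratio with scale invariance", {
  expect_equal(softness(-25, 2.0), 0.08)
  expect_equal(softness(-50, 4.0), 0.08)
  expect_error(softness(0, 1), class = "interfilm_domain_error")
  expect_error(softness(5, 1), class = "interfilm_domain_error")
  tr <- simulate_qcmd(noise_sigma = 0)
  ls <- layer_softness(tr, "equilibrium", baseline_event = "slb_formed",
                       context = "at_equilibrium")
  expect_equal(ls$softness, 2.0 / 25.1, tolerance = 0.01)
})

test_that("desorption extrapolation recovers linear trends and flags deviations", {
  t <- seq(0, 40, by = 0.05)
  f <- -30 + 0.1 * t
  tr <- qcmd_trace(tibble::tibble(time_min = t, overtone = 3, delta_f = f,
                                  delta_d = 1),
                   tibble::tibble(time_min = 10, label = "rinse"))
  fit <- desorption_extrapolation(tr, c(5, 15))
  expect_equal(fit$rate, 0.1, tolerance = 1e-9)

  # a later segment on the same line (with noise) stays within 2 residual SD
  set.seed(9)
  f_noisy <- f + rnorm(length(t), 0, 0.1)
  tr_same <- qcmd_trace(tibble::tibble(time_min = t, overtone = 3,
                                       delta_f = f_noisy, delta_d = 1),
                        tibble::tibble(time_min = 20, label = "salt"))
  fit_n <- desorption_extrapolation(tr_same, c(5, 18))
  dev_same <- desorption_deviation(fit_n, tr_same, c(20, 30))
  expect_lt(abs(dev_same$n_sd), 2)

  # desorption accelerating threefold after the event deviates strongly
  f_acc <- ifelse(t < 20, f_noisy, f_noisy + 0.2 * (t - 20))
  tr_acc <- qcmd_trace(tibble::tibble(time_min = t, overtone = 3,
                                      delta_f = f_acc, delta_d = 1),
                       tibble::tibble(time_min = 20, label = "salt"))
  dev_acc <- desorption_deviation(fit_n, tr_acc, c(25, 35))
  expect_gt(dev_acc$n_sd, 5)

  expect_error(desorption_extrapolation(tr, c(100, 110)),
               class = "interfilm_data_error")
})

test_that("trace validation rejects malformed input", {
  good <- tibble::tibble(time_min = 1:20, overtone = 3, delta_f = 0, delta_d = 0)
  expect_error(qcmd_trace(good[, -1], tibble::tibble(time_min = 5, label = "x")),
               class = "interfilm_data_error")
  expect_error(qcmd_trace(good, tibble::tibble(time_min = 50, label = "x")),
               class = "interfilm_data_error")
  bad_t <- good
  bad_t$time_min[2] <- 1
  expect_error(qcmd_trace(bad_t, tibble::tibble(time_min = 5, label = "x")),
               class = "interfilm_data_error")
})

test_that("qcmd file dialect round-trips through write and read", {
  tr <- simulate_qcmd(noise_sigma = 0.1, seed = 4, overtones = c(3, 5), dt = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qcmd(tr, path)
  tr2 <- read_qcmd(path, paste0(sub("\\.csv$", "", path), "_events.csv"))
  expect_equal(sort(unique(tr2$overtone)), c(3, 5))
  expect_equal(tr2$delta_f, tr$delta_f, tolerance = 1e-9)
  expect_equal(qcmd_events(tr2)$label, qcmd_events(tr)$label)
  s1 <- shift_at_event(tr, "equilibrium", baseline_event = "slb_formed")
  s2 <- shift_at_event(tr2, "equilibrium", baseline_event = "slb_formed")
  expect_equal(s2$delta_f, s1$delta_f, tolerance = 1e-6)
})

test_that("sauerbrey helper converts rigid-film shifts", {
  expect_equal(sauerbrey_mass(-10), 177)
})
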