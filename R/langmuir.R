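#' Langmuir monolayer adsorption analysis
#'
#' A protein injected underneath a lipid monolayer held at initial surface
#' pressure pi0 raises the pressure by delta_pi as it inserts. Repeating the
#' experiment at several pi0 and regressing delta_pi on pi0 yields the
#' maximum insertion pressure (MIP, the x-intercept: the lateral pressure
#' beyond which the protein can no longer insert) and the synergy factor
#' a = slope + 1 (a > 0 indicates attractive protein-lipid interactions).
#'
#' @name langmuir
NULL

#' Equilibrium surface-pressure change of an adsorption curve
#'
#' Reads the surface pressure at `readout_time` minutes after injection
#' (mean over a +-`window` minute interval) and subtracts the initial
#' pressure pi0.
#'
#' @param curve Data frame with columns `time_min` and `pressure`
#'   (surface pressure, mN/m).
#' @param pi0 Initial surface pressure before injection (mN/m). Defaults to
#'   the mean pressure recorded at or before `injection_time`, or the first
#'   sample if nothing precedes the injection.
#' @param injection_time Injection time (minutes into the record).
#' @param readout_time Readout time in minutes *after* injection
#'   (default 20).
#' @param window Half-width of the averaging window (minutes, default 0.5).
#' @return Delta-pi in mN/m (scalar).
#' @export
equilibrium_delta_pi <- function(curve, pi0 = NULL, injection_time = 0,
                                 readout_time = 20, window = 0.5) {
  if (!all(c("time_min", "pressure") %in% names(curve))) {
    abort("curve needs columns time_min, pressure.", class = "interfilm_data_error")
  }
  if (any(diff(curve$time_min) <= 0)) {
    abort("time must be strictly increasing.", class = "interfilm_data_error")
  }
  t_read <- injection_time + readout_time
  if (t_read > max(curve$time_min)) {
    abort(sprintf("readout at t = %g min is beyond the record (last sample %g min).",
                  t_read, max(curve$time_min)), class = "interfilm_data_error")
  }
  if (is.null(pi0)) {
    pre <- curve$pressure[curve$time_min <= injection_time]
    pi0 <- if (length(pre) > 0) mean(pre) else curve$pressure[1]
  }
  sel <- abs(curve$time_min - t_read) <= window
  mean(curve$pressure[sel]) - pi0
}

#' Maximum insertion pressure and synergy factor
#'
#' Ordinary least-squares regression delta_pi = slope * pi0 + intercept over
#' at least three distinct initial pressures. The synergy factor is
#' a = slope + 1; the MIP is the x-intercept -intercept/slope (defined for
#' negative slope), with its SD propagated from the OLS covariance of
#' (intercept, slope) by the delta method.
#'
#' @param data Data frame with the regression variables (default column
#'   names `pi0` and `delta_pi`).
#' @param pi0,delta_pi Column names (tidy-eval) of the initial pressure and
#'   pressure change.
#' @return List of class `insertion_analysis` with `slope`, `intercept`,
#'   `synergy_a`, `mip`, `mip_sd`, `r_squared`, `n`, `mip_defined` and the
#'   fitted `lm` object.
#' @examples
#' mip_synergy(tibble::tibble(pi0 = c(20, 25, 30), delta_pi = c(9.5, 6.55, 3.6)))
#' @export
mip_synergy <- function(data, pi0 = pi0, delta_pi = delta_pi) {
  d <- tibble(
    pi0 = dplyr::pull(data, {{ pi0 }}),
    delta_pi = dplyr::pull(data, {{ delta_pi }})
  )
  if (length(unique(d$pi0)) < 3) {
    abort("need at least 3 distinct pi0 values.", class = "interfilm_domain_error")
  }
  fit <- stats::lm(delta_pi ~ pi0, data = d)
  b <- stats::coef(fit)
  # OLS covariance computed directly (summary.lm warns on exact lines)
  X <- stats::model.matrix(fit)
  sigma2 <- sum(stats::resid(fit)^2) / (nrow(d) - 2)
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  slope <- unname(b[2]); intercept <- unname(b[1])
  # a slope indistinguishable from zero has no physical x-intercept either
  mip_defined <- is.finite(slope) && slope < -1e-10
  if (mip_defined) {
    mip <- -intercept / slope
    # delta method on f(b0, b1) = -b0/b1
    grad <- c(-1 / slope, intercept / slope^2)
    mip_sd <- sqrt(drop(t(grad) %*% V %*% grad))
  } else {
    mip <- NA_real_
    mip_sd <- NA_real_
    warn("slope >= 0: MIP undefined (no x-intercept in the physical range).")
  }
  ss_tot <- sum((d$delta_pi - mean(d$delta_pi))^2)
  r_squared <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(list(
    slope = slope, intercept = intercept, synergy_a = slope + 1,
    mip = mip, mip_sd = mip_sd,
    r_squared = r_squared, n = nrow(d),
    mip_defined = mip_defined, data = d, fit = fit, vcov = V
  ), class = "insertion_analysis")
}

#' @export
print.insertion_analysis <- function(x, ...) {
  cat(sprintf("<insertion_analysis> n = %d: slope = %.4f, synergy a = %.4f\n",
              x$n, x$slope, x$synergy_a))
  if (x$mip_defined) {
    cat(sprintf("  MIP = %.2f +- %.2f mN/m (R^2 = %.4f)\n", x$mip, x$mip_sd, x$r_squared))
  } else {
    cat("  MIP undefined (non-negative slope)\n")
  }
  invisible(x)
}

#' @export
tidy.insertion_analysis <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = sqrt(diag(x$vcov)))
}

#' @export
glance.insertion_analysis <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, synergy_a = x$synergy_a,
         mip = x$mip, mip_sd = x$mip_sd, r_squared = x$r_squared,
         n = x$n, mip_defined = x$mip_defined)
}

#' Classify monolayer insertion by MIP
#'
#' A protein whose MIP exceeds the monolayer-bilayer equivalence pressure
#' (about 30 mN/m) is considered well-incorporated into bilayer membranes.
#' The comparison is strict: exactly at the equivalence pressure counts as
#' non-inserting.
#'
#' @param mip Maximum insertion pressure (mN/m).
#' @param equivalence_pressure Monolayer-bilayer equivalence pressure
#'   (mN/m, default 30).
#' @return `"inserting"` or `"non-inserting"` (vectorized).
#' @export
classify_insertion <- function(mip, equivalence_pressure = 30) {
  if (any(!is.finite(mip))) abort("mip must be finite.", class = "interfilm_domain_error")
  ifelse(mip > equivalence_pressure, "inserting", "non-inserting")
}

#' Read a monolayer adsorption time series
#'
#' Two delimited columns (time_min, pressure mN/m) with optional `# pi0=` and
#' `# injection_time=` header lines.
#'
#' @param path File path.
#' @return Tibble with columns `time_min`, `pressure` and attributes `pi0`,
#'   `injection_time` when present in the header.
#' @export
read_adsorption <- function(path) {
  p <- read_delimited_columns(path, 2)
  out <- tibble(time_min = p$data[, 1], pressure = p$data[, 2])
  if (!is.null(p$meta$pi0)) attr(out, "pi0") <- as.numeric(p$meta$pi0)
  if (!is.null(p$meta$injection_time)) {
    attr(out, "injection_time") <- as.numeric(p$meta$injection_time)
  }
  out
}
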