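#' Band windows
#'
#' A wavenumber interval used for integration or PCA. Defaults elsewhere in
#' the package: amide I' 1600-1700 cm^-1, lipid ester carbonyl
#' 1700-1760 cm^-1 (around the ~1640 and ~1730 cm^-1 band maxima).
#'
#' @param low,high Window bounds (cm^-1), `low < high`.
#' @param label Free text.
#' @return One-row tibble with `low`, `high`, `label`.
#' @export
band_window <- function(low, high, label = "") {
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    abort("band window requires low < high.", class = "interfilm_domain_error")
  }
  tibble(low = low, high = high, label = label)
}

# trapezoidal band integral with optional linear endpoint baseline
integrate_window <- function(wavenumber, values, window, baseline) {
  sel <- wavenumber >= window$low & wavenumber <= window$high
  if (sum(sel) < 2) {
    abort("band window contains fewer than 2 grid points.", class = "interfilm_data_error")
  }
  x <- wavenumber[sel]; y <- values[sel]
  if (baseline == "linear") {
    y <- y - (y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1]))
  }
  pracma::trapz(x, y)
}

#' Band-integral intensity ratio
#'
#' Trapezoidal integral of the (optionally baseline-corrected) spectrum over
#' the numerator window divided by the same over the denominator window.
#' With `baseline = "linear"` a straight line connecting the window endpoints
#' is subtracted before integration. Used e.g. as amide I' / lipid C=O, a
#' per-spectrum measure of adsorbed protein per lipid.
#'
#' @param spectrum A spectra tibble containing exactly one spectrum (or the
#'   columns `wavenumber`, `ra`).
#' @param numerator,denominator [band_window()]s, both inside the grid.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return Dimensionless ratio (scalar).
#' @export
band_integral_ratio <- function(spectrum,
                                numerator = band_window(1600, 1700, "amide I'"),
                                denominator = band_window(1700, 1760, "lipid C=O"),
                                baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  if (!all(c("wavenumber", "ra") %in% names(spectrum))) {
    abort("spectrum needs columns wavenumber, ra.", class = "interfilm_data_error")
  }
  ids <- unique(spectrum[intersect(c("label", "angle_deg", "polarization"),
                                   names(spectrum))])
  if (nrow(ids) > 1) {
    abort("band_integral_ratio expects a single spectrum; filter the set first.",
          class = "interfilm_data_error")
  }
  if (min(spectrum$wavenumber) > min(numerator$low, denominator$low) ||
      max(spectrum$wavenumber) < max(numerator$high, denominator$high)) {
    abort("band windows extend beyond the spectral grid.", class = "interfilm_data_error")
  }
  num <- integrate_window(spectrum$wavenumber, spectrum$ra, numerator, baseline)
  den <- integrate_window(spectrum$wavenumber, spectrum$ra, denominator, baseline)
  if (den <= 0) {
    abort("denominator band integral is <= 0; ratio undefined.",
          class = "interfilm_data_error")
  }
  num / den
}

#' PCA of the carbonyl spectral region
#'
#' Mean-centered principal-component analysis of a set of spectra restricted
#' to `window` (covariance PCA; the spectra share units). The first component
#' typically tracks the dominant systematic change across the set, e.g. the
#' extent of carbonyl hydration before and after protein adsorption. Each
#' loading vector is oriented so that its largest-magnitude element is
#' positive, making the output deterministic.
#'
#' @param spectra A spectra tibble with >= 3 spectra; resampled onto a common
#'   grid if needed.
#' @param window [band_window()] to analyse (default the lipid ester carbonyl
#'   region 1700-1760 cm^-1).
#' @return List of class `spectra_pca`: `components` (loadings matrix,
#'   wavenumbers x components), `explained_variance_fraction`, `scores`
#'   (tibble with spectrum metadata and per-component scores), `wavenumber`.
#' @export
pca_co_region <- function(spectra, window = band_window(1700, 1760, "lipid C=O")) {
  spectra <- spectrum_ids(validate_spectra(spectra))
  n_spec <- length(unique(spectra$.spectrum))
  if (n_spec < 3) {
    abort("PCA needs at least 3 spectra.", class = "interfilm_domain_error")
  }
  win <- spectra |> filter(.data$wavenumber >= window$low,
                           .data$wavenumber <= window$high)
  # common grid: intersection of per-spectrum grids; resample if they differ
  grids <- win |> group_by(.data$.spectrum) |> group_split()
  common <- Reduce(intersect, lapply(grids, function(g) g$wavenumber))
  if (length(common) < length(grids[[1]]$wavenumber)) {
    win <- resample_spectra(win, sort(common))
    win <- spectrum_ids(win)
  }
  wide <- win |>
    select(".spectrum", "label", "angle_deg", "polarization", "wavenumber", "ra") |>
    tidyr::pivot_wider(names_from = "wavenumber", values_from = "ra")
  meta <- wide |> select(".spectrum", "label", "angle_deg", "polarization")
  X <- as.matrix(wide[, -(1:4)])
  if (any(!is.finite(X))) abort("spectra incomplete on the common grid.",
                                class = "interfilm_data_error")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| element positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(
    components = pc$rotation,
    explained_variance_fraction = ev / sum(ev),
    scores = dplyr::bind_cols(meta, as_tibble(pc$x)),
    wavenumber = as.numeric(colnames(wide)[-(1:4)]),
    center = pc$center
  ), class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  f <- x$explained_variance_fraction
  cat(sprintf("<spectra_pca> %d spectra x %d points; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(x$wavenumber),
              100 * f[1], if (length(f) > 1) 100 * f[2] else 0))
  invisible(x)
}

#' @export
tidy.spectra_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance_fraction),
         explained_variance_fraction = x$explained_variance_fraction)
}

#' @export
glance.spectra_pca <- function(x, ...) {
  f <- x$explained_variance_fraction
  tibble(n_spectra = nrow(x$scores), n_points = length(x$wavenumber),
         pc1_fraction = f[1], pc2_fraction = if (length(f) > 1) f[2] else NA_real_)
}

#' Circular-dichroism 222/208 nm ellipticity ratio
#'
#' Reads the ellipticity at 222 nm and 208 nm (linear interpolation on the
#' wavelength grid) and returns their ratio. A ratio above 1 (the two minima
#' of an alpha-helical spectrum becoming unequal) indicates increased
#' hydrophobicity of the helix environment: interhelical packing or burial
#' at a membrane.
#'
#' @param cd Data frame with columns `wavelength` (nm) and `ellipticity`;
#'   must cover 205-225 nm.
#' @return One-row tibble with `theta_222`, `theta_208`, `ratio`.
#' @examples
#' cd <- tibble::tibble(wavelength = 195:250, ellipticity = -10)
#' cd_ratio(cd)$ratio # 1
#' @export
cd_ratio <- function(cd) {
  if (!all(c("wavelength", "ellipticity") %in% names(cd))) {
    abort("CD spectrum needs columns wavelength, ellipticity.",
          class = "interfilm_data_error")
  }
  if (min(cd$wavelength) > 205 || max(cd$wavelength) < 225) {
    abort("CD spectrum must cover 205-225 nm.", class = "interfilm_data_error")
  }
  th <- stats::approx(cd$wavelength, cd$ellipticity, xout = c(208, 222))$y
  if (th[1] == 0) {
    abort("ellipticity at 208 nm is zero; ratio undefined.",
          class = "interfilm_data_error")
  }
  tibble(theta_222 = th[2], theta_208 = th[1], ratio = th[2] / th[1])
}

#' @rdname cd_ratio
#' @param x Result of [cd_ratio()] (or a numeric ratio).
#' @return For `cd_ratio_exceeds_unity()`: logical.
#' @export
cd_ratio_exceeds_unity <- function(x) {
  r <- if (is.data.frame(x)) x$ratio else x
  r > 1
}
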