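#' Spectra tibbles
#'
#' IRRA spectra are kept in long ("tidy") form: one row per grid point, with
#' the acquisition metadata repeated along the curve. A *set* of spectra is a
#' single tibble; individual spectra are identified by the combination of
#' `label`, `angle_deg` and `polarization`.
#'
#' @param wavenumber Strictly increasing wavenumbers (cm^-1).
#' @param ra Reflection-absorbance values, RA = -log10(R/R0) (dimensionless).
#' @param angle_deg Angle of incidence in degrees from the surface normal,
#'   in (0, 90).
#' @param polarization `"p"` or `"s"`.
#' @param label Free-text sample/reference identifier.
#' @return A tibble with columns `label`, `angle_deg`, `polarization`,
#'   `wavenumber`, `ra`.
#' @examples
#' sp <- spectra_tbl(seq(1600, 1700, 10), rnorm(11, 0, 1e-4), 40, "p")
#' @export
spectra_tbl <- function(wavenumber, ra, angle_deg, polarization, label = "spectrum") {
  out <- tibble(
    label = label, angle_deg = angle_deg, polarization = polarization,
    wavenumber = wavenumber, ra = ra
  )
  validate_spectra(out)
}

#' Validate a spectra tibble
#'
#' Checks the invariants of the spectra representation: strictly increasing
#' grid within each spectrum, matching lengths, angle of incidence in
#' (0, 90) degrees and polarization in {p, s}.
#'
#' @param x A data frame with columns `label`, `angle_deg`, `polarization`,
#'   `wavenumber`, `ra`.
#' @return `x`, as a validated tibble.
#' @export
validate_spectra <- function(x) {
  need <- c("label", "angle_deg", "polarization", "wavenumber", "ra")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("spectra tibble lacks column(s): ", paste(miss, collapse = ", ")),
          class = "interfilm_data_error")
  }
  x <- as_tibble(x)
  if (!all(x$polarization %in% c("p", "s"))) {
    abort("`polarization` must be 'p' or 's'.", class = "interfilm_domain_error")
  }
  assert_number(x$angle_deg, "angle_deg", 0, 90, closed_lower = FALSE, closed_upper = FALSE)
  if (any(!is.finite(x$wavenumber)) || any(!is.finite(x$ra))) {
    abort("non-finite values in spectrum.", class = "interfilm_data_error")
  }
  ok <- x |>
    group_by(.data$label, .data$angle_deg, .data$polarization) |>
    summarise(mono = all(diff(.data$wavenumber) > 0), .groups = "drop")
  if (!all(ok$mono)) {
    abort("wavenumber grid must be strictly increasing within each spectrum.",
          class = "interfilm_data_error")
  }
  x
}

#' Identify individual spectra within a set
#'
#' @param x A spectra tibble.
#' @return `x` with an added `.spectrum` integer id column.
#' @keywords internal
spectrum_ids <- function(x) {
  x |> mutate(.spectrum = dplyr::cur_group_id(),
              .by = c("label", "angle_deg", "polarization"))
}

#' Default amide I' simulation grid
#'
#' 1590 to 1790 cm^-1 at 2 cm^-1 spacing, covering the amide I' and lipid
#' ester carbonyl bands.
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
default_grid <- function() seq(1590, 1790, by = 2)

#' Resample spectra onto a common grid
#'
#' Linear interpolation of each spectrum in the set onto `grid`. Grid points
#' outside a spectrum's support are dropped for that spectrum.
#'
#' @param x A spectra tibble.
#' @param grid Target wavenumbers (cm^-1), strictly increasing.
#' @return A spectra tibble on the new grid.
#' @export
resample_spectra <- function(x, grid = default_grid()) {
  x <- validate_spectra(x)
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.",
                                  class = "interfilm_domain_error")
  x |>
    group_by(.data$label, .data$angle_deg, .data$polarization) |>
    reframe({
      w <- .data$wavenumber
      v <- .data$ra
      g <- grid[grid >= min(w) & grid <= max(w)]
      tibble(wavenumber = g, ra = stats::approx(w, v, xout = g)$y)
    }) |>
    select("label", "angle_deg", "polarization", "wavenumber", "ra")
}

# ---- file dialect -----------------------------------------------------------

parse_header_meta <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", hdr))
  kv <- kv[lengths(kv) == 3]
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) m[2], ""))
}

read_delimited_columns <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header_meta(lines)
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # tolerate comma, tab or whitespace delimiters
  fields <- strsplit(trimws(dat), "[,\t ]+")
  bad <- lengths(fields) != n_cols
  if (any(bad)) {
    abort(sprintf("%s: expected %d columns, got %d on line(s) starting '%s'",
                  path, n_cols, lengths(fields)[bad][1], dat[bad][1]),
          class = "interfilm_data_error")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = n_cols, byrow = TRUE)
  if (any(!is.finite(m))) {
    abort(sprintf("%s: non-numeric data values.", path), class = "interfilm_data_error")
  }
  list(meta = meta, data = m)
}

#' Read an IRRA spectrum file
#'
#' Two delimited columns (wavenumber cm^-1, reflection-absorbance) with
#' `#`-prefixed `key=value` header lines carrying `angle_deg`, `polarization`
#' and `label`. Comma, tab or whitespace delimiters are accepted.
#'
#' @param path File path.
#' @return A spectra tibble (one spectrum).
#' @export
read_spectrum <- function(path) {
  p <- read_delimited_columns(path, 2)
  meta <- p$meta
  if (is.null(meta$angle_deg) || is.null(meta$polarization)) {
    abort(sprintf("%s: header must carry angle_deg and polarization.", path),
          class = "interfilm_data_error")
  }
  spectra_tbl(p$data[, 1], p$data[, 2],
              angle_deg = as.numeric(meta$angle_deg),
              polarization = meta$polarization,
              label = meta$label %||% basename(path))
}

#' Read all spectrum files in a directory
#'
#' @param dir Directory containing spectrum files.
#' @param pattern Filename regexp (default all `.csv`/`.txt`/`.dat`).
#' @return A spectra tibble combining every file.
#' @export
read_spectra_dir <- function(dir, pattern = "\\.(csv|txt|dat)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no spectrum files found in '%s'.", dir), class = "interfilm_data_error")
  }
  purrr::map(files, read_spectrum) |> purrr::list_rbind()
}

#' Write spectra to files
#'
#' One file per spectrum in the set, using the same dialect `read_spectrum()`
#' reads (comma-delimited, `#` metadata header).
#'
#' @param x A spectra tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(x, dir) {
  x <- spectrum_ids(validate_spectra(x))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- x |>
    group_by(.data$.spectrum) |>
    group_map(function(g, key) {
      path <- file.path(dir, sprintf("%s_phi%02d_%s.csv",
                                     gsub("[^A-Za-z0-9_.-]", "_", g$label[1]),
                                     round(g$angle_deg[1]), g$polarization[1]))
      hdr <- c(sprintf("# label=%s", g$label[1]),
               sprintf("# angle_deg=%s", format(g$angle_deg[1])),
               sprintf("# polarization=%s", g$polarization[1]))
      writeLines(c(hdr, sprintf("%.6f,%.10e", g$wavenumber, g$ra)), path)
      path
    }) |>
    unlist()
  invisible(paths)
}

#' Read a CD spectrum file
#'
#' Two delimited columns: wavelength (nm), ellipticity (mdeg).
#'
#' @param path File path.
#' @return Tibble with columns `wavelength`, `ellipticity`.
#' @export
read_cd <- function(path) {
  p <- read_delimited_columns(path, 2)
  tibble(wavelength = p$data[, 1], ellipticity = p$data[, 2])
}
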