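#' Helix axis from C-alpha coordinates
#'
#' Rotational-fit axis estimate: for each sliding window of four consecutive
#' C-alpha atoms, the two inner bisector lines (each perpendicular to the
#' local helix axis and pointing at it) are intersected in the
#' closest-approach sense, giving one local axis point per window. The axis
#' direction is the first principal component of these axis points, oriented
#' N to C. Perfectly collinear input returns the line direction directly.
#'
#' @param coords Ordered N-to-C C-alpha coordinates: a numeric matrix or data
#'   frame with columns x, y, z and at least 7 rows.
#' @return List of class `helix_axis` with unit `direction`, `origin`
#'   (centroid of the local axis points) and the `axis_points` matrix.
#' @export
helix_axis <- function(coords) {
  if (is.data.frame(coords)) {
    xyz <- as.matrix(coords[, c("x", "y", "z")])
  } else {
    xyz <- as.matrix(coords)
    if (!is.null(colnames(xyz)) && all(c("x", "y", "z") %in% colnames(xyz))) {
      xyz <- xyz[, c("x", "y", "z")]
    }
  }
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3) abort("coordinates must be 3-column.", class = "interfilm_data_error")
  n <- nrow(xyz)
  if (n < 7) abort("need at least 7 C-alpha positions.", class = "interfilm_domain_error")
  nc_vec <- xyz[n, ] - xyz[1, ]

  # collinearity check via singular values of the centered coordinates
  cen <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(cen, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * sv$d[1]) {
    dir <- sv$v[, 1]
    if (sum(dir * nc_vec) < 0) dir <- -dir
    return(structure(list(direction = dir / sqrt(sum(dir^2)),
                          origin = colMeans(xyz), axis_points = xyz),
                     class = "helix_axis"))
  }

  unit <- function(v) v / sqrt(sum(v^2))
  axis_points <- matrix(NA_real_, n - 3, 3)
  for (i in seq_len(n - 3)) {
    p1 <- xyz[i, ]; p2 <- xyz[i + 1, ]; p3 <- xyz[i + 2, ]; p4 <- xyz[i + 3, ]
    b2 <- unit(unit(p1 - p2) + unit(p3 - p2))  # bisector at p2, points at axis
    b3 <- unit(unit(p2 - p3) + unit(p4 - p3))
    # closest approach of lines p2 + t b2 and p3 + s b3
    w <- p2 - p3
    bb <- sum(b2 * b3)
    denom <- 1 - bb^2
    t <- (bb * sum(w * b3) - sum(w * b2)) / denom
    s <- (sum(w * b3) - bb * sum(w * b2)) / denom
    axis_points[i, ] <- ((p2 + t * b2) + (p3 + s * b3)) / 2
  }
  cen <- sweep(axis_points, 2, colMeans(axis_points))
  dir <- svd(cen, nu = 0, nv = 3)$v[, 1]
  if (sum(dir * nc_vec) < 0) dir <- -dir
  structure(list(direction = unit(dir), origin = colMeans(axis_points),
                 axis_points = axis_points),
            class = "helix_axis")
}

# ---- structures -------------------------------------------------------------

# normalize input to a CA tibble: chain, resno, x, y, z
as_ca_tbl <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- bio3d::read.pdb(x)
  }
  if (inherits(x, "pdb")) {
    ca <- x$atom[x$atom$elety == "CA", , drop = FALSE]
    return(tibble(chain = ca$chain, resno = ca$resno,
                  x = ca$x, y = ca$y, z = ca$z))
  }
  if (is.data.frame(x)) {
    need <- c("chain", "resno", "x", "y", "z")
    if (!all(need %in% names(x))) {
      abort("coordinate data frame needs columns chain, resno, x, y, z.",
            class = "interfilm_data_error")
    }
    return(as_tibble(x[, need]))
  }
  abort("unsupported structure input.", class = "interfilm_data_error")
}

# longest run of residue numbers resolved in every requested chain
common_helical_range <- function(ca, chains) {
  sets <- lapply(chains, function(ch) sort(unique(ca$resno[ca$chain == ch])))
  common <- Reduce(intersect, sets)
  if (length(common) == 0) {
    abort("chains share no resolved residues.", class = "interfilm_data_error")
  }
  common <- sort(common)
  runs <- split(common, cumsum(c(1, diff(common) != 1)))
  best <- runs[[which.max(lengths(runs))]]
  c(min(best), max(best))
}

#' Helix axes and helix-to-bundle angles of a coiled coil
#'
#' Extracts one helix axis per chain ([helix_axis()], N-to-C oriented),
#' computes the bundle axis as the principal direction of the stacked
#' (sign-aligned) helix directions, and reports the angle delta between each
#' helix and the bundle axis.
#'
#' @param x A PDB file path, a `bio3d` pdb object, or a data frame of
#'   C-alpha coordinates with columns `chain`, `resno`, `x`, `y`, `z`.
#' @param chains Chain identifiers to use (default: all chains present).
#' @param residue_range Length-2 numeric (first, last residue) or `NULL` to
#'   auto-detect the longest residue run resolved in every chain.
#' @return List of class `bundle_geometry`: `helices` (tibble with `chain`,
#'   `delta_deg` and list-columns `direction`, `origin`), `bundle_axis`
#'   (unit 3-vector), `delta_per_helix`, `delta_mean`, `residue_range`.
#' @export
bundle_angles <- function(x, chains = NULL, residue_range = NULL) {
  ca <- as_ca_tbl(x)
  have <- unique(ca$chain)
  chains <- chains %||% have
  missing <- setdiff(chains, have)
  if (length(missing) > 0) {
    abort(sprintf("chain(s) %s not in structure; available: %s",
                  paste(missing, collapse = ","), paste(have, collapse = ",")),
          class = "interfilm_data_error")
  }
  if (length(chains) < 2) {
    abort("need at least two chains for a bundle.", class = "interfilm_domain_error")
  }
  residue_range <- residue_range %||% common_helical_range(ca, chains)
  axes <- lapply(chains, function(ch) {
    sel <- ca$chain == ch & ca$resno >= residue_range[1] & ca$resno <= residue_range[2]
    seg <- ca[sel, ]
    seg <- seg[order(seg$resno), ]
    helix_axis(seg[, c("x", "y", "z")])
  })
  dirs <- t(vapply(axes, function(a) a$direction, numeric(3)))
  # principal direction of the (N->C aligned) helix directions
  sv <- svd(dirs, nu = 0, nv = 3)
  bundle <- sv$v[, 1]
  if (sum(bundle * colMeans(dirs)) < 0) bundle <- -bundle
  bundle <- bundle / sqrt(sum(bundle^2))
  delta <- rad2deg(acos(pmin(1, pmax(-1, as.vector(dirs %*% bundle)))))
  structure(list(
    helices = tibble(chain = chains, delta_deg = delta,
                     direction = lapply(axes, function(a) a$direction),
                     origin = lapply(axes, function(a) a$origin)),
    bundle_axis = bundle,
    delta_per_helix = stats::setNames(delta, chains),
    delta_mean = mean(delta),
    residue_range = residue_range
  ), class = "bundle_geometry")
}

#' @export
print.bundle_geometry <- function(x, ...) {
  cat(sprintf("<bundle_geometry> %d helices, residues %d-%d\n",
              nrow(x$helices), x$residue_range[1], x$residue_range[2]))
  cat(sprintf("  delta per helix (deg): %s; mean %.2f\n",
              paste(sprintf("%.2f", x$delta_per_helix), collapse = ", "),
              x$delta_mean))
  invisible(x)
}

#' @export
tidy.bundle_geometry <- function(x, ...) {
  x$helices |> select("chain", "delta_deg")
}

#' @export
glance.bundle_geometry <- function(x, ...) {
  tibble(n_helices = nrow(x$helices), delta_mean = x$delta_mean,
         delta_min = min(x$delta_per_helix), delta_max = max(x$delta_per_helix),
         res_first = x$residue_range[1], res_last = x$residue_range[2])
}

# ---- helix <-> bundle inclination mapping -----------------------------------

#' Map between helix inclination and bundle inclination
#'
#' For a coiled-coil bundle whose axis is inclined `beta` degrees from the
#' film plane, with helices at a fixed angle `delta` from the bundle axis,
#' the orientation-sensitive spectroscopic quantity is the second moment of
#' the helix direction about the surface normal, averaged over rotation of
#' the bundle about its own axis and about the normal. The *effective*
#' individual-helix inclination gamma_eff is defined through that second
#' moment:
#' `sin^2(gamma_eff) = cos^2(delta) sin^2(beta) + 1/2 sin^2(delta) cos^2(beta)`.
#' The relation is nonlinear; at beta = 0 the effective inclination is
#' `arcsin(sin(delta)/sqrt(2))` > 0, the geometric minimum for an intact
#' bundle.
#'
#' `effective_helix_inclination()` maps beta -> gamma_eff;
#' `trimer_inclination()` inverts the map (defined only for gamma_eff at or
#' above the delta-dependent minimum); `min_effective_inclination()` returns
#' that minimum.
#'
#' @param beta Bundle inclination from the film plane (degrees, 0-90).
#' @param delta Helix-to-bundle angle (degrees, 0 <= delta < 90).
#' @param gamma_eff Effective individual-helix inclination (degrees).
#' @return Degrees (vectorized over the first argument).
#' @examples
#' effective_helix_inclination(0, 17)   # ~12
#' trimer_inclination(22.5, 17)         # ~20
#' @export
effective_helix_inclination <- function(beta, delta) {
  assert_number(beta, "beta", 0, 90)
  assert_number(delta, "delta", 0, 90, closed_upper = FALSE)
  b <- deg2rad(beta); d <- deg2rad(delta)
  s2 <- cos(d)^2 * sin(b)^2 + 0.5 * sin(d)^2 * cos(b)^2
  rad2deg(safe_asin(sqrt(s2)))
}

#' @rdname effective_helix_inclination
#' @export
min_effective_inclination <- function(delta) {
  assert_number(delta, "delta", 0, 90, closed_upper = FALSE)
  rad2deg(asin(sin(deg2rad(delta)) / sqrt(2)))
}

#' @rdname effective_helix_inclination
#' @export
trimer_inclination <- function(gamma_eff, delta) {
  assert_number(gamma_eff, "gamma_eff", 0, 90)
  assert_number(delta, "delta", 0, 90, closed_upper = FALSE)
  d <- deg2rad(delta)
  gmin <- min_effective_inclination(delta)
  if (any(gamma_eff < gmin - 1e-9)) {
    abort(sprintf(
      "gamma_eff below the geometric minimum %.4f deg for delta = %g deg: an intact bundle cannot produce it.",
      gmin, delta), class = "interfilm_domain_error")
  }
  s2g <- sin(deg2rad(gamma_eff))^2
  denom <- cos(d)^2 - 0.5 * sin(d)^2
  if (abs(denom) < 1e-12) {
    abort("mapping degenerate at the magic helix-to-bundle angle.",
          class = "interfilm_domain_error")
  }
  s2b <- (s2g - 0.5 * sin(d)^2) / denom
  rad2deg(safe_asin(sqrt(pmin(1, pmax(0, s2b)))))
}
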