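#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance augment
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# clamp tiny numerical overshoot before asin/acos
safe_asin <- function(x, tol = 1e-12) {
  stopifnot(all(x >= -1 - tol & x <= 1 + tol))
  asin(pmin(1, pmax(-1, x)))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric.", name), class = "interfilm_domain_error")
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!all(lo_ok & hi_ok)) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s.",
      name, if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")"
    ), class = "interfilm_domain_error")
  }
  invisible(x)
}

# re-export broom-style generics so users need not attach {generics}
#' @export
generics::tidy

#' @export
generics::glance
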