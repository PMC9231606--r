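#' QCM-D trace container
#'
#' Quartz crystal microbalance with dissipation traces are kept long: one row
#' per (time, overtone) with frequency shift `delta_f` (Hz) and dissipation
#' shift `delta_d` (x 1e-6). Event markers (sample injection, buffer rinse,
#' salt switch, ...) are a tibble attribute.
#'
#' @param data Tibble with columns `time_min`, `overtone`, `delta_f`,
#'   `delta_d`.
#' @param events Tibble with columns `time_min`, `label`; every event time
#'   must lie within the record.
#' @return A validated `qcmd_trace` tibble.
#' @export
qcmd_trace <- function(data, events) {
  need <- c("time_min", "overtone", "delta_f", "delta_d")
  if (!all(need %in% names(data))) {
    abort(paste("trace needs columns", paste(need, collapse = ", ")),
          class = "interfilm_data_error")
  }
  data <- as_tibble(data)
  bad <- data |>
    group_by(.data$overtone) |>
    summarise(mono = all(diff(.data$time_min) > 0), .groups = "drop")
  if (!all(bad$mono)) {
    abort("time must be strictly increasing per overtone.", class = "interfilm_data_error")
  }
  if (!all(c("time_min", "label") %in% names(events))) {
    abort("events need columns time_min, label.", class = "interfilm_data_error")
  }
  if (any(events$time_min < min(data$time_min) | events$time_min > max(data$time_min))) {
    abort("event time outside the record.", class = "interfilm_data_error")
  }
  attr(data, "events") <- as_tibble(events)
  class(data) <- c("qcmd_trace", class(data))
  data
}

#' @export
#' @rdname qcmd_trace
#' @param x A `qcmd_trace`.
qcmd_events <- function(x) attr(x, "events")

event_time <- function(trace, label) {
  ev <- qcmd_events(trace)
  hit <- ev$time_min[ev$label == label]
  if (length(hit) == 0) {
    abort(sprintf("no event '%s'; available: %s", label,
                  paste(ev$label, collapse = ", ")), class = "interfilm_data_error")
  }
  hit[1]
}

window_stat <- function(trace, t_end, overtone, window_s) {
  d <- trace[trace$overtone == overtone, ]
  if (nrow(d) == 0) {
    abort(sprintf("overtone %d not recorded.", overtone), class = "interfilm_data_error")
  }
  sel <- d$time_min > t_end - window_s / 60 & d$time_min <= t_end
  if (!any(sel)) sel <- which.min(abs(d$time_min - t_end))
  c(f = mean(d$delta_f[sel]), d = mean(d$delta_d[sel]), n = sum(sel))
}

#' Event-referenced frequency and dissipation shifts
#'
#' Mean frequency and dissipation over a short window (default 30 s) ending
#' at the event, minus the same statistic at the baseline event.
#'
#' @param trace A [qcmd_trace()].
#' @param event Event label at which to read the shift.
#' @param baseline_event Event label for the reference state; `NULL` uses the
#'   start of the record.
#' @param overtone Overtone number (default 3, the overtone conventionally
#'   reported).
#' @param window_s Averaging window in seconds ending at each event
#'   (default 30).
#' @return One-row tibble with `delta_f` (Hz), `delta_d` (x 1e-6), plus the
#'   event labels and overtone.
#' @export
shift_at_event <- function(trace, event, baseline_event = NULL, overtone = 3,
                           window_s = 30) {
  stopifnot(inherits(trace, "qcmd_trace"))
  t1 <- event_time(trace, event)
  a <- window_stat(trace, t1, overtone, window_s)
  if (is.null(baseline_event)) {
    d <- trace[trace$overtone == overtone, ]
    t0 <- min(d$time_min) + window_s / 60
    b <- window_stat(trace, t0, overtone, window_s)
    baseline_event <- "(start)"
  } else {
    b <- window_stat(trace, event_time(trace, baseline_event), overtone, window_s)
  }
  tibble(event = event, baseline = baseline_event, overtone = overtone,
         delta_f = unname(a["f"] - b["f"]), delta_d = unname(a["d"] - b["d"]))
}

#' Softness of an adsorbed layer
#'
#' The dissipation-to-frequency ratio delta_d / (-delta_f)
#' (x 1e-6 per Hz): soft, hydrated, loosely coupled layers dissipate more
#' energy per unit of added mass than stiff dense ones. Defined only for
#' delta_f < 0 (adsorbed mass present).
#'
#' @param delta_f Frequency shift (Hz), must be negative.
#' @param delta_d Dissipation shift (x 1e-6).
#' @return Softness (x 1e-6 / Hz), vectorized.
#' @examples
#' softness(-25, 2) # 0.08
#' @export
softness <- function(delta_f, delta_d) {
  if (any(!is.finite(delta_f)) || any(delta_f >= 0)) {
    abort("softness requires delta_f < 0 (no adsorbed mass otherwise).",
          class = "interfilm_domain_error")
  }
  delta_d / (-delta_f)
}

#' Layer softness at an event
#'
#' Convenience wrapper: [shift_at_event()] followed by [softness()].
#'
#' @inheritParams shift_at_event
#' @param context Free-text context tag (e.g. `"after_rinse"`,
#'   `"at_equilibrium"`).
#' @return One-row tibble with `delta_f`, `delta_d`, `softness`, `context`.
#' @export
layer_softness <- function(trace, event, baseline_event = NULL, overtone = 3,
                           window_s = 30, context = event) {
  s <- shift_at_event(trace, event, baseline_event, overtone, window_s)
  tibble(delta_f = s$delta_f, delta_d = s$delta_d,
         softness = softness(s$delta_f, s$delta_d), context = context)
}

#' Desorption-baseline extrapolation
#'
#' Fits an OLS line to the frequency trace inside a time window (typically
#' the slow desorption following the first buffer rinse) and predicts the
#' frequency expected at later times if that trend simply continued. The
#' deviation of the observed trace from the prediction, in units of the
#' residual SD, tests whether a subsequent treatment (e.g. a high-salt rinse)
#' caused desorption beyond the pre-existing trend.
#'
#' @param trace A [qcmd_trace()].
#' @param window Length-2 numeric: start and end time (minutes) of the
#'   fitting window; needs >= 10 samples.
#' @param overtone Overtone number (default 3).
#' @return List of class `desorption_fit` with `rate` (Hz/min), `intercept`,
#'   `residual_sd`, `window`, the `lm` fit and a `predict(fit, time)` method.
#' @export
desorption_extrapolation <- function(trace, window, overtone = 3) {
  stopifnot(inherits(trace, "qcmd_trace"))
  d <- trace[trace$overtone == overtone, ]
  sel <- d$time_min >= window[1] & d$time_min <= window[2]
  if (sum(sel) < 10) {
    abort(sprintf("need >= 10 samples in the window (%g found); record spans %g-%g min.",
                  sum(sel), min(d$time_min), max(d$time_min)),
          class = "interfilm_data_error")
  }
  fit <- stats::lm(delta_f ~ time_min, data = d[sel, ])
  structure(list(
    rate = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_sd = sqrt(sum(stats::resid(fit)^2) / (sum(sel) - 2)),
    window = window, overtone = overtone, fit = fit
  ), class = "desorption_fit")
}

#' @export
print.desorption_fit <- function(x, ...) {
  cat(sprintf("<desorption_fit> rate = %.4f Hz/min over %g-%g min (residual SD %.3g Hz)\n",
              x$rate, x$window[1], x$window[2], x$residual_sd))
  invisible(x)
}

#' @export
#' @param object A `desorption_fit`.
#' @param time Times (minutes) at which to predict the baseline frequency.
#' @param ... Unused.
#' @rdname desorption_extrapolation
predict.desorption_fit <- function(object, time, ...) {
  object$intercept + object$rate * time
}

#' Deviation of the observed trace from the extrapolated desorption baseline
#'
#' @param fit A `desorption_fit`.
#' @param trace The [qcmd_trace()] to compare.
#' @param window Length-2 numeric: time window (minutes) over which to assess
#'   the deviation.
#' @return One-row tibble with mean `observed`, `predicted`, `deviation`
#'   (observed - predicted, Hz), `residual_sd` and `n_sd` (deviation in units
#'   of the residual SD).
#' @export
desorption_deviation <- function(fit, trace, window) {
  stopifnot(inherits(fit, "desorption_fit"))
  d <- trace[trace$overtone == fit$overtone, ]
  sel <- d$time_min >= window[1] & d$time_min <= window[2]
  if (!any(sel)) abort("deviation window outside the record.", class = "interfilm_data_error")
  obs <- mean(d$delta_f[sel])
  pred <- mean(predict(fit, d$time_min[sel]))
  dev <- obs - pred
  tibble(observed = obs, predicted = pred, deviation = dev,
         residual_sd = fit$residual_sd, n_sd = dev / fit$residual_sd)
}

#' Read a QCM-D trace file
#'
#' Wide delimited text with a `time` column and per-overtone columns named
#' `F3`/`D3` (or `f3`/`d3`) etc. Events come from a sidecar file with columns
#' (time_min, label) or a tibble.
#'
#' @param path Trace file.
#' @param events Events file path or tibble with columns `time_min`, `label`.
#' @return A [qcmd_trace()].
#' @export
read_qcmd <- function(path, events) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  body <- strsplit(trimws(lines[-1]), "[,\t ]+")
  m <- matrix(as.numeric(unlist(body)), ncol = length(hdr), byrow = TRUE)
  colnames(m) <- hdr
  tcol <- grep("^time", hdr, ignore.case = TRUE, value = TRUE)[1]
  if (is.na(tcol)) abort("no time column found.", class = "interfilm_data_error")
  fcols <- grep("^[Ff]([0-9]+)$", hdr, value = TRUE)
  if (length(fcols) == 0) abort("no F<overtone> columns found.", class = "interfilm_data_error")
  long <- purrr::map(fcols, function(fc) {
    n <- as.integer(sub("^[Ff]", "", fc))
    dc <- grep(sprintf("^[Dd]%d$", n), hdr, value = TRUE)
    tibble(time_min = m[, tcol], overtone = n, delta_f = m[, fc],
           delta_d = if (length(dc) > 0) m[, dc[1]] else NA_real_)
  }) |> purrr::list_rbind()
  if (is.character(events) && length(events) == 1) {
    p <- read_delimited_columns_labelled(events)
    events <- p
  }
  qcmd_trace(long, events)
}

# two-column (numeric, text) sidecar: time_min,label
read_delimited_columns_labelled <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[,\t]+")
  tibble(time_min = as.numeric(vapply(fields, `[`, "", 1)),
         label = trimws(vapply(fields, `[`, "", 2)))
}

#' Write a QCM-D trace (and events sidecar) to files
#'
#' @param trace A [qcmd_trace()].
#' @param path Trace file path; events go to `<path>_events.csv` unless
#'   `events_path` is given.
#' @param events_path Optional events file path.
#' @return Invisibly, the paths written.
#' @export
write_qcmd <- function(trace, path, events_path = NULL) {
  wide <- trace |>
    as_tibble() |>
    tidyr::pivot_wider(names_from = "overtone",
                       values_from = c("delta_f", "delta_d"),
                       names_glue = "{ifelse(.value == 'delta_f', 'F', 'D')}{overtone}")
  writeLines(c(paste(c("time_min", names(wide)[-1]), collapse = ","),
               apply(wide, 1, function(r) paste(format(r, trim = TRUE, digits = 12),
                                                collapse = ","))), path)
  events_path <- events_path %||% paste0(sub("\\.[^.]*$", "", path), "_events.csv")
  ev <- qcmd_events(trace)
  writeLines(sprintf("%g,%s", ev$time_min, ev$label), events_path)
  invisible(c(path, events_path))
}

#' Sauerbrey mass of a rigid adsorbed layer
#'
#' Optional helper converting a (normalized) frequency shift to areal mass
#' with the standard constant of a 5 MHz AT-cut crystal,
#' C = 17.7 ng cm^-2 Hz^-1. Only meaningful for rigid films (low softness);
#' raw frequency shifts are the primary quantity elsewhere in the package.
#'
#' @param delta_f Normalized frequency shift (Hz, negative for adsorption).
#' @param c_sauerbrey Mass sensitivity constant (ng cm^-2 Hz^-1).
#' @return Areal mass (ng/cm^2).
#' @export
sauerbrey_mass <- function(delta_f, c_sauerbrey = 17.7) {
  -c_sauerbrey * delta_f
}
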