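#' Freeze-trace feature extraction
#'
#' A cryo-application trace is a two-column table of `time_s` (strictly
#' increasing, seconds) and `temp_c` (balloon temperature, deg C). The
#' biophysical summaries computed here treat the trace as piecewise linear
#' between samples; no resampling is performed and irregular sampling is
#' tolerated.
#'
#' @name trace-features
NULL

# check + coerce a trace; returns a list(time, temp)
.as_trace <- function(trace) {
  if (is.data.frame(trace)) {
    if (!all(c("time_s", "temp_c") %in% names(trace))) {
      abort("a trace needs columns time_s and temp_c")
    }
    time <- as.numeric(trace$time_s)
    temp <- as.numeric(trace$temp_c)
  } else {
    abort("trace must be a data frame with columns time_s and temp_c")
  }
  if (length(time) < 2) abort("a trace needs at least 2 samples")
  if (anyNA(time) || anyNA(temp) || any(!is.finite(time)) || any(!is.finite(temp))) {
    abort("trace samples must be finite and non-missing")
  }
  if (any(diff(time) <= 0)) abort("trace times must be strictly increasing")
  list(time = time, temp = temp)
}

# Area (positive magnitude) and duration of the sub-zero part of one
# piecewise-linear segment, with linear interpolation of the 0 deg C crossing.
.segment_subzero <- function(t1, t2, y1, y2) {
  if (y1 >= 0 && y2 >= 0) return(c(area = 0, dur = 0))
  if (y1 < 0 && y2 < 0) {
    return(c(area = -(y1 + y2) / 2 * (t2 - t1), dur = t2 - t1))
  }
  tc <- t1 + (0 - y1) * (t2 - t1) / (y2 - y1)
  if (y1 < 0) {                       # leaves the sub-zero region
    c(area = -y1 / 2 * (tc - t1), dur = tc - t1)
  } else {                            # enters the sub-zero region
    c(area = -y2 / 2 * (t2 - tc), dur = t2 - tc)
  }
}

.subzero <- function(tr) {
  n <- length(tr$time)
  parts <- vapply(seq_len(n - 1L), function(i) {
    .segment_subzero(tr$time[i], tr$time[i + 1L], tr$temp[i], tr$temp[i + 1L])
  }, c(area = 0, dur = 0))
  c(area = sum(parts["area", ]), dur = sum(parts["dur", ]))
}

#' Freeze area under the curve
#'
#' Area between the temperature curve and the 0 deg C axis, counted only
#' where the temperature is below 0 deg C, by trapezoidal integration with
#' linear interpolation of the zero crossings. Returned as a positive
#' magnitude in deg C * s. Exact for piecewise-linear traces, and invariant
#' under refinement of the sampling grid.
#'
#' @param trace Data frame with columns `time_s`, `temp_c`.
#' @return Freeze AUC in deg C * s (>= 0). A trace that never drops below
#'   0 deg C yields 0 with a warning.
#' @export
#' @examples
#' tri <- data.frame(time_s = c(0, 100, 120), temp_c = c(0, -40, 0))
#' freeze_auc(tri)  # 2400
freeze_auc <- function(trace) {
  tr <- .as_trace(trace)
  sz <- .subzero(tr)
  if (sz[["dur"]] == 0) warn("trace never falls below 0 deg C; freeze AUC is 0")
  unname(sz[["area"]])
}

#' Freeze magnitude
#'
#' Freeze AUC divided by the total time (s) the curve spends below 0 deg C
#' (interpolated crossings included): a time-normalised freeze intensity in
#' deg C. Always lies in `[0, |nadir|]`.
#'
#' @inheritParams freeze_auc
#' @return Freeze magnitude in deg C, or `NA` with a warning when the trace
#'   never drops below 0 deg C.
#' @export
freeze_magnitude <- function(trace) {
  tr <- .as_trace(trace)
  sz <- .subzero(tr)
  if (sz[["dur"]] == 0) {
    warn("no time below 0 deg C; freeze magnitude undefined")
    return(NA_real_)
  }
  unname(sz[["area"]] / sz[["dur"]])
}

#' Temperature at a given time
#'
#' Linear interpolation between the bracketing samples; the exact sample
#' value when `t` coincides with a sample time. Never extrapolates: times
#' outside the sampled span return `NA` with a warning.
#'
#' @inheritParams freeze_auc
#' @param t Times (s) at which to evaluate the curve; vectorised.
#' @return Temperatures in deg C.
#' @export
temperature_at <- function(trace, t) {
  tr <- .as_trace(trace)
  out <- rep(NA_real_, length(t))
  inside <- !is.na(t) & t >= tr$time[1] & t <= tr$time[length(tr$time)]
  if (any(!inside & !is.na(t))) {
    warn("temperature_at: time(s) outside the sampled span return NA")
  }
  if (any(inside)) {
    out[inside] <- approx(tr$time, tr$temp, xout = t[inside], ties = "ordered")$y
  }
  out
}

# earliest index attaining the global minimum temperature
.nadir_index <- function(tr) which.min(tr$temp)

#' Warming time to a temperature threshold
#'
#' Elapsed time from the warming reference point -- by default the time of
#' the global temperature nadir (earliest sample in case of ties) -- to the
#' first interpolated upward crossing of `threshold`. When the threshold is
#' never reached because the console stopped recording at balloon deflation
#' (`deflation_truncated = TRUE`), the elapsed time to the final sample is
#' returned with attribute `truncated = TRUE`; without the truncation flag
#' the result is `NA` with a warning.
#'
#' @inheritParams freeze_auc
#' @param threshold Temperature threshold in deg C; must not be below the
#'   trace nadir (unreachable by warming).
#' @param warming_ref `"nadir"` (default) or `"marker"` to use an explicit
#'   thaw-start marker time.
#' @param marker_time Marker time (s) when `warming_ref = "marker"`.
#' @param deflation_truncated Whether the recording ends at balloon
#'   deflation; defaults to the trace's `deflation_truncated` attribute.
#' @return Time in seconds with logical attribute `"truncated"`.
#' @export
warming_time_to <- function(trace, threshold,
                            warming_ref = c("nadir", "marker"),
                            marker_time = NULL,
                            deflation_truncated = NULL) {
  tr <- .as_trace(trace)
  warming_ref <- match.arg(warming_ref)
  if (is.null(deflation_truncated)) {
    deflation_truncated <- isTRUE(attr(trace, "deflation_truncated"))
  }
  nadir <- min(tr$temp)
  if (threshold < nadir) {
    abort("threshold lies below the trace nadir and cannot be reached by warming")
  }
  ref_time <- if (warming_ref == "nadir") {
    tr$time[.nadir_index(tr)]
  } else {
    if (is.null(marker_time)) abort("marker_time needed when warming_ref = 'marker'")
    marker_time
  }
  keep <- tr$time >= ref_time
  tt <- tr$time[keep]
  yy <- tr$temp[keep]
  if (length(tt) == 0) abort("warming reference point beyond the trace")
  out <- NA_real_
  truncated <- FALSE
  if (yy[1] >= threshold) {
    out <- 0
  } else {
    for (i in seq_len(length(tt) - 1L)) {
      if (yy[i] < threshold && yy[i + 1L] >= threshold) {
        tc <- tt[i] + (threshold - yy[i]) * (tt[i + 1L] - tt[i]) / (yy[i + 1L] - yy[i])
        out <- tc - ref_time
        break
      }
    }
  }
  if (is.na(out)) {
    if (deflation_truncated) {
      out <- tt[length(tt)] - ref_time
      truncated <- TRUE
    } else {
      warn(paste0("threshold ", threshold,
                  " deg C never reached and trace not flagged as truncated"))
    }
  }
  structure(out, truncated = truncated)
}

#' Extract all biophysical features from a trace
#'
#' Bundles the freeze AUC, freeze magnitude, nadir balloon temperature
#' (earliest sample at the minimum), temperatures at 30 s / 60 s / time to
#' isolation, and warming times to 0, 15 and 20 deg C into a one-row tibble.
#' The temperature at the time to isolation is computed only when `tti_s` is
#' supplied (it is an electrogram annotation, never derivable from the
#' temperature curve).
#'
#' @inheritParams warming_time_to
#' @param tti_s Time to isolation in seconds, or `NA`.
#' @param at_times Times (s) at which spot temperatures are reported.
#' @param warming_thresholds Warming thresholds (deg C) to report.
#' @return One-row tibble of features, with a `warming_truncated` flag set
#'   when any requested warming threshold was cut short by balloon deflation.
#' @export
extract_features <- function(trace, tti_s = NA_real_,
                             deflation_truncated = NULL,
                             warming_ref = "nadir", marker_time = NULL,
                             at_times = c(30, 60),
                             warming_thresholds = c(0, 15, 20)) {
  tr <- .as_trace(trace)
  if (is.null(deflation_truncated)) {
    deflation_truncated <- isTRUE(attr(trace, "deflation_truncated"))
  }
  sz <- .subzero(tr)
  auc <- unname(sz[["area"]])
  mag <- if (sz[["dur"]] > 0) auc / sz[["dur"]] else NA_real_
  i_nadir <- .nadir_index(tr)
  spot <- suppressWarnings(temperature_at(trace, at_times))
  temp_tti <- if (is.na(tti_s)) NA_real_ else suppressWarnings(temperature_at(trace, tti_s))
  trunc_any <- FALSE
  wt <- lapply(warming_thresholds, function(th) {
    w <- suppressWarnings(
      warming_time_to(trace, th, warming_ref = warming_ref,
                      marker_time = marker_time,
                      deflation_truncated = deflation_truncated))
    trunc_any <<- trunc_any || isTRUE(attr(w, "truncated"))
    as.numeric(w)
  })
  out <- tibble(
    freeze_auc = auc,
    freeze_magnitude = mag,
    nadir_temp_c = tr$temp[i_nadir],
    nadir_time_s = tr$time[i_nadir],
    time_below_zero_s = unname(sz[["dur"]]),
    temp_at_tti = temp_tti,
    warming_truncated = trunc_any
  )
  for (i in seq_along(at_times)) {
    out[[paste0("temp_at_", at_times[i], "s")]] <- spot[i]
  }
  for (i in seq_along(warming_thresholds)) {
    out[[paste0("warming_time_to_", warming_thresholds[i])]] <- wt[[i]]
  }
  out
}

#' Read a trace CSV
#'
#' @param path Path to a two-column delimited file with `time_s`, `temp_c`.
#' @param delim Field delimiter.
#' @return Tibble with columns `time_s`, `temp_c`.
#' @export
read_trace <- function(path, delim = ",") {
  tr <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(time_s = readr::col_double(),
                                                  temp_c = readr::col_double()),
                          progress = FALSE)
  .as_trace(tr)
  tr
}

#' Extract features for every application in a manifest
#'
#' The manifest is a delimited table with one row per cryo-application:
#' `trace_file` (path relative to `dir`), and optionally `tti_s`,
#' `deflation_truncated`, `aborted`.
#'
#' @param manifest Data frame or path to a manifest CSV.
#' @param dir Directory that trace paths are relative to.
#' @param ... Passed on to [extract_features()].
#' @return Tibble with one feature row per application, keyed by
#'   `trace_file`.
#' @export
extract_features_from_manifest <- function(manifest, dir = ".", ...) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  manifest <- as_tibble(manifest)
  if (!"trace_file" %in% names(manifest)) abort("manifest needs a trace_file column")
  if (!"tti_s" %in% names(manifest)) manifest$tti_s <- NA_real_
  if (!"deflation_truncated" %in% names(manifest)) manifest$deflation_truncated <- FALSE
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    tr <- read_trace(file.path(dir, manifest$trace_file[i]))
    feats <- extract_features(tr, tti_s = manifest$tti_s[i],
                              deflation_truncated = isTRUE(manifest$deflation_truncated[i]),
                              ...)
    bind_cols(tibble(trace_file = manifest$trace_file[i]), feats)
  })
  list_rbind(rows)
}
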