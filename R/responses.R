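# Event-locked responses, tuning curves and HSV topographic response maps.
#
# The per-trial response statistic is the mean dF/F0 over the post-event
# window (configurable to the peak). Tuning width is formalized as the
# full width at half maximum (FWHM) of the trial-averaged tuning curve
# above its minimum, linearly interpolated between grid points.

#' Event-locked trial tensor
#'
#' Cuts peri-event windows out of the dF/F0 traces and regroups them by
#' variable value. Windows are half-open `[t - pre, t + post)`; trials
#' whose window crosses a recording edge are dropped with a warning. A
#' trial is flagged significant when any significant transient frame falls
#' in its post-event window.
#'
#' @param dff a `dff_traces`, or a `transient_raster` to use `masked_dff`
#'   (significant transients only; the default recommendation).
#' @param events an [event_timeline()].
#' @param frame_rate Hz.
#' @param window `c(pre, post)` seconds (both non-negative).
#' @param raster optional `transient_raster` used only for the
#'   `significant_trial` flags.
#' @return A list of class `trial_tensor`: `responses` is a 4-d array
#'   `(ROI, value, trial, peri-frame)` (NA-padded for unequal trial
#'   counts), `grid`, `window`, `frame_rate`, `pre_frames`, and
#'   `significant_trial` (`ROI x value x trial`).
#' @export
event_locked <- function(dff, events, frame_rate, window = c(2, 5),
                         raster = NULL) {
  if (inherits(dff, "transient_raster")) {
    raster <- dff
    X <- dff$masked_dff
  } else {
    X <- dff$dff
  }
  stopifnot(all(window >= 0))
  nt <- ncol(X); n <- nrow(X)
  grid <- attr(events, "grid")
  pre_f <- round(window[1] * frame_rate)
  post_f <- round(window[2] * frame_rate)
  len <- pre_f + post_f
  ev_frame <- round(events$time_s * frame_rate) + 1L
  keep <- ev_frame - pre_f >= 1L & ev_frame + post_f - 1L <= nt
  if (!all(keep))
    warning(sum(!keep), " trial(s) dropped: window crosses recording edge")
  ev <- events[keep, , drop = FALSE]
  ev_frame <- ev_frame[keep]
  trials_per_value <- table(factor(ev$value, levels = grid))
  max_tr <- max(c(1L, trials_per_value))
  resp <- array(NA_real_, dim = c(n, length(grid), max_tr, len))
  sig_tr <- array(FALSE, dim = c(n, length(grid), max_tr))
  counter <- integer(length(grid))
  for (j in seq_len(nrow(ev))) {
    v <- match(ev$value[j], grid)
    counter[v] <- counter[v] + 1L
    fr <- (ev_frame[j] - pre_f):(ev_frame[j] + post_f - 1L)
    resp[, v, counter[v], ] <- X[, fr]
    if (!is.null(raster)) {
      post <- fr[fr >= ev_frame[j]]
      sig_tr[, v, counter[v]] <-
        rowSums(raster$significant[, post, drop = FALSE]) > 0
    }
  }
  structure(list(responses = resp, grid = grid, window = window,
                 frame_rate = frame_rate, pre_frames = pre_f,
                 significant_trial = sig_tr,
                 has_significance = !is.null(raster)),
            class = "trial_tensor")
}

#' Tuning curves from a trial tensor
#'
#' The scalar response per trial is the mean (or peak) dF/F0 over the
#' post-event window. Per (ROI, value): mean and SEM over trials;
#' `v_peak` is the grid argmax of the mean curve (lowest value on ties),
#' `peak_amp` the mean at `v_peak`, and `width` the FWHM of the mean curve
#' above its minimum, linearly interpolated and clamped to the grid span.
#' ROIs with an all-zero (or non-positive-range) curve — and, when the
#' tensor carries transient-significance flags, ROIs without a reliably
#' driven value (no stimulus value reaching `min_sig_trials` significant
#' trials; an isolated single-trial event is indistinguishable from a
#' spontaneous transient) — get `width = grid span` and are flagged
#' unresponsive (their map saturation is 0: whitish).
#'
#' @param trials a `trial_tensor`.
#' @param statistic `"mean"` (default) or `"peak"` post-event statistic.
#' @param min_sig_trials significant trials required at some value for a
#'   ROI to count as responsive (default 2; only with significance flags).
#' @return A data frame of class `tuning_curves` with one row per ROI:
#'   `roi`, `v_peak`, `peak_amp`, `width`, `responsive`; the per-value
#'   curves are in `attr(, "mean")` and `attr(, "sem")`
#'   (`ROI x value` matrices).
#' @export
tuning_curves <- function(trials, statistic = c("mean", "peak"),
                          min_sig_trials = 2L) {
  statistic <- match.arg(statistic)
  resp <- trials$responses
  post <- seq(trials$pre_frames + 1L, dim(resp)[4])
  stat <- apply(resp[, , , post, drop = FALSE], c(1, 2, 3),
                function(x) {
                  if (all(is.na(x))) return(NA_real_)
                  if (statistic == "mean") mean(x, na.rm = TRUE)
                  else max(x, na.rm = TRUE)
                })
  mcurve <- apply(stat, c(1, 2), mean, na.rm = TRUE)
  scurve <- apply(stat, c(1, 2), function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  })
  grid <- trials$grid
  span <- diff(range(grid))
  n <- dim(resp)[1]
  v_peak <- peak_amp <- width <- numeric(n)
  responsive <- logical(n)
  no_sig <- if (isTRUE(trials$has_significance))
    apply(trials$significant_trial, 1,
          function(m) max(rowSums(matrix(m, ncol = dim(trials$responses)[3])))
          < min_sig_trials)
  else rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- mcurve[i, ]
    k <- which.max(y)                 # ties -> lowest grid value
    v_peak[i] <- grid[k]
    peak_amp[i] <- y[k]
    rng <- max(y) - min(y)
    if (!is.finite(rng) || rng <= 0 || no_sig[i]) {
      width[i] <- span
      responsive[i] <- FALSE
      next
    }
    responsive[i] <- TRUE
    half <- min(y) + rng / 2
    width[i] <- .fwhm(grid, y, k, half, span)
  }
  structure(data.frame(roi = seq_len(n), v_peak = v_peak,
                       peak_amp = peak_amp, width = width,
                       responsive = responsive),
            mean = mcurve, sem = scurve, grid = grid,
            class = c("tuning_curves", "data.frame"))
}

# FWHM around peak index k by linear interpolation, clamped to grid span
.fwhm <- function(grid, y, k, half, span) {
  left <- grid[1]
  if (k > 1L) {
    for (j in seq(k - 1L, 1L)) {
      if (y[j] <= half) {
        left <- grid[j] + (grid[j + 1] - grid[j]) *
          (half - y[j]) / (y[j + 1] - y[j])
        break
      }
      if (j == 1L) left <- grid[1]
    }
  }
  right <- grid[length(grid)]
  if (k < length(y)) {
    for (j in seq(k + 1L, length(y))) {
      if (y[j] <= half) {
        right <- grid[j - 1] + (grid[j] - grid[j - 1]) *
          (y[j - 1] - half) / (y[j - 1] - y[j])
        break
      }
      if (j == length(y)) right <- grid[length(grid)]
    }
  }
  min(max(right - left, 0), span)
}

#' HSV response-map parameters
#'
#' Clip/offset rescaling bounds for the saturation and value channels:
#' `x -> clamp((x - offset) / (clip - offset), 0, 1)`. Clipping flattens
#' the few dominant responses of a skewed response distribution; offsets
#' suppress the weak tail.
#'
#' @param sat_offset,sat_clip saturation rescaling bounds (offset < clip).
#' @param val_offset,val_clip value rescaling bounds (offset < clip).
#' @param transparency if `TRUE`, response amplitude also drives an alpha
#'   channel so weak noisy responses fade out.
#' @return A list of class `hsv_map_params`.
#' @export
hsv_map_params <- function(sat_offset = 0, sat_clip = 1,
                           val_offset = 0, val_clip = 1,
                           transparency = FALSE) {
  stopifnot(sat_offset < sat_clip, val_offset < val_clip)
  structure(list(sat_offset = sat_offset, sat_clip = sat_clip,
                 val_offset = val_offset, val_clip = val_clip,
                 transparency = transparency),
            class = "hsv_map_params")
}

#' Map tuning curves to HSV colors
#'
#' Hue encodes the preferred variable value `v_peak` (scaled onto the
#' `[0, 0.75]` segment of the hue wheel, so the two grid extremes stay
#' visually distinct); saturation encodes selectivity
#' (`1 - width / span`: flat tuning is whitish); value encodes response
#' amplitude (`peak_amp / max(peak_amp)`), both after clip/offset
#' rescaling. Requires a continuous parametric variable grid with at least
#' two values.
#'
#' @param tuning a `tuning_curves` data frame.
#' @param params an [hsv_map_params()].
#' @return A data frame `roi, hue, sat, val, alpha`, all in `[0, 1]`.
#' @export
hsv_map <- function(tuning, params = hsv_map_params()) {
  grid <- attr(tuning, "grid")
  if (length(grid) < 2L)
    stop("degenerate variable grid: hue undefined for a single value")
  span <- diff(range(grid))
  resc <- function(x, off, clip) pmin(pmax((x - off) / (clip - off), 0), 1)
  hue <- 0.75 * (tuning$v_peak - min(grid)) / span
  sat_raw <- 1 - tuning$width / span
  vmax <- max(tuning$peak_amp, na.rm = TRUE)
  val_raw <- if (vmax > 0) tuning$peak_amp / vmax else rep(0, nrow(tuning))
  val_raw <- pmax(val_raw, 0)
  sat <- resc(sat_raw, params$sat_offset, params$sat_clip)
  val <- resc(val_raw, params$val_offset, params$val_clip)
  data.frame(roi = tuning$roi, hue = hue, sat = sat, val = val,
             alpha = if (params$transparency) val else rep(1, nrow(tuning)))
}

#' Render an HSV response map over the imaged plane
#'
#' ROI pixels are colored by HSV -> RGB conversion and alpha-composited
#' over the grayscale background; non-ROI pixels show the background.
#'
#' @param rois a [roi_map()].
#' @param hsv data frame from [hsv_map()] (one row per ROI).
#' @param background 2-D matrix (rescaled to `[0, 1]` for display).
#' @return An `rows x cols x 3` RGB array in `[0, 1]`.
#' @export
render_map <- function(rois, hsv, background) {
  stopifnot(nrow(hsv) == length(rois))
  bg <- background - min(background)
  if (max(bg) > 0) bg <- bg / max(bg)
  out <- array(rep(bg, 3), dim = c(dim(bg), 3))
  rgb <- t(grDevices::col2rgb(grDevices::hsv(hsv$hue, hsv$sat, hsv$val))) / 255
  for (i in seq_along(rois$rois)) {
    p <- rois$rois[[i]]
    a <- hsv$alpha[i]
    for (ch in 1:3) {
      v <- out[, , ch]
      v[p] <- a * rgb[i, ch] + (1 - a) * v[p]
      out[, , ch] <- v
    }
  }
  out
}
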