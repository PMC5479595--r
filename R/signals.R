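# Trace extraction, perisomatic neuropil decontamination, baseline (F0)
# estimation and dF/F0 computation.

#' Fluorescence traces container
#'
#' @param F numeric `N x T` matrix of fluorescence, arbitrary units.
#' @param source one of `"raw"`, `"neuropil"`, `"corrected"`.
#' @param bad_frames artifact frame indices (columns masked as `NA`).
#' @return A list of class `fluo_traces`.
#' @export
fluo_traces <- function(F, source = c("raw", "neuropil", "corrected"),
                        bad_frames = integer(0)) {
  source <- match.arg(source)
  stopifnot(is.matrix(F))
  if (length(bad_frames)) F[, bad_frames] <- NA_real_
  structure(list(F = F, source = source,
                 bad_frames = sort(unique(as.integer(bad_frames)))),
            class = "fluo_traces")
}

#' Extract per-ROI fluorescence traces
#'
#' `F[i, t]` is the mean intensity over ROI `i`'s pixels at frame `t`.
#' Artifact frames are masked (`NA`); pixels invalidated by registration
#' are ignored in the mean. A ROI whose pixels are all invalid at some
#' frame yields `NA` there with a warning.
#'
#' @param movie a [movie_stack()].
#' @param rois a [roi_map()].
#' @return A `fluo_traces` with `source = "raw"`.
#' @export
extract_traces <- function(movie, rois) {
  nt <- n_frames(movie)
  npx <- prod(dim(movie$data)[1:2])
  flat <- matrix(movie$data, npx, nt)
  F <- matrix(NA_real_, length(rois), nt)
  for (i in seq_along(rois$rois)) {
    p <- rois$rois[[i]]
    lin <- (p[, 2] - 1L) * dim(movie$data)[1] + p[, 1]
    F[i, ] <- colMeans(flat[lin, , drop = FALSE], na.rm = TRUE)
  }
  ok_frames <- setdiff(seq_len(nt), movie$bad_frames)
  if (any(is.nan(F[, ok_frames, drop = FALSE]))) {
    warning("ROI(s) entirely outside the valid region at some frames")
    F[is.nan(F)] <- NA_real_
  }
  fluo_traces(F, "raw", bad_frames = movie$bad_frames)
}

#' Perisomatic neuropil masks
#'
#' For every ROI: the disk of radius `radius` um centered on its centroid,
#' minus the pixels of *all* detected ROIs. Masks of different ROIs may
#' overlap each other, but each ROI has exactly one mask.
#'
#' @param rois a [roi_map()].
#' @param radius disk radius, um (default 20).
#' @param pixel_size um per pixel.
#' @return A list of pixel matrices (one per ROI); an empty matrix (with a
#'   warning) where the neighborhood is fully covered by ROIs.
#' @export
perisomatic_masks <- function(rois, radius = 20, pixel_size = 1) {
  stopifnot(radius > 0)
  r_px <- radius / pixel_size
  nr <- rois$field_dim[1]; nc <- rois$field_dim[2]
  occ <- matrix(FALSE, nr, nc)
  for (p in rois$rois) occ[p] <- TRUE
  out <- vector("list", length(rois))
  for (i in seq_along(rois$rois)) {
    cy <- rois$centroids[i, 1]; cx <- rois$centroids[i, 2]
    rr <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
    cc <- max(1L, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
    g <- expand.grid(row = rr, col = cc)
    d2 <- (g$row - cy)^2 + (g$col - cx)^2
    g <- g[d2 <= r_px^2, , drop = FALSE]
    g <- g[!occ[cbind(g$row, g$col)], , drop = FALSE]
    out[[i]] <- cbind(row = as.integer(g$row), col = as.integer(g$col))
    if (nrow(out[[i]]) == 0L)
      warning("empty perisomatic mask for ROI ", i,
              ": neuropil trace undefined")
  }
  out
}

#' Extract local neuropil traces
#'
#' Convenience wrapper: mean intensity over each ROI's perisomatic mask.
#'
#' @inheritParams perisomatic_masks
#' @param movie a [movie_stack()].
#' @return A `fluo_traces` with `source = "neuropil"` (`NA` rows for
#'   ROIs with empty masks).
#' @export
extract_neuropil <- function(movie, rois, radius = 20,
                             pixel_size = movie$pixel_size) {
  masks <- perisomatic_masks(rois, radius, pixel_size)
  nt <- n_frames(movie)
  flat <- matrix(movie$data, prod(dim(movie$data)[1:2]), nt)
  F <- matrix(NA_real_, length(rois), nt)
  for (i in seq_along(masks)) {
    if (nrow(masks[[i]]) == 0L) next
    lin <- (masks[[i]][, 2] - 1L) * dim(movie$data)[1] + masks[[i]][, 1]
    F[i, ] <- colMeans(flat[lin, , drop = FALSE], na.rm = TRUE)
  }
  fluo_traces(F, "neuropil", bad_frames = movie$bad_frames)
}

#' Subtract neuropil contamination
#'
#' Under the contamination model
#' `F_measured = F_soma + alpha * F_neuropil`, returns
#' `soma - alpha * npil`. Linear in alpha:
#' `correct(correct(s, n, a1), n, a2) = correct(s, n, a1 + a2)`.
#'
#' @param soma `fluo_traces` measured over the ROIs.
#' @param npil `fluo_traces` measured over the perisomatic masks.
#' @param alpha contamination factor in `[0, 1]` (default 0.9; the
#'   appropriate value is preparation-dependent).
#' @return A `fluo_traces` with `source = "corrected"`.
#' @export
neuropil_correct <- function(soma, npil, alpha = 0.9) {
  stopifnot(identical(dim(soma$F), dim(npil$F)), alpha >= 0, alpha <= 1)
  fluo_traces(soma$F - alpha * npil$F, "corrected",
              bad_frames = union(soma$bad_frames, npil$bad_frames))
}

#' Data sanity report
#'
#' Flags, per ROI: non-finite samples on valid frames, negative corrected
#' fluorescence (over-subtraction), saturation (>= 1% of frames pinned at
#' the trace maximum of the recording), and zero-variance traces.
#'
#' @param traces a `fluo_traces`.
#' @param saturation_level sensor maximum; default `max(F)` over all ROIs.
#' @return A data frame with one row per flagged ROI and columns
#'   `roi`, `flag`, `fraction`. Zero rows mean a clean dataset.
#' @export
sanity_check <- function(traces, saturation_level = NULL) {
  F <- traces$F
  ok <- setdiff(seq_len(ncol(F)), traces$bad_frames)
  Fv <- F[, ok, drop = FALSE]
  if (is.null(saturation_level)) saturation_level <- max(Fv, na.rm = TRUE)
  rows <- list()
  for (i in seq_len(nrow(F))) {
    x <- Fv[i, ]
    n <- length(x)
    bad <- mean(!is.finite(x))
    if (bad > 0)
      rows[[length(rows) + 1]] <- data.frame(roi = i, flag = "nonfinite",
                                             fraction = bad)
    xf <- x[is.finite(x)]
    if (length(xf) == 0L) next
    neg <- mean(xf < 0)
    if (neg > 0)
      rows[[length(rows) + 1]] <- data.frame(roi = i, flag = "negative",
                                             fraction = neg)
    sat <- mean(xf >= saturation_level)
    if (sat >= 0.01 && stats::sd(xf) > 0)
      rows[[length(rows) + 1]] <- data.frame(roi = i, flag = "saturated",
                                             fraction = sat)
    if (stats::sd(xf) == 0)
      rows[[length(rows) + 1]] <- data.frame(roi = i, flag = "zero_variance",
                                             fraction = 1)
  }
  if (length(rows) == 0L)
    return(data.frame(roi = integer(0), flag = character(0),
                      fraction = numeric(0)))
  do.call(rbind, rows)
}

#' Baseline F0 from a fixed time window
#'
#' F0 is the mean fluorescence over a half-open time window `[t0, t1)`
#' seconds, either global or relative to each event (window times added to
#' each event time), e.g. the seconds just before a stimulus.
#'
#' @param traces a `fluo_traces`.
#' @param frame_rate Hz.
#' @param window `c(t0, t1)` seconds; absolute, or relative to events.
#' @param events optional [event_timeline()]; when supplied, returns one
#'   F0 per (ROI, event).
#' @return Numeric vector `N` (global) or matrix `N x n_events`.
#' @export
estimate_f0_window <- function(traces, frame_rate, window,
                               events = NULL) {
  F <- traces$F
  win_frames <- function(t0, t1) {
    fr <- seq_len(ncol(F))
    tt <- (fr - 1) / frame_rate
    setdiff(fr[tt >= t0 & tt < t1], traces$bad_frames)
  }
  one <- function(t0, t1) {
    idx <- win_frames(t0, t1)
    if (length(idx) == 0L) return(rep(NA_real_, nrow(F)))
    rowMeans(F[, idx, drop = FALSE], na.rm = TRUE)
  }
  if (is.null(events)) {
    f0 <- one(window[1], window[2])
    if (anyNA(f0)) warning("window covers no valid frames for some ROIs")
    return(f0)
  }
  out <- vapply(events$time_s,
                function(te) one(te + window[1], te + window[2]),
                numeric(nrow(F)))
  if (anyNA(out)) warning("some event windows cover no valid frames")
  matrix(out, nrow = nrow(F))
}

#' Slow baseline F_smooth
#'
#' Estimates the slow fluorescence baseline fluctuations, unrelated to the
#' faster calcium transients: a running percentile (default 8th) of F in a
#' centered sliding window, smoothed by a moving average of the same
#' width. A low percentile sits `qnorm(p) * sigma` below the true baseline
#' under Gaussian noise; that offset is added back (sigma estimated
#' robustly from the residuals), so transient-free dF/F0 is centred on
#' zero. The window must be much longer than the indicator decay constant
#' (warned below `10 * tau`). Output is floored at a small positive
#' fraction of the trace scale, so it can serve directly as F0.
#'
#' @param traces a `fluo_traces`.
#' @param frame_rate Hz.
#' @param window window width, seconds (default 30).
#' @param percentile running percentile in (0, 100), default 8.
#' @param tau_decay indicator decay constant for the window validation, s.
#' @return `N x T` matrix of per-frame baselines.
#' @export
estimate_f_smooth <- function(traces, frame_rate, window = 30,
                              percentile = 8, tau_decay = NULL) {
  if (!is.null(tau_decay) && window < 10 * tau_decay)
    warning("baseline window < 10 * tau_decay: transients may leak into F0")
  F <- traces$F
  w <- max(3L, round(window * frame_rate))
  out <- matrix(NA_real_, nrow(F), ncol(F))
  for (i in seq_len(nrow(F))) {
    x <- F[i, ]
    xi <- x
    if (anyNA(xi)) xi <- zoo::na.approx(xi, na.rm = FALSE, rule = 2)
    rp <- zoo::rollapply(zoo::zoo(xi), width = w,
                         FUN = stats::quantile, probs = percentile / 100,
                         names = FALSE, partial = TRUE, align = "center")
    sm <- zoo::rollapply(rp, width = w, FUN = mean, partial = TRUE,
                         align = "center")
    sm <- as.numeric(sm)
    # undo the percentile offset under Gaussian noise
    sig_hat <- stats::mad(xi - sm)
    sm <- sm - stats::qnorm(percentile / 100) * sig_hat
    floor_eps <- 1e-6 * max(abs(xi), 1e-12)
    out[i, ] <- pmax(sm, floor_eps)
  }
  out
}

#' Relative fluorescence change dF/F0
#'
#' `dff = (F - F0) / F0`, with `F0` a per-ROI scalar (window method) or a
#' per-(ROI, frame) matrix (smooth method).
#'
#' @param traces a `fluo_traces` (typically neuropil-corrected).
#' @param F0 numeric vector of length `N` or `N x T` matrix, strictly
#'   positive.
#' @return A list of class `dff_traces` with elements `dff` (`N x T`),
#'   `F0`, `f0_method` and `bad_frames`.
#' @export
compute_dff <- function(traces, F0) {
  F <- traces$F
  if (is.matrix(F0)) {
    stopifnot(identical(dim(F0), dim(F)))
    method <- "smooth"
  } else {
    stopifnot(length(F0) == nrow(F))
    method <- "window"
    F0 <- matrix(F0, nrow(F), ncol(F))
  }
  ok <- setdiff(seq_len(ncol(F)), traces$bad_frames)
  if (any(F0[, ok] <= 0, na.rm = TRUE))
    stop("F0 <= 0: run sanity_check(); neuropil over-subtraction likely")
  structure(list(dff = (F - F0) / F0, F0 = F0, f0_method = method,
                 bad_frames = traces$bad_frames),
            class = "dff_traces")
}
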