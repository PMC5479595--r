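# Rigid within-plane registration and motion-artifact flagging.
#
# Displacements are estimated frame-by-frame by FFT cross-correlation
# against a template, refined to sub-pixel precision by parabolic
# interpolation of the correlation peak, and temporally smoothed with a
# centered moving average ("smooth registration").

#' Pick template frames by mutual correlation
#'
#' Selects the `n` frames with the highest mean pairwise correlation to the
#' other candidate frames; their average is a template robust to calcium
#' transients and to transient motion.
#'
#' @param movie a [movie_stack()].
#' @param n number of frames to select (default 100, capped at `T`).
#' @param max_candidates at most this many evenly spaced frames enter the
#'   pairwise-correlation computation (keeps cost quadratic in a constant).
#' @return integer vector of frame indices.
#' @export
select_template_frames <- function(movie, n = 100L, max_candidates = 200L) {
  nt <- n_frames(movie)
  cand <- unique(round(seq(1, nt, length.out = min(nt, max_candidates))))
  fmat <- apply(movie$data[, , cand, drop = FALSE], 3, as.numeric)
  sds <- apply(fmat, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(cand[seq_len(min(n, length(cand)))])
  cand <- cand[keep]; fmat <- fmat[, keep, drop = FALSE]
  cc <- stats::cor(fmat)
  score <- (rowSums(cc) - 1) / pmax(ncol(cc) - 1, 1)
  cand[order(score, decreasing = TRUE)][seq_len(min(n, length(cand)))]
}

#' Estimate rigid frame displacements
#'
#' Cross-correlates every frame with the mean of `template_frames`,
#' locating the correlation peak at sub-pixel precision, then smooths the
#' raw displacement series with a centered moving average of width
#' `smooth_window` seconds.
#'
#' @param movie a [movie_stack()].
#' @param template_frames frame indices averaged into the template;
#'   default [select_template_frames()].
#' @param smooth_window moving-average width in seconds (0 disables
#'   smoothing).
#' @return An object of class `displacement_series` with per-frame `dy`,
#'   `dx` (smoothed, in pixels; positive = frame content shifted down /
#'   right relative to template), `raw_dy`, `raw_dx`, the `template`
#'   image, and `quality` (correlation of each aligned frame with the
#'   template, in `[-1, 1]`).
#' @export
estimate_displacements <- function(movie, template_frames = NULL,
                                   smooth_window = 1) {
  if (is.null(template_frames)) template_frames <- select_template_frames(movie)
  stopifnot(length(template_frames) >= 1L)
  tmpl <- apply(movie$data[, , template_frames, drop = FALSE], c(1, 2), mean)
  if (stats::sd(as.numeric(tmpl)) == 0)
    stop("degenerate template: zero variance")
  nt <- n_frames(movie)
  ft <- stats::fft(tmpl - mean(tmpl))
  raw <- matrix(0, nt, 2)
  for (t in seq_len(nt)) {
    fr <- movie$data[, , t]
    fr[is.na(fr)] <- mean(fr, na.rm = TRUE)
    raw[t, ] <- .xcorr_peak(fr - mean(fr), ft, dim(tmpl))
  }
  w <- max(1L, round(smooth_window * movie$frame_rate))
  dy <- .movavg(raw[, 1], w)
  dx <- .movavg(raw[, 2], w)
  quality <- vapply(seq_len(nt), function(t) {
    al <- .translate_bilinear(movie$data[, , t], dy[t], dx[t])
    ok <- !is.na(al)
    if (sum(ok) < 4L || stats::sd(al[ok]) == 0) return(0)
    stats::cor(al[ok], tmpl[ok])
  }, numeric(1))
  structure(list(dy = dy, dx = dx, raw_dy = raw[, 1], raw_dx = raw[, 2],
                 template = tmpl, quality = quality),
            class = "displacement_series")
}

# cross-correlation peak of frame against template spectrum, sub-pixel
.xcorr_peak <- function(frame, ft_template, dims) {
  cc <- Re(stats::fft(stats::fft(frame) * Conj(ft_template), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dims)
  sub <- function(i, n, axis) {
    at <- function(d) {
      idx <- pk
      idx[axis] <- ((idx[axis] - 1L + d) %% n) + 1L
      cc[idx[1], idx[2]]
    }
    c0 <- at(0L); cm <- at(-1L); cp <- at(1L)
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  # peak index i corresponds to circular shift i-1; unwrap to signed shift
  d <- pk - 1L
  d <- ifelse(d > dims / 2, d - dims, d)
  c(d[1] + sub(pk[1], dims[1], 1L), d[2] + sub(pk[2], dims[2], 2L))
}

# centered moving average, edges use the available window
.movavg <- function(x, w) {
  if (w <= 1L) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = w, FUN = mean,
                            partial = TRUE, align = "center"))
}

# bilinear translation: output(r, c) = input(r + dy, c + dx); NA outside
.translate_bilinear <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  rs <- seq_len(nr) + dy
  cs <- seq_len(nc) + dx
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  out <- matrix(NA_real_, nr, nc)
  gv <- function(ri, ci) {
    ok <- ri >= 1L & ri <= nr
    m <- matrix(NA_real_, nr, nc)
    okc <- ci >= 1L & ci <= nc
    if (any(ok) && any(okc)) m[ok, okc] <- img[ri[ok], ci[okc], drop = FALSE]
    m
  }
  v00 <- gv(r0, c0); v10 <- gv(r0 + 1L, c0)
  v01 <- gv(r0, c0 + 1L); v11 <- gv(r0 + 1L, c0 + 1L)
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  w00 <- (1 - wr) * (1 - wc); w10 <- wr * (1 - wc)
  w01 <- (1 - wr) * wc; w11 <- wr * wc
  # corners with zero weight may lie outside the field without invalidating
  bad <- (w00 > 1e-12 & is.na(v00)) | (w10 > 1e-12 & is.na(v10)) |
    (w01 > 1e-12 & is.na(v01)) | (w11 > 1e-12 & is.na(v11))
  z <- function(v) { v[is.na(v)] <- 0; v }
  out <- z(v00) * w00 + z(v10) * w10 + z(v01) * w01 + z(v11) * w11
  out[bad] <- NA_real_
  out
}

#' Apply estimated displacements to a movie
#'
#' Translates every frame by the negative of its displacement with
#' bilinear sub-pixel interpolation; pixels that fall outside the field
#' are marked invalid (`NA`).
#'
#' @param movie a [movie_stack()].
#' @param disp a `displacement_series` from [estimate_displacements()].
#' @return A registered [movie_stack()].
#' @export
apply_registration <- function(movie, disp) {
  nt <- n_frames(movie)
  stopifnot(length(disp$dy) == nt)
  out <- movie$data
  all_invalid <- FALSE
  for (t in seq_len(nt)) {
    out[, , t] <- .translate_bilinear(movie$data[, , t],
                                      disp$dy[t], disp$dx[t])
    if (all(is.na(out[, , t]))) all_invalid <- TRUE
  }
  if (all_invalid)
    warning("displacement exceeds the field: frame(s) entirely invalid")
  movie_stack(out, movie$frame_rate, movie$pixel_size, movie$plane_id,
              movie$bad_frames)
}

#' Flag motion-artifact frames
#'
#' A frame is flagged when its template-similarity `quality` falls below
#' `quality_thr` or the residual displacement left after smoothing exceeds
#' `disp_thr` pixels in magnitude. Flagged frames should be stored in
#' `movie$bad_frames`; downstream trace statistics mask them.
#'
#' @param disp a `displacement_series`.
#' @param quality_thr correlation threshold; default
#'   `median(quality) - max(3 * mad(quality), 0.05)` (the floor keeps
#'   immaterial sub-0.05 correlation fluctuations from being flagged on
#'   very stable recordings).
#' @param disp_thr residual-displacement threshold in pixels (default 5).
#' @return sorted integer vector of flagged frame indices.
#' @export
detect_artifact_frames <- function(disp, quality_thr = NULL, disp_thr = 5) {
  stopifnot(is.finite(disp_thr) || is.infinite(disp_thr))
  if (is.null(quality_thr))
    quality_thr <- stats::median(disp$quality) -
      max(3 * stats::mad(disp$quality), 0.05)
  res <- sqrt((disp$raw_dy - disp$dy)^2 + (disp$raw_dx - disp$dx)^2)
  which(disp$quality < quality_thr | res > disp_thr)
}
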