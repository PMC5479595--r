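#' Fluorescence movie stack
#'
#' Container for a single optical plane of a calcium-imaging recording:
#' a `rows x cols x frames` intensity array plus the acquisition metadata
#' that downstream stages need (frame rate, pixel size) and the set of
#' frames flagged as motion artifacts.
#'
#' Pixel coordinates are 1-based `(row, col)` and frames are 1-based,
#' following R convention; time windows throughout the package are
#' half-open `[t0, t1)` in seconds.
#'
#' @param data numeric array, `rows x cols x frames` (a matrix is accepted
#'   as a single-frame movie).
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param pixel_size lateral pixel size in micrometres (> 0).
#' @param plane_id integer id of the optical plane (volumetric sets keep
#'   one `movie_stack` per plane).
#' @param bad_frames integer vector of frame indices flagged as artifacts;
#'   these frames are masked from all downstream trace statistics.
#'
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate, pixel_size, plane_id = 1L,
                        bad_frames = integer(0)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number (Hz)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/pixel)")
  nt <- dim(data)[3]
  bad_frames <- sort(unique(as.integer(bad_frames)))
  if (length(bad_frames) && (min(bad_frames) < 1L || max(bad_frames) > nt))
    stop("bad_frames out of range [1, T]")
  ok <- setdiff(seq_len(nt), bad_frames)
  if (length(ok)) {
    v <- data[, , ok, drop = FALSE]
    # NA marks pixels invalidated by registration; NaN/Inf are rejected
    if (any(is.infinite(v)) || any(is.nan(v)))
      stop("non-finite intensities in non-artifact frames")
  }
  structure(
    list(data = data, frame_rate = frame_rate, pixel_size = pixel_size,
         plane_id = as.integer(plane_id), bad_frames = bad_frames),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "movie_stack: %d x %d px, %d frames @ %g Hz, %g um/px (plane %d, %d bad frames)\n",
    d[1], d[2], d[3], x$frame_rate, x$pixel_size, x$plane_id,
    length(x$bad_frames)))
  invisible(x)
}

#' Number of frames of a movie
#' @param movie a [movie_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' ROI map
#'
#' An ordered collection of regions of interest over one or more optical
#' planes. Each ROI is a set of `(row, col)` pixels in one plane; within a
#' plane ROI pixel sets are pairwise disjoint.
#'
#' @param rois list of integer matrices with columns `row`, `col`
#'   (one matrix per ROI, at least one pixel each).
#' @param field_dim `c(rows, cols)` of the imaged field.
#' @param plane integer plane id per ROI (recycled if scalar).
#' @param labels optional character tags per ROI.
#' @param check if `TRUE` (default) verify within-plane disjointness.
#'
#' @return An object of class `roi_map` with elements `rois`, `centroids`
#'   (`N x 2` matrix, rows/cols, pixel units), `plane`, `labels`,
#'   `field_dim`.
#' @export
roi_map <- function(rois, field_dim, plane = 1L, labels = NULL,
                    check = TRUE) {
  stopifnot(is.list(rois), length(field_dim) == 2L)
  n <- length(rois)
  rois <- lapply(rois, function(p) {
    p <- matrix(as.integer(p), ncol = 2L,
                dimnames = list(NULL, c("row", "col")))
    if (nrow(p) == 0L) stop("empty ROI pixel set")
    if (min(p) < 1L || any(p[, 1] > field_dim[1]) || any(p[, 2] > field_dim[2]))
      stop("ROI pixels outside the field")
    p
  })
  plane <- rep_len(as.integer(plane), n)
  if (is.null(labels)) labels <- rep("", n)
  if (check && n > 1L) {
    for (pl in unique(plane)) {
      idx <- which(plane == pl)
      lin <- unlist(lapply(rois[idx],
                           function(p) (p[, 2] - 1L) * field_dim[1] + p[, 1]))
      if (anyDuplicated(lin))
        stop("ROIs within one plane must be pairwise disjoint")
    }
  }
  cent <- t(vapply(rois, colMeans, numeric(2)))
  colnames(cent) <- c("row", "col")
  structure(list(rois = rois, centroids = cent, plane = plane,
                 labels = as.character(labels),
                 field_dim = as.integer(field_dim)),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("roi_map: %d ROIs over a %d x %d field (%d plane(s))\n",
              length(x$rois), x$field_dim[1], x$field_dim[2],
              length(unique(x$plane))))
  invisible(x)
}

#' @export
length.roi_map <- function(x) length(x$rois)

#' Event timeline
#'
#' Timing of experimental events (stimuli, behavioral events) together with
#' the value of the experimental variable at each event. Values lie on an
#' ordered grid (the sorted unique values, or a user-declared grid).
#'
#' @param time_s event times in seconds.
#' @param value variable value at each event.
#' @param variable_name name of the experimental variable.
#' @param grid optional strictly increasing value grid; defaults to the
#'   sorted unique values.
#' @return An object of class `event_timeline`: a data frame with columns
#'   `time_s`, `value`, sorted by time (ties ordered by value), with
#'   attributes `variable_name` and `grid`.
#' @export
event_timeline <- function(time_s, value, variable_name = "variable",
                           grid = NULL) {
  if (length(time_s) != length(value)) stop("time_s and value lengths differ")
  if (!all(is.finite(time_s)) || !all(is.finite(value)))
    stop("non-numeric or non-finite event entries")
  if (is.null(grid)) grid <- sort(unique(value))
  if (any(diff(grid) <= 0)) stop("grid values must be strictly ordered")
  if (!all(value %in% grid)) stop("event values outside declared grid")
  o <- order(time_s, value)
  ev <- data.frame(time_s = as.numeric(time_s)[o],
                   value = as.numeric(value)[o])
  structure(ev, variable_name = variable_name, grid = as.numeric(grid),
            class = c("event_timeline", "data.frame"))
}

#' Acquisition parameters
#'
#' Physical parameters of the recording used across pipeline stages.
#'
#' @param tau_decay indicator fluorescence decay constant in seconds
#'   (e.g. 0.25 for GCaMP6f).
#' @param confidence confidence level in (0,1) for transient inference.
#' @param alpha_neuropil neuropil contamination factor in `[0, 1]` in
#'   `F_measured = F_soma + alpha * F_neuropil`.
#' @param neuropil_radius radius of the perisomatic neuropil mask, um.
#' @return A list of class `acquisition_params`.
#' @export
acquisition_params <- function(tau_decay = 0.25, confidence = 0.95,
                               alpha_neuropil = 0.9, neuropil_radius = 20) {
  stopifnot(tau_decay > 0, confidence > 0, confidence < 1,
            alpha_neuropil >= 0, alpha_neuropil <= 1, neuropil_radius > 0)
  structure(list(tau_decay = tau_decay, confidence = confidence,
                 alpha_neuropil = alpha_neuropil,
                 neuropil_radius = neuropil_radius),
            class = "acquisition_params")
}
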