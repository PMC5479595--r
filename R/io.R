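#' Read a multi-page TIFF movie
#'
#' Reads a grayscale multi-page TIFF (8/16-bit or float) into a
#' [movie_stack()]. Pages become frames; all pages must share one shape.
#' `tiff::readTIFF` rescales integer data to `[0, 1]`; intensities are kept
#' on that scale (all downstream quantities are ratios, so the scale is
#' immaterial).
#'
#' @param path path to the TIFF file.
#' @param frame_rate acquisition rate, Hz.
#' @param pixel_size pixel size, um.
#' @param plane_id optical plane id.
#' @return A [movie_stack()] with `T` = page count and no bad frames.
#' @export
read_movie <- function(path, frame_rate, pixel_size, plane_id = 1L) {
  if (!file.exists(path)) stop("cannot read movie: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("unreadable TIFF: ",
                                             conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF format error: file contains 0 pages")
  shp <- dim(pages[[1]])[1:2]
  ok <- vapply(pages, function(p) identical(dim(p)[1:2], shp), logical(1))
  if (!all(ok)) stop("TIFF format error: inconsistent page shapes")
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  data <- array(unlist(pages, use.names = FALSE), dim = c(shp, length(pages)))
  movie_stack(data, frame_rate, pixel_size, plane_id)
}

#' Write a movie to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` (dividing by `scale`, which
#' defaults to the movie maximum when that exceeds 1) and quantized to the
#' 16-bit sample grid, the standard storage for fluorescence microscopy.
#' Data already on that grid — in particular anything returned by
#' [read_movie()] or by a previous `write_movie` — round-trips
#' bit-exactly. All downstream quantities are fluorescence ratios, so the
#' stored scale is immaterial.
#'
#' @param movie a [movie_stack()].
#' @param path output path.
#' @param scale divisor applied before quantization.
#' @return Invisibly, the [movie_stack()] exactly as written (rescaled and
#'   quantized), for round-trip verification.
#' @export
write_movie <- function(movie, path, scale = NULL) {
  x <- movie$data
  x[is.na(x)] <- 0
  if (is.null(scale)) scale <- max(1, max(x))
  x <- pmin(pmax(x / scale, 0), 1)
  x <- round(x * 65535) / 65535
  frames <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(movie_stack(x, movie$frame_rate, movie$pixel_size,
                        movie$plane_id, movie$bad_frames))
}

#' Read an event table from CSV
#'
#' The CSV must have columns `time_s` and `value`. Events are returned
#' sorted by time (ties kept stable by value); the variable grid is the
#' sorted set of unique values.
#'
#' @param path CSV path.
#' @param variable_name name of the experimental variable.
#' @return An [event_timeline()].
#' @export
read_events <- function(path, variable_name = "variable") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("event CSV format error: columns time_s and value required")
  tm <- suppressWarnings(as.numeric(df$time_s))
  vl <- suppressWarnings(as.numeric(df$value))
  if (anyNA(tm) || anyNA(vl))
    stop("event CSV format error: non-numeric entries")
  event_timeline(tm, vl, variable_name)
}

#' Import / export ROI definitions as JSON
#'
#' The exchange format is
#' `{"rois": [{"pixels": [[r, c], ...], "plane": k, "label": s}, ...],`
#' `"field_dim": [rows, cols]}` with 0-based pixel coordinates; conversion
#' to the package's 1-based convention happens here at the boundary.
#'
#' @param path JSON path.
#' @return For `read_rois`, a [roi_map()].
#' @export
read_rois <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$rois) || is.null(js$field_dim))
    stop("ROI JSON format error: 'rois' and 'field_dim' required")
  rois <- lapply(js$rois, function(r) {
    px <- do.call(rbind, lapply(r$pixels, as.integer)) + 1L
    px
  })
  plane <- vapply(js$rois, function(r) as.integer(r$plane %||% 1L), integer(1))
  labels <- vapply(js$rois, function(r) as.character(r$label %||% ""),
                   character(1))
  roi_map(rois, field_dim = as.integer(unlist(js$field_dim)),
          plane = plane, labels = labels)
}

#' @rdname read_rois
#' @param rois a [roi_map()].
#' @export
write_rois <- function(rois, path) {
  js <- list(
    field_dim = rois$field_dim,
    rois = lapply(seq_along(rois$rois), function(i) {
      list(pixels = unname(apply(rois$rois[[i]] - 1L, 1, as.list,
                                 simplify = FALSE)),
           plane = rois$plane[i], label = rois$labels[i])
    }))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.session_version <- 1L

#' Save / load a pipeline session
#'
#' Persists any collection of pipeline products (movies, ROI maps, traces,
#' rasters, assembly sets, ...) to a single versioned container. Round trip
#' is lossless: all numeric fields are restored bit-identically.
#'
#' @param objects a named list of pipeline products.
#' @param path file path for the session container.
#' @return For `load_session`, the named list of restored objects.
#' @export
save_session <- function(objects, path) {
  stopifnot(is.list(objects))
  if (is.null(names(objects)) || any(names(objects) == ""))
    stop("all session objects must be named")
  saveRDS(list(format = "capop-session", version = .session_version,
               objects = objects),
          path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  sess <- tryCatch(readRDS(path), error = function(e)
    stop("incompatible or corrupt session file: ", conditionMessage(e)))
  if (!is.list(sess) || !identical(sess$format, "capop-session"))
    stop("incompatible session file: not a capop session")
  if (!identical(sess$version, .session_version))
    stop("incompatible session version: file v", sess$version,
         ", package supports v", .session_version)
  sess$objects
}

`%||%` <- function(a, b) if (is.null(a)) b else a
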