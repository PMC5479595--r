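# Morphology-based segmentation of the time-averaged image into
# single-neuron ROIs. Two labeling regimes are supported: nucleus-labeled
# cells appear as uniformly filled bright spots; cytosol-labeled,
# nucleus-excluded cells appear as bright rings around a dark nucleus.

#' Segmentation parameters
#'
#' @param mode `"labeled_nuclei"` (filled bright somata) or
#'   `"unlabeled_nuclei"` (bright ring, dark nucleus).
#' @param roi_size_opt `"bigger"` or `"smaller"`: morphological scale
#'   preset of the seeding / growth structuring element.
#' @param local_contrast neighborhood scale (pixels) of the spatial
#'   normalization.
#' @param thr_soma cell-center threshold on the normalized image, `[0,1]`.
#' @param thr_neuropil neuropil-border threshold, `[0,1]`.
#' @param area_min,area_max ROI area bounds, pixels.
#' @param intensity_min minimum mean normalized ROI intensity.
#' @param circ_min,circ_max circularity bounds; circularity is
#'   `perimeter^2 / (4 * pi * area)` (1 for a circle).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(mode = c("labeled_nuclei", "unlabeled_nuclei"),
                                roi_size_opt = c("bigger", "smaller"),
                                local_contrast = 20,
                                thr_soma = 0.5, thr_neuropil = 0.15,
                                area_min = 1, area_max = Inf,
                                intensity_min = 0,
                                circ_min = 0, circ_max = Inf) {
  mode <- match.arg(mode)
  roi_size_opt <- match.arg(roi_size_opt)
  stopifnot(thr_soma >= 0, thr_soma <= 1, thr_neuropil >= 0,
            thr_neuropil <= 1, area_min <= area_max, circ_min <= circ_max,
            local_contrast >= 3)
  structure(list(mode = mode, roi_size_opt = roi_size_opt,
                 local_contrast = local_contrast, thr_soma = thr_soma,
                 thr_neuropil = thr_neuropil, area_min = area_min,
                 area_max = area_max, intensity_min = intensity_min,
                 circ_min = circ_min, circ_max = circ_max),
            class = "segmentation_params")
}

#' Spatially normalize an image by local contrast
#'
#' Rescales each pixel by the local intensity range in a disc neighborhood
#' of scale `local_contrast` pixels:
#' `(image - local_min) / (local_range + eps)`, clipped to `[0, 1]`.
#' The output is invariant under global affine intensity changes
#' `a * image + b` (a > 0).
#'
#' @param image 2-D numeric matrix, finite.
#' @param local_contrast neighborhood scale in pixels (>= 3).
#' @return Normalized matrix in `[0, 1]`.
#' @export
normalize_contrast <- function(image, local_contrast = 20) {
  stopifnot(is.matrix(image), all(is.finite(image)), local_contrast >= 3)
  if (stats::sd(as.numeric(image)) == 0) {
    warning("constant image: normalized output is all 0.5")
    return(matrix(0.5, nrow(image), ncol(image)))
  }
  sz <- 2L * floor(local_contrast / 2) + 1L
  br <- EBImage::makeBrush(sz, shape = "disc")
  # rescale to [0, 1] first: grayscale morphology expects that range, and
  # min/max filters commute with increasing affine maps, so the output is
  # exactly invariant under global affine intensity changes
  img01 <- (image - min(image)) / (max(image) - min(image))
  lmin <- EBImage::erode(img01, br)
  lmax <- EBImage::dilate(img01, br)
  rng <- lmax - lmin
  eps <- 1e-9 * max(rng)
  out <- (img01 - lmin) / (rng + eps)
  pmin(pmax(out, 0), 1)
}

# label image (integer matrix, 0 = background) -> roi_map
.label_to_rois <- function(lab, plane = 1L) {
  labs <- sort(setdiff(unique(as.integer(lab)), 0L))
  rois <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    cbind(row = idx[, 1], col = idx[, 2])
  })
  if (length(rois) == 0L)
    return(structure(list(rois = list(), centroids = matrix(0, 0, 2),
                          plane = integer(0), labels = character(0),
                          field_dim = dim(lab)),
                     class = "roi_map"))
  roi_map(rois, field_dim = dim(lab), plane = plane)
}

# roi_map -> label image
.rois_to_label <- function(rois) {
  lab <- matrix(0L, rois$field_dim[1], rois$field_dim[2])
  for (i in seq_along(rois$rois)) {
    p <- rois$rois[[i]]
    lab[cbind(p[, 1], p[, 2])] <- i
  }
  lab
}

#' Detect single-neuron ROIs in a normalized image
#'
#' In `labeled_nuclei` mode the image is thresholded at `thr_soma`,
#' touching cells are split by a distance-transform watershed, and pixels
#' below `thr_neuropil` are excluded from each ROI. In `unlabeled_nuclei`
#' mode dark nucleus seeds (below `thr_soma`) that are enclosed by bright
#' cytosol (above `thr_neuropil`) are grown onto the surrounding ring;
#' contested pixels go to the geodesically nearest seed, so ROIs stay
#' disjoint. `roi_size_opt` sets the growth radius (3 um for "bigger",
#' 1.5 um for "smaller" somata, converted by `pixel_size`).
#'
#' @param norm normalized image in `[0, 1]` (see [normalize_contrast()]).
#' @param params a [segmentation_params()].
#' @param pixel_size um per pixel.
#' @return A [roi_map()]; empty (with a warning) if nothing is found.
#' @export
detect_rois <- function(norm, params, pixel_size = 1) {
  stopifnot(min(norm) >= 0, max(norm) <= 1)
  if (params$mode == "labeled_nuclei") {
    mask <- norm > params$thr_soma
    if (!any(mask)) {
      warning("no ROIs detected")
      return(.label_to_rois(matrix(0L, nrow(norm), ncol(norm))))
    }
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    lab <- EBImage::imageData(lab)
    lab[norm < params$thr_neuropil] <- 0L
  } else {
    grow_um <- if (params$roi_size_opt == "bigger") 3 else 1.5
    grow_px <- max(2L, ceiling(grow_um / pixel_size))
    seeds <- EBImage::bwlabel(norm < params$thr_soma)
    seeds <- EBImage::imageData(seeds)
    if (max(seeds) > 0) {
      # a valid nucleus seed is enclosed by bright cytosol: most of its
      # dilated shell must exceed the neuropil-border threshold
      shell_ok <- logical(max(seeds))
      sb <- EBImage::makeBrush(2L * grow_px + 1L, "disc")
      for (l in seq_len(max(seeds))) {
        sm <- seeds == l
        shell <- EBImage::dilate(sm, sb) & !sm
        shell_ok[l] <- mean(norm[shell] > params$thr_neuropil) >= 0.5
      }
      seeds[!shell_ok[pmax(seeds, 1L)] | seeds == 0L] <- 0L
    }
    if (max(seeds) == 0) {
      warning("no ROIs detected")
      return(.label_to_rois(matrix(0L, nrow(norm), ncol(norm))))
    }
    reach <- EBImage::dilate(seeds > 0, EBImage::makeBrush(2L * grow_px + 1L,
                                                          "disc"))
    grow_mask <- reach & (norm > params$thr_neuropil | seeds > 0)
    lab <- EBImage::propagate(norm, seeds, mask = grow_mask)
    lab <- EBImage::imageData(lab)
  }
  res <- .label_to_rois(lab)
  if (length(res) == 0L) warning("no ROIs detected")
  res
}

#' Filter ROIs by morphological criteria
#'
#' Keeps ROIs whose area lies in `[area_min, area_max]` pixels, whose mean
#' normalized intensity is at least `intensity_min`, and whose perimeter
#' circularity `perimeter^2 / (4 * pi * area)` lies in
#' `[circ_min, circ_max]`. Idempotent.
#'
#' @param rois a [roi_map()].
#' @param norm the normalized image the ROIs were detected in.
#' @param params a [segmentation_params()].
#' @return The filtered [roi_map()].
#' @export
filter_rois <- function(rois, norm, params) {
  if (length(rois) == 0L) return(rois)
  lab <- .rois_to_label(rois)
  shp <- EBImage::computeFeatures.shape(lab)
  area <- shp[, "s.area"]
  per <- shp[, "s.perimeter"]
  circ <- per^2 / (4 * pi * area)
  meanI <- vapply(rois$rois, function(p) mean(norm[p]), numeric(1))
  keep <- area >= params$area_min & area <= params$area_max &
    meanI >= params$intensity_min &
    circ >= params$circ_min & circ <= params$circ_max
  subset_rois(rois, which(keep))
}

#' Subset a roi_map by ROI index
#' @param rois a [roi_map()].
#' @param idx integer indices of ROIs to keep (in order).
#' @return A [roi_map()] with the selected ROIs.
#' @export
subset_rois <- function(rois, idx) {
  structure(list(rois = rois$rois[idx],
                 centroids = rois$centroids[idx, , drop = FALSE],
                 plane = rois$plane[idx], labels = rois$labels[idx],
                 field_dim = rois$field_dim),
            class = "roi_map")
}

#' Hexagonal grid of ROIs
#'
#' Tiles the field (or a mask) with pointy-top regular hexagons of the
#' given circumscribed diameter. Each pixel belongs to at most one
#' hexagon; hexagons clipped by the mask are retained only if they keep at
#' least half of the nominal hexagon area.
#'
#' @param shape `c(rows, cols)` of the field.
#' @param diameter hexagon diameter (vertex to vertex), um.
#' @param pixel_size um per pixel.
#' @param mask optional logical matrix restricting the tiling.
#' @return A [roi_map()] of hexagonal ROIs.
#' @export
hexagonal_grid <- function(shape, diameter, pixel_size = 1, mask = NULL) {
  R <- (diameter / 2) / pixel_size
  if (2 * R < 2) stop("hexagon diameter must span at least 2 pixels")
  nr <- shape[1]; nc <- shape[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!any(mask)) return(.label_to_rois(matrix(0L, nr, nc)))
  y <- matrix(seq_len(nr) - 0.5, nr, nc)          # pixel centers
  x <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  # axial coordinates of a pointy-top hexagonal lattice, cube-rounded
  qf <- (sqrt(3) / 3 * x - y / 3) / R
  rf <- (2 / 3 * y) / R
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fixq <- dq > dr & dq > ds
  fixr <- !fixq & dr > ds
  q[fixq] <- -r[fixq] - s[fixq]
  r[fixr] <- -q[fixr] - s[fixr]
  key <- paste(q, r)
  key[!mask] <- NA
  nominal <- 3 * sqrt(3) / 2 * R^2
  tab <- table(key)
  keep <- names(tab)[tab >= 0.5 * nominal]
  lab <- matrix(0L, nr, nc)
  lab[key %in% keep] <- as.integer(factor(key[key %in% keep], levels = keep))
  .label_to_rois(lab)
}

#' Programmatically edit a ROI map
#'
#' Applies removals first, then additions; indices are re-assigned stably
#' (kept ROIs keep their relative order, additions are appended). Added
#' pixel sets must be disjoint from kept ROIs.
#'
#' @param rois a [roi_map()].
#' @param add list of pixel matrices (`row`, `col`) to append as new ROIs.
#' @param remove integer indices of ROIs to delete.
#' @return The edited [roi_map()].
#' @export
modify_rois <- function(rois, add = list(), remove = integer(0)) {
  keep <- setdiff(seq_along(rois$rois), remove)
  out <- subset_rois(rois, keep)
  if (length(add)) {
    occ <- matrix(FALSE, rois$field_dim[1], rois$field_dim[2])
    for (p in out$rois) occ[p] <- TRUE
    for (j in seq_along(add)) {
      p <- matrix(as.integer(add[[j]]), ncol = 2L)
      hit <- which(occ[p])
      if (length(hit)) {
        px <- p[hit[1], ]
        bad <- which(vapply(out$rois, function(q)
          any(q[, 1] == px[1] & q[, 2] == px[2]), logical(1)))
        stop("added pixel set ", j, " overlaps ROI ", bad[1])
      }
      occ[p] <- TRUE
    }
    out <- roi_map(c(out$rois, lapply(add, function(p)
      matrix(as.integer(p), ncol = 2L))),
      field_dim = rois$field_dim,
      plane = c(out$plane,
                rep(if (length(out$plane)) out$plane[1] else 1L,
                    length(add))),
      labels = c(out$labels, rep("", length(add))))
  }
  out
}
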