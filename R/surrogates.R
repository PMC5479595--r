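# Surrogate control assemblies: Random surrogate assemblies (RSA) place
# the same number of ROIs at random; Topographical surrogate assemblies
# (TSA) re-place the members while preserving the distribution of pairwise
# physical distances of the original assembly. Both preserve every ROI's
# own fluorescence dynamics exactly — only the membership is surrogate.

#' Random surrogate assemblies (RSA)
#'
#' For each original assembly and replicate, a uniform sample without
#' replacement of the same number of ROIs from all ROIs.
#'
#' @param assemblies an `assembly_set`.
#' @param n_roi total number of ROIs to draw from.
#' @param n_rep number of replicates (default 1000).
#' @param seed RNG seed.
#' @return A list of class `surrogate_set`: `kind = "RSA"`, `replicates`
#'   (list of lists of member index vectors), `seed`.
#' @export
random_surrogates <- function(assemblies, n_roi, n_rep = 1000, seed = 1L) {
  sizes <- lengths(assemblies$members)
  stopifnot(all(sizes <= n_roi))
  set.seed(seed)
  reps <- lapply(seq_len(n_rep), function(r)
    lapply(sizes, function(m) sort(sample.int(n_roi, m))))
  structure(list(kind = "RSA", replicates = reps, seed = seed),
            class = "surrogate_set")
}

.pairdist <- function(cent, idx, pixel_size = 1) {
  as.numeric(stats::dist(cent[idx, , drop = FALSE])) * pixel_size
}

#' Topographical surrogate assemblies (TSA)
#'
#' For each replicate and assembly: a random rigid transform (rotation,
#' optional reflection, random translation) is applied to the original
#' member centroids, each transformed point is snapped to the nearest
#' not-yet-used ROI centroid, and the replicate is accepted only if the
#' two-sample Kolmogorov-Smirnov distance between the original and
#' surrogate pairwise-distance distributions is at most `ks_tol`.
#'
#' @param assemblies an `assembly_set`.
#' @param rois a [roi_map()] providing centroids.
#' @param n_rep number of replicates.
#' @param ks_tol acceptance bound on the pairwise-distance KS distance
#'   (default 0.1).
#' @param pixel_size um per pixel (distances in um).
#' @param seed RNG seed.
#' @param max_attempts transform attempts per assembly per replicate.
#' @return A `surrogate_set` with `kind = "TSA"`.
#' @export
topographic_surrogates <- function(assemblies, rois, n_rep = 1000,
                                   ks_tol = 0.1, pixel_size = 1,
                                   seed = 1L, max_attempts = 1000L) {
  cent <- rois$centroids
  n <- nrow(cent)
  set.seed(seed)
  one <- function(members) {
    d_orig <- .pairdist(cent, members, pixel_size)
    for (att in seq_len(max_attempts)) {
      th <- stats::runif(1, 0, 2 * pi)
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      if (stats::runif(1) < 0.5) Rm[, 1] <- -Rm[, 1]      # reflection
      pts <- cent[members, , drop = FALSE]
      ctr <- colMeans(pts)
      moved <- sweep(pts, 2, ctr) %*% Rm
      # translate so the rotated constellation stays within the span of
      # the ROI centroids; snapping against the field edge would distort
      # the pairwise distances
      lo <- apply(cent, 2, min) - apply(moved, 2, min)
      hi <- apply(cent, 2, max) - apply(moved, 2, max)
      lo <- pmin(lo, hi)
      hi2 <- pmax(lo, hi)
      tgt <- c(stats::runif(1, lo[1], hi2[1]),
               stats::runif(1, lo[2], hi2[2]))
      moved <- sweep(moved, 2, tgt, `+`)
      used <- logical(n)
      pick <- integer(nrow(moved))
      ok <- TRUE
      for (j in seq_len(nrow(moved))) {
        d2 <- (cent[, 1] - moved[j, 1])^2 + (cent[, 2] - moved[j, 2])^2
        d2[used] <- Inf
        pick[j] <- which.min(d2)
        used[pick[j]] <- TRUE
      }
      d_surr <- .pairdist(cent, pick, pixel_size)
      ks <- suppressWarnings(stats::ks.test(d_orig, d_surr)$statistic)
      if (ks <= ks_tol) return(sort(pick))
    }
    stop("TSA acceptance impossible after ", max_attempts,
         " attempts (field too small or assembly too rigid)")
  }
  reps <- lapply(seq_len(n_rep), function(r)
    lapply(assemblies$members, one))
  structure(list(kind = "TSA", replicates = reps, seed = seed,
                 ks_tol = ks_tol),
            class = "surrogate_set")
}

#' Per-ROI / per-pair feature constructors for [pool_compare()]
#'
#' `feature_mean_activity` gives each ROI's mean activity per frame (use
#' `masked_dff` of a raster for mean significant dF/F0). `feature_pairwise_correlation`
#' gives the Pearson correlation of every member pair.
#' `feature_pairwise_distance` gives the physical distance of every member
#' pair in um.
#'
#' @param M `N x T` activity matrix (dff or masked dff).
#' @return A function mapping a member index vector to feature values.
#' @export
feature_mean_activity <- function(M) {
  m <- rowMeans(M, na.rm = TRUE)
  function(members) m[members]
}

#' @rdname feature_mean_activity
#' @export
feature_pairwise_correlation <- function(M) {
  function(members) {
    C <- stats::cor(t(M[members, , drop = FALSE]),
                    use = "pairwise.complete.obs")
    C[upper.tri(C)]
  }
}

#' @rdname feature_mean_activity
#' @param rois a [roi_map()].
#' @param pixel_size um per pixel.
#' @export
feature_pairwise_distance <- function(rois, pixel_size = 1) {
  function(members) .pairdist(rois$centroids, members, pixel_size)
}

#' Compare pooled assembly features against surrogates
#'
#' Pools a per-ROI or per-pair feature over all original assemblies and
#' over all surrogate replicates, builds normalized frequency histograms
#' on shared Freedman-Diaconis bins, and reports the two-sample
#' Kolmogorov-Smirnov p-value.
#'
#' @param assemblies an `assembly_set`.
#' @param surrogates a `surrogate_set`.
#' @param feature a function mapping a member index vector to numeric
#'   feature values (see [feature_mean_activity()] and friends).
#' @return A list: `original`, `surrogate` (pooled values), `breaks`,
#'   `density_original`, `density_surrogate`, `ks_statistic`, `p_value`.
#' @export
pool_compare <- function(assemblies, surrogates, feature) {
  orig <- unlist(lapply(assemblies$members, feature))
  surr <- unlist(lapply(surrogates$replicates,
                        function(rep) lapply(rep, feature)))
  if (!length(orig) || !length(surr))
    stop("feature produced no values")
  pooled <- c(orig, surr)
  bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  if (bw <= 0) bw <- diff(range(pooled)) / 30 + 1e-12
  breaks <- seq(min(pooled) - bw, max(pooled) + bw, by = bw)
  h_o <- graphics::hist(orig, breaks = breaks, plot = FALSE)
  h_s <- graphics::hist(surr, breaks = breaks, plot = FALSE)
  if (identical(orig, surr)) {
    ks <- 0; p <- 1
  } else {
    kt <- suppressWarnings(stats::ks.test(orig, surr))
    ks <- unname(kt$statistic); p <- kt$p.value
  }
  list(original = orig, surrogate = surr, breaks = breaks,
       density_original = h_o$density, density_surrogate = h_s$density,
       ks_statistic = ks, p_value = p)
}
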