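# Unsupervised detection of non-exclusive neuronal assemblies.
#
# The PCA-promax method: z-score each ROI's activity, eigen-decompose the
# ROI x ROI correlation matrix, keep components whose eigenvalues exceed
# the Marchenko-Pastur upper edge (with a finite-size correction), rotate
# the retained loadings obliquely (varimax then promax), threshold the
# z-scored rotated loadings at zMax to define (possibly overlapping)
# member sets, merge near-duplicate components, and keep only assemblies
# that are significantly correlated and synchronous against membership-
# shuffled nulls. k-means and hierarchical clustering are provided as
# exclusive-partition baselines.

#' Z-scored activity matrix
#'
#' Z-scores each ROI's activity over valid (non-artifact) frames, from
#' either the raw dF/F0 or the significant-transient-masked dF/F0.
#' Zero-variance ROIs are dropped with a report.
#'
#' @param x a `dff_traces` or a `transient_raster` (uses `masked_dff`).
#' @param source `"dff"` or `"significant"`; defaults to what `x` is.
#' @return A list of class `activity_matrix`: `Z` (`N x T`, rows mean 0
#'   and SD 1 over valid frames), `source`, `kept` (original ROI indices),
#'   `bad_frames`.
#' @export
build_activity <- function(x, source = NULL) {
  if (inherits(x, "transient_raster")) {
    M <- x$masked_dff
    source <- source %||% "significant"
    bad <- integer(0)
  } else {
    M <- x$dff
    source <- source %||% "dff"
    bad <- x$bad_frames
  }
  if (nrow(M) < 2L) stop("at least 2 ROIs required")
  ok <- setdiff(seq_len(ncol(M)), bad)
  mu <- rowMeans(M[, ok, drop = FALSE], na.rm = TRUE)
  sd_ <- apply(M[, ok, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  kept <- which(is.finite(sd_) & sd_ > 0)
  if (length(kept) == 0L) stop("all ROIs have zero variance")
  if (length(kept) < nrow(M))
    message(nrow(M) - length(kept), " zero-variance ROI(s) dropped")
  Z <- (M[kept, , drop = FALSE] - mu[kept]) / sd_[kept]
  if (length(bad)) Z[, bad] <- NA_real_
  if (ncol(Z) < nrow(Z))
    warning("T < N: random-matrix eigenvalue threshold is unreliable")
  structure(list(Z = Z, source = source, kept = kept, bad_frames = bad),
            class = "activity_matrix")
}

#' PCA with a Marchenko-Pastur component threshold
#'
#' Eigen-decomposes the ROI x ROI correlation matrix and retains the
#' components whose eigenvalues exceed
#' `lambda_max = (1 + sqrt(N / T))^2 + N^(-2/3)` — the Marchenko-Pastur
#' upper edge for an `N x T` random matrix plus a Tracy-Widom-scale
#' finite-size correction — the theoretical bound below which eigenvalues
#' are indistinguishable from noise.
#'
#' @param act an `activity_matrix`.
#' @param finite_size_correction add the `N^(-2/3)` term (default `TRUE`).
#' @return A list of class `pca_space`: `eigenvalues` (descending),
#'   `loadings` (`N x n_retained`, eigenvectors scaled by
#'   `sqrt(eigenvalue)`), `vectors` (unit eigenvectors), `lambda_max`,
#'   `n_retained`, `n_roi`, `n_frames`.
#' @export
pca_mp <- function(act, finite_size_correction = TRUE) {
  Z <- act$Z
  ok <- setdiff(seq_len(ncol(Z)), act$bad_frames)
  Z <- Z[, ok, drop = FALSE]
  n <- nrow(Z); nt <- ncol(Z)
  stopifnot(n >= 2L, nt >= 2L)
  C <- stats::cor(t(Z))
  eg <- eigen(C, symmetric = TRUE)
  lambda_max <- (1 + sqrt(n / nt))^2 +
    if (finite_size_correction) n^(-2 / 3) else 0
  keep <- which(eg$values > lambda_max)
  loadings <- if (length(keep))
    eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(eg$values[keep]), length(keep))
  else matrix(0, n, 0)
  structure(list(eigenvalues = eg$values,
                 loadings = loadings,
                 vectors = eg$vectors[, keep, drop = FALSE],
                 lambda_max = lambda_max,
                 n_retained = length(keep), n_roi = n, n_frames = nt),
            class = "pca_space")
}

#' Oblique (promax) rotation of retained components
#'
#' Kaiser-normalized varimax rotation of the retained loadings followed by
#' a promax oblique target rotation of power `kappa`, which sparsely
#' concentrates loadings along non-orthogonal rotated components —
#' relaxing PCA's orthogonality so overlapping assemblies can each claim a
#' component. Component signs are flipped so each component's
#' largest-magnitude loading is positive.
#'
#' @param pca a `pca_space`.
#' @param kappa promax power (default 4).
#' @return A list of class `rotated_space`: `loadings`
#'   (`N x n_retained`), `components` (unit-norm rotated component
#'   vectors, `N x n_retained`), `kappa`.
#' @export
promax_rotate <- function(pca, kappa = 4) {
  if (pca$n_retained == 0L) stop("no informative components to rotate")
  L <- pca$loadings
  if (ncol(L) == 1L) {
    if (max(L) < max(-L)) L <- -L
    comp <- L / sqrt(sum(L^2))
    return(structure(list(loadings = L, components = comp, kappa = kappa),
                     class = "rotated_space"))
  }
  vm <- stats::varimax(L, normalize = TRUE)
  pm <- stats::promax(vm$loadings, m = kappa)
  rot <- unclass(pm$loadings)
  # sign convention: dominant loading positive
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  comps <- apply(rot, 2, function(v) v / sqrt(sum(v^2)))
  structure(list(loadings = rot, components = comps, kappa = kappa),
            class = "rotated_space")
}

#' Z-score rotated loadings per component
#' @param rotated a `rotated_space`.
#' @return `N x n_components` matrix of loadings z-scored across ROIs
#'   within each component (so maxima are comparable across components).
#' @export
zscore_loadings <- function(rotated) {
  apply(rotated$loadings, 2, function(v) (v - mean(v)) / stats::sd(v))
}

#' Select the zMax membership threshold
#'
#' Takes each ROI's maximal z-scored loading over components, builds a
#' kernel-density estimate, and returns the location of the first local
#' minimum of the density (the first valley after the leftmost mode):
#' the valley separating the non-member bulk from the high-loading
#' members. A `manual` value overrides the automatic choice.
#'
#' @param rotated a `rotated_space` (or the matrix from
#'   [zscore_loadings()]).
#' @param smooth bandwidth scale factor applied to Silverman's rule
#'   (default 1).
#' @param manual optional manual threshold overriding the estimate.
#' @return The zMax threshold (scalar).
#' @export
select_zmax <- function(rotated, smooth = 1, manual = NULL) {
  if (!is.null(manual)) return(manual)
  zl <- if (is.matrix(rotated)) rotated else zscore_loadings(rotated)
  mx <- apply(zl, 1, max)
  d <- stats::density(mx, bw = stats::bw.nrd0(mx) * smooth)
  y <- d$y
  dy <- diff(y)
  # interior local minima: descending into i, non-descending out of i
  mins <- which(dy[-1] > 0 & dy[-length(dy)] <= 0) + 1L
  maxs <- which(dy[-1] <= 0 & dy[-length(dy)] > 0) + 1L
  first_max <- if (length(maxs)) maxs[1] else which.max(y)
  mins <- mins[mins > first_max]
  if (!length(mins))
    stop("no local minimum in the loading-maxima density: ",
         "choose zMax manually")
  d$x[mins[1]]
}

#' Build assemblies from rotated loadings at a threshold
#'
#' A ROI belongs to an assembly when its z-scored loading on that rotated
#' component exceeds `zmax`; member sets may overlap (non-exclusive).
#' Empty member sets are dropped.
#'
#' @param rotated a `rotated_space`.
#' @param zmax membership threshold on z-scored loadings.
#' @return A list of class `assembly_set`: `members` (list of integer
#'   ROI-index vectors), `components` (unit component per assembly),
#'   `zmax`; plus empty `activity`/`significance` slots filled by
#'   [assembly_activity()] / [test_significance()].
#' @export
build_assemblies <- function(rotated, zmax) {
  stopifnot(is.finite(zmax) || is.infinite(zmax))
  zl <- zscore_loadings(rotated)
  members <- lapply(seq_len(ncol(zl)), function(j) which(zl[, j] > zmax))
  keep <- lengths(members) > 0L
  if (!any(keep)) warning("no assembly has any member at this zMax")
  structure(list(members = members[keep],
                 components = rotated$components[, keep, drop = FALSE],
                 zmax = zmax, activity = NULL, significance = NULL),
            class = "assembly_set")
}

#' @export
print.assembly_set <- function(x, ...) {
  cat(sprintf("assembly_set: %d assemblies, sizes [%s]\n",
              length(x$members),
              paste(lengths(x$members), collapse = ", ")))
  invisible(x)
}

#' Merge assemblies with near-identical components
#'
#' While any two assemblies' unit component vectors have a dot product
#' above `dot_thr` (default 0.6), the pair with the largest dot product
#' (ties to the lower index pair) is merged: members are unioned and the
#' component becomes the renormalized mean; the scan then restarts.
#'
#' @param assemblies an `assembly_set`.
#' @param dot_thr merge threshold on component dot products (default 0.6).
#' @return The merged `assembly_set`.
#' @export
merge_similar <- function(assemblies, dot_thr = 0.6) {
  members <- assemblies$members
  comps <- assemblies$components
  repeat {
    k <- length(members)
    if (k < 2L) break
    G <- crossprod(comps)
    diag(G) <- -Inf
    best <- which(G == max(G), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    if (G[best[1], best[2]] <= dot_thr) break
    a <- min(best); b <- max(best)
    members[[a]] <- sort(union(members[[a]], members[[b]]))
    v <- (comps[, a] + comps[, b]) / 2
    comps[, a] <- v / sqrt(sum(v^2))
    members[[b]] <- NULL
    comps <- comps[, -b, drop = FALSE]
  }
  structure(list(members = members, components = comps,
                 zmax = assemblies$zmax, activity = assemblies$activity,
                 significance = assemblies$significance),
            class = "assembly_set")
}

#' Keep only significantly correlated and synchronous assemblies
#'
#' For each assembly of size `m`, two statistics are compared against
#' `n_shuffle` shuffled assemblies (random `m`-ROI subsets; ROI activity
#' itself is untouched): the mean pairwise correlation among members, and
#' the peak per-frame count of co-active members (z > 2). Empirical
#' p-values are `(1 + #null >= observed) / (1 + n_shuffle)`; assemblies
#' are kept when both are below `alpha`. Singleton assemblies are dropped
#' with a report.
#'
#' @param assemblies an `assembly_set`.
#' @param act the `activity_matrix` the assemblies were detected in.
#' @param n_shuffle number of shuffled assemblies (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return The filtered `assembly_set`; per-assembly p-values (all
#'   assemblies, pre-filter) in `$significance`.
#' @export
test_significance <- function(assemblies, act, n_shuffle = 1000,
                              alpha = 0.05, seed = 1L) {
  stopifnot(n_shuffle >= 100)
  set.seed(seed)
  Z <- act$Z
  ok <- setdiff(seq_len(ncol(Z)), act$bad_frames)
  Z <- Z[, ok, drop = FALSE]
  n <- nrow(Z)
  co <- Z > 2
  mean_pair_cor <- function(idx) {
    C <- stats::cor(t(Z[idx, , drop = FALSE]))
    mean(C[upper.tri(C)])
  }
  peak_coactive <- function(idx) max(colSums(co[idx, , drop = FALSE]))
  members <- assemblies$members
  sizes <- lengths(members)
  if (any(sizes < 2L))
    message(sum(sizes < 2L), " singleton assembly(ies) dropped")
  p_cor <- p_syn <- rep(NA_real_, length(members))
  for (a in seq_along(members)) {
    m <- sizes[a]
    if (m < 2L) next
    obs_cor <- mean_pair_cor(members[[a]])
    obs_syn <- peak_coactive(members[[a]])
    null_cor <- null_syn <- numeric(n_shuffle)
    for (s in seq_len(n_shuffle)) {
      idx <- sample.int(n, m)
      null_cor[s] <- mean_pair_cor(idx)
      null_syn[s] <- peak_coactive(idx)
    }
    p_cor[a] <- (1 + sum(null_cor >= obs_cor)) / (1 + n_shuffle)
    p_syn[a] <- (1 + sum(null_syn >= obs_syn)) / (1 + n_shuffle)
  }
  keep <- which(!is.na(p_cor) & p_cor < alpha & p_syn < alpha)
  structure(list(members = members[keep],
                 components = assemblies$components[, keep, drop = FALSE],
                 zmax = assemblies$zmax, activity = NULL,
                 significance = data.frame(assembly = seq_along(members),
                                           size = sizes, p_correlation = p_cor,
                                           p_synchrony = p_syn,
                                           kept = seq_along(members) %in% keep)),
            class = "assembly_set")
}

#' Exclusive clustering baselines
#'
#' Partitions ROIs into `k` disjoint clusters by k-means (10 restarts,
#' best inertia) or hierarchical clustering (correlation distance, average
#' linkage) on the rows of `Z`, optionally projected onto the retained
#' principal components first.
#'
#' @param act an `activity_matrix`.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param k number of clusters (2..N).
#' @param reduce project onto MP-retained PCs before clustering.
#' @param seed RNG seed (k-means restarts).
#' @return An `assembly_set` whose member sets form a disjoint partition.
#' @export
cluster_baseline <- function(act, method = c("kmeans", "hierarchical"),
                             k, reduce = FALSE, seed = 1L) {
  method <- match.arg(method)
  Z <- act$Z
  ok <- setdiff(seq_len(ncol(Z)), act$bad_frames)
  Z <- Z[, ok, drop = FALSE]
  n <- nrow(Z)
  stopifnot(k >= 2L, k <= n)
  X <- Z
  if (reduce) {
    pca <- pca_mp(act)
    if (pca$n_retained == 0L) stop("reduce = TRUE but no retained components")
    X <- pca$loadings
  }
  if (k == n) {
    grp <- seq_len(n)               # singleton clusters, no fit needed
  } else if (method == "kmeans") {
    set.seed(seed)
    cl <- tryCatch(stats::kmeans(X, centers = k, nstart = 10,
                                 iter.max = 100),
                   error = function(e) stop("kmeans did not converge: ",
                                            conditionMessage(e)))
    grp <- cl$cluster
  } else {
    D <- stats::as.dist(1 - stats::cor(t(X)))
    grp <- stats::cutree(stats::hclust(D, method = "average"), k = k)
  }
  members <- lapply(seq_len(k), function(g) which(grp == g))
  members <- members[lengths(members) > 0L]
  structure(list(members = members,
                 components = matrix(NA_real_, n, length(members)),
                 zmax = NA_real_, activity = NULL, significance = NULL),
            class = "assembly_set")
}

#' Assembly activation time courses
#'
#' `activation[a, t]` is the mean z-scored activity over assembly `a`'s
#' members at frame `t`.
#'
#' @param assemblies an `assembly_set`.
#' @param act an `activity_matrix`.
#' @return `n_assemblies x T` matrix.
#' @export
assembly_activity <- function(assemblies, act) {
  t(vapply(assemblies$members,
           function(idx) colMeans(act$Z[idx, , drop = FALSE]),
           numeric(ncol(act$Z))))
}

#' Full PCA-promax assembly detection
#'
#' Convenience pipeline: [build_activity()] -> [pca_mp()] ->
#' [promax_rotate()] -> [select_zmax()] -> [build_assemblies()] ->
#' [merge_similar()] -> [test_significance()], returning the final
#' `assembly_set` with activation traces attached.
#'
#' @param x a `dff_traces` or `transient_raster`.
#' @param kappa promax power.
#' @param zmax manual threshold (default: automatic first-minimum rule).
#' @param smooth KDE bandwidth scale for the automatic zMax.
#' @param dot_thr component-merge threshold.
#' @param n_shuffle,alpha,seed significance-test settings.
#' @return An `assembly_set` (members indexed into the kept ROIs of the
#'   activity matrix; the mapping is in `$kept`).
#' @export
detect_assemblies <- function(x, kappa = 4, zmax = NULL, smooth = 1,
                              dot_thr = 0.6, n_shuffle = 1000,
                              alpha = 0.05, seed = 1L) {
  act <- build_activity(x)
  pca <- pca_mp(act)
  rot <- promax_rotate(pca, kappa = kappa)
  z <- select_zmax(rot, smooth = smooth, manual = zmax)
  asm <- build_assemblies(rot, z)
  asm <- merge_similar(asm, dot_thr = dot_thr)
  asm <- test_significance(asm, act, n_shuffle = n_shuffle, alpha = alpha,
                           seed = seed)
  asm$activity <- assembly_activity(asm, act)
  asm$kept <- act$kept
  asm
}
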