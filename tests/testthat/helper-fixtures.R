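# shared fixture builders and small oracles

# wrap a plain dF/F0 matrix as dff_traces (for stages downstream of
# trace extraction)
as_dff <- function(M, bad_frames = integer(0)) {
  structure(list(dff = M, F0 = matrix(1, nrow(M), ncol(M)),
                 f0_method = "window", bad_frames = bad_frames),
            class = "dff_traces")
}

as_activity <- function(Z, bad_frames = integer(0)) {
  structure(list(Z = Z, source = "dff", kept = seq_len(nrow(Z)),
                 bad_frames = bad_frames),
            class = "activity_matrix")
}

# intersection-over-union of two pixel sets (brute force)
iou <- function(a, b) {
  ka <- paste(a[, 1], a[, 2]); kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# z-scored activity with planted correlated groups
planted_Z <- function(n = 120, nt = 1500, groups = list(1:20, 31:55),
                      strength = 1, noise = 0.5, seed = 1) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * nt, 0, noise), n, nt)
  for (g in groups) {
    common <- stats::rnorm(nt)
    Z[g, ] <- Z[g, ] + strength * matrix(rep(common, each = length(g)),
                                         length(g))
  }
  t(scale(t(Z)))
}

# a simple blob image: planted disk cells on a flat background
blob_image <- function(cells, background = 0.1, level = 1,
                       nucleus_level = 0.25, noise = 0.02, seed = 1) {
  set.seed(seed)
  img <- matrix(background, cells$field[1], cells$field[2])
  for (i in seq_along(cells$masks)) {
    img[cells$masks[[i]]] <- level
    if (!is.null(cells$nucleus[[i]]))
      img[cells$nucleus[[i]]] <- nucleus_level * level
  }
  img + matrix(stats::rnorm(length(img), 0, noise), nrow(img))
}
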