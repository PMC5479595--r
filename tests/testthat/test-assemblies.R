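test_that("activity matrices are row-standardized over valid frames", {
  set.seed(10)
  M <- matrix(rnorm(400, 3, 2), 4, 100)
  M[2, ] <- 5                     # zero variance: dropped
  d <- as_dff(M, bad_frames = c(7L, 8L))
  expect_message(act <- build_activity(d), "zero-variance")
  ok <- setdiff(1:100, c(7, 8))
  expect_lt(max(abs(rowMeans(act$Z[, ok]))), 1e-10)
  expect_lt(max(abs(apply(act$Z[, ok], 1, sd) - 1)), 1e-10)
  expect_equal(act$kept, c(1L, 3L, 4L))
  expect_error(build_activity(as_dff(matrix(1, 3, 50))), "zero variance")
})

test_that("the eigenvalue threshold follows the adopted closed form", {
  # N = T: lambda_max = 4 + N^(-2/3)
  set.seed(11)
  Z <- matrix(rnorm(50 * 50), 50, 50)
  p <- pca_mp(as_activity(t(scale(t(Z)))))
  expect_equal(p$lambda_max, 4 + 50^(-2 / 3), tolerance = 1e-12)
  # eigenvalue sum equals the correlation-matrix trace (= N)
  expect_lt(abs(sum(p$eigenvalues) - 50), 1e-6 * 50)
})

test_that("MP threshold rejects i.i.d. noise and keeps a planted component", {
  set.seed(12)
  frac <- replicate(10, {
    Z <- t(scale(t(matrix(rnorm(100 * 1000), 100, 1000))))
    pca_mp(as_activity(Z))$n_retained / 100
  })
  expect_lt(mean(frac), 0.01)
  Z <- planted_Z(n = 200, nt = 2000, groups = list(1:20), strength = 3,
                 noise = 0.1, seed = 13)
  p <- pca_mp(as_activity(Z))
  expect_equal(p$n_retained, 1)
  expect_setequal(order(abs(p$loadings[, 1]), decreasing = TRUE)[1:20], 1:20)
})

test_that("promax concentrates loadings and allows oblique structure", {
  # two orthogonal planted assemblies
  Z <- planted_Z(groups = list(1:20, 31:55), strength = 2, noise = 0.3,
                 seed = 14)
  p <- pca_mp(as_activity(Z))
  expect_gte(p$n_retained, 2)
  rot <- promax_rotate(p, kappa = 4)
  zl <- zscore_loadings(rot)
  # each of the two leading components is concentrated on one group
  g1 <- rowMeans(abs(rot$loadings[1:20, 1:2, drop = FALSE]))
  top2 <- order(colSums(abs(rot$loadings[1:20, ])), decreasing = TRUE)[1]
  w_in <- mean(abs(rot$loadings[1:20, top2]))
  w_out <- mean(abs(rot$loadings[56:120, top2]))
  expect_lt(w_out, 0.1 * w_in)
  # single retained component: rotation is identity up to sign
  Z1 <- planted_Z(n = 150, groups = list(1:25), strength = 3, noise = 0.2,
                  seed = 15)
  p1 <- pca_mp(as_activity(Z1))
  r1 <- promax_rotate(p1)
  expect_equal(abs(r1$loadings), abs(p1$loadings), tolerance = 1e-9)
  expect_error(promax_rotate(structure(list(n_retained = 0),
                                       class = "pca_space")),
               "no informative")
  # overlapping assemblies: rotated components are non-orthogonal
  set.seed(16)
  Zo <- planted_Z(n = 150, nt = 2000, groups = list(1:25, 21:45),
                  strength = 2, noise = 0.3, seed = 16)
  po <- pca_mp(as_activity(Zo))
  ro <- promax_rotate(po)
  G <- crossprod(ro$components[, 1:2])
  expect_gt(abs(G[1, 2]), 0)
})

test_that("zMax selection finds the bimodal valley and honors overrides", {
  set.seed(17)
  mx <- matrix(c(rnorm(80, 0, 1), rnorm(20, 5, 1)), ncol = 1)
  fake <- structure(list(loadings = mx * sd(mx) + mean(mx)),
                    class = "rotated_space")
  z <- select_zmax(structure(list(loadings = mx), class = "rotated_space"))
  # back on the raw scale of mx via the per-component z-score
  zs <- (mx - mean(mx)) / sd(mx)
  thr_raw <- z * sd(mx) + mean(mx)
  expect_gt(thr_raw, 1.5); expect_lt(thr_raw, 3.5)
  expect_equal(select_zmax(NULL, manual = 2), 2)
  uni <- structure(list(loadings = matrix(rnorm(200), ncol = 1)),
                   class = "rotated_space")
  expect_error(select_zmax(uni, smooth = 3), "manual")
})

test_that("membership thresholding is monotone and non-exclusive", {
  Zo <- planted_Z(n = 150, nt = 2000, groups = list(1:25, 21:45),
                  strength = 2, noise = 0.3, seed = 18)
  act <- as_activity(Zo)
  rot <- promax_rotate(pca_mp(act))
  expect_warning(a_inf <- build_assemblies(rot, Inf), "no assembly")
  expect_length(a_inf$members, 0)
  a_lo <- build_assemblies(rot, -Inf)
  expect_true(all(lengths(a_lo$members) == 150))
  z <- select_zmax(rot)
  a <- build_assemblies(rot, z)
  # monotone: raising zmax never grows any member set
  a_hi <- build_assemblies(rot, z + 0.5)
  for (j in seq_along(a_hi$members))
    expect_true(all(a_hi$members[[j]] %in% a$members[[j]]))
  # the shared ROIs 21:25 appear in two assemblies (non-exclusive)
  asm <- merge_similar(a, 0.6)
  counts <- table(unlist(asm$members))
  expect_true(any(counts[as.character(21:25)] >= 2))
})

test_that("near-duplicate components merge at the 0.6 dot-product rule", {
  v1 <- c(1, 0, 0); v2 <- c(0.9, 0.1, 0); v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(0, 0, 1)
  asm <- structure(list(members = list(1:3, 2:4, 7:9),
                        components = cbind(v1, v2, v3), zmax = 2,
                        activity = NULL, significance = NULL),
                   class = "assembly_set")
  m <- merge_similar(asm, 0.6)
  expect_length(m$members, 2)
  expect_equal(m$members[[1]], 1:4)
  # orthogonal components never merge
  asm2 <- structure(list(members = list(1:2, 3:4),
                         components = diag(2), zmax = 2,
                         activity = NULL, significance = NULL),
                    class = "assembly_set")
  expect_length(merge_similar(asm2, 0.6)$members, 2)
})

test_that("shuffle test keeps correlated assemblies and rejects random ones", {
  set.seed(19)
  Z <- planted_Z(n = 100, nt = 1500, groups = list(1:15), strength = 1.2,
                 noise = 1, seed = 19)
  act <- as_activity(Z)
  asm <- structure(list(members = list(1:15, sample(100, 15)),
                        components = matrix(0, 100, 2), zmax = 2,
                        activity = NULL, significance = NULL),
                   class = "assembly_set")
  out <- test_significance(asm, act, n_shuffle = 1000, alpha = 0.05,
                           seed = 20)
  sig <- out$significance
  expect_lte(sig$p_correlation[1], 0.001)
  expect_true(sig$kept[1])
  # null calibration: a random member set is rejected at ~ alpha
  expect_gt(sig$p_correlation[2], 0.05)
})

test_that("baseline clustering partitions exclusively and is seed-stable", {
  # two well-separated exclusive clusters covering all ROIs
  Z <- planted_Z(n = 80, nt = 1200, groups = list(1:40, 41:80),
                 strength = 3, noise = 0.3, seed = 21)
  act <- as_activity(Z)
  for (m in c("kmeans", "hierarchical")) {
    cl <- cluster_baseline(act, m, k = 2, seed = 5)
    all_m <- unlist(cl$members)
    expect_false(any(duplicated(all_m)))      # exclusive partition
    expect_setequal(all_m, 1:80)
    for (g in list(1:40, 41:80)) {
      best <- max(vapply(cl$members, jaccard, numeric(1), a = g))
      expect_gte(best, 0.95)
    }
  }
  k1 <- cluster_baseline(act, "kmeans", k = 4, seed = 9)
  k2 <- cluster_baseline(act, "kmeans", k = 4, seed = 9)
  expect_identical(k1$members, k2$members)
  kN <- cluster_baseline(act, "kmeans", k = 80, seed = 9)
  expect_true(all(lengths(kN$members) == 1))
})

test_that("assembly activation is the member-mean z-score", {
  Z <- matrix(rnorm(300), 3, 100)
  act <- as_activity(Z)
  asm <- structure(list(members = list(2L, 1:3), components = NULL),
                   class = "assembly_set")
  A <- assembly_activity(asm, act)
  expect_equal(A[1, ], Z[2, ])
  expect_equal(A[2, ], colMeans(Z))
})
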