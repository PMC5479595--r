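test_that("trace extraction averages ROI pixels and masks bad frames", {
  dat <- array(7, c(10, 10, 5))
  dat[3, 3, ] <- c(1, 2, 3, 4, 5)
  mv <- movie_stack(dat, 2, 1, bad_frames = 4L)
  rois <- roi_map(list(cbind(3L, 3L), cbind(c(8L, 8L), c(8L, 9L))),
                  field_dim = c(10, 10))
  tr <- extract_traces(mv, rois)
  expect_equal(tr$F[1, c(1:3, 5)], c(1, 2, 3, 5))  # single-pixel ROI
  expect_true(is.na(tr$F[1, 4]))                    # artifact masked
  expect_equal(tr$F[2, 1], 7)                       # constant movie
})

test_that("perisomatic masks equal brute-force disk-minus-ROIs enumeration", {
  rois <- roi_map(list(cbind(rep(10:12, 3), rep(10:12, each = 3)),
                       cbind(rep(14:15, 2), rep(14:15, each = 2))),
                  field_dim = c(40, 40))
  masks <- perisomatic_masks(rois, radius = 6, pixel_size = 1)
  occ <- matrix(FALSE, 40, 40)
  for (p in rois$rois) occ[p] <- TRUE
  for (i in 1:2) {
    ctr <- rois$centroids[i, ]
    g <- expand.grid(row = 1:40, col = 1:40)
    inside <- (g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= 36
    brute <- g[inside & !occ[cbind(g$row, g$col)], ]
    expect_equal(nrow(masks[[i]]), nrow(brute))
    expect_setequal(paste(masks[[i]][, 1], masks[[i]][, 2]),
                    paste(brute$row, brute$col))
  }
  # single ROI: mask excludes only its own pixels
  r1 <- roi_map(list(cbind(20L, 20L)), field_dim = c(40, 40))
  m1 <- perisomatic_masks(r1, 6, 1)[[1]]
  expect_false(any(m1[, 1] == 20 & m1[, 2] == 20))
})

test_that("neuropil correction is linear and exactly inverts construction", {
  set.seed(1)
  n <- rnorm(200)
  s <- matrix(rnorm(600), 3, 200)
  meas <- fluo_traces(sweep(s, 2, 0.9 * n, `+`), "raw")
  npil <- fluo_traces(matrix(rep(n, each = 3), 3, 200), "neuropil")
  corr <- neuropil_correct(meas, npil, 0.9)
  expect_equal(corr$F, s, tolerance = 1e-12)
  expect_equal(corr$source, "corrected")
  # alpha = 0 is the identity
  expect_equal(neuropil_correct(meas, npil, 0)$F, meas$F)
  # linearity in alpha
  two_step <- neuropil_correct(neuropil_correct(meas, npil, 0.4), npil, 0.5)
  expect_equal(two_step$F, neuropil_correct(meas, npil, 0.9)$F,
               tolerance = 1e-12)
})

test_that("sanity report flags over-subtraction, saturation and flat traces", {
  set.seed(2)
  clean <- fluo_traces(matrix(abs(rnorm(400)) + 1, 2, 200), "corrected")
  expect_equal(nrow(sanity_check(clean)), 0)
  F <- matrix(abs(rnorm(800)) + 1, 4, 200)
  F[1, 1:20] <- -0.5                       # 10% negative
  F[2, 1:10] <- 65535                      # >= 1% saturated
  F[3, ] <- 2                              # zero variance
  rep_ <- sanity_check(fluo_traces(F, "corrected"),
                       saturation_level = 65535)
  expect_true(any(rep_$roi == 1 & rep_$flag == "negative"))
  expect_true(any(rep_$roi == 2 & rep_$flag == "saturated"))
  expect_true(any(rep_$roi == 3 & rep_$flag == "zero_variance"))
  expect_false(any(rep_$roi == 4))
})

test_that("window F0 equals brute-force means, per event and globally", {
  fr <- 4
  F <- matrix(seq_len(40), 2, 20, byrow = TRUE)
  tr <- fluo_traces(F, "corrected")
  # global window [0, 0.5): frames 1..2 at 4 Hz
  expect_equal(estimate_f0_window(tr, fr, c(0, 0.5)),
               rowMeans(F[, 1:2]))
  # constant trace: F0 = the constant
  trc <- fluo_traces(matrix(3, 1, 20), "corrected")
  expect_equal(estimate_f0_window(trc, fr, c(0, 5)), 3)
  # event-wise: window [-0.5, 0) before each event
  ev <- event_timeline(c(1, 3), c(0, 1))
  f0 <- estimate_f0_window(tr, fr, c(-0.5, 0), events = ev)
  brute <- cbind(rowMeans(F[, 3:4]), rowMeans(F[, 11:12]))
  expect_equal(unname(f0), unname(brute))
})

test_that("F_smooth tracks slow drift and ignores sparse transients", {
  set.seed(3)
  fr <- 5; nt <- 1500
  t <- (seq_len(nt) - 1) / fr
  drift <- 100 + 0.05 * t
  x <- drift + rnorm(nt, 0, 0.5)
  spk <- sort(sample(nt - 30, 12))
  for (f in spk) x[f:(f + 29)] <- x[f:(f + 29)] + 8 * exp(-(0:29) / (fr * 2))
  tr <- fluo_traces(matrix(x, 1, nt), "corrected")
  fs <- estimate_f_smooth(tr, fr, window = 30, percentile = 8)
  mid <- 200:1300
  expect_lt(max(abs(fs[1, mid] - drift[mid])), 1.5)
  resid <- x[mid] - fs[1, mid]
  expect_lt(abs(median(resid)), 0.5)
  # constant trace stays constant
  fc <- estimate_f_smooth(fluo_traces(matrix(5, 1, 400), "raw"), fr, 30)
  expect_equal(unique(as.numeric(fc)), 5)
  # warns when window is short relative to indicator decay
  expect_warning(estimate_f_smooth(tr, fr, window = 1, tau_decay = 1),
                 "tau_decay")
})

test_that("dF/F0 has the defining ratio values and rejects bad baselines", {
  F <- matrix(c(1, 2, 4, 2), 1, 4)
  tr <- fluo_traces(F, "corrected")
  d <- compute_dff(tr, F0 = 2)
  expect_equal(as.numeric(d$dff), c(-0.5, 0, 1, 0))
  expect_error(compute_dff(tr, F0 = 0), "sanity_check")
  # per-frame F0 (smooth method)
  d2 <- compute_dff(tr, F0 = matrix(c(1, 2, 4, 2), 1, 4))
  expect_equal(as.numeric(d2$dff), rep(0, 4))
  expect_equal(d2$f0_method, "smooth")
})

test_that("neuropil correction restores pairwise correlations on synthetic data", {
  set.seed(9)
  cells <- make_cells(25, "disk", field = c(140, 140), radius = 4,
                      min_gap = 6, seed = 31)
  gt <- make_activity(25, duration = 120, frame_rate = 5, tau_decay = 0.5,
                      amplitude = 1.2, noise_sigma = 0, background_rate = 0.08,
                      seed = 32)
  rend <- render_movie(cells, gt, background = 0.1, neuropil_gain = 0.8,
                       alpha_inside = 0.9, pixel_noise = 0.005, seed = 33)
  soma <- extract_traces(rend$movie, cells$rois)
  npil <- extract_neuropil(rend$movie, cells$rois, radius = 20, pixel_size = 1)
  corr <- neuropil_correct(soma, npil, alpha = 0.9)
  # corrected traces match ground-truth soma signals
  r <- vapply(1:25, function(i) cor(corr$F[i, ], gt$true_dff[i, ]),
              numeric(1))
  expect_gt(min(r), 0.95)
  # mean off-diagonal correlation restored to ground truth within 0.05
  offdiag <- function(M) { C <- cor(t(M)); mean(C[upper.tri(C)]) }
  expect_gt(offdiag(soma$F) - offdiag(gt$true_dff), 0.1)  # contaminated
  expect_lt(abs(offdiag(corr$F) - offdiag(gt$true_dff)), 0.05)
})
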