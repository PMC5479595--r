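test_that("contrast normalization is affine-invariant and flattens gradients", {
  set.seed(2)
  cells <- make_cells(20, "disk", field = c(96, 96), radius = 4,
                      min_gap = 4, seed = 3)
  img <- blob_image(cells, seed = 4)
  n1 <- normalize_contrast(img, 20)
  n2 <- normalize_contrast(2 * img + 7, 20)
  expect_equal(n1, n2, tolerance = 1e-9)
  expect_true(min(n1) >= 0 && max(n1) <= 1)

  # planted 2x illumination gradient: normalized cell-center values stay
  # uniform across the field
  grad <- matrix(seq(1, 2, length.out = 96), 96, 96, byrow = TRUE)
  ng <- normalize_contrast(img * grad, 20)
  centers <- round(cells$centers)
  vals <- ng[centers]
  expect_lt((max(vals) - min(vals)) / mean(vals), 0.10)

  expect_warning(nc <- normalize_contrast(matrix(3, 20, 20), 5), "constant")
  expect_true(all(nc == 0.5))
})

test_that("planted disk cells are detected in labeled_nuclei mode", {
  cells <- make_cells(50, "disk", field = c(160, 160), radius = 4,
                      min_gap = 3, seed = 7)
  nrm <- normalize_contrast(blob_image(cells, seed = 7), 20)
  p <- segmentation_params("labeled_nuclei", thr_soma = 0.5,
                           thr_neuropil = 0.3, area_min = 10)
  det <- filter_rois(detect_rois(nrm, p, 1), nrm, p)
  hits <- vapply(cells$masks, function(m)
    max(vapply(det$rois, iou, numeric(1), a = m)), numeric(1))
  expect_gte(mean(hits >= 0.5), 0.90)
  # disjointness after detection
  lin <- unlist(lapply(det$rois, function(q) (q[, 2] - 1) * 160 + q[, 1]))
  expect_false(anyDuplicated(lin) > 0)
})

test_that("planted ring cells are detected in unlabeled_nuclei mode", {
  cells <- make_cells(50, "ring", field = c(160, 160), radius = 4,
                      min_gap = 3, seed = 8)
  img <- blob_image(cells, background = 0.3, nucleus_level = 0.15, seed = 8)
  nrm <- normalize_contrast(img, 20)
  p <- segmentation_params("unlabeled_nuclei", roi_size_opt = "smaller",
                           thr_soma = 0.1, thr_neuropil = 0.5, area_min = 10)
  det <- filter_rois(detect_rois(nrm, p, 1), nrm, p)
  hits <- vapply(cells$masks, function(m)
    max(c(0, vapply(det$rois, iou, numeric(1), a = m))), numeric(1))
  expect_gte(mean(hits >= 0.5), 0.85)
})

test_that("a blank image yields zero ROIs with a warning, not an error", {
  p <- segmentation_params("labeled_nuclei", thr_soma = 0.5)
  expect_warning(det <- detect_rois(matrix(0, 32, 32), p), "no ROIs")
  expect_equal(length(det), 0)
})

test_that("morphological filtering applies area, intensity and circularity", {
  # one disk r=6, one tiny 10-px blob, one elongated bar
  img <- matrix(0, 60, 60)
  g <- expand.grid(r = 1:60, c = 1:60)
  disk <- g[(g$r - 15)^2 + (g$c - 15)^2 <= 36, ]
  img[cbind(disk$r, disk$c)] <- 1
  img[cbind(rep(40, 10), 11:20)] <- 1            # 10-px line
  img[cbind(rep(50:51, 12), rep(30:41, each = 2))] <- 1
  rois <- capop:::.label_to_rois(
    EBImage::imageData(EBImage::bwlabel(img > 0.5)))
  # minimal area 18 filters the 10-pixel ROI
  p <- segmentation_params("labeled_nuclei", area_min = 18)
  kept <- filter_rois(rois, img, p)
  expect_false(any(vapply(kept$rois, nrow, integer(1)) == 10))
  # a rasterized disk of radius 6 has circularity near 1 and survives
  # typical bounds [~0.48, ~1.7]
  lab_disk <- matrix(0L, 60, 60)
  lab_disk[cbind(disk$r, disk$c)] <- 1L
  shp <- EBImage::computeFeatures.shape(lab_disk)
  circ <- shp[, "s.perimeter"]^2 / (4 * pi * shp[, "s.area"])
  expect_gt(circ, 0.7); expect_lt(circ, 1.3)
  p2 <- segmentation_params("labeled_nuclei", circ_min = 0.48,
                            circ_max = 1.7)
  kept2 <- filter_rois(rois, img, p2)
  expect_true(any(vapply(kept2$rois, nrow, integer(1)) == nrow(disk)))
  # vacuous criteria are the identity, and filtering is idempotent
  p3 <- segmentation_params("labeled_nuclei")
  expect_identical(filter_rois(rois, img, p3)$rois, rois$rois)
  expect_identical(filter_rois(kept, img, p)$rois, kept$rois)
})

test_that("hexagonal tiling matches a brute-force nearest-center oracle", {
  R <- 4.5  # 9 um at 1 um/px
  hex <- hexagonal_grid(c(90, 90), diameter = 9, pixel_size = 1)
  # oracle: assign pixels to the nearest enumerated lattice center
  ctr <- expand.grid(q = -30:30, r = -30:30)
  cx <- sqrt(3) * R * (ctr$q + ctr$r / 2)
  cy <- 1.5 * R * ctr$r
  px <- expand.grid(y = seq_len(90) - 0.5, x = seq_len(90) - 0.5)
  lab <- vapply(seq_len(nrow(px)), function(i)
    which.min((cx - px$x[i])^2 + (cy - px$y[i])^2), integer(1))
  nominal <- 3 * sqrt(3) / 2 * R^2
  oracle_n <- sum(table(lab) >= 0.5 * nominal)
  expect_equal(length(hex), oracle_n)
  # full-frame mask is identical to no mask
  hex2 <- hexagonal_grid(c(90, 90), 9, 1, mask = matrix(TRUE, 90, 90))
  expect_identical(hex$rois, hex2$rois)
  # degenerate: hexagon as large as the field
  big <- hexagonal_grid(c(40, 40), diameter = 40, pixel_size = 1)
  expect_lte(length(big), 2)
  expect_gte(length(big), 1)
  # empty mask
  expect_equal(length(hexagonal_grid(c(40, 40), 9, 1,
                                     matrix(FALSE, 40, 40))), 0)
})

test_that("programmatic ROI edits apply removals then additions", {
  rm0 <- roi_map(list(cbind(1:2, 1:2), cbind(4:5, 4:5), cbind(8L, 8L)),
                 field_dim = c(10, 10))
  expect_identical(modify_rois(rm0)$rois, rm0$rois)
  out <- modify_rois(rm0, remove = 2)
  expect_equal(length(out), 2)
  expect_identical(out$rois[[2]], rm0$rois[[3]])
  expect_error(modify_rois(rm0, add = list(cbind(1L, 1L))), "overlaps ROI 1")
  out2 <- modify_rois(rm0, add = list(cbind(9L, 9L)), remove = 1)
  expect_equal(length(out2), 3)
})
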