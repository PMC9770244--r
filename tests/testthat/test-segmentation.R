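test_that("masking zeroes outside-larva and excluded voxels exactly", {
  set.seed(9)
  a <- array(runif(16 * 16 * 4, 1, 2), c(16, 16, 4))
  g <- VoxelGrid(a)
  whole <- cbind(c(-1, 17, 17, -1), c(-1, -1, 17, 17))
  expect_equal(voxelData(applyMasks(g, whole, list())), a)
  expect_true(all(voxelData(applyMasks(g, whole, list(whole))) == 0))

  # left-half exclusion, checked voxelwise against a point-in-polygon oracle
  left <- cbind(c(-1, 8, 8, -1), c(-1, -1, 17, 17))
  masked <- voxelData(applyMasks(g, whole, list(left)))
  for (x in 1:16) {
    inLeft <- (x - 0.5) < 8   # pixel centre against the exclusion edge
    for (z in 1:4) {
      if (inLeft) expect_true(all(masked[, x, z] == 0))
      else expect_equal(masked[, x, z], a[, x, z])
    }
  }
})

test_that("3D median filter matches the exhaustive sliding-window oracle", {
  cst <- VoxelGrid(array(4, c(5, 5, 5)))
  expect_equal(voxelData(median3d(cst, c(1, 1, 1))), array(4, c(5, 5, 5)))

  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 100
  expect_true(all(voxelData(median3d(VoxelGrid(imp), c(1, 1, 1))) == 0))

  set.seed(21)
  for (i in 1:4) {
    a <- array(sample(0:30, 6^3, replace = TRUE), c(6, 6, 6))
    radii <- list(c(1, 1, 1), c(2, 2, 1), c(1, 2, 2), c(3, 1, 2))[[i]]
    expect_equal(voxelData(median3d(VoxelGrid(a), radii)),
                 oracleMedian3d(a, radii))
  }
})

test_that("seed detection finds one seed per intensity peak", {
  flat <- VoxelGrid(array(5, c(8, 8, 4)))
  expect_identical(nrow(detectSeeds(flat, 5, c(1, 1, 1))), 0L)  # ties at B

  blob <- blobArray(c(15, 15, 7), c(7.5, 7.5, 3.5), 2, 100)
  s <- detectSeeds(VoxelGrid(blob), 10, c(2, 2, 1))
  expect_identical(nrow(s), 1L)
  expect_equal(unname(s[1, c("y", "x", "z")]), c(8, 8, 4))

  two <- blobArray(c(12, 30, 7), c(6, 6, 3.5), 2, 100) +
         blobArray(c(12, 30, 7), c(26, 6, 3.5), 2, 100)
  s2 <- detectSeeds(VoxelGrid(two), 10, c(2, 2, 1))
  expect_identical(nrow(s2), 2L)
  expect_equal(sort(s2[, "x"]), c(6, 26))
})

test_that("an equal-valued plateau yields exactly one seed at lowest (z,y,x)", {
  a <- array(0, c(7, 7, 3))
  a[3:4, 3:4, 2] <- 10   # 2x2 plateau
  s <- detectSeeds(VoxelGrid(a), 1, c(1, 1, 1))
  expect_identical(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(3, 3, 2))
})

test_that("raising the background cutoff never adds seeds", {
  set.seed(33)
  a <- blobArray(c(20, 20, 8), c(6, 6, 4), 2.5, 80) +
       blobArray(c(20, 20, 8), c(14, 13, 4), 2, 50) +
       array(runif(20 * 20 * 8, 0, 5), c(20, 20, 8))
  g <- median3d(VoxelGrid(a), c(1, 1, 1))
  counts <- vapply(seq(1, 70, length.out = 10),
                   function(B) nrow(detectSeeds(g, B, c(2, 2, 1))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed floods single and saddle-joined blobs correctly", {
  blob <- blobArray(c(15, 15, 7), c(7.5, 7.5, 3.5), 2, 100)
  g <- VoxelGrid(blob)
  seeds <- detectSeeds(g, 10, c(2, 2, 1))
  lab <- labelData(watershed3d(g, seeds, 10))
  expect_identical(max(lab), 1L)
  expect_identical(lab > 0, blob > 10)  # one basin covers all supra-B voxels

  expect_identical(max(labelData(watershed3d(
    g, matrix(integer(0), 0, 3, dimnames = list(NULL, c("y", "x", "z"))),
    10))), 0L)

  # two blobs joined through a saddle below both peaks
  two <- blobArray(c(15, 15, 7), c(4.5, 7.5, 3.5), 2.2, 100) +
         blobArray(c(15, 15, 7), c(11.5, 7.5, 3.5), 2.2, 90)
  gt <- VoxelGrid(two)
  s2 <- detectSeeds(gt, 10, c(2, 2, 1))
  expect_identical(nrow(s2), 2L)
  lab2 <- labelData(watershed3d(gt, s2, 10))
  expect_identical(max(lab2), 2L)
  expect_identical(lab2, oracleWatershed(two, s2, 10))
  expect_error(watershed3d(gt, matrix(c(1L, 1L, 1L), 1,
    dimnames = list(NULL, c("y", "x", "z"))), 10), "above background")
})

test_that("watershed matches the priority-flood oracle on random grids", {
  set.seed(55)
  for (i in 1:12) {
    d <- c(sample(5:10, 1), sample(5:10, 1), sample(3:6, 1))
    a <- array(sample(0:4, prod(d), replace = TRUE), d)  # many ties
    sup <- which(a > 0, arr.ind = TRUE)
    if (nrow(sup) < 2) next
    ns <- sample(1:4, 1)
    seeds <- sup[sample(nrow(sup), min(ns, nrow(sup))), , drop = FALSE]
    seeds <- seeds[order(seeds[, 3], seeds[, 1], seeds[, 2]), , drop = FALSE]
    colnames(seeds) <- c("y", "x", "z")
    conn <- if (i %% 2 == 0) 6L else 26L
    got <- labelData(watershed3d(VoxelGrid(a), seeds, 0, conn))
    expect_identical(got, oracleWatershed(a, seeds, 0, conn))
  }
})

test_that("watershed output partitions the reachable supra-B voxels", {
  set.seed(77)
  a <- blobArray(c(15, 15, 7), c(5, 6, 3.5), 2.5, 100) +
       blobArray(c(15, 15, 7), c(11, 9, 3.5), 2, 80)
  g <- VoxelGrid(a)
  seeds <- detectSeeds(g, 8, c(2, 2, 1))
  lab <- labelData(watershed3d(g, seeds, 8))
  expect_true(all(a[lab > 0] > 8))              # only foreground is labelled
  expect_identical(sort(unique(as.integer(lab[lab > 0]))),
                   seq_len(nrow(seeds)))        # contiguous labels
  # volume conservation through measurement
  st <- ConfocalStack(list(bf = VoxelGrid(array(1, dim(a))), fl = g),
                      c(bf = "brightfield", fl = "fluorescence"))
  obj <- measureObjects(LabelMap(lab, c(1, 1, 1)), st)
  expect_identical(sum(obj$voxel_count), sum(lab > 0))
  expect_equal(sum(obj$volume_um3), sum(lab > 0) * 1)
})

test_that("whole-voxel translation shifts centroids and keeps volumes", {
  base <- blobArray(c(18, 18, 12), c(6, 6, 6), 2, 100)  # fully interior blob
  shifted <- array(0, dim(base))
  shifted[4:18, 3:18, 2:12] <- base[1:15, 1:16, 1:11]  # +3y, +2x, +1z voxels
  seg <- function(a) {
    g <- VoxelGrid(a, c(0.5, 0.5, 2))
    st <- ConfocalStack(list(bf = VoxelGrid(array(1, dim(a)), c(0.5, 0.5, 2)),
                             fl = g),
                        c(bf = "brightfield", fl = "fluorescence"))
    measureObjects(watershed3d(g, detectSeeds(g, 10, c(2, 2, 1)), 10), st)
  }
  o1 <- seg(base); o2 <- seg(shifted)
  expect_identical(o1$voxel_count, o2$voxel_count)
  expect_equal(o2$centroid_x_um - o1$centroid_x_um, 2 * 0.5)
  expect_equal(o2$centroid_y_um - o1$centroid_y_um, 3 * 0.5)
  expect_equal(o2$centroid_z_um - o1$centroid_z_um, 1 * 2)
})

test_that("object measurement gives exact volumes, ESD and centroids", {
  lab <- array(0L, c(14, 14, 12)); lab[3:12, 3:12, 2:11] <- 1L  # 10^3 cube
  st <- ConfocalStack(list(bf = VoxelGrid(array(1, c(14, 14, 12))),
                           fl = VoxelGrid(array(3, c(14, 14, 12)))),
                      c(bf = "brightfield", fl = "fluorescence"))
  obj <- measureObjects(LabelMap(lab, c(1, 1, 1)), st)
  expect_equal(obj$volume_um3, 1000)
  expect_equal(obj$esd_um, (6 * 1000 / pi)^(1 / 3), tolerance = 1e-12)
  # centrally symmetric: centroid at the cube centre
  expect_equal(obj$centroid_x_um, 7, tolerance = 1e-9)
  expect_equal(obj$centroid_y_um, 7, tolerance = 1e-9)
  expect_equal(obj$centroid_z_um, 6, tolerance = 1e-9)
  expect_equal(obj$mean_fl, 3)
  expect_equal(obj$sum_fl, 3000)
  # bounding box is 0-based half-open
  expect_identical(c(obj$bbox_x0, obj$bbox_x1), c(2, 12))
})

test_that("cut-outs clip to bounds and re-measure identically", {
  a <- blobArray(c(20, 24, 10), c(10, 9, 5), 2, 100)
  g <- VoxelGrid(a)
  st <- ConfocalStack(list(bf = VoxelGrid(array(1, dim(a))), fl = g),
                      c(bf = "brightfield", fl = "fluorescence"))
  lab <- watershed3d(g, detectSeeds(g, 10, c(2, 2, 1)), 10)
  obj <- measureObjects(lab, st)
  cut0 <- extractCutout(st, obj[1, ], margin = 0)
  d0 <- dim(voxelData(channels(cut0)$fl))
  expect_equal(d0, c(obj$bbox_y1 - obj$bbox_y0, obj$bbox_x1 - obj$bbox_x0,
                     obj$bbox_z1 - obj$bbox_z0))
  cutBig <- extractCutout(st, obj[1, ], margin = 1000)
  expect_identical(dim(voxelData(channels(cutBig)$fl)), dim(a))
  # standalone re-segmentation of the cut-out recovers the same voxel count
  gc <- channels(extractCutout(st, obj[1, ], margin = 3))$fl
  labc <- watershed3d(gc, detectSeeds(gc, 10, c(2, 2, 1)), 10)
  expect_identical(sum(labelData(labc) > 0), obj$voxel_count)
})

test_that("full pipeline handles empty stacks and composes stage outputs", {
  dark <- ConfocalStack(
    list(bf = VoxelGrid(array(1, c(16, 32, 6))),
         fl = VoxelGrid(array(2, c(16, 32, 6)))),
    c(bf = "brightfield", fl = "fluorescence"))
  res <- segmentLarva(dark, outline = NULL, config = segmentationConfig(50))
  expect_identical(nrow(res$objects), 0L)
  expect_identical(max(labelData(res$labels)), 0L)
})
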