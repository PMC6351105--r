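test_that("thresholding is exact, global, and monotone", {
  sc <- generate_scene(clean_scene_config(3, grid = c(64L, 64L, 8L),
                                          n_aggregates = 2,
                                          vr = c(150, 500)))
  # all-background plane
  bg <- threshold_plane(sc$stack, 1, 1e6)
  expect_false(any(bg))
  # threshold 0 selects everything
  expect_true(all(threshold_plane(sc$stack, 1, 0)))
  # clean scene: mask at mid-threshold equals the aggregate footprint
  # exactly (planktonic cells render below the threshold)
  z <- sc$truth$objects$center_z_um[1] / 2  # dz = 2 um
  z <- max(1L, min(8L, round(z)))
  m <- threshold_plane(sc$stack, z, 70)
  agg_ids <- sc$truth$objects$id[sc$truth$objects$class == "aggregate"]
  expect_identical(m, matrix(sc$truth$label_volume[, , z] %in% agg_ids,
                             nrow(m), ncol(m)))
  # raising the threshold never grows the mask
  for (th in c(10, 30, 60, 90, 130)) {
    lo <- threshold_plane(sc$stack, z, th)
    hi <- threshold_plane(sc$stack, z, th + 10)
    expect_true(all(lo | !hi))
  }
})

test_that("labeling respects connectivity and raster label order", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE   # diagonal touch
  expect_equal(max(label_plane(m, 8)), 1)
  expect_equal(max(label_plane(m, 4)), 2)
  # two disks separated by >= 2 background pixels
  m2 <- coords_to_mask(rbind(disk_coords(10, 10, 4, 32, 32),
                             disk_coords(10, 24, 4, 32, 32)), 32, 32)
  expect_equal(max(label_plane(m2, 8)), 2)
  # label 1 must contain the raster-first pixel
  lab <- label_plane(m2, 8)
  first <- which(t(lab) > 0)[1]  # row-major scan
  expect_equal(t(lab)[first], 1L)
  expect_equal(max(label_plane(matrix(FALSE, 5, 5), 8)), 0)
})

test_that("labeling agrees with the EBImage component oracle", {
  # EBImage::bwlabel is an independent 4-connectivity implementation
  withr::with_seed(42, {
    for (i in 1:5) {
      m <- matrix(runif(40 * 40) < 0.35, 40, 40)
      ours <- label_plane(m, 4)
      ref <- EBImage::bwlabel(m * 1)
      expect_equal(max(ours), max(ref))
      # identical partitions: label pairs must be in bijection
      expect_equal(length(unique(paste(ours[m], ref[m]))), max(ref))
    }
  })
})

test_that("convexity score is zero for convex and degenerate objects", {
  rect <- as.matrix(expand.grid(y = 5:12, x = 3:20))
  expect_equal(score_convexity(rect), 0)
  row3 <- cbind(y = rep(4L, 5), x = 2:6)
  expect_equal(score_convexity(row3), 0)
  expect_equal(score_convexity(rbind(c(1L, 1L), c(1L, 2L))), 0)
  d <- disk_coords(20, 20, 8, 40, 40)
  expect_equal(score_convexity(d), 0)
})

test_that("convexity score matches direct pixel counting on a dumbbell", {
  dd <- rbind(disk_coords(25, 20, 10, 50, 60), disk_coords(25, 38, 10, 50, 60))
  dd <- dd[!duplicated(paste(dd[, 1], dd[, 2])), ]
  hull <- hull_pixels_oracle(dd)
  A <- nrow(dd)
  H <- nrow(hull)
  expect_gt(H, A)
  expect_equal(score_convexity(dd), sqrt((H - A) / H))
  expect_equal(score_convexity(dd, method = "raw_deficit"), H - A)
})

test_that("hull rasterization contains the object and matches the oracle", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(10:80, 1)
      pts <- unique(cbind(sample(3:30, n, TRUE), sample(3:30, n, TRUE)))
      hull <- convex_hull_pixels(pts)
      expect_true(all(paste(pts[, 1], pts[, 2]) %in%
                        paste(hull[, 1], hull[, 2])))
      oracle <- hull_pixels_oracle(pts)
      expect_setequal(paste(hull[, 1], hull[, 2]),
                      paste(oracle[, 1], oracle[, 2]))
    }
  })
})

test_that("a convex object below the cutoff is never bisected", {
  d <- disk_coords(20, 20, 9, 40, 40)
  bi <- bisect_object(d, 40, 40, rmsd_cutoff = 0.2)
  expect_length(bi$pieces, 1)
  expect_equal(bi$pieces[[1]], d)
  expect_equal(nrow(bi$cuts), 0)
})

test_that("a symmetric dumbbell splits into its two source disks", {
  ny <- 60; nx <- 80
  d1 <- disk_coords(30, 30, 10, ny, nx)
  d2 <- disk_coords(30, 48, 10, ny, nx)
  m <- coords_to_mask(rbind(d1, d2), ny, nx)
  cc <- which(m, arr.ind = TRUE)
  expect_gt(score_convexity(cc), 0.2)
  bi <- bisect_object(cc, ny, nx, rmsd_cutoff = 0.2)
  expect_length(bi$pieces, 2)
  j <- vapply(bi$pieces, function(p) max(jaccard(p, d1), jaccard(p, d2)), 0)
  expect_true(all(j >= 0.9))
  # pixel conservation: children + cut pixels partition the parent
  n_child <- sum(vapply(bi$pieces, nrow, 0L))
  expect_equal(n_child + sum(bi$cuts$n_cut_pixels), nrow(cc))
  keys <- unlist(lapply(bi$pieces, function(p) paste(p[, 1], p[, 2])))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("three merged disks split recursively into three objects", {
  ny <- 60; nx <- 90
  m <- matrix(FALSE, ny, nx)
  for (cx in c(30, 48, 66)) m[disk_coords(30, cx, 10, ny, nx)] <- TRUE
  cc <- which(m, arr.ind = TRUE)
  bi <- bisect_object(cc, ny, nx, rmsd_cutoff = 0.2, max_iterations = 3)
  expect_length(bi$pieces, 3)
  expect_equal(nrow(bi$cuts), 2)
})

test_that("bisection is idempotent on its own children", {
  ny <- 60; nx <- 80
  m <- coords_to_mask(rbind(disk_coords(30, 30, 10, ny, nx),
                            disk_coords(30, 48, 10, ny, nx)), ny, nx)
  bi <- bisect_object(which(m, arr.ind = TRUE), ny, nx, rmsd_cutoff = 0.2)
  for (p in bi$pieces) {
    again <- bisect_object(p, ny, nx, rmsd_cutoff = 0.2)
    expect_length(again$pieces, 1)
    expect_equal(again$pieces[[1]][order(again$pieces[[1]][, 1],
                                         again$pieces[[1]][, 2]), ],
                 p[order(p[, 1], p[, 2]), ])
  }
})

test_that("segment_planes matches truth footprints on clean scenes", {
  sc <- generate_scene(clean_scene_config(11, n_aggregates = 5,
                                          n_planktonic = 0))
  pl <- segment_planes(sc$stack, run_config())
  for (z in seq_len(dim(sc$truth$label_volume)[3])) {
    n_truth <- length(setdiff(unique(as.vector(
      sc$truth$label_volume[, , z])), 0L))
    expect_equal(max(pl$planes[[z]]), n_truth)
  }
})

test_that("planes through a touching pair contain two objects after splitting", {
  sc <- generate_scene(clean_scene_config(8, n_aggregates = 2, touching = 1,
                                          n_planktonic = 0,
                                          vr = c(300, 1200)))
  lab <- sc$truth$label_volume
  pl <- segment_planes(sc$stack, run_config())
  merged_planes <- 0L
  for (z in seq_len(dim(lab)[3])) {
    both <- all(c(1L, 2L) %in% lab[, , z])
    if (both && max(label_plane(lab[, , z] > 0L, 8)) == 1L) {
      merged_planes <- merged_planes + 1L
      expect_equal(max(pl$planes[[z]]), 2L)
    }
  }
  expect_gte(merged_planes, 1L)  # the fixture must actually exercise a merge
})

test_that("an empty stack yields empty label planes", {
  st <- image_stack(array(0, c(16, 16, 3)), c(1, 1, 1))
  pl <- segment_planes(st, run_config(intensity_threshold = 10))
  expect_true(all(vapply(pl$planes, max, 0) == 0))
})
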