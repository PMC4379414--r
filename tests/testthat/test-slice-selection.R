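test_that("axial profile is the mask-restricted per-slice mean", {
  vol <- array(7, c(6, 6, 5))
  mask <- array(TRUE, dim = dim(vol))
  expect_equal(as.numeric(axial_profile(vol, mask)), rep(7, 5))
  # two bright slabs with a dark gap produce an interior minimum
  vol2 <- array(100, c(6, 6, 9))
  vol2[, , 4:6] <- 10
  p <- axial_profile(vol2, mask2 <- array(TRUE, dim = dim(vol2)))
  expect_equal(which.min(p), 4)
  expect_true(all(p[1:3] > p[5]))
  # restricting the mask changes only the affected slices
  vol3 <- array(10, c(6, 6, 4)); vol3[1:2, 1:2, 2] <- 1000
  full <- axial_profile(vol3, array(TRUE, dim = dim(vol3)))
  m <- array(TRUE, dim = dim(vol3)); m[1:2, 1:2, ] <- FALSE
  part <- axial_profile(vol3, m)
  expect_equal(as.numeric(part), rep(10, 4))
  expect_gt(full[2], part[2])
  # empty slices are flagged and fully empty masks raise
  m2 <- array(TRUE, dim = dim(vol3)); m2[, , 3] <- FALSE
  expect_true(attr(axial_profile(vol3, m2), "empty")[3])
  expect_error(axial_profile(vol3, array(FALSE, dim = dim(vol3))), "empty")
})

ru_profile <- function(dip_min, L = 100) {
  # flat plateau, dip at z = 45, symmetric peak at z = 50, steep descent,
  # then a gently decreasing tail without further local maxima
  p <- numeric(L)
  p[1:40] <- 128
  p[41:45] <- seq(128, dip_min, length.out = 5)
  p[46:50] <- seq(dip_min + (130 - dip_min) / 5, 130, length.out = 5)
  p[51:55] <- seq(120, 90, length.out = 5)
  p[56:L] <- seq(89.8, 85, length.out = L - 55)
  p
}

test_that("radioulnar slice classifier applies the depth and distance rules", {
  # deep (about 30%) minimum shortly before the peak at z = 50
  expect_equal(select_radioulnar_slice(ru_profile(80)), 50)
  # dip too shallow (about 5%): no qualifying maximum anywhere
  expect_error(select_radioulnar_slice(ru_profile(123)), "failed")
  # deep dip but too far from the peak (beyond 15% of the extent):
  # flat at 80 up to z=30, then a slow shallow rise to the peak
  p <- numeric(100)
  p[1:25] <- 100
  p[26:30] <- seq(100, 80, length.out = 5)
  p[31:50] <- seq(118, 130, length.out = 20)
  p[51:100] <- seq(129.5, 90, length.out = 50)
  expect_error(select_radioulnar_slice(p), "failed")
})

test_that("radioulnar slice selection is deterministic and lands inside the bones", {
  for (s in 41:60) {
    ph <- tiny_phantom(seed = s)
    hm <- build_hand_mask(ph$volume, select_mask_threshold(ph$volume))
    prof <- axial_profile(ph$volume$data, hm)
    z <- select_radioulnar_slice(prof)
    expect_identical(z, select_radioulnar_slice(prof))
    slice_labels <- unique(ph$labels[, , z])
    # the slice cuts both radius and ulna, proximal to the joint gap
    expect_true(all(c(1L, 2L) %in% slice_labels), info = paste("seed", s))
    expect_false(any(slice_labels %in% 8:15), info = paste("seed", s))
  }
})

test_that("cluster features measure axial extent in the distal-positive frame", {
  lab <- array(0L, c(6, 6, 20))
  lab[3, 3, 5] <- 1L               # single voxel
  lab[4, 4, 3:12] <- 2L            # bar spanning slices 3..12
  cf <- cluster_features(lab, spacing = c(1, 1, 2))
  one <- cf[cf$label == 1, ]
  expect_equal(one$d_slices, 1L)
  expect_equal(one$x_min, one$x_max)
  bar <- cf[cf$label == 2, ]
  expect_equal(bar$d_slices, 10L)
  # x = (L - z) * dz with dz = 2 and L = 20 slices
  expect_equal(bar$x_min, (20 - 12) * 2)
  expect_equal(bar$x_max, (20 - 3) * 2)
  # flipping the volume along z swaps the roles of x_min and x_max
  flip <- lab[, , 20:1]
  cff <- cluster_features(flip, spacing = c(1, 1, 2))
  barf <- cff[cff$label == 2, ]
  expect_equal(barf$z_min, 20 - bar$z_max + 1)
  expect_equal(barf$d_slices, bar$d_slices)
})

test_that("metacarpal slice selection filters carpal-like clusters and keeps at most N", {
  d <- c(48, 48, 48)
  vol <- array(0L, dim = d)
  # five metacarpal bars, distal (low z): x_min = (48-14)/48 = 0.71 L
  bar_x <- c(6, 15, 24, 33, 42)
  for (x in bar_x) vol[(x - 1):(x + 1), 23:25, 1:14] <- 1000L
  # eight carpal-like blobs whose proximal tips pass z = 32 (x_min < 0.35 L)
  blob_x <- round(seq(6, 42, length.out = 8))
  for (x in blob_x) vol[(x - 1):(x + 1), 35:37, 26:32] <- 1000L
  z <- select_metacarpal_slice(wrist_volume(vol, c(1, 1, 1)), th_me = 500)
  expect_lte(z, 14)
  cl <- attr(z, "clusters")
  expect_equal(nrow(cl), 5)           # all carpal blobs filtered out
  expect_true(all(cl$d_slices == 14))
  # the chosen slice crosses all five bars
  expect_equal(sum(vol[, , z] > 700) >= 5 * 9, TRUE)
  # with 12 qualifying clusters only the 10 with the largest extent remain
  vol2 <- array(0L, dim = d)
  for (i in 1:12) vol2[3 * i, 24, 1:(2 + i)] <- 1000L
  z2 <- select_metacarpal_slice(wrist_volume(vol2, c(1, 1, 1)), th_me = 500)
  cl2 <- attr(z2, "clusters")
  expect_equal(nrow(cl2), 10)
  expect_equal(sort(cl2$d_slices), sort(2 + 3:12))
  # single bar, fattest cross section wins
  vol3 <- array(0L, dim = d)
  vol3[20:22, 20:22, 1:10] <- 1000L
  vol3[18:24, 18:24, 6] <- 1000L
  z3 <- select_metacarpal_slice(wrist_volume(vol3, c(1, 1, 1)), th_me = 500)
  expect_equal(as.integer(z3), 6)
  expect_error(select_metacarpal_slice(wrist_volume(array(0L, c(8, 8, 8)), c(1, 1, 1)), 500),
               "empty")
})

test_that("metacarpal slice crosses all five phantom bars", {
  hits <- 0L
  for (s in 61:80) {
    ph <- tiny_phantom(seed = s)
    th_me <- max_entropy_threshold(intensity_histogram(ph$volume))
    z <- tryCatch(select_metacarpal_slice(ph$volume, th_me),
                  error = function(e) NA_integer_)
    if (!is.na(z) && all(3:7 %in% ph$labels[, , z])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # at least 95% of random phantoms
})
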