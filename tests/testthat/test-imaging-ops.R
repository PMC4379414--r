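test_that("unit morphology reproduces definition-level cases", {
  px <- array(FALSE, c(7, 7)); px[4, 4] <- TRUE
  # closing is extensive + idempotent on an element-shaped set: a point stays a point
  expect_identical(morph(px, "close", "square", 1), px)
  sq <- array(FALSE, c(7, 7)); sq[3:5, 3:5] <- TRUE
  er <- morph(sq, "erode", "diamond", 1)
  expect_identical(which(er), which(px))
  di <- morph(px, "dilate", "diamond", 1)
  expect_equal(sum(di), 5)
  expect_true(all(di[cbind(c(3, 4, 4, 4, 5), c(4, 3, 4, 5, 4))]))
})

test_that("iterated-unit and direct size-n morphology agree", {
  set.seed(21)
  for (rep in 1:5) {
    m2 <- array(runif(18 * 18) > 0.55, dim = c(18, 18))
    m3 <- array(runif(10^3) > 0.6, dim = c(10, 10, 10))
    for (h in 1:3) for (kind in c("diamond", "square")) for (op in c("erode", "dilate")) {
      expect_identical(morph(m2, op, kind, h),
                       morph(m2, op, kind, h, direct = TRUE))
      expect_identical(morph(m3, op, kind, h),
                       morph(m3, op, kind, h, direct = TRUE))
    }
  }
})

test_that("morphological duality and opening/closing laws hold", {
  set.seed(22)
  for (rep in 1:5) {
    m <- array(runif(16^3) > 0.5, dim = c(16, 16, 16))
    # exact duality with foreground padding for the erosion
    expect_identical(morph(m, "erode", "diamond", 1, pad = 1),
                     !morph(!m, "dilate", "diamond", 1))
    # with default background padding the same identity holds away from borders
    inner <- m; inner[c(1, 16), , ] <- FALSE; inner[, c(1, 16), ] <- FALSE
    inner[, , c(1, 16)] <- FALSE
    expect_identical(morph(inner, "erode", "diamond", 1)[2:15, 2:15, 2:15],
                     (!morph(!inner, "dilate", "diamond", 1))[2:15, 2:15, 2:15])
    op <- morph(m, "open", "diamond", 1)
    expect_true(all(op <= m))            # anti-extensive (any mask)
    # extensivity and idempotence hold for sets away from the grid border
    # (with background padding a closing can clip border voxels)
    cl <- morph(inner, "close", "diamond", 1)
    opi <- morph(inner, "open", "diamond", 1)
    expect_true(all(inner <= cl))        # extensive
    expect_identical(morph(opi, "open", "diamond", 1), opi)   # idempotent
    expect_identical(morph(cl, "close", "diamond", 1), cl)
  }
})

test_that("2D hole filling floods only regions cut off from the border", {
  ring <- array(FALSE, c(9, 9)); ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE
  filled <- fill_holes_2d(ring)
  full <- array(FALSE, c(9, 9)); full[3:7, 3:7] <- TRUE
  expect_identical(filled, full)
  solid <- array(runif(81) > 0.8, dim = c(9, 9))
  solid[2:8, 2:8] <- FALSE  # sparse border pixels only, no enclosed holes
  expect_identical(fill_holes_2d(solid), solid)
  # two nested rings fill to the full outer square
  nest <- array(FALSE, c(13, 13))
  nest[2:12, 2:12] <- TRUE; nest[3:11, 3:11] <- FALSE
  nest[4:10, 4:10] <- TRUE; nest[5:9, 5:9] <- FALSE
  out <- fill_holes_2d(nest)
  full2 <- array(FALSE, c(13, 13)); full2[2:12, 2:12] <- TRUE
  expect_identical(out, full2)
})

test_that("connected components follow the requested adjacency", {
  m <- array(FALSE, c(5, 5)); m[1, 1] <- TRUE; m[5, 5] <- TRUE
  expect_length(connected_components(m)$sizes, 2)
  dg <- array(FALSE, c(4, 4)); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_length(connected_components(dg, "face")$sizes, 2)
  expect_length(connected_components(dg, "full")$sizes, 1)
  expect_length(connected_components(array(FALSE, c(3, 3)))$sizes, 0)
  # deterministic label order: first component holds the smallest linear index
  lab <- connected_components(m)$labels
  expect_equal(lab[1, 1], 1L)
  expect_equal(lab[5, 5], 2L)
})

test_that("keep_largest retains the k biggest components", {
  m <- array(FALSE, c(12, 12))
  m[1:5, 1] <- TRUE        # size 5
  m[1:3, 5] <- TRUE        # size 3
  m[8, 8] <- TRUE          # size 1
  kept <- keep_largest(m, 2)
  expect_equal(sum(kept), 8)
  expect_false(kept[8, 8])
  expect_identical(keep_largest(m, 10), m)
  e <- array(FALSE, c(4, 4))
  expect_identical(keep_largest(e, 2), e)
})

test_that("gradient magnitude responds to edges, not offsets", {
  const <- array(7, dim = c(6, 6, 6))
  expect_true(all(gradient_magnitude(const) == 0))
  # axis-aligned step: maximal response on the edge plane, symmetric about it
  step <- array(0, dim = c(7, 7, 7)); step[5:7, , ] <- 100
  g <- gradient_magnitude(step)
  prof <- apply(g, 1, mean)
  expect_true(which.max(prof) %in% 4:5)  # maximal at the jump
  expect_equal(prof[4], prof[5], tolerance = 1e-10)  # symmetric about the edge
  expect_equal(prof[3], prof[6], tolerance = 1e-10)
  # offset invariance, gain linearity
  set.seed(9)
  v <- array(runif(6^3, 0, 50), dim = c(6, 6, 6))
  expect_equal(gradient_magnitude(v + 100), gradient_magnitude(v), tolerance = 1e-9)
  expect_equal(gradient_magnitude(v * 3), 3 * gradient_magnitude(v), tolerance = 1e-9)
  # 90-degree rotation equivariance (exact for axis permutations)
  vr <- aperm(v, c(2, 1, 3))
  expect_equal(gradient_magnitude(vr), aperm(gradient_magnitude(v), c(2, 1, 3)),
               tolerance = 1e-9)
  expect_error(gradient_magnitude(array(0, c(2, 5, 5))), "3 voxels")
})

test_that("maximum-entropy threshold separates modes and matches exhaustive search", {
  h <- numeric(64)
  h[11] <- 500; h[51] <- 400
  th <- max_entropy_threshold(h)
  expect_gte(th, 10)
  expect_lt(th, 50)
  # scale invariance of the criterion
  expect_identical(max_entropy_threshold(h * 17), th)
  expect_error(max_entropy_threshold(c(0, 5, 0)), "two occupied")
  set.seed(13)
  for (i in 1:200) {
    nb <- sample(8:64, 1)
    hh <- rpois(nb, lambda = sample(c(2, 20, 80), 1))
    if (sum(hh > 0) < 2) hh[c(1, nb)] <- hh[c(1, nb)] + 1
    expect_equal(max_entropy_threshold(hh), oracle_kapur(hh), info = paste("hist", i))
  }
})

test_that("histogram smoothing is a mass-preserving running average", {
  h <- c(1, 5, 2, 8, 3, 7, 1)
  expect_equal(smooth_histogram(h, 1), h)
  imp <- numeric(31); imp[16] <- 1
  sm <- smooth_histogram(imp, 11)
  expect_equal(sum(sm > 0), 11)
  expect_equal(unique(round(sm[sm > 0], 12)), round(1 / 11, 12))
  expect_equal(sum(sm), 1)  # interior impulse: mass preserved exactly
  const <- rep(4, 20)
  expect_equal(smooth_histogram(const, 5), const)
  expect_error(smooth_histogram(h, 4), "odd")
})
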