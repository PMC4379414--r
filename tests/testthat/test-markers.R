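test_that("growth in a uniform tube walks a straight axial column", {
  vol <- array(100, c(9, 9, 20))
  res <- grow_marker(vol, c(5, 5, 3), depth_slices = 10, direction = "proximal")
  expect_equal(nrow(res$path), 11)            # seed + 10 slices
  expect_true(all(res$path[, 1] == 5))
  expect_true(all(res$path[, 2] == 5))
  expect_equal(sort(res$path[, 3]), 3:13)
  expect_false(res$truncated)
  expect_lte(sum(res$marker), res$grown)      # path is a subset of the grown set
})

test_that("growth follows a bright curved channel", {
  vol <- array(0, c(20, 20, 20))
  # face-connected channel drifting one voxel in x every two slices
  xs <- 5 + floor((0:11) / 2)
  for (k in 0:11) {
    vol[xs[k + 1], 10, 5 + k] <- 1000
    if (k > 0 && xs[k + 1] != xs[k]) vol[xs[k + 1], 10, 4 + k] <- 1000
  }
  res <- grow_marker(vol, c(5, 10, 5), depth_slices = 10, direction = "proximal")
  stopv <- res$path[1, ]
  expect_equal(unname(stopv[3]), 15L)
  # every path voxel is on the bright channel
  expect_true(all(vol[res$path] == 1000))
})

test_that("growth matches the naive best-first oracle, including ties", {
  set.seed(55)
  for (rep in 1:5) {
    d <- c(7, 7, 12)
    vol <- array(sample(1:6, prod(d), replace = TRUE), dim = d)
    seed <- c(4, 4, 3)
    res <- grow_marker(vol, seed, depth_slices = 6, direction = "proximal")
    lin_path <- (res$path[, 1] - 1) + d[1] * ((res$path[, 2] - 1) + d[2] * (res$path[, 3] - 1)) + 1
    expect_identical(as.integer(lin_path), as.integer(oracle_grow(vol, seed, 6, +1)),
                     info = paste("rep", rep))
  }
})

test_that("growth warns and truncates at the volume edge", {
  vol <- array(100, c(5, 5, 6))
  expect_warning(res <- grow_marker(vol, c(3, 3, 2), depth_slices = 10), "truncated")
  expect_true(res$truncated)
})

test_that("central pixel maximizes the city-block distance to background", {
  sq <- array(FALSE, c(9, 9)); sq[3:7, 3:7] <- TRUE
  expect_equal(unname(central_pixel(sq)), c(5, 5))
  single <- array(FALSE, c(5, 5)); single[2, 4] <- TRUE
  expect_equal(unname(central_pixel(single)), c(2, 4))
  # L-shaped region: exhaustive distance-transform argmax
  L <- array(FALSE, c(12, 12)); L[2:11, 2:4] <- TRUE; L[8:11, 2:9] <- TRUE
  cp <- central_pixel(L)
  dt <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) if (L[i, j]) {
    best <- Inf
    for (a in 1:12) for (b in 1:12) if (!L[a, b])
      best <- min(best, abs(i - a) + abs(j - b))
    best <- min(best, i, j, 13 - i, 13 - j)  # frame counts as background
    dt[i, j] <- best
  }
  expect_equal(dt[cp[1], cp[2]], max(dt))
  expect_error(central_pixel(array(FALSE, c(3, 3))), "empty")
})

test_that("support lines are common tangents leaving both bodies on one side", {
  # two ellipse point clouds and a region blob between/medial to them
  th <- seq(0, 2 * pi, length.out = 60)
  A <- cbind(10 + 4 * cos(th), 30 + 6 * sin(th))
  B <- cbind(16 + 3 * cos(th), 8 + 4 * sin(th))
  region <- array(FALSE, c(40, 40, 40))
  region[25:35, , 15:25] <- TRUE
  pl <- wristseg:::support_line(A, B, region)
  expect_false(is.null(pl))
  valsA <- pl$normal[1] * A[, 1] + pl$normal[2] * A[, 2]
  valsB <- pl$normal[1] * B[, 1] + pl$normal[2] * B[, 2]
  expect_true(all(c(valsA, valsB) <= pl$offset + 1e-6))
  # the line is tangent: it touches at least one point of each body
  expect_lt(min(abs(c(valsA, valsB) - pl$offset)), 1e-6 + max(abs(pl$normal)))
})

test_that("the carpal region contains the carpals and excludes the other stages", {
  ph <- tiny_phantom(seed = 17)
  hm <- build_hand_mask(ph$volume, select_mask_threshold(ph$volume))
  ur <- array(ifelse(ph$labels %in% 1:2, ph$labels, 0L), dim = dim(ph$labels))
  mc <- array(ifelse(ph$labels %in% 3:7, ph$labels, 0L), dim = dim(ph$labels))
  region <- carpal_region(ur, mc, hm)
  for (l in 8:15)
    expect_equal(sum(ph$labels == l & region), sum(ph$labels == l),
                 info = paste("carpal", l))
  expect_equal(sum(region & (ur > 0 | mc > 0)), 0)
  expect_true(all(region <= hm))       # clipped by the hand mask
  expect_error(carpal_region(array(0L, dim = dim(ur)), mc, hm), "nonempty")
})

test_that("carpal marker finalization filters dark voxels and keeps eight components", {
  d <- c(40, 40, 20)
  vol <- array(500L, dim = d)
  cand <- array(FALSE, dim = d)
  centers <- expand.grid(x = c(8, 18, 28, 38) - 2, y = c(12, 28))
  for (i in seq_len(8)) {
    xs <- centers$x[i] + (-2:2); ys <- centers$y[i] + (-2:2)
    cand[xs, ys, 8:12] <- TRUE
    vol[xs, ys, 8:12] <- 900L
  }
  # one candidate blob dips into a dark joint space: those voxels must go
  vol[centers$x[1] + (-2:0), centers$y[1] + (-2:2), 8:12] <- 400L
  out <- finalize_carpal_markers(cand, vol, th_me = 500, buffer = 200)
  expect_length(out, 8)
  expect_true(all(vapply(out, function(m) all(vol[m] >= 700), logical(1))))
  # 12 candidate components reduce to the 8 largest
  cand12 <- cand
  vol12 <- vol
  for (k in 1:4) { cand12[k * 3, 36:37, 3] <- TRUE; vol12[k * 3, 36:37, 3] <- 900L }
  out12 <- finalize_carpal_markers(cand12, vol12, th_me = 500, buffer = 200)
  expect_length(out12, 8)
  # fewer than eight components is a hard error naming the count
  few <- array(FALSE, dim = d); few[10:14, 10:14, 9:11] <- TRUE
  expect_error(finalize_carpal_markers(few, vol, th_me = 500, buffer = 200),
               "only 1 carpal marker")
})

test_that("marker sets validate disjointness and trim the background", {
  d <- c(10, 10, 4)
  a <- array(FALSE, dim = d); a[2:3, 2:3, 2] <- TRUE
  b <- array(FALSE, dim = d); b[7:8, 7:8, 2] <- TRUE
  bg <- array(FALSE, dim = d); bg[, , 4] <- TRUE
  ms <- assemble_markers(list(R = a, U = b), bg)
  expect_identical(ms$objects$R, a)
  expect_identical(ms$background, bg)
  # background overlapping an object is trimmed with a warning
  bg2 <- bg; bg2[2, 2, 2] <- TRUE
  expect_warning(ms2 <- assemble_markers(list(R = a, U = b), bg2), "trimmed")
  expect_false(ms2$background[2, 2, 2])
  # overlapping object markers are ambiguous
  b2 <- b; b2[2, 2, 2] <- TRUE
  expect_error(assemble_markers(list(R = a, U = b2), bg), "overlap")
  # empty object markers name the bone
  expect_error(assemble_markers(list(R = a, U = array(FALSE, dim = d)), bg), "U")
  # label-array conversion keeps marker order and appends the background
  lab <- as_marker_array(ms)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L, 3L))
  expect_true(all(lab[a] == 1L))
  expect_true(all(lab[bg] == 3L))
})
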