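test_that("confusion counts match exhaustive voxel enumeration", {
  # identity and complement cases
  m <- array(c(TRUE, FALSE, TRUE, TRUE), dim = c(2, 2))
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  cc2 <- confusion_counts(m, !m)
  expect_equal(cc2$tp, 0)
  expect_equal(cc2$tn, 0)
  # 4x4 hand-enumerable overlap
  set.seed(11)
  g <- array(runif(16) > 0.5, dim = c(4, 4))
  s <- array(runif(16) > 0.5, dim = c(4, 4))
  cc3 <- confusion_counts(g, s)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:4) for (j in 1:4) {
    if (g[i, j] && s[i, j]) tp <- tp + 1
    if (!g[i, j] && s[i, j]) fp <- fp + 1
    if (!g[i, j] && !s[i, j]) tn <- tn + 1
    if (g[i, j] && !s[i, j]) fn <- fn + 1
  }
  expect_equal(unclass(cc3)[c("tp", "fp", "tn", "fn")],
               list(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 16)
  expect_error(confusion_counts(g, array(TRUE, c(3, 3))), "shape")
})

test_that("three-point ROC area matches its closed form and the trapezoid oracle", {
  expect_identical(auc_roc3(fpr = 0, tpr = 1), 1)
  expect_equal(auc_roc3(fpr = 0.3, tpr = 0.3), 0.5)
  expect_equal(auc_roc3(fpr = 0.2, tpr = 0.8), oracle_auc_trapezoid(0.2, 0.8))
  expect_equal(auc_roc3(fpr = 0.2, tpr = 0.8), 0.8)
  # diagonal ROC gives chance level for any rate
  for (t in seq(0, 1, by = 0.1))
    expect_equal(auc_roc3(fpr = t, tpr = t), 0.5)
  # random rates agree with the trapezoid oracle
  set.seed(3)
  for (i in 1:20) {
    fpr <- runif(1); tpr <- runif(1)
    expect_equal(auc_roc3(fpr = fpr, tpr = tpr), oracle_auc_trapezoid(fpr, tpr))
  }
  # undefined rates raise instead of silently returning
  cc <- confusion_counts(array(TRUE, c(2, 2)), array(TRUE, c(2, 2)))
  expect_error(auc_roc3(cc), "negative class")
  cc2 <- confusion_counts(array(FALSE, c(2, 2)), array(FALSE, c(2, 2)))
  expect_error(auc_roc3(cc2), "positive class")
})

test_that("mean similarity is the Jaccard index and is symmetric", {
  m <- array(FALSE, c(4, 4)); m[2:3, 2:3] <- TRUE
  expect_equal(mean_similarity(m, m), 1)
  s <- array(FALSE, c(4, 4)); s[1, 1] <- TRUE
  expect_equal(mean_similarity(m, s), 0)
  # 2x2 block vs the same block shifted one column: |cap| = 2, |cup| = 6
  s2 <- array(FALSE, c(4, 4)); s2[2:3, 3:4] <- TRUE
  expect_equal(mean_similarity(m, s2), 1 / 3)
  expect_equal(mean_similarity(s2, m), mean_similarity(m, s2))
  expect_error(mean_similarity(array(FALSE, c(2, 2)), array(FALSE, c(2, 2))),
               "empty")
})

test_that("xor_mask is the symmetric difference", {
  set.seed(5)
  a <- array(runif(64) > 0.5, dim = c(4, 4, 4))
  b <- array(runif(64) > 0.5, dim = c(4, 4, 4))
  expect_identical(xor_mask(a, a), array(FALSE, dim = dim(a)))
  d1 <- array(FALSE, c(3, 3)); d1[1, 1] <- TRUE
  d2 <- array(FALSE, c(3, 3)); d2[3, 3] <- TRUE
  expect_identical(xor_mask(d1, d2), d1 | d2)
  # truth table, voxel by voxel
  expect_identical(as.vector(xor_mask(a, b)),
                   as.vector((a & !b) | (b & !a)))
  expect_identical(xor_mask(a, b), xor_mask(b, a))
})

test_that("pattern spectrum matches direct evaluation on canonical shapes", {
  one <- array(FALSE, c(5, 5)); one[3, 3] <- TRUE
  expect_equal(as.numeric(pattern_spectrum(one)), 1)
  expect_equal(names(pattern_spectrum(one)), "1")
  sq <- array(FALSE, c(9, 9)); sq[4:6, 4:6] <- TRUE
  ps <- pattern_spectrum(sq)
  expect_equal(stats::setNames(as.numeric(ps), names(ps)), c("1" = 4, "2" = 5))
  expect_length(pattern_spectrum(array(FALSE, c(4, 4))), 0)
})

test_that("pattern spectrum equals the brute-force opening oracle on all 3x3 masks", {
  for (code in 0:511) {
    m <- array(as.logical(bitwAnd(bitwShiftR(code, 0:8), 1L)), dim = c(3, 3))
    ps <- pattern_spectrum(m)
    or <- oracle_pattern_spectrum(m)
    expect_equal(stats::setNames(as.numeric(ps), names(ps)), or,
                 info = paste("mask code", code))
    # mass conservation
    expect_equal(sum(ps), sum(m))
  }
})

test_that("MAD follows the size-weighted spectrum mean and its conventions", {
  m <- array(runif(100) > 0.4, dim = c(10, 10))
  expect_equal(granulometric_mad(m, m), 0)
  a <- array(FALSE, c(7, 7)); b <- a; b[4, 4] <- TRUE
  expect_equal(granulometric_mad(a, b), 1)
  sq <- array(FALSE, c(9, 9)); sq2 <- sq; sq2[4:6, 4:6] <- TRUE
  expect_equal(granulometric_mad(sq, sq2), 14 / 9)
  # symmetry
  set.seed(8)
  x <- array(runif(144) > 0.6, dim = c(12, 12))
  y <- array(runif(144) > 0.6, dim = c(12, 12))
  expect_equal(granulometric_mad(x, y), granulometric_mad(y, x))
})

test_that("MAD of a dilated rectangle matches the definition-level oracle", {
  # A k-dilation leaves an XOR band of width k around the rectangle. Under
  # the granulometric definition a band of width w is removed at the first
  # opening of size ceil(w/2) (a width-2 band already dies at size 1), so
  # the expected value is 1 for both k = 1 and k = 2 up to corner effects;
  # the implementation must agree with the brute-force opening oracle.
  rect <- array(FALSE, c(40, 40)); rect[9:32, 11:34] <- TRUE
  for (k in 1:2) {
    dil <- morph(rect, "dilate", "diamond", k)
    expect_equal(granulometric_mad(rect, dil), oracle_mad(rect, dil))
  }
  dil1 <- morph(rect, "dilate", "diamond", 1)
  expect_lt(abs(granulometric_mad(rect, dil1) - 1), 0.2)
  # a width-3 band (erosion by 1 vs dilation by 2) is removed at opening size 2
  er1 <- morph(rect, "erode", "diamond", 1)
  dil2 <- morph(rect, "dilate", "diamond", 2)
  expect_lt(abs(granulometric_mad(er1, dil2) - 2), 0.2)
})

test_that("majority vote counts foreground strictly above half", {
  m <- array(runif(25) > 0.5, dim = c(5, 5))
  expect_identical(majority_vote(rep(list(m), 5)), m)
  a <- array(FALSE, c(2, 2)); b <- a; a[1, 1] <- TRUE; b[1, 1] <- TRUE
  z <- array(FALSE, c(2, 2))
  # 2 of 3 -> foreground
  expect_true(majority_vote(list(a, b, z))[1, 1])
  # 2 of 5 -> background
  expect_false(majority_vote(list(a, b, z, z, z))[1, 1])
  expect_error(majority_vote(list()), "non-empty")
})

test_that("per-label evaluation matches per-label brute force", {
  lab <- array(0L, c(12, 12, 6))
  lab[3:5, 3:5, 2:4] <- 1L
  lab[8:10, 8:10, 2:4] <- 2L
  expect_warning(rep0 <- evaluate_labels(lab, lab), NA)
  expect_true(all(rep0$auc == 1))
  expect_true(all(rep0$ms == 1))
  expect_true(all(rep0$mad == 0))
  # perturbed second label
  seg <- lab
  seg[seg == 2L] <- 0L
  seg[8:11, 8:10, 2:4] <- 2L
  rep1 <- evaluate_labels(lab, seg)
  expect_equal(rep1$ms[rep1$label == 1], 1)
  expect_equal(rep1$ms[rep1$label == 2],
               mean_similarity(lab == 2, seg == 2))
  expect_equal(rep1$mad[rep1$label == 2],
               granulometric_mad(lab == 2, seg == 2))
  # a label missing from the segmentation becomes a missing entry, not an error
  seg2 <- lab; seg2[seg2 == 2L] <- 0L
  rep2 <- evaluate_labels(lab, seg2, labels = 1:2)
  expect_true(rep2$missing[rep2$label == 2])
  expect_false(rep2$missing[rep2$label == 1])
})

test_that("one-voxel dilation of a label yields MAD about 1", {
  lab <- array(0L, c(20, 20, 12)); lab[6:14, 6:14, 4:9] <- 1L
  seg <- array(0L, dim = dim(lab))
  seg[morph(lab == 1L, "dilate", "diamond", 1L)] <- 1L
  rep <- evaluate_labels(lab, seg)
  expect_lt(abs(rep$mad[1] - 1), 0.2)
})

test_that("metrics reports serialize to CSV and JSON", {
  lab <- array(0L, c(8, 8, 4)); lab[2:4, 2:4, 2:3] <- 1L
  rep <- evaluate_labels(lab, lab)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics(rep, csv); write_metrics(rep, js)
  back <- utils::read.csv(csv)
  expect_equal(back$auc, rep$auc)
  jj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jj$per_label$ms, rep$ms)
  unlink(c(csv, js))
})
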