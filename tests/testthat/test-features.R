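test_that("peak_local_max suppresses by distance with intensity priority", {
  img <- matrix(0, 100, 100)
  img[20, 20] <- 0.9; img[20, 70] <- 0.8       # 50 px apart
  p <- peak_local_max(as_image(img, "float"), 20)
  expect_equal(length(p$rows), 2L)
  img2 <- matrix(0, 100, 100)
  img2[20, 20] <- 0.8; img2[20, 30] <- 0.9     # 10 px apart
  p2 <- peak_local_max(as_image(img2, "float"), 20)
  expect_equal(cbind(p2$rows, p2$cols), cbind(20L, 30L))
  expect_length(peak_local_max(as_image(matrix(0.3, 30, 30), "float"),
                               5)$rows, 0L)
})

test_that("peak_local_max agrees with the exhaustive suppression oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    v <- matrix(runif(64 * 64), 64, 64)
    for (md in c(3L, 10L, 20L)) {
      got <- peak_local_max(as_image(v, "float"), md)
      want <- peak_oracle(v, md)
      expect_equal(got$rows, want$rows, info = sprintf("seed %d md %d", s, md))
      expect_equal(got$cols, want$cols, info = sprintf("seed %d md %d", s, md))
    }
  }
})

test_that("FAST-9 fires on isolated points and corners, not edges or flats", {
  expect_length(detect_fast(as_image(matrix(0.5, 30, 30), "float"),
                            0.05)$rows, 0L)
  f <- matrix(0.5, 30, 30); f[15, 15] <- 0.9
  d <- detect_fast(as_image(f, "float"), 0.1)
  expect_true(any(d$rows == 15 & d$cols == 15))
  sq <- matrix(0.1, 40, 40); sq[11:30, 11:30] <- 0.9
  d2 <- detect_fast(as_image(sq, "float"), 0.2)
  expect_gt(length(d2$rows), 0L)
  # every detection clusters at one of the four corners ...
  near_corner <- outer(d2$rows, c(11, 30), function(a, b) abs(a - b) <= 3)
  near_corner_c <- outer(d2$cols, c(11, 30), function(a, b) abs(a - b) <= 3)
  expect_true(all(rowSums(near_corner) > 0 & rowSums(near_corner_c) > 0))
  # ... and never at edge midpoints (only 8 contiguous circle pixels differ)
  expect_false(any(d2$rows == 20 & d2$cols %in% c(11, 30)))
  expect_false(any(d2$cols == 20 & d2$rows %in% c(11, 30)))
})

test_that("ORB keypoint counts, orientation and rotation robustness behave", {
  # fewer corners than requested: all are returned
  f <- matrix(0.5, 60, 60); f[25, 25] <- 0.9; f[40, 35] <- 0.1
  o <- orb_detect_and_extract(as_image(f, "float"), n_keypoints = 100,
                              fast_threshold = 0.1, n_scales = 1)
  expect_lt(nrow(o$keypoints), 100L)
  expect_equal(nrow(o$keypoints), nrow(o$descriptors))
  # orientation: bright mass due east of a dark corner pixel -> theta ~ 0
  east <- matrix(0.2, 61, 61)
  east[29:33, 31:44] <- 0.9
  oe <- orb_detect_and_extract(as_image(east, "float"), 5, 0.2, n_scales = 1)
  k <- which.min((oe$keypoints$row - 31)^2 + (oe$keypoints$col - 31)^2)
  expect_lt(abs(oe$keypoints$orientation[k]), pi / 6)
  # matching an image to its 90-degree rotation: distances far below the
  # 128-bit random expectation
  tex <- make_textured_pair(shape = c(120, 120), seed = 11)$image1
  rot <- as_image(t(unclass(tex))[, 120:1], "float")
  f1 <- orb_detect_and_extract(tex, 150, 0.05)
  f2 <- orb_detect_and_extract(rot, 150, 0.05)
  mm <- match_descriptors(f1$descriptors, f2$descriptors, cross_check = TRUE)
  expect_gt(nrow(mm), 30L)
  expect_lt(median(mm$distance), 64)
  expect_error(orb_detect_and_extract(as_image(matrix(0.5, 20, 20), "float")),
               "too small")
})

test_that("descriptor matching recovers permutations and stays injective", {
  set.seed(4)
  d1 <- matrix(runif(40 * 256) > 0.5, 40, 256)
  perm <- sample(40)
  d2 <- d1[perm, ]
  m <- match_descriptors(d1, d2, cross_check = TRUE)
  expect_equal(nrow(m), 40L)
  expect_true(all(m$distance == 0))
  expect_equal(order(perm)[m$idx1], m$idx2)
  # self-distance zero
  ms <- match_descriptors(d1, d1, cross_check = TRUE)
  expect_true(all(ms$idx1 == ms$idx2) && all(ms$distance == 0))
  # duplicated identical descriptors: tie-break by lowest index keeps a
  # partial one-to-one mapping
  dup <- d1[c(1, 1, 2, 2), ]
  md <- match_descriptors(dup, dup, cross_check = TRUE)
  expect_true(!any(duplicated(md$idx1)) && !any(duplicated(md$idx2)))
  # empty input gives an empty match set
  e <- match_descriptors(matrix(logical(0), 0, 256), d1)
  expect_equal(nrow(e), 0L)
})

test_that("cross-checked matches on a rotated pair land near the truth mapping", {
  rotn <- transform_similarity(rotation = 0.3,
                               translation = c(30, -12))
  pp <- make_textured_pair(shape = c(140, 140), transform = rotn, seed = 6)
  f1 <- orb_detect_and_extract(pp$image1, 250, 0.05)
  f2 <- orb_detect_and_extract(pp$image2, 250, 0.05)
  mm <- match_descriptors(f1$descriptors, f2$descriptors, cross_check = TRUE)
  expect_false(any(duplicated(mm$idx1)))
  expect_false(any(duplicated(mm$idx2)))
  src <- cbind(f2$keypoints$col[mm$idx2] - 1, f2$keypoints$row[mm$idx2] - 1)
  dst <- cbind(f1$keypoints$col[mm$idx1] - 1, f1$keypoints$row[mm$idx1] - 1)
  pred <- transform_apply(pp$truth$transform, src)
  err <- sqrt(rowSums((pred - dst)^2))
  expect_gte(mean(err <= 2), 0.5)
})
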