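test_that("gaussian filtering preserves DC and normalizes the impulse", {
  const <- as_image(matrix(0.4, 20, 20), "float")
  expect_equal(max(abs(unclass(gaussian_filter(const, 2)) - 0.4)), 0,
               tolerance = 1e-12)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  g <- unclass(gaussian_filter(as_image(imp, "float"), 1))
  k <- exp(-(-4:4)^2 / 2); k <- k / sum(k)
  expect_equal(g[21, 21], max(k)^2, tolerance = 1e-9)
  expect_equal(sum(g), 1, tolerance = 1e-6)
  # mean conservation under the reflective boundary
  set.seed(2)
  r <- matrix(runif(900), 30, 30)
  expect_equal(mean(unclass(gaussian_filter(as_image(r, "float"), 3))),
               mean(r), tolerance = 1e-6)
  expect_error(gaussian_filter(const, -1), "sigma")
  expect_true(all(gaussian_filter(const, 0) == const))
})

test_that("sobel responds to steps, not constants or offsets", {
  expect_lt(max(sobel(as_image(matrix(0.7, 15, 15), "float"))), 1e-12)
  step <- matrix(0.2, 20, 20); step[, 11:20] <- 0.9
  s <- sobel(as_image(step, "float"))
  expect_true(all(s[, c(10, 11)] == max(s)))
  expect_lt(max(s[, c(1:8, 13:20)]), 1e-12)
  # invariance to a constant offset
  s2 <- sobel(as_image(step - 0.1, "float"))
  expect_equal(s, s2, tolerance = 1e-12)
})

test_that("filters commute with transposition", {
  set.seed(5)
  m <- matrix(runif(400), 20, 20)
  fm <- as_image(m, "float"); ft <- as_image(t(m), "float")
  expect_equal(t(unclass(gaussian_filter(fm, 1.5))),
               unclass(gaussian_filter(ft, 1.5)), tolerance = 1e-12)
  expect_equal(t(sobel(fm)), sobel(ft), tolerance = 1e-12)
  expect_equal(t(difference_of_gaussians(fm, 1, 2)),
               difference_of_gaussians(ft, 1, 2), tolerance = 1e-12)
  u <- as_image(matrix(sample(0:255, 400, TRUE), 20, 20), "u8")
  ut <- as_image(t(matrix(unclass(u), 20, 20)), "u8")
  expect_equal(t(matrix(unclass(median_filter(u, 1)), 20, 20)),
               matrix(unclass(median_filter(ut, 1)), 20, 20))
})

test_that("median filtering removes salt, keeps lines, and is idempotent on flats", {
  flat <- as_image(matrix(20L, 15, 15), "u8")
  expect_true(all(median_filter(flat, 2) == flat))
  salt <- matrix(10L, 20, 20); salt[7, 9] <- 255L
  expect_true(all(median_filter(as_image(salt, "u8"), 1) == 10))
  line <- matrix(10L, 30, 30); line[15, ] <- 200L
  mf <- median_filter(as_image(line, "u8"), 1)
  expect_true(all(unclass(mf)[15, ] == 200))
  expect_true(all(unclass(mf)[-15, ] == 10))
  # piecewise-constant fixed point
  expect_true(all(median_filter(mf, 1) == mf))
  expect_error(median_filter(as_image(matrix(0.5, 5, 5), "float"), 1), "u8")
})

test_that("difference of Gaussians is zero-mean band-pass with center-surround", {
  const <- as_image(matrix(0.6, 25, 25), "float")
  expect_equal(max(abs(difference_of_gaussians(const, 1, 3))), 0,
               tolerance = 1e-12)
  set.seed(3)
  r <- as_image(matrix(runif(625), 25, 25), "float")
  expect_equal(mean(difference_of_gaussians(r, 1, 3)), 0, tolerance = 1e-3)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  d <- difference_of_gaussians(as_image(imp, "float"), 1, 3)
  expect_gt(d[21, 21], 0)
  expect_lt(d[21, 24], 0)   # surround outside the zero crossing (~2.2 px)
  expect_error(difference_of_gaussians(r, 2, 1), "low_sigma")
})

test_that("canny localizes a square contour to within one pixel", {
  img <- matrix(0.2, 100, 100); img[31:70, 31:70] <- 0.8
  e <- canny(as_image(img, "float"), sigma = 1, low_threshold = 0.3,
             high_threshold = 0.8)
  expect_type(e, "logical")
  pix <- which(e, arr.ind = TRUE)
  expect_gt(nrow(pix), 100)
  d <- rect_outline_distance(pix[, 1], pix[, 2], 30.5, 70.5, 30.5, 70.5)
  expect_gte(mean(d <= 1), 0.95)
  # recall along the boundary, corners excluded
  tb <- rbind(cbind(seq(36, 65, by = 0.5), 30.5),
              cbind(seq(36, 65, by = 0.5), 70.5),
              cbind(30.5, seq(36, 65, by = 0.5)),
              cbind(70.5, seq(36, 65, by = 0.5)))
  rec <- vapply(seq_len(nrow(tb)), function(i)
    min(sqrt((pix[, 1] - tb[i, 1])^2 + (pix[, 2] - tb[i, 2])^2)) <= 1,
    logical(1))
  expect_gte(mean(rec), 0.95)
  # the contour is closed: a single 8-connected component
  expect_equal(label(e, 2L)$n_labels, 1L)
})

test_that("canny hysteresis drops weak-only fragments and is monotone in high", {
  expect_equal(sum(canny(as_image(matrix(0.5, 40, 40), "float"), 1,
                         0.1, 0.2)), 0)
  weak <- matrix(0.2, 60, 60); weak[20:40, 20:40] <- 0.35
  expect_equal(sum(canny(as_image(weak, "float"), 1, 0.3, 0.8)), 0)
  # same geometry at full contrast is found
  strong <- matrix(0.2, 60, 60); strong[20:40, 20:40] <- 0.8
  e1 <- canny(as_image(strong, "float"), 1, 0.3, 0.8)
  expect_gt(sum(e1), 0)
  e2 <- canny(as_image(strong, "float"), 1, 0.3, 1.2)
  expect_true(all(which(e2) %in% which(e1)))
  expect_error(canny(as_image(strong, "float"), 1, 0.9, 0.2), "low_threshold")
})

test_that("adaptive thresholding tracks local illumination", {
  const <- as_image(matrix(0.5, 30, 30), "float")
  expect_true(all(threshold_adaptive(const, 15, offset = 0.1)))
  expect_true(!any(threshold_adaptive(const, 15, offset = 0)))
  expect_true(!any(threshold_adaptive(const, 15, offset = -0.1)))
  expect_error(threshold_adaptive(const, 14, 0), "odd")
  # bright disk on dark field: detected as (a tight superset of) the disk
  img <- matrix(0.2, 90, 90)
  rr <- matrix(seq_len(90), 90, 90); cc <- t(rr)
  disk <- (rr - 45)^2 + (cc - 45)^2 <= 15^2
  img[disk] <- 0.8
  bw <- threshold_adaptive(as_image(img, "float"), 89, 0)
  expect_true(all(bw[disk]))
  dil <- (rr - 45)^2 + (cc - 45)^2 <= 17^2
  expect_true(!any(bw[!dil]))
  # ramp + blobs: a global Otsu split misses one end, the local one does not
  ramp <- matrix(rep(seq(0.1, 0.7, length.out = 100), each = 80), 80, 100)
  for (ctr in c(15, 85))
    ramp[37:43, (ctr - 3):(ctr + 3)] <- ramp[37:43, (ctr - 3):(ctr + 3)] + 0.25
  ramp <- pmin(ramp, 1)
  bw2 <- threshold_adaptive(as_image(ramp, "float"), 21, -0.05)
  expect_true(any(bw2[37:43, 12:18]))
  expect_true(any(bw2[37:43, 82:88]))
  expect_lt(mean(bw2), 0.1)
  u8 <- round(ramp * 255)
  tg <- otsu_oracle(as.vector(u8)) / 255
  global <- ramp > tg
  misses_left <- !any(global[37:43, 12:18]) || mean(global[, 90:100]) > 0.5
  expect_true(misses_left)
})
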