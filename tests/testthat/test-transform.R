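test_that("homogeneous point action follows the (x, y) convention", {
  p <- cbind(c(0, 3, -2), c(0, 1, 7))
  expect_equal(transform_apply(transform_identity(), p), p)
  tr <- transform_similarity(translation = c(4, -2))
  expect_equal(transform_apply(tr, cbind(0, 0)), cbind(4, -2))
  # perspective division
  H <- diag(3); H[3, 1] <- 0.001
  pt <- transform_apply(transform_from_matrix(H, "projective"),
                        cbind(100, 0))
  expect_equal(pt, cbind(100 / 1.1, 0), tolerance = 1e-12)
  # line at infinity
  H2 <- diag(3); H2[3, ] <- c(-0.01, 0, 1)
  expect_error(transform_apply(transform_from_matrix(H2, "projective"),
                               cbind(100, 0)), "infinity")
})

test_that("inverse and composition obey the 'a then b' algebra", {
  t1 <- transform_similarity(1.3, 0.7, c(5, -3))
  comp <- transform_compose(t1, transform_inverse(t1))
  expect_equal(comp$matrix, diag(3), tolerance = 1e-9)
  ta <- transform_similarity(translation = c(1, 2))
  tb <- transform_similarity(translation = c(3, 4))
  expect_equal(transform_compose(ta, tb)$matrix,
               transform_similarity(translation = c(4, 6))$matrix)
  # action order: a then b
  pr <- random_projective()
  p <- cbind(c(1, 10), c(2, 5))
  expect_equal(transform_apply(transform_compose(t1, pr), p),
               transform_apply(pr, transform_apply(t1, p)),
               tolerance = 1e-9)
  # kind lattice
  expect_equal(transform_compose(t1, pr)$kind, "projective")
  expect_equal(transform_compose(t1, ta)$kind, "similarity")
  expect_error(transform_from_matrix(matrix(0, 3, 3)), "singular")
})

test_that("estimation reproduces exact correspondences to 1e-8 for all kinds", {
  for (kind in c("similarity", "affine", "projective")) {
    for (s in 1:50) {
      set.seed(1000 + s)
      t_true <- random_transform(kind)
      src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
      dst <- transform_apply(t_true, src)
      est <- estimate_transform(kind, src, dst)
      expect_lt(max(abs(transform_apply(est, src) - dst)), 1e-8)
      expect_equal(est$kind, kind)
    }
  }
  # unit-square corners under a known homography: matrix recovered
  H <- matrix(c(1.1, 0.2, 3, -0.1, 0.9, 1, 2e-3, -1e-3, 1), 3, byrow = TRUE)
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  est <- estimate_transform("projective", sq,
                            transform_apply(transform_from_matrix(H), sq))
  expect_lt(max(abs(est$matrix - H)), 1e-8)
  # src = dst gives the identity
  expect_equal(estimate_transform("affine", sq, sq)$matrix, diag(3),
               tolerance = 1e-10)
  # degenerate (collinear) configurations are rejected
  col_pts <- cbind(1:4, 2 * (1:4))
  expect_error(estimate_transform("projective", col_pts, col_pts),
               "degenerate")
})

test_that("noisy similarity estimation recovers the rotation", {
  t_true <- transform_similarity(1.2, 0.6, c(10, -5))
  set.seed(99)
  src <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  dst <- transform_apply(t_true, src) + matrix(rnorm(100, 0, 0.1), 50)
  est <- estimate_transform("similarity", src, dst)
  ang <- atan2(est$matrix[2, 1], est$matrix[1, 1])
  expect_lt(abs(ang - 0.6), 0.01)
})

test_that("warp is exact on identity and integer translations", {
  img <- make_textured_pair(shape = c(48, 48), seed = 2)$image1
  expect_identical(unclass(warp(img, transform_identity())), unclass(img))
  # inverse map shifting by (+5, +3) moves content and fills with cval
  w <- warp(img, transform_similarity(translation = c(5, 3)),
            cval = -1)
  wv <- unclass(w); iv <- unclass(img)
  expect_equal(wv[1:45, 1:43], iv[4:48, 6:48])
  expect_true(all(wv[46:48, ] == -1))
  expect_true(all(wv[, 44:48] == -1))
  # constant images survive any warp where samples stay in-bounds
  cimg <- as_image(matrix(0.33, 40, 40), "float")
  rotw <- warp(cimg, transform_similarity(rotation = 0.3,
                                          translation = c(10, -18)),
               cval = 0.33)
  expect_equal(max(abs(unclass(rotw) - 0.33)), 0, tolerance = 1e-12)
})

test_that("warp round trip through a smooth image stays within tolerance", {
  sm <- make_textured_pair(shape = c(80, 80), seed = 9)$image1
  t1 <- transform_similarity(rotation = 0.25, translation = c(4, 2))
  fwd <- warp(sm, transform_inverse(t1), output_shape = c(120, 120),
              cval = -1)
  fwd_img <- as_image(pmin(pmax(unclass(fwd), 0), 1), "float")
  back <- warp(fwd_img, t1, output_shape = c(80, 80), cval = -1)
  interior <- unclass(back)[20:60, 20:60]
  truth <- unclass(sm)[20:60, 20:60]
  expect_lt(max(abs(interior - truth)), 0.02)
})

test_that("rescale honors shapes, constants and the identity factor", {
  img <- make_textured_pair(shape = c(100, 100), seed = 1)$image1
  expect_identical(unclass(rescale(img, 1)), unclass(img))
  expect_equal(dim(rescale(img, 0.25))[1:2], c(25, 25))
  expect_equal(dim(rescale(img, 0.5))[1:2], c(50, 50))
  const <- as_image(matrix(0.77, 60, 60), "float")
  expect_equal(max(abs(unclass(rescale(const, 0.25)) - 0.77)), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(unclass(rescale(const, 2)) - 0.77)), 0,
               tolerance = 1e-9)
  expect_error(rescale(img, 0), "factor")
})

test_that("line Hough voting is conserved and localizes axis lines", {
  empty <- hough_line(matrix(FALSE, 30, 30))
  expect_true(all(empty$accumulator == 0))
  expect_equal(nrow(empty$peaks), 0L)
  b <- matrix(FALSE, 100, 100); b[, 31] <- TRUE
  hl <- hough_line(b)
  expect_equal(hl$peaks$count[1], 100)
  expect_equal(hl$peaks$theta[1], 0)
  expect_equal(hl$peaks$rho[1], 30)
  # votes conserved: every ON pixel votes once per theta
  expect_equal(sum(hl$accumulator), sum(b) * length(hl$thetas))
  b2 <- matrix(FALSE, 80, 80); b2[21, ] <- TRUE; b2[, 31] <- TRUE
  pk <- hough_line(b2, threshold = 60)$peaks
  expect_equal(nrow(pk), 2L)
  expect_true(any(abs(pk$theta) < 1e-9 & pk$rho == 30))
  expect_true(any(abs(pk$theta + pi / 2) < 1e-9 & pk$rho == -20))
  set.seed(8)
  rb <- matrix(runif(900) < 0.1, 30, 30)
  hr <- hough_line(rb)
  expect_equal(sum(hr$accumulator), sum(rb) * length(hr$thetas))
})

test_that("circle Hough recovers drawn circles exactly", {
  b <- matrix(FALSE, 120, 120)
  b <- paint(b, draw_circle_perimeter(51, 61, 20), TRUE)
  pk <- hough_circle(b, 15:25)$peaks
  expect_equal(c(pk$row[1], pk$col[1], pk$radius[1]), c(51, 61, 20))
  expect_equal(nrow(hough_circle(matrix(FALSE, 40, 40), 5:8)$peaks), 0L)
  # two disjoint circles, both found at their true parameters
  b2 <- matrix(FALSE, 100, 100)
  b2 <- paint(b2, draw_circle_perimeter(26, 26, 10), TRUE)
  b2 <- paint(b2, draw_circle_perimeter(70, 65, 14), TRUE)
  pk2 <- hough_circle(b2, c(8:16), num_peaks = 2)$peaks
  got <- pk2[order(pk2$radius), c("row", "col", "radius")]
  expect_equal(unname(as.matrix(got)),
               rbind(c(26, 26, 10), c(70, 65, 14)))
})
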