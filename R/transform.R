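#' Planar geometric transforms
#'
#' A `geom_transform` is a 3x3 homogeneous matrix acting on (x, y) =
#' (column, row) points, 0-based — the usual literature convention,
#' dual to the (row, column) indexing of image arrays.  Three kinds
#' form a lattice: `"similarity"` (rotation + isotropic scale +
#' translation) within `"affine"` within `"projective"`.
#'
#' @param matrix 3x3 invertible matrix.
#' @param kind one of `"similarity"`, `"affine"`, `"projective"`.
#' @return A `geom_transform` object.
#' @name geom_transform
NULL

#' @rdname geom_transform
#' @export
transform_from_matrix <- function(matrix, kind = "projective") {
  kind <- match.arg(kind, c("similarity", "affine", "projective"))
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3L, 3L)))
  if (abs(det(matrix)) < 1e-14)
    stop("transform matrix is singular", call. = FALSE)
  if (kind != "projective" &&
      max(abs(matrix[3L, ] - c(0, 0, 1))) > 1e-12)
    stop(sprintf("%s transform must have last row (0, 0, 1)", kind),
         call. = FALSE)
  if (abs(matrix[3L, 3L]) > 1e-14) matrix <- matrix / matrix[3L, 3L]
  structure(list(matrix = matrix, kind = kind), class = "geom_transform")
}

#' @rdname geom_transform
#' @export
transform_identity <- function() {
  transform_from_matrix(diag(3), "similarity")
}

#' @rdname geom_transform
#' @param scale isotropic scale factor.
#' @param rotation rotation angle in radians (counter-clockwise in
#'   (x, y)).
#' @param translation length-2 (tx, ty).
#' @export
transform_similarity <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  m <- diag(3)
  m[1:2, 1:2] <- scale * rbind(c(cos(rotation), -sin(rotation)),
                               c(sin(rotation),  cos(rotation)))
  m[1:2, 3L] <- translation
  transform_from_matrix(m, "similarity")
}

#' @export
print.geom_transform <- function(x, ...) {
  cat(sprintf("<geom_transform: %s>\n", x$kind))
  print(x$matrix)
  invisible(x)
}

#' Apply a transform to (x, y) points
#'
#' Homogeneous action with perspective division.  Points on the line at
#' infinity (w = 0) raise a singularity error.
#'
#' @param t a [geom_transform].
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed (x, y).
#' @export
transform_apply <- function(t, points) {
  points <- rbind(points)
  h <- t$matrix %*% rbind(t(points), 1)
  w <- h[3L, ]
  if (any(abs(w) < 1e-12))
    stop("point mapped to the line at infinity", call. = FALSE)
  cbind(h[1L, ] / w, h[2L, ] / w)
}

#' @rdname transform_apply
#' @export
transform_inverse <- function(t) {
  transform_from_matrix(solve(t$matrix), t$kind)
}

#' Compose two transforms ("a then b")
#'
#' `transform_apply(transform_compose(a, b), p)` equals
#' `transform_apply(b, transform_apply(a, p))`.  The composite's kind
#' is the least restrictive of the two.
#'
#' @param a,b [geom_transform]s.
#' @export
transform_compose <- function(a, b) {
  lattice <- c(similarity = 1L, affine = 2L, projective = 3L)
  kind <- names(lattice)[max(lattice[a$kind], lattice[b$kind])]
  transform_from_matrix(b$matrix %*% a$matrix, kind)
}

#' Least-squares transform estimation from point correspondences
#'
#' Similarity uses the closed-form rotation/scale/translation fit
#' (Umeyama); affine is a linear least-squares solve; projective uses
#' the direct linear transform on Hartley-normalized coordinates.
#' Exact correspondences are reproduced to 1e-8.
#'
#' @param kind `"similarity"`, `"affine"` or `"projective"`.
#' @param src,dst n x 2 matrices of (x, y) points; n must be at least
#'   2, 3, 4 respectively, and the points non-degenerate.
#' @return A [geom_transform] mapping `src` onto `dst`.
#' @export
estimate_transform <- function(kind, src, dst) {
  kind <- match.arg(kind, c("similarity", "affine", "projective"))
  src <- rbind(src); dst <- rbind(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  n <- nrow(src)
  need <- c(similarity = 2L, affine = 3L, projective = 4L)[kind]
  if (n < need)
    stop(sprintf("%s estimation needs >= %d correspondences", kind, need),
         call. = FALSE)
  m <- switch(kind,
    similarity = est_similarity(src, dst),
    affine = est_affine(src, dst),
    projective = est_projective(src, dst))
  transform_from_matrix(m, kind)
}

est_similarity <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  xs <- sweep(src, 2L, ms); xd <- sweep(dst, 2L, md)
  sigma <- crossprod(xd, xs) / nrow(src)        # 2x2 covariance
  sv <- svd(sigma)
  s <- diag(2)
  if (det(sv$u) * det(sv$v) < 0) s[2L, 2L] <- -1
  R <- sv$u %*% s %*% t(sv$v)
  var_s <- sum(xs^2) / nrow(src)
  if (var_s < 1e-20) stop("degenerate similarity configuration", call. = FALSE)
  scale <- sum(diag(diag(sv$d, 2L) %*% s)) / var_s
  t_vec <- md - scale * R %*% ms
  m <- diag(3)
  m[1:2, 1:2] <- scale * R
  m[1:2, 3L] <- t_vec
  m
}

est_affine <- function(src, dst) {
  A <- cbind(src, 1)
  if (qr(A)$rank < 3L)
    stop("degenerate (collinear) affine configuration", call. = FALSE)
  coef <- qr.solve(A, dst)                      # 3x2
  m <- diag(3)
  m[1L, ] <- c(coef[1L, 1L], coef[2L, 1L], coef[3L, 1L])
  m[2L, ] <- c(coef[1L, 2L], coef[2L, 2L], coef[3L, 2L])
  m
}

hartley_normalize <- function(p) {
  mu <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2L, mu)^2))
  s <- if (mean(d) < 1e-12) 1 else sqrt(2) / mean(d)
  T <- rbind(c(s, 0, -s * mu[1L]), c(0, s, -s * mu[2L]), c(0, 0, 1))
  list(T = T, p = cbind(s * (p[, 1L] - mu[1L]), s * (p[, 2L] - mu[2L])))
}

est_projective <- function(src, dst) {
  ns <- hartley_normalize(src); nd <- hartley_normalize(dst)
  x <- ns$p[, 1L]; y <- ns$p[, 2L]
  u <- nd$p[, 1L]; v <- nd$p[, 2L]
  n <- length(x)
  A <- matrix(0, 2L * n, 9L)
  A[seq_len(n) * 2L - 1L, ] <- cbind(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
  A[seq_len(n) * 2L, ]      <- cbind(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  sv <- svd(A, nu = 0L, nv = 9L)
  if (sv$d[8L] < 1e-10 * max(sv$d))
    stop("degenerate projective configuration", call. = FALSE)
  h <- sv$v[, 9L]
  H <- matrix(h, 3L, 3L, byrow = TRUE)
  m <- solve(nd$T) %*% H %*% ns$T
  if (abs(m[3L, 3L]) < 1e-14)
    stop("degenerate projective configuration", call. = FALSE)
  m / m[3L, 3L]
}

#' Inverse-mapping image warp with bilinear interpolation
#'
#' For each output pixel, `inverse_map` sends its 0-based (x, y)
#' coordinates into the input image, where the value is sampled
#' bilinearly; samples falling outside the input are set to `cval`.
#' At exact integer coordinates the sample equals the pixel value, so
#' identity and integer-translation maps are lossless.
#'
#' @param image a single-channel image.
#' @param inverse_map a [geom_transform] mapping output (x, y) to input
#'   (x, y).
#' @param output_shape rows, cols of the output (default: input shape).
#' @param cval fill value for out-of-bounds samples (the panorama
#'   pipeline uses -1 as a background sentinel).
#' @param mode `"constant"` fills out-of-bounds samples with `cval`;
#'   `"edge"` clamps sample coordinates to the image border.
#' @return A float image when all samples lie in \[0, 1\], otherwise a
#'   plain numeric matrix (e.g. when `cval` is a sentinel).
#' @export
warp <- function(image, inverse_map, output_shape = NULL, cval = 0,
                 mode = c("constant", "edge")) {
  mode <- match.arg(mode)
  v <- as_gray_float(image)
  if (is.null(output_shape)) output_shape <- dim(v)
  nr <- as.integer(output_shape[1L]); nc <- as.integer(output_shape[2L])
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  p <- transform_apply(inverse_map, cbind(xs, ys))
  px <- p[, 1L]; py <- p[, 2L]
  if (mode == "edge") {
    px <- pmin(pmax(px, 0), ncol(v) - 1)
    py <- pmin(pmax(py, 0), nrow(v) - 1)
  }
  out <- bilinear_sample(v, px, py, cval)
  out <- matrix(out, nr, nc)
  if (min(out) >= 0 && max(out) <= 1) as_image(out, "float") else out
}

# bilinear sampling at 0-based continuous (x, y); outside [0, nc-1] x
# [0, nr-1] -> cval
bilinear_sample <- function(v, x, y, cval = 0) {
  nr <- nrow(v); nc <- ncol(v)
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  out <- rep(cval, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  val <- (1 - fy) * ((1 - fx) * v[i00] + fx * v[i01]) +
         fy * ((1 - fx) * v[i10] + fx * v[i11])
  out[inside] <- val
  out
}

#' Rescale an image by a constant factor
#'
#' Implemented as a [warp()] whose inverse map is an isotropic scale by
#' `1/factor`; the output shape is `ceiling(shape * factor)`.  For
#' `factor < 1` the input is first smoothed with an anti-aliasing
#' Gaussian of sigma `(1/factor - 1)/2`.
#'
#' @param image a single-channel image.
#' @param factor scale factor (> 0); 1 returns the input unchanged.
#' @return A float image.
#' @export
rescale <- function(image, factor) {
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  v <- as_gray_float(image)
  if (factor == 1) return(as_image(v, "float"))
  if (factor < 1) v <- gaussian_blur_matrix(v, (1 / factor - 1) / 2)
  out_shape <- ceiling(dim(v) * factor)
  w <- warp(as_image(pmin(pmax(v, 0), 1), "float"),
            transform_similarity(scale = 1 / factor),
            output_shape = out_shape, mode = "edge")
  as_image(pmin(pmax(img_data(w), 0), 1), "float")
}

#' Line Hough transform
#'
#' Every ON pixel (r, c) votes, for each angle theta, at the signed
#' distance `rho = c*cos(theta) + r*sin(theta)` (0-based coordinates),
#' rounded to a unit-spaced rho grid covering +/- the image diagonal.
#' Peaks are accumulator local maxima at or above `threshold` (default
#' half the maximum count).
#'
#' @param binary logical matrix of edge pixels.
#' @param thetas angle grid in radians (default: 180 values evenly
#'   spaced over \[-pi/2, pi/2)).
#' @param threshold minimum vote count for a peak, or `NULL` for half
#'   the accumulator maximum.
#' @param num_peaks maximum number of peaks to report.
#' @return list with `accumulator` (rho x theta count matrix), `thetas`,
#'   `rhos`, and `peaks` (data.frame with count, theta, rho).
#' @export
hough_line <- function(binary, thetas = NULL, threshold = NULL,
                       num_peaks = Inf) {
  if (is.null(thetas)) thetas <- seq(-pi / 2, pi / 2, length.out = 181L)[1:180]
  stopifnot(is.logical(binary) || all(binary %in% c(0, 1)))
  nr <- nrow(binary); nc <- ncol(binary)
  diag_len <- ceiling(sqrt((nr - 1)^2 + (nc - 1)^2))
  rhos <- seq(-diag_len, diag_len)
  acc <- matrix(0L, length(rhos), length(thetas))
  on <- which(binary != 0, arr.ind = TRUE)
  if (nrow(on) > 0L) {
    r <- on[, 1L] - 1; c <- on[, 2L] - 1
    for (j in seq_along(thetas)) {
      rho <- round(c * cos(thetas[j]) + r * sin(thetas[j]))
      idx <- rho + diag_len + 1
      acc[, j] <- acc[, j] + tabulate(idx, nbins = length(rhos))
    }
  }
  peaks <- hough_line_peaks(acc, thetas, rhos, threshold, num_peaks)
  list(accumulator = acc, thetas = thetas, rhos = rhos, peaks = peaks)
}

hough_line_peaks <- function(acc, thetas, rhos, threshold, num_peaks) {
  if (is.null(threshold)) threshold <- max(acc) / 2
  cand <- which(acc >= pmax(threshold, 1), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(count = integer(0), theta = numeric(0),
                      rho = numeric(0)))
  # strict local maxima in the 3x3 accumulator neighborhood (ties kept
  # once, preferring lower rho then lower theta index)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; c <- cand[i, 2L]
    win <- acc[max(1, r - 1):min(nrow(acc), r + 1),
               max(1, c - 1):min(ncol(acc), c + 1)]
    keep[i] <- acc[r, c] == max(win)
  }
  cand <- cand[keep, , drop = FALSE]
  counts <- acc[cand]
  ord <- order(-counts, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  counts <- counts[ord]
  n <- min(nrow(cand), num_peaks)
  data.frame(count = counts[seq_len(n)],
             theta = thetas[cand[seq_len(n), 2L]],
             rho = rhos[cand[seq_len(n), 1L]])
}

#' Circle Hough transform
#'
#' Each ON pixel votes for candidate centers along a rasterized circle
#' of every candidate radius around itself (center-candidate
#' accumulation).  Peaks are ranked across radii by vote count
#' normalized by the circle circumference `2*pi*R`, which removes the
#' large-radius bias.
#'
#' @param binary logical matrix of edge pixels.
#' @param radii integer vector of candidate radii (>= 1).
#' @param num_peaks maximum number of peaks to report.
#' @return list with `accumulators` (one count matrix per radius) and
#'   `peaks` (data.frame with count, normalized count, row, col,
#'   radius; 1-based row/col).
#' @export
hough_circle <- function(binary, radii, num_peaks = 1L) {
  stopifnot(all(radii >= 1))
  nr <- nrow(binary); nc <- ncol(binary)
  on <- which(binary != 0, arr.ind = TRUE)
  accs <- vector("list", length(radii))
  names(accs) <- as.character(radii)
  peak_rows <- list()
  for (k in seq_along(radii)) {
    R <- radii[k]
    acc <- matrix(0L, nr, nc)
    if (nrow(on) > 0L) {
      off <- draw_circle_perimeter(0L, 0L, R)
      pr <- rep(on[, 1L], times = length(off$rows)) +
            rep(off$rows, each = nrow(on))
      pc <- rep(on[, 2L], times = length(off$rows)) +
            rep(off$cols, each = nrow(on))
      ok <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
      idx <- (pc[ok] - 1L) * nr + pr[ok]
      acc <- matrix(tabulate(idx, nbins = nr * nc), nr, nc)
    }
    accs[[k]] <- acc
    if (max(acc) > 0L) {
      best <- which.max(acc)       # first (row-major within column) max
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(count = max(acc), norm = max(acc) / (2 * pi * R),
                   row = (best - 1L) %% nr + 1L,
                   col = (best - 1L) %/% nr + 1L, radius = R)
    }
  }
  peaks <- if (length(peak_rows) > 0L) do.call(rbind, peak_rows)
           else data.frame(count = integer(0), norm = numeric(0),
                           row = integer(0), col = integer(0),
                           radius = numeric(0))
  if (nrow(peaks) > 0L) {
    peaks <- peaks[order(-peaks$norm), , drop = FALSE]
    peaks <- utils::head(peaks, num_peaks)
    rownames(peaks) <- NULL
  }
  list(accumulators = accs, peaks = peaks)
}
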