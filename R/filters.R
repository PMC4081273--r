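# ---- low-level helpers -------------------------------------------------

pad_reflect <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmax(1L, pmin(nr, reflect_seq(nr, h)))
  ci <- pmax(1L, pmin(nc, reflect_seq(nc, h)))
  m[ri, ci, drop = FALSE]
}

# symmetric boundary index sequence: ... 2 1 | 1 2 ... n | n n-1 ...
reflect_seq <- function(n, h) {
  i <- seq(1L - h, n + h)
  # fold into [1, n] by repeated reflection about the half-sample edges
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j)
}

gaussian_kernel1d <- function(sigma, truncate = 4) {
  h <- as.integer(truncate * sigma + 0.5)
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution of a plain matrix with a symmetric 1-D kernel,
# symmetric (reflect) boundary
conv_sep <- function(m, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pm <- m[reflect_seq(nr, h), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kernel))
    out <- out + kernel[k] * pm[seq_len(nr) + (k - 1L), , drop = FALSE]
  pm <- out[, reflect_seq(nc, h), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kernel))
    out <- out + kernel[k] * pm[, seq_len(nc) + (k - 1L), drop = FALSE]
  out
}

gaussian_blur_matrix <- function(m, sigma, truncate = 4) {
  if (sigma == 0) return(m)
  conv_sep(m, gaussian_kernel1d(sigma, truncate))
}

# neighbor fetch with 1-px edge-replication (equals symmetric reflect at
# distance 1), used by the 3x3 stencils
shift1 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
    pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
}

sobel_pair <- function(m) {
  gx <- (shift1(m, -1L, 1L) + 2 * shift1(m, 0L, 1L) + shift1(m, 1L, 1L) -
         shift1(m, -1L, -1L) - 2 * shift1(m, 0L, -1L) - shift1(m, 1L, -1L))
  gy <- (shift1(m, 1L, -1L) + 2 * shift1(m, 1L, 0L) + shift1(m, 1L, 1L) -
         shift1(m, -1L, -1L) - 2 * shift1(m, -1L, 0L) - shift1(m, -1L, 1L))
  list(gx = gx, gy = gy)
}

as_gray_float <- function(image) {
  image <- as_image(image, pixel_kind(image))
  if (n_channels(image) != 1L)
    stop("expected a single-channel image", call. = FALSE)
  v <- img_data(to_float(image))
  if (length(dim(v)) == 3L) dim(v) <- dim(v)[1:2]
  v
}

# ---- public filters ----------------------------------------------------

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with the kernel truncated at 4 sigma
#' and symmetric (reflect) boundary handling, which conserves the image
#' mean.  `sigma = 0` returns the input unchanged (as float).
#'
#' @param image a single-channel image.
#' @param sigma smoothing scale in px (>= 0).
#' @return A float image.
#' @export
gaussian_filter <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  v <- as_gray_float(image)
  as_image(pmin(pmax(gaussian_blur_matrix(v, sigma), 0), 1), "float")
}

#' Sobel gradient magnitude
#'
#' `sqrt(gx^2 + gy^2)` from the 3x3 Sobel pair with each kernel scaled
#' by 1/4, so a unit step yields a response of 1 on the two columns
#' astride the step.  Symmetric boundary.
#'
#' @param image a single-channel image.
#' @return A plain numeric matrix of gradient magnitudes (they can
#'   exceed 1, so no range contract applies).
#' @export
sobel <- function(image) {
  v <- as_gray_float(image)
  g <- sobel_pair(v)
  sqrt((g$gx / 4)^2 + (g$gy / 4)^2)
}

#' Band-pass filtering as a difference of Gaussians
#'
#' `gaussian(image, low_sigma) - gaussian(image, high_sigma)`; the DC
#' component cancels, so the response to a constant image is zero.
#'
#' @param image a single-channel image.
#' @param low_sigma,high_sigma smoothing scales, `0 < low < high`.
#' @return A plain numeric matrix (signed response).
#' @export
difference_of_gaussians <- function(image, low_sigma, high_sigma) {
  if (!(low_sigma > 0 && low_sigma < high_sigma))
    stop("need 0 < low_sigma < high_sigma", call. = FALSE)
  v <- as_gray_float(image)
  gaussian_blur_matrix(v, low_sigma) - gaussian_blur_matrix(v, high_sigma)
}

#' Median (rank) filter for u8 images
#'
#' Each output pixel is the exact median of its neighborhood under
#' symmetric boundary handling.  The footprint is the digital disk of
#' the given radius (all offsets with Euclidean norm at most `radius`;
#' radius 1 is the 5-pixel cross), the conventional rank-filter
#' structuring element — a disk median preserves 1-px axis-aligned
#' lines, which a square window cannot.  Restricted to the u8
#' contract; float input is rejected.
#'
#' @param image a single-channel u8 image.
#' @param radius neighborhood radius in px (>= 1).
#' @return A u8 image.
#' @export
median_filter <- function(image, radius) {
  image <- as_image(image, pixel_kind(image))
  if (pixel_kind(image) != "u8")
    stop("median_filter operates on u8 images only", call. = FALSE)
  if (n_channels(image) != 1L)
    stop("expected a single-channel image", call. = FALSE)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  v <- img_data(image)
  if (length(dim(v)) == 3L) dim(v) <- dim(v)[1:2]
  nr <- nrow(v); nc <- ncol(v)
  p <- pad_reflect(v, radius)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  stacked <- matrix(0, nr * nc, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    stacked[, i] <- p[radius + seq_len(nr) + offs$dr[i],
                      radius + seq_len(nc) + offs$dc[i]]
  }
  med <- apply(stacked, 1L, stats::median)
  as_image(matrix(med, nr, nc), "u8")
}

#' Canny edge detection
#'
#' The classic chain: Gaussian smoothing at `sigma`, gradients from the
#' (unnormalized) 3x3 Sobel pair, non-maximum suppression along the
#' gradient direction with linear interpolation of the two flanking
#' magnitudes, then double-threshold hysteresis: pixels at or above
#' `high_threshold` seed edges, pixels at or above `low_threshold`
#' survive only when 8-connected to a seed.  Resulting edges are at
#' most one pixel wide across the gradient.
#'
#' Thresholds are expressed in the float contract's intensity units;
#' parameter sets quoted for 8-bit images divide by 255 (so the classic
#' coin setting 10/80 becomes 10/255, 80/255).
#'
#' @param image a single-channel image.
#' @param sigma smoothing scale (px).
#' @param low_threshold,high_threshold hysteresis thresholds,
#'   `0 < low <= high`.
#' @return A logical matrix marking edge pixels.
#' @export
canny <- function(image, sigma = 1, low_threshold = 0.1,
                  high_threshold = 0.2) {
  if (!(low_threshold > 0 && low_threshold <= high_threshold))
    stop("need 0 < low_threshold <= high_threshold", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  v <- as_gray_float(image)
  sm <- gaussian_blur_matrix(v, sigma)
  g <- sobel_pair(sm)
  gx <- g$gx; gy <- g$gy
  mag <- sqrt(gx^2 + gy^2)
  nr <- nrow(mag); nc <- ncol(mag)

  ax <- abs(gx); ay <- abs(gy)
  s <- sign(gx * gy)          # +1: gradient in the (+row,+col)/( -,-) diagonal
  horiz <- ax >= ay           # gradient closer to the column axis
  w <- matrix(0, nr, nc)
  w[horiz] <- (ay / pmax(ax, .Machine$double.eps))[horiz]
  w[!horiz] <- (ax / pmax(ay, .Machine$double.eps))[!horiz]

  # build the two interpolated neighbor magnitudes case by case
  m_plus <- matrix(0, nr, nc)
  m_minus <- matrix(0, nr, nc)
  for (dcase in c(-1, 1)) {     # sign of gx*gy selects the diagonal
    sel <- horiz & (s == dcase | (dcase == 1 & s == 0))
    if (any(sel)) {
      p0 <- shift1(mag, 0L, 1L); p1 <- shift1(mag, dcase, 1L)
      q0 <- shift1(mag, 0L, -1L); q1 <- shift1(mag, -dcase, -1L)
      m_plus[sel] <- ((1 - w) * p0 + w * p1)[sel]
      m_minus[sel] <- ((1 - w) * q0 + w * q1)[sel]
    }
    sel <- (!horiz) & (s == dcase | (dcase == 1 & s == 0))
    if (any(sel)) {
      p0 <- shift1(mag, 1L, 0L); p1 <- shift1(mag, 1L, dcase)
      q0 <- shift1(mag, -1L, 0L); q1 <- shift1(mag, -1L, -dcase)
      m_plus[sel] <- ((1 - w) * p0 + w * p1)[sel]
      m_minus[sel] <- ((1 - w) * q0 + w * q1)[sel]
    }
  }
  keep <- (mag >= m_plus) & (mag > m_minus) & mag > 0
  keep[c(1L, nr), ] <- FALSE
  keep[, c(1L, nc)] <- FALSE

  weak <- keep & mag >= low_threshold
  strong <- keep & mag >= high_threshold
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- label(weak, connectivity = 2L)
  good <- sort(unique(lab$labels[strong]))
  good <- good[good > 0L]
  matrix(lab$labels %in% good, nr, nc)
}

#' Adaptive (local Gaussian-mean) thresholding
#'
#' The threshold at each pixel is the Gaussian-weighted mean of its
#' `block_size` x `block_size` neighborhood (sigma fixed at
#' `(block_size - 1)/6`) minus `offset`; the output is
#' `image > threshold`.  A negative offset therefore makes the
#' segmentation stricter.  Intensities and `offset` share the input
#' image's native units.
#'
#' @param image a single-channel image.
#' @param block_size odd window width in px (>= 3).
#' @param offset intensity subtracted from the local mean.
#' @return A logical matrix.
#' @export
threshold_adaptive <- function(image, block_size, offset = 0) {
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("block_size must be odd and >= 3", call. = FALSE)
  image <- as_image(image, pixel_kind(image))
  if (n_channels(image) != 1L)
    stop("expected a single-channel image", call. = FALSE)
  v <- img_data(image)
  if (length(dim(v)) == 3L) dim(v) <- dim(v)[1:2]
  sigma <- (block_size - 1) / 6
  h <- (block_size - 1L) %/% 2L
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  t_img <- conv_sep(v, k)
  v > (t_img - offset)
}
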