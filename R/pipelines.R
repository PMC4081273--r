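#' Coin-style particle measurement pipeline
#'
#' The classic demonstration chain on a grayscale image of bright
#' particles: intensity histogram (255 unit bins over the u8 levels),
#' adaptive local thresholding, local-maximum detection, Canny edge
#' detection, connected-component labeling of the edge map, and region
#' properties, reported as bounding boxes.  Defaults are the printed
#' classic parameters (95-px block, offset -15, min_distance 20, sigma
#' 3, thresholds 10/80), rescaled to the float contract when the input
#' is float.
#'
#' @param image a single-channel image.
#' @param block_size,offset adaptive-threshold parameters (u8 units;
#'   `offset` is divided by 255 for float input).
#' @param min_distance peak suppression radius.
#' @param sigma Canny smoothing scale.
#' @param low_threshold,high_threshold Canny thresholds in u8 units
#'   (divided by 255 internally).
#' @return A `coin_report`: list with `n_regions`, `bboxes` (half-open,
#'   one row per region), `peak_coords`, `histogram` (255 counts),
#'   `regions` (full [regionprops()] table) and `edges`.
#' @export
coins_pipeline <- function(image, block_size = 95L, offset = -15,
                           min_distance = 20L, sigma = 3,
                           low_threshold = 10, high_threshold = 80) {
  image <- as_image(image, pixel_kind(image))
  if (n_channels(image) != 1L)
    stop("coins_pipeline expects a single-channel image", call. = FALSE)
  u8 <- to_ubyte(image)
  fl <- to_float(image)
  # histogram over unit-width bins [0,1), ..., [254,255]
  v <- img_data(u8)
  hist_counts <- tabulate(pmin(as.integer(v), 254L) + 1L, nbins = 255L)
  bw <- threshold_adaptive(fl, block_size, offset / 255)
  peaks <- peak_local_max(fl, min_distance)
  edges <- canny(fl, sigma = sigma, low_threshold = low_threshold / 255,
                 high_threshold = high_threshold / 255)
  lab <- label(edges, connectivity = 2L)
  regions <- regionprops(lab)
  structure(list(
    n_regions = lab$n_labels,
    bboxes = regions[, c("min_row", "min_col", "max_row", "max_col")],
    peak_coords = cbind(row = peaks$rows, col = peaks$cols),
    histogram = hist_counts,
    threshold_mask = bw,
    regions = regions,
    edges = edges), class = "coin_report")
}

#' @export
print.coin_report <- function(x, ...) {
  cat(sprintf("<coin_report> %d region(s), %d peak(s)\n",
              x$n_regions, nrow(x$peak_coords)))
  invisible(x)
}

#' Feature-based panorama registration and mosaicking
#'
#' Registers two overlapping grayscale views with ORB features matched
#' by Hamming distance (cross-checked), estimates a projective
#' transform with RANSAC, computes the mosaic extent from both images'
#' warped corners, warps both views with a -1 background sentinel, and
#' alpha-averages them.  Feature detection runs at `scale` (default
#' 0.25, the classic downscaled setting); the returned model maps
#' image-2 (x, y) onto image-1 (x, y) at full resolution.
#'
#' @param image0,image1 single-channel images (the reference view and
#'   the view to be registered); RGB input is collapsed with
#'   [rgb2gray()].
#' @param scale working-resolution factor for feature detection.
#' @param n_keypoints,fast_threshold ORB parameters.
#' @param min_samples,residual_threshold,max_trials,seed RANSAC
#'   parameters (residuals in working-resolution px).
#' @return A `panorama_result`: list with `model` (full-resolution
#'   [geom_transform]), `inlier_count`, `match_count`, `mosaic`,
#'   `offset` (the mosaic shift), and `output_shape`.
#' @export
stitch_pair <- function(image0, image1, scale = 0.25,
                        n_keypoints = 1000L, fast_threshold = 0.05,
                        min_samples = 4L, residual_threshold = 2,
                        max_trials = 1000L, seed = 1L) {
  g0 <- if (n_channels(image0) == 3L) rgb2gray(image0) else image0
  g1 <- if (n_channels(image1) == 3L) rgb2gray(image1) else image1
  s0 <- rescale(g0, scale)
  s1 <- rescale(g1, scale)
  f0 <- orb_detect_and_extract(s0, n_keypoints, fast_threshold)
  f1 <- orb_detect_and_extract(s1, n_keypoints, fast_threshold)
  if (nrow(f0$keypoints) < min_samples || nrow(f1$keypoints) < min_samples)
    stop("registration failed: too few keypoints detected", call. = FALSE)
  matches <- match_descriptors(f0$descriptors, f1$descriptors,
                               cross_check = TRUE)
  if (nrow(matches) < min_samples)
    stop("registration failed: too few descriptor matches", call. = FALSE)
  # (row, col) keypoints -> (x, y) points; src = view 2, dst = view 1
  src <- cbind(f1$keypoints$col[matches$idx2] - 1,
               f1$keypoints$row[matches$idx2] - 1)
  dst <- cbind(f0$keypoints$col[matches$idx1] - 1,
               f0$keypoints$row[matches$idx1] - 1)
  fit <- tryCatch(
    ransac(src, dst, "projective", min_samples, residual_threshold,
           max_trials, seed),
    error = function(e)
      stop("registration failed at RANSAC: ", conditionMessage(e),
           call. = FALSE))
  if (sum(fit$inlier_mask) < max(3L * min_samples, 10L))
    stop(sprintf(
      "registration failed: RANSAC consensus of %d matches is too small",
      sum(fit$inlier_mask)), call. = FALSE)
  # guided refinement: refit on progressively tighter inlier sets, which
  # sharpens the consensus model once gross outliers are gone
  wmodel <- fit$model
  for (thr in residual_threshold / c(2, 4, 6)) {
    resid <- sqrt(rowSums((transform_apply(wmodel, src) - dst)^2))
    keep <- resid <= thr
    if (sum(keep) < max(8L, 4L * min_samples)) break
    wmodel <- estimate_transform("projective", src[keep, , drop = FALSE],
                                 dst[keep, , drop = FALSE])
  }
  fit$model <- wmodel
  # lift the working-resolution model to full resolution
  S <- transform_similarity(scale = scale)
  model <- transform_compose(transform_compose(S, fit$model),
                             transform_inverse(S))
  d0 <- dim(g0)[1:2]; d1 <- dim(g1)[1:2]
  corners0 <- cbind(c(0, d0[2L] - 1, 0, d0[2L] - 1),
                    c(0, 0, d0[1L] - 1, d0[1L] - 1))
  corners1 <- transform_apply(model,
                              cbind(c(0, d1[2L] - 1, 0, d1[2L] - 1),
                                    c(0, 0, d1[1L] - 1, d1[1L] - 1)))
  all_corners <- rbind(corners0, corners1)
  corner_min <- apply(all_corners, 2L, min)
  corner_max <- apply(all_corners, 2L, max)
  output_shape <- ceiling(rev(corner_max - corner_min)) + 1
  offset <- transform_similarity(translation = -corner_min)
  warped0 <- warp(g0, transform_inverse(offset),
                  output_shape = output_shape, cval = -1)
  warped1 <- warp(g1, transform_inverse(transform_compose(model, offset)),
                  output_shape = output_shape, cval = -1)
  a0 <- add_alpha(warped0); a1 <- add_alpha(warped1)
  alpha <- a0[, , 4L] + a1[, , 4L]
  mosaic <- (a0[, , 1L] * a0[, , 4L] + a1[, , 1L] * a1[, , 4L]) /
    pmax(alpha, 1)
  structure(list(model = model, inlier_count = sum(fit$inlier_mask),
                 match_count = nrow(matches),
                 mosaic = as_image(pmin(pmax(mosaic, 0), 1), "float"),
                 alpha = alpha, offset = offset,
                 output_shape = output_shape), class = "panorama_result")
}

#' @export
print.panorama_result <- function(x, ...) {
  cat(sprintf("<panorama_result> %d/%d inlier matches, mosaic %d x %d\n",
              x$inlier_count, x$match_count, x$output_shape[1L],
              x$output_shape[2L]))
  invisible(x)
}

#' Crack-front space-time diagram from a drying-drop image stack
#'
#' Detects the drop contact line on the first frame with a circular
#' Hough transform of its Canny edge map, draws a smaller concentric
#' sampling circle at `annulus_fraction` of the drop radius, and
#' collects the intensities on that circle (ordered by angle) from
#' every frame.  The stack is thereby reduced to a single
#' frames x angle image in which radial cracks appear as dark traces.
#'
#' @param stack an [image_collection] or list of same-shaped images.
#' @param annulus_fraction sampling radius as a fraction of the drop
#'   radius (default 0.75).
#' @param radii_range candidate drop radii for the Hough search.
#' @param canny_sigma,canny_low,canny_high edge-map parameters (float
#'   units).
#' @return A `spacetime_diagram`: list with `matrix` (frames x
#'   samples), `angles` (radians per column, increasing), and `drop`
#'   (row, col, radius of the detected contact line, 1-based).
#' @export
crack_spacetime <- function(stack, annulus_fraction = 0.75,
                            radii_range = NULL, canny_sigma = 1,
                            canny_low = 0.1, canny_high = 0.3) {
  n <- length(stack)
  if (n < 1L) stop("empty stack", call. = FALSE)
  get_frame <- function(i) if (inherits(stack, "image_collection"))
    stack[[i]] else stack[[i]]
  first <- get_frame(1L)
  d <- dim(first)[1:2]
  if (is.null(radii_range))
    radii_range <- seq(round(min(d) / 6), round(min(d) / 2 - 2))
  edges <- canny(first, sigma = canny_sigma, low_threshold = canny_low,
                 high_threshold = canny_high)
  hc <- hough_circle(edges, radii_range, num_peaks = 1L)
  if (nrow(hc$peaks) == 0L)
    stop("no circle detected in the first frame", call. = FALSE)
  drop <- c(row = hc$peaks$row[1L], col = hc$peaks$col[1L],
            radius = hc$peaks$radius[1L])
  ring <- draw_circle_perimeter(drop[1L], drop[2L],
                                max(1L, round(annulus_fraction * drop[3L])))
  ang <- atan2(ring$rows - drop[1L], ring$cols - drop[2L])
  ord <- order(ang)
  ring <- list(rows = ring$rows[ord], cols = ring$cols[ord])
  ang <- ang[ord]
  mat <- matrix(0, n, length(ang))
  for (f in seq_len(n)) {
    fr <- get_frame(f)
    if (!all(dim(fr)[1:2] == d))
      stop("stack frames differ in shape", call. = FALSE)
    v <- as_gray_float(fr)
    mat[f, ] <- v[cbind(ring$rows, ring$cols)]
  }
  structure(list(matrix = mat, angles = ang, drop = drop),
            class = "spacetime_diagram")
}

#' @export
print.spacetime_diagram <- function(x, ...) {
  cat(sprintf(
    "<spacetime_diagram> %d frame(s) x %d samples, drop (%d, %d) r=%d\n",
    nrow(x$matrix), ncol(x$matrix), x$drop[1L], x$drop[2L], x$drop[3L]))
  invisible(x)
}
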