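#' Synthetic coin scene with ground truth
#'
#' Emulates a gray photograph of non-overlapping bright coins on a dark
#' background: base intensity 0.2, disks peaking at 0.8 with a smooth
#' radial shading that leaves the rim near 0.6, plus additive Gaussian
#' noise clipped to \[0, 1\].  The 0.6-versus-0.2 rim contrast is chosen
#' so that the classic coin-measurement parameter set (95-px adaptive
#' block, Canny at sigma 3 with 10/255 and 80/255 thresholds) operates
#' in its intended regime.
#'
#' @param n_disks number of coins to place (0 allowed).
#' @param shape image rows, cols (default 256 x 256).
#' @param noise_sigma additive Gaussian noise sd (default 0.02; the
#'   printed-parameter regime assumes at most 0.05).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param radius_range min/max coin radius in px.
#' @return list with `image` (float [as_image()]) and `truth`: a list
#'   with `centers` (n x 2 matrix of 1-based row, col) and `radii`.
#' @export
make_coins_scene <- function(n_disks, shape = c(256L, 256L),
                             noise_sigma = 0.02, seed = 1L,
                             radius_range = c(14L, 20L)) {
  stopifnot(n_disks >= 0, noise_sigma >= 0)
  with_seed(seed, {
    nr <- shape[1L]; nc <- shape[2L]
    centers <- matrix(0, 0L, 2L); radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n_disks) {
      if ((tries <- tries + 1L) > 200L * max(n_disks, 1L))
        stop("could not place disks without overlap: reduce n_disks or radii",
             call. = FALSE)
      rad <- sample(seq(radius_range[1L], radius_range[2L]), 1L)
      margin <- rad + 6
      if (2 * margin >= min(nr, nc)) next
      r <- runif(1, margin, nr - margin)
      c <- runif(1, margin, nc - margin)
      if (nrow(centers) > 0L) {
        d <- sqrt((centers[, 1L] - r)^2 + (centers[, 2L] - c)^2)
        if (any(d < radii + rad + 8)) next
      }
      centers <- rbind(centers, c(r, c)); radii <- c(radii, rad)
    }
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    img <- matrix(0.2, nr, nc)
    for (k in seq_len(nrow(centers))) {
      d2 <- (rr - centers[k, 1L])^2 + (cc - centers[k, 2L])^2
      inside <- d2 <= radii[k]^2
      img[inside] <- 0.8 * (1 - 0.25 * d2[inside] / radii[k]^2)
    }
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    img <- pmin(pmax(img, 0), 1)
    list(image = as_image(img, "float"),
         truth = list(centers = centers, radii = radii))
  })
}

#' Textured image pair under a known planar transform
#'
#' Renders one smoothed random texture twice: once as-is (`image1`) and
#' once through a known [geometric transform][geom_transform] that maps
#' view-2 coordinates onto view-1 coordinates (`image2`).  The texture
#' canvas extends beyond the first view as far as the transform needs,
#' so the second view never samples undefined scene content.  The truth
#' transform is returned for registration benchmarks.
#'
#' @param shape rows, cols of both views.
#' @param transform a [geom_transform] mapping image-2 (x, y) to
#'   image-1 (x, y), 0-based; default identity.
#' @param overlap_fraction minimum fraction of view-2 pixels that must
#'   land inside view 1 (error otherwise).
#' @param seed integer seed.
#' @param texture_sigma Gaussian smoothing scale of the texture (px).
#' @return list with `image1`, `image2` (float images) and `truth`
#'   (list with `transform`).
#' @export
make_textured_pair <- function(shape = c(200L, 200L),
                               transform = transform_identity(),
                               overlap_fraction = 0.5, seed = 1L,
                               texture_sigma = 3) {
  nr <- shape[1L]; nc <- shape[2L]
  if (abs(det(transform$matrix)) < 1e-12)
    stop("degenerate transform", call. = FALSE)
  # extent of view-2 pixel grid in view-1 coordinates (0-based corners)
  corners <- cbind(x = c(0, nc - 1, 0, nc - 1), y = c(0, 0, nr - 1, nr - 1))
  mapped <- transform_apply(transform, corners)
  pad_left <- max(0, ceiling(-min(mapped[, 1L])) + 2L)
  pad_right <- max(0, ceiling(max(mapped[, 1L]) - (nc - 1)) + 2L)
  pad_top <- max(0, ceiling(-min(mapped[, 2L])) + 2L)
  pad_bottom <- max(0, ceiling(max(mapped[, 2L]) - (nr - 1)) + 2L)
  # overlap guarantee, checked on the full view-2 grid
  gx <- rep(seq(0, nc - 1, by = 4), each = length(seq(0, nr - 1, by = 4)))
  gy <- rep(seq(0, nr - 1, by = 4), times = length(seq(0, nc - 1, by = 4)))
  m <- transform_apply(transform, cbind(gx, gy))
  frac <- mean(m[, 1L] >= 0 & m[, 1L] <= nc - 1 & m[, 2L] >= 0 & m[, 2L] <= nr - 1)
  if (frac < overlap_fraction)
    stop(sprintf("transform leaves only %.0f%% overlap (need %.0f%%)",
                 100 * frac, 100 * overlap_fraction), call. = FALSE)
  with_seed(seed, {
    cr <- nr + pad_top + pad_bottom
    ccn <- nc + pad_left + pad_right
    canvas <- matrix(stats::runif(cr * ccn), cr, ccn)
    canvas <- gaussian_blur_matrix(canvas, texture_sigma)
    canvas <- (canvas - min(canvas)) / (max(canvas) - min(canvas)) * 0.9 + 0.05
    image1 <- canvas[pad_top + seq_len(nr), pad_left + seq_len(nc)]
    shift <- transform_similarity(translation = c(pad_left, pad_top))
    image2 <- warp(as_image(canvas, "float"),
                   inverse_map = transform_compose(transform, shift),
                   output_shape = c(nr, nc), cval = 0)
    list(image1 = as_image(image1, "float"),
         image2 = as_image(pmin(pmax(img_data(image2), 0), 1), "float"),
         truth = list(transform = transform))
  })
}

# 4-connected digital line: Bresenham plus an intermediate pixel at
# every diagonal step.  A 4-connected path cannot cross an 8-connected
# closed curve without sharing a pixel, so cracks drawn this way are
# guaranteed to intersect any sampling circle they traverse.
line4 <- function(r0, c0, r1, c1) {
  l <- draw_line(r0, c0, r1, c1)
  rr <- l$rows[1L]; cc <- l$cols[1L]
  for (i in seq_along(l$rows)[-1L]) {
    dr <- l$rows[i] - l$rows[i - 1L]
    dc <- l$cols[i] - l$cols[i - 1L]
    if (dr != 0L && dc != 0L) {
      rr <- c(rr, l$rows[i - 1L] + dr); cc <- c(cc, l$cols[i - 1L])
    }
    rr <- c(rr, l$rows[i]); cc <- c(cc, l$cols[i])
  }
  list(rows = rr, cols = cc)
}

#' Synthetic drying-drop crack image stack
#'
#' Emulates a time series of a drying colloidal drop: a bright circular
#' drop (intensity 0.9, sharp rim) on a dark background (0.1), with
#' dark 1-px-wide radial cracks that appear at fixed angular positions
#' and grow from the rim toward the center over the frames.  Frame 1
#' has no cracks; every crack reaches the center in the final frame.
#'
#' @param n_frames number of frames (>= 2).
#' @param drop_center 1-based (row, col) of the drop center.
#' @param drop_radius drop radius in px.
#' @param n_cracks number of cracks (>= 1).
#' @param seed integer seed.
#' @param shape image rows, cols.
#' @return list with `frames` (list of float images) and `truth`: a
#'   list with `center`, `radius`, `angles` (radians, in \[-pi, pi\),
#'   measured as atan2(row offset, col offset)) and `appear_frames`
#'   (first frame index in which each crack is visible).
#' @export
make_crack_stack <- function(n_frames = 10L, drop_center = c(64L, 64L),
                             drop_radius = 40L, n_cracks = 6L, seed = 1L,
                             shape = c(128L, 128L)) {
  stopifnot(n_frames >= 2L, n_cracks >= 1L, drop_radius >= 8L)
  with_seed(seed, {
    nr <- shape[1L]; nc <- shape[2L]
    # crack angles with enough separation that 1-px cracks stay distinct
    min_sep <- max(0.25, 8 / drop_radius)
    repeat {
      ang <- sort(stats::runif(n_cracks, -pi, pi))
      gaps <- diff(c(ang, ang[1L] + 2 * pi))
      if (all(gaps > min_sep)) break
    }
    appear <- sample(2:max(2L, ceiling(n_frames / 2)), n_cracks,
                     replace = TRUE)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2 <- (rr - drop_center[1L])^2 + (cc - drop_center[2L])^2
    base <- matrix(0.1, nr, nc)
    base[d2 <= drop_radius^2] <- 0.9
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      img <- base
      for (k in seq_len(n_cracks)) {
        if (f < appear[k]) next
        frac <- (f - appear[k] + 1) / (n_frames - appear[k] + 1)
        tip <- 1 - min(frac, 1)
        rim_r <- drop_center[1L] + round(drop_radius * sin(ang[k]))
        rim_c <- drop_center[2L] + round(drop_radius * cos(ang[k]))
        tip_r <- drop_center[1L] + round(tip * drop_radius * sin(ang[k]))
        tip_c <- drop_center[2L] + round(tip * drop_radius * cos(ang[k]))
        img <- paint(img, line4(rim_r, rim_c, tip_r, tip_c), 0.05)
      }
      frames[[f]] <- as_image(img, "float")
    }
    list(frames = frames,
         truth = list(center = drop_center, radius = drop_radius,
                      angles = ang, appear_frames = appear))
  })
}
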