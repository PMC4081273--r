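#' Local intensity maxima with minimum-distance suppression
#'
#' Candidates are strict maxima of their `(2*min_distance+1)^2`
#' neighborhood.  They are then visited in order of decreasing
#' intensity (ties by row, then column) and any candidate within
#' Euclidean `min_distance` of an already accepted peak is suppressed.
#'
#' @param image a single-channel image.
#' @param min_distance suppression radius in px (>= 1).
#' @return list with integer vectors `rows` and `cols` (1-based).
#' @export
peak_local_max <- function(image, min_distance = 1L) {
  min_distance <- as.integer(min_distance)
  if (min_distance < 1L) stop("min_distance must be >= 1", call. = FALSE)
  v <- as_gray_float(image)
  nr <- nrow(v); nc <- ncol(v)
  mx <- window_max(v, min_distance)
  cand <- which(v >= mx)
  # strictness: the window maximum must be attained exactly once
  strict <- vapply(cand, function(i) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    win <- v[max(1L, r - min_distance):min(nr, r + min_distance),
             max(1L, c - min_distance):min(nc, c + min_distance)]
    sum(win == v[i]) == 1L
  }, logical(1))
  cand <- cand[strict]
  if (length(cand) == 0L) return(list(rows = integer(0), cols = integer(0)))
  r <- (cand - 1L) %% nr + 1L
  c <- (cand - 1L) %/% nr + 1L
  ord <- order(-v[cand], r, c)
  r <- r[ord]; c <- c[ord]
  acc_r <- integer(0); acc_c <- integer(0)
  for (i in seq_along(r)) {
    if (length(acc_r) == 0L ||
        all((acc_r - r[i])^2 + (acc_c - c[i])^2 > min_distance^2)) {
      acc_r <- c(acc_r, r[i]); acc_c <- c(acc_c, c[i])
    }
  }
  list(rows = acc_r, cols = acc_c)
}

# separable sliding window maximum (window = 2h+1, edge-truncated)
window_max <- function(v, h) {
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  for (d in seq_len(h)) {
    out <- pmax(out,
                rbind(v[-seq_len(d), , drop = FALSE],
                      matrix(-Inf, d, nc)),
                rbind(matrix(-Inf, d, nc),
                      v[seq_len(nr - d), , drop = FALSE]))
  }
  tmp <- out
  for (d in seq_len(h)) {
    out <- pmax(out,
                cbind(tmp[, -seq_len(d), drop = FALSE],
                      matrix(-Inf, nr, d)),
                cbind(matrix(-Inf, nr, d),
                      tmp[, seq_len(nc - d), drop = FALSE]))
  }
  out
}

# 16 offsets of the radius-3 Bresenham circle, clockwise from 12 o'clock
fast_circle_offsets <- function() {
  cbind(r = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L),
        c = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L))
}

#' FAST-9 corner detection
#'
#' A pixel is a corner when at least 9 contiguous pixels on its
#' 16-pixel Bresenham circle of radius 3 are all brighter than the
#' center plus `threshold`, or all darker than the center minus
#' `threshold`.  Corners are scored with the Harris response (k = 0.04,
#' computed on the sigma = 1 smoothed image) for ranking.  A border of
#' `border` px is excluded.
#'
#' @param image a single-channel float image.
#' @param threshold contrast threshold in float intensity units.
#' @param border excluded margin (>= 3; ORB uses the descriptor patch
#'   margin).
#' @return list with `rows`, `cols` (1-based) and `scores`.
#' @export
detect_fast <- function(image, threshold = 0.05, border = 3L) {
  v <- as_gray_float(image)
  nr <- nrow(v); nc <- ncol(v)
  border <- max(3L, as.integer(border))
  if (nr <= 2L * border || nc <= 2L * border)
    return(list(rows = integer(0), cols = integer(0), scores = numeric(0)))
  off <- fast_circle_offsets()
  core_r <- (border + 1L):(nr - border)
  core_c <- (border + 1L):(nc - border)
  ctr <- v[core_r, core_c]
  brighter <- array(FALSE, c(length(core_r), length(core_c), 16L))
  darker <- brighter
  for (k in 1:16) {
    nbv <- v[core_r + off[k, 1L], core_c + off[k, 2L]]
    brighter[, , k] <- nbv > ctr + threshold
    darker[, , k] <- nbv < ctr - threshold
  }
  is_corner <- segment_test(brighter) | segment_test(darker)
  hits <- which(is_corner, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(list(rows = integer(0), cols = integer(0), scores = numeric(0),
                rows_sub = numeric(0), cols_sub = numeric(0)))
  rows <- core_r[hits[, 1L]]
  cols <- core_c[hits[, 2L]]
  H <- harris_response(v)
  sub <- refine_subpixel(H, rows, cols)
  list(rows = rows, cols = cols, scores = H[cbind(rows, cols)],
       rows_sub = sub$rows, cols_sub = sub$cols)
}

# sub-pixel corner localization: quadratic fit of the Harris response in
# the 3x3 neighborhood; offsets are clipped to half a pixel and dropped
# when the local Hessian is not a proper peak
refine_subpixel <- function(H, rows, cols) {
  i <- cbind(rows, cols)
  gx <- (H[i + rep(c(0L, 1L), each = nrow(i))] -
         H[i + rep(c(0L, -1L), each = nrow(i))]) / 2
  gy <- (H[i + rep(c(1L, 0L), each = nrow(i))] -
         H[i + rep(c(-1L, 0L), each = nrow(i))]) / 2
  hxx <- H[i + rep(c(0L, 1L), each = nrow(i))] +
         H[i + rep(c(0L, -1L), each = nrow(i))] - 2 * H[i]
  hyy <- H[i + rep(c(1L, 0L), each = nrow(i))] +
         H[i + rep(c(-1L, 0L), each = nrow(i))] - 2 * H[i]
  hxy <- (H[i + rep(c(1L, 1L), each = nrow(i))] -
          H[i + rep(c(1L, -1L), each = nrow(i))] -
          H[i + rep(c(-1L, 1L), each = nrow(i))] +
          H[i + rep(c(-1L, -1L), each = nrow(i))]) / 4
  det <- hxx * hyy - hxy^2
  ok <- det > .Machine$double.eps & hxx < 0 & hyy < 0
  dx <- ifelse(ok, -(hyy * gx - hxy * gy) / det, 0)
  dy <- ifelse(ok, -(hxx * gy - hxy * gx) / det, 0)
  dx <- pmin(pmax(dx, -0.5), 0.5)
  dy <- pmin(pmax(dy, -0.5), 0.5)
  list(rows = rows + dy, cols = cols + dx)
}

# >= 9 contiguous TRUE on the wrapped 16-ring
segment_test <- function(ring) {
  d <- dim(ring)
  run <- array(0L, d[1:2])
  best <- array(0L, d[1:2])
  # unroll the ring twice to handle wrap-around, capping runs at 16
  for (k in c(1:16, 1:16)) {
    run <- ifelse(ring[, , k], run + 1L, 0L)
    best <- pmax(best, pmin(run, 16L))
  }
  best >= 9L
}

# Harris corner response, k = 0.04, structure tensor smoothed at sigma 1
harris_response <- function(v, k = 0.04, sigma = 1) {
  sm <- gaussian_blur_matrix(v, sigma)
  g <- sobel_pair(sm)
  gx <- g$gx / 4; gy <- g$gy / 4
  Axx <- gaussian_blur_matrix(gx * gx, sigma)
  Ayy <- gaussian_blur_matrix(gy * gy, sigma)
  Axy <- gaussian_blur_matrix(gx * gy, sigma)
  (Axx * Ayy - Axy^2) - k * (Axx + Ayy)^2
}

# fixed rBRIEF-style sampling pattern: 256 point pairs from an isotropic
# Gaussian (sd = patch/5), redrawn into the radius-13 disk, frozen by a
# dedicated seed so every build ships the same table
brief_pattern <- local({
  pat <- NULL
  function() {
    if (is.null(pat)) {
      pat <<- with_seed(20140619, {
        draw <- function(n) {
          out <- matrix(0, 0L, 2L)
          while (nrow(out) < n) {
            p <- matrix(stats::rnorm(2L * n, 0, 31 / 5), ncol = 2L)
            p <- p[rowSums(p^2) <= 13^2, , drop = FALSE]
            out <- rbind(out, p)
          }
          out[seq_len(n), , drop = FALSE]
        }
        list(p1 = draw(256L), p2 = draw(256L))   # (x, y) offsets
      })
    }
    pat
  }
})

#' ORB keypoints and binary descriptors
#'
#' FAST-9 corners are detected on an image pyramid (`n_scales` levels,
#' each downscaled by `downscale`), ranked by Harris score, and the
#' strongest `n_keypoints` kept.  Each keypoint's orientation is the
#' intensity-centroid angle `atan2(m01, m10)` over its circular
#' 31-px patch; the descriptor is 256 pairwise intensity comparisons
#' of a fixed Gaussian-drawn point-pair table, rotated by the
#' orientation discretized to 12-degree bins.  Positions are reported
#' in level-0 (full resolution) coordinates.
#'
#' @param image a single-channel image.
#' @param n_keypoints target number of keypoints.
#' @param fast_threshold FAST contrast threshold (float units).
#' @param n_scales pyramid levels.
#' @param downscale per-level scale factor (> 1).
#' @return list with `keypoints` (data.frame: row, col at full
#'   resolution, score, orientation, scale) and `descriptors` (logical
#'   n x 256 matrix).
#' @export
orb_detect_and_extract <- function(image, n_keypoints = 500L,
                                   fast_threshold = 0.05,
                                   n_scales = 8L, downscale = 1.2) {
  stopifnot(n_keypoints >= 1L, downscale > 1)
  v0 <- as_gray_float(image)
  if (min(dim(v0)) < 32L)
    stop("image too small for the 31-px descriptor patch", call. = FALSE)
  margin <- 16L
  kp <- list()
  for (lev in seq_len(n_scales) - 1L) {
    f <- downscale^(-lev)
    lv <- if (lev == 0L) v0 else img_data(rescale(as_image(v0, "float"), f))
    if (min(dim(lv)) < 2L * margin + 1L) break
    det <- detect_fast(as_image(lv, "float"), fast_threshold,
                       border = margin)
    if (length(det$rows) == 0L) next
    sm <- gaussian_blur_matrix(lv, 1)
    ori <- patch_orientation(sm, det$rows, det$cols)
    kp[[length(kp) + 1L]] <- data.frame(
      row = det$rows, col = det$cols, level = lev,
      row_sub = det$rows_sub, col_sub = det$cols_sub,
      score = det$scores, orientation = ori)
  }
  if (length(kp) == 0L)
    return(list(keypoints = data.frame(row = numeric(0), col = numeric(0),
                                       score = numeric(0),
                                       orientation = numeric(0),
                                       scale = numeric(0)),
                descriptors = matrix(FALSE, 0L, 256L)))
  kp <- do.call(rbind, kp)
  kp <- kp[order(-kp$score), , drop = FALSE]
  kp <- utils::head(kp, n_keypoints)
  # descriptors are extracted at each keypoint's own level
  desc <- matrix(FALSE, nrow(kp), 256L)
  pat <- brief_pattern()
  bins <- round(kp$orientation / (pi / 15)) %% 30   # 12-degree bins
  lv_cache <- list()
  for (i in seq_len(nrow(kp))) {
    lev <- kp$level[i]
    key <- as.character(lev)
    if (is.null(lv_cache[[key]])) {
      f <- downscale^(-lev)
      lv <- if (lev == 0L) v0 else img_data(rescale(as_image(v0, "float"), f))
      lv_cache[[key]] <- gaussian_blur_matrix(lv, 1)
    }
    sm <- lv_cache[[key]]
    a <- bins[i] * (pi / 15)
    Rm <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    q1 <- round(pat$p1 %*% t(Rm))     # rotated (x, y) offsets
    q2 <- round(pat$p2 %*% t(Rm))
    r <- kp$row[i]; c <- kp$col[i]
    i1 <- cbind(r + q1[, 2L], c + q1[, 1L])
    i2 <- cbind(r + q2[, 2L], c + q2[, 1L])
    desc[i, ] <- sm[i1] < sm[i2]
  }
  keypoints <- data.frame(
    row = (kp$row_sub - 1) * downscale^kp$level + 1,
    col = (kp$col_sub - 1) * downscale^kp$level + 1,
    score = kp$score, orientation = kp$orientation,
    scale = downscale^kp$level)
  list(keypoints = keypoints, descriptors = desc)
}

# intensity-centroid orientation over the radius-15 disk
patch_orientation <- function(v, rows, cols, radius = 15L) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  vapply(seq_along(rows), function(i) {
    rr <- rows[i] + offs$dr; cc <- cols[i] + offs$dc
    ok <- rr >= 1L & rr <= nrow(v) & cc >= 1L & cc <= ncol(v)
    w <- v[cbind(rr[ok], cc[ok])]
    atan2(sum(offs$dr[ok] * w), sum(offs$dc[ok] * w))
  }, numeric(1))
}

#' Brute-force binary descriptor matching
#'
#' Nearest neighbors under Hamming distance; ties are broken by the
#' lowest index.  With `cross_check`, a pair (i, j) is kept only when j
#' is i's nearest neighbor in set 2 and i is j's nearest in set 1,
#' which makes the result a partial one-to-one mapping.
#'
#' @param d1,d2 logical descriptor matrices (n x 256), as returned by
#'   [orb_detect_and_extract()].
#' @param cross_check keep mutual nearest neighbors only (default
#'   TRUE).
#' @return data.frame with columns `idx1`, `idx2`, `distance`.
#' @export
match_descriptors <- function(d1, d2, cross_check = TRUE) {
  if (nrow(d1) == 0L || nrow(d2) == 0L)
    return(data.frame(idx1 = integer(0), idx2 = integer(0),
                      distance = integer(0)))
  a <- matrix(as.numeric(d1), nrow(d1))
  b <- matrix(as.numeric(d2), nrow(d2))
  D <- a %*% (1 - t(b)) + (1 - a) %*% t(b)      # Hamming distances
  nn12 <- apply(D, 1L, which.min)               # first min = lowest index
  if (cross_check) {
    nn21 <- apply(D, 2L, which.min)
    keep <- which(nn21[nn12] == seq_len(nrow(d1)))
    data.frame(idx1 = keep, idx2 = nn12[keep],
               distance = D[cbind(keep, nn12[keep])])
  } else {
    data.frame(idx1 = seq_len(nrow(d1)), idx2 = nn12,
               distance = D[cbind(seq_len(nrow(d1)), nn12)])
  }
}
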