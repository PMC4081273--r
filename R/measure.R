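#' Connected-component labeling
#'
#' Two-pass union-find labeling of a binary image.  Components are
#' numbered 1..n in row-major first-encounter order (background is 0),
#' so labels are deterministic.  `connectivity = 1` is the
#' 4-neighborhood, `connectivity = 2` (default) the 8-neighborhood, the
#' right choice for linking diagonal edge chains.
#'
#' @param binary logical (or 0/1) matrix.
#' @param connectivity 1 (4-connected) or 2 (8-connected).
#' @return list with `labels` (integer matrix) and `n_labels`.
#' @export
label <- function(binary, connectivity = 2L) {
  stopifnot(connectivity %in% c(1L, 2L))
  b <- binary != 0
  nr <- nrow(b); nc <- ncol(b)
  idx <- which(b)
  if (length(idx) == 0L)
    return(list(labels = matrix(0L, nr, nc), n_labels = 0L))
  parent <- seq_along(idx)                  # union-find over ON pixels
  pix_id <- integer(nr * nc)                # linear index -> ON ordinal
  pix_id[idx] <- seq_along(idx)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]       # path halving
      i <- parent[i]
    }
    i
  }
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 2L)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  for (off in offsets) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- b[nb]
    a_ids <- pix_id[idx[ok]][hit]
    b_ids <- pix_id[nb][hit]
    for (k in seq_along(a_ids)) {
      ra <- find_root(a_ids[k]); rb <- find_root(b_ids[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(idx), find_root, integer(1))
  # renumber roots by row-major first encounter
  scan_order <- order(r, c)
  first_seen <- roots[scan_order][!duplicated(roots[scan_order])]
  relabel <- integer(length(idx))
  relabel[first_seen] <- seq_along(first_seen)
  labels <- matrix(0L, nr, nc)
  labels[idx] <- relabel[roots]
  list(labels = labels, n_labels = length(first_seen))
}

#' Region properties of labeled components
#'
#' One record per label, in ascending label order: pixel count, the
#' half-open bounding box (max row/col exclusive, so width is
#' `max_col - min_col`), the centroid, raw and central moments to order
#' 3, eccentricity of the second-moment ellipse
#' `sqrt(1 - lambda_min/lambda_max)`, the chain-code perimeter (axial
#' steps weigh 1, diagonal steps sqrt(2)), and, when an intensity image
#' is supplied, the mean intensity.
#'
#' @param labelmap result of [label()] (or an integer label matrix).
#' @param intensity optional image of matching shape.
#' @return A data.frame with one row per region; the `moments` are
#'   returned in list-columns `mu` (raw, indexed `m[p+1, q+1]` for
#'   order p in rows/y and q in cols/x... see Details) and `mu_central`.
#' @details Moments use 0-based (row, col) pixel coordinates:
#'   `m_pq = sum r^p c^q` and the central equivalents; `mu[p+1, q+1]`
#'   stores order p in the row coordinate and q in the column
#'   coordinate, both up to 3.
#' @export
regionprops <- function(labelmap, intensity = NULL) {
  labels <- if (is.list(labelmap)) labelmap$labels else labelmap
  n <- max(labels)
  rows <- vector("list", n)
  for (lb in seq_len(n)) {
    pix <- which(labels == lb, arr.ind = TRUE)
    r <- pix[, 1L] - 1; c <- pix[, 2L] - 1       # 0-based for moments
    area <- nrow(pix)
    mu <- outer(0:3, 0:3, Vectorize(function(p, q) sum(r^p * c^q)))
    cen_r <- mu[2L, 1L] / area; cen_c <- mu[1L, 2L] / area
    rc <- r - cen_r; cc <- c - cen_c
    muc <- outer(0:3, 0:3, Vectorize(function(p, q) sum(rc^p * cc^q)))
    # second-moment (inertia) ellipse
    cov <- rbind(c(muc[3L, 1L], muc[2L, 2L]),
                 c(muc[2L, 2L], muc[1L, 3L])) / area
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    ecc <- if (ev[1L] < 1e-12) 0 else sqrt(max(0, 1 - ev[2L] / ev[1L]))
    rows[[lb]] <- data.frame(
      label = lb, area = area,
      min_row = min(pix[, 1L]), min_col = min(pix[, 2L]),
      max_row = max(pix[, 1L]) + 1L, max_col = max(pix[, 2L]) + 1L,
      centroid_row = cen_r + 1, centroid_col = cen_c + 1,
      eccentricity = ecc,
      perimeter = chain_perimeter(labels == lb),
      mean_intensity = if (is.null(intensity)) NA_real_
                       else mean(img_data(intensity)[pix]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), area = integer(0),
                      min_row = integer(0), min_col = integer(0),
                      max_row = integer(0), max_col = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      eccentricity = numeric(0), perimeter = numeric(0),
                      mean_intensity = numeric(0))
  attr(out, "moments") <- lapply(seq_len(n), function(lb) {
    pix <- which(labels == lb, arr.ind = TRUE)
    r <- pix[, 1L] - 1; c <- pix[, 2L] - 1
    area <- nrow(pix)
    mu <- outer(0:3, 0:3, Vectorize(function(p, q) sum(r^p * c^q)))
    rc <- r - mu[2L, 1L] / area; cc <- c - mu[1L, 2L] / area
    list(raw = mu,
         central = outer(0:3, 0:3,
                         Vectorize(function(p, q) sum(rc^p * cc^q))))
  })
  out
}

# Freeman chain-code perimeter on the 8-connected outer boundary:
# Moore-neighbor tracing, steps weighted 1 (axial) / sqrt(2) (diagonal).
chain_perimeter <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 1L) return(0)
  # start at the row-major-first pixel; trace clockwise
  start <- pix[order(pix[, 1L], pix[, 2L])[1L], ]
  nbr <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  wt <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(p) p[1L] >= 1L && p[1L] <= nr && p[2L] >= 1L &&
                    p[2L] <= nc && mask[p[1L], p[2L]]
  cur <- start
  dir <- 7L                      # came from the upper-left
  per <- 0
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      cand <- cur + nbr[d + 1L, ]
      if (at(cand)) {
        per <- per + wt[d + 1L]
        cur <- cand
        if (is.null(first_move)) first_move <- c(cand, d)
        dir <- (d + 6L) %% 8L    # backtrack, then continue clockwise
        found <- TRUE
        break
      }
    }
    if (!found) return(0)        # isolated pixel
    if (all(cur == start)) {
      # Jacob's criterion: stop when re-entering the start the same way
      nxt <- NULL
      for (k in 0:7) {
        d <- (dir + k) %% 8L
        cand <- cur + nbr[d + 1L, ]
        if (at(cand)) { nxt <- c(cand, d); break }
      }
      if (is.null(nxt) || all(nxt == first_move)) return(per)
    }
    if (per > 8 * (nrow(pix) + 4)) return(per)   # safety bound
  }
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at unit spacing from
#' `src` to `dst`, both endpoints included (a trailing partial step
#' contributes the endpoint itself).  For `linewidth > 1` the profile
#' is averaged over that many parallel lines offset perpendicular to
#' the segment at unit spacing, centered on it.
#'
#' @param image a single-channel image.
#' @param src,dst (row, col) endpoints, 1-based (fractional allowed).
#' @param linewidth odd width (>= 1) of the averaging band.
#' @return Numeric vector of sampled (or band-averaged) intensities.
#' @export
profile_line <- function(image, src, dst, linewidth = 1L) {
  linewidth <- as.integer(linewidth)
  if (linewidth < 1L || linewidth %% 2L == 0L)
    stop("linewidth must be odd and >= 1", call. = FALSE)
  v <- as_gray_float(image)
  d <- c(dst[1L] - src[1L], dst[2L] - src[2L])
  len <- sqrt(sum(d^2))
  if (len == 0)
    return(bilinear_sample(v, src[2L] - 1, src[1L] - 1, cval = 0))
  ts <- seq(0, floor(len))
  if (max(ts) < len) ts <- c(ts, len)
  u <- d / len
  perp <- c(-u[2L], u[1L])
  offs <- seq(-(linewidth - 1L) / 2L, (linewidth - 1L) / 2L)
  acc <- 0
  for (o in offs) {
    rr <- src[1L] + ts * u[1L] + o * perp[1L]
    cc <- src[2L] + ts * u[2L] + o * perp[2L]
    acc <- acc + bilinear_sample(v, cc - 1, rr - 1, cval = 0)
  }
  acc / linewidth
}

#' RANSAC-robust transform estimation
#'
#' Repeats `max_trials` times: draw `min_samples` distinct
#' correspondences, fit with [estimate_transform()], and count inliers
#' whose Euclidean reprojection residual is at most
#' `residual_threshold`.  The trial with the most inliers wins (ties
#' broken by lower total inlier residual), and the returned model is
#' re-estimated on all of that trial's inliers.  Degenerate subsets are
#' redrawn without consuming the trial budget, up to a cap.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points.
#' @param model_kind `"similarity"`, `"affine"` or `"projective"`.
#' @param min_samples minimal subset size (4 for projective).
#' @param residual_threshold inlier residual bound in point units.
#' @param max_trials number of random subsets (fixed, not adaptive).
#' @param seed integer seed for the subset draws.
#' @return list with `model` ([geom_transform]), `inlier_mask` (logical
#'   per correspondence) and `n_trials_run`.
#' @export
ransac <- function(src, dst, model_kind = "projective", min_samples = 4L,
                   residual_threshold = 2, max_trials = 1000L, seed = 1L) {
  src <- rbind(src); dst <- rbind(dst)
  n <- nrow(src)
  if (n < min_samples)
    stop("fewer correspondences than min_samples", call. = FALSE)
  with_seed(seed, {
    best_count <- -1L
    best_resid <- Inf
    best_mask <- NULL
    trials <- 0L
    degenerate <- 0L
    while (trials < max_trials) {
      pick <- sample.int(n, min_samples)
      model <- tryCatch(
        estimate_transform(model_kind, src[pick, , drop = FALSE],
                           dst[pick, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(model)) {
        degenerate <- degenerate + 1L
        if (degenerate > 10L * max_trials)
          stop("no non-degenerate minimal subset found", call. = FALSE)
        next
      }
      trials <- trials + 1L
      proj <- tryCatch(transform_apply(model, src), error = function(e) NULL)
      if (is.null(proj)) next
      resid <- sqrt(rowSums((proj - dst)^2))
      mask <- resid <= residual_threshold
      cnt <- sum(mask)
      tot <- sum(resid[mask])
      if (cnt > best_count || (cnt == best_count && tot < best_resid)) {
        best_count <- cnt; best_resid <- tot; best_mask <- mask
      }
    }
    if (is.null(best_mask) || best_count < min_samples)
      stop("RANSAC failed to find a consensus model", call. = FALSE)
    final <- estimate_transform(model_kind,
                                src[best_mask, , drop = FALSE],
                                dst[best_mask, , drop = FALSE])
    list(model = final, inlier_mask = best_mask, n_trials_run = trials)
  })
}
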