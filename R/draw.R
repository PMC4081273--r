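#' Rasterize a straight line segment (Bresenham)
#'
#' Returns the 8-connected digital line from (r0, c0) to (r1, c1), both
#' endpoints included, as parallel row/column vectors.  The pixel count
#' is always `max(|dr|, |dc|) + 1`.
#'
#' @param r0,c0,r1,c1 integer endpoint coordinates (any sign).
#' @return list with integer vectors `rows` and `cols`.
#' @export
draw_line <- function(r0, c0, r1, c1) {
  r0 <- as.integer(r0); c0 <- as.integer(c0)
  r1 <- as.integer(r1); c1 <- as.integer(c1)
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  if (n == 1L) return(list(rows = r0, cols = c0))
  # classic integer error accumulation along the major axis
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  rows <- integer(n); cols <- integer(n)
  r <- r0; c <- c0
  err <- dc - dr
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 <  dc) { err <- err + dc; r <- r + sr }
  }
  list(rows = rows, cols = cols)
}

#' Rasterize a circle perimeter (midpoint algorithm)
#'
#' Emits the 8 octant reflections of the midpoint-circle recurrence:
#' an 8-connected closed curve whose pixels all lie within half a pixel
#' (plus rounding) of Euclidean distance `radius` from the center.
#' Duplicate pixels at octant seams are removed; ordering is not
#' angular (use [order()] on `atan2` if needed).
#'
#' @param r,c integer center.
#' @param radius integer radius >= 1.
#' @return list with integer vectors `rows` and `cols`.
#' @export
draw_circle_perimeter <- function(r, c, radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  x <- radius; y <- 0L
  d <- 1L - radius
  xs <- integer(0); ys <- integer(0)
  while (y <= x) {
    xs <- c(xs, x); ys <- c(ys, y)
    y <- y + 1L
    if (d < 0L) {
      d <- d + 2L * y + 1L
    } else {
      x <- x - 1L
      d <- d + 2L * (y - x) + 1L
    }
  }
  rr <- c( ys,  xs,  xs,  ys, -ys, -xs, -xs, -ys)
  cc <- c( xs,  ys, -ys, -xs, -xs, -ys,  ys,  xs)
  keep <- !duplicated(cbind(rr, cc))
  list(rows = as.integer(r) + rr[keep], cols = as.integer(c) + cc[keep])
}

#' Paint a coordinate list into an image
#'
#' Convenience wrapper around the rasterizers, which return coordinate
#' lists rather than painting in place.  Coordinates are 1-based;
#' out-of-bounds pixels are clipped silently.
#'
#' @param image numeric matrix.
#' @param coords list with `rows` and `cols` (as from [draw_line()]).
#' @param value sample value to write.
#' @return The painted matrix.
#' @export
paint <- function(image, coords, value = 1) {
  d <- dim(image)
  ok <- coords$rows >= 1L & coords$rows <= d[1L] &
        coords$cols >= 1L & coords$cols <= d[2L]
  image[cbind(coords$rows[ok], coords$cols[ok])] <- value
  image
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
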