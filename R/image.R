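#' Image container with a sample-type contract
#'
#' Images are plain numeric matrices (grayscale) or 3-D arrays with the
#' channel axis last (RGB or RGB+alpha), tagged with a sample kind that
#' fixes the legal intensity range:
#'
#' * `"u8"`: integer samples in \{0, ..., 255\},
#' * `"float"`: continuous samples in \[0, 1\].
#'
#' Every filter and transform in the package states its contract in terms
#' of these two kinds.  `as_image()` wraps existing data, inferring the
#' kind when it is not given: arrays containing values above 1 (or stored
#' as R integers) are taken as `"u8"`, everything else as `"float"`.
#'
#' @param data numeric matrix or 3-D array; channels, when present, on
#'   the last axis (1, 3 or 4 of them).
#' @param kind `"u8"`, `"float"`, or `NULL` to infer.
#' @return An object of class `mimage`: the same array with a
#'   `pixel_kind` attribute.
#' @examples
#' img <- as_image(matrix(0:255, 16, 16), "u8")
#' pixel_kind(img)
#' range(to_float(img))
#' @export
as_image <- function(data, kind = NULL) {
  if (!is.numeric(data) && !is.logical(data))
    stop("image data must be numeric", call. = FALSE)
  d <- dim(data)
  if (is.null(d) || length(d) < 2L || length(d) > 3L)
    stop("image data must be a matrix or a 3-D array", call. = FALSE)
  if (d[1L] < 1L || d[2L] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (length(d) == 3L && !d[3L] %in% c(1L, 3L, 4L))
    stop("channel axis must have 1, 3 or 4 entries", call. = FALSE)
  if (is.null(kind)) {
    kind <- if (is.integer(data) || any(data > 1, na.rm = TRUE)) "u8" else "float"
  }
  kind <- match.arg(kind, c("u8", "float"))
  x <- structure(as.double(data), dim = d, pixel_kind = kind,
                 class = "mimage")
  check_range_contract(x)
  x
}

#' @rdname as_image
#' @param x an image (or plain array).
#' @export
pixel_kind <- function(x) {
  k <- attr(x, "pixel_kind")
  if (is.null(k)) k <- if (is.integer(x) || any(x > 1, na.rm = TRUE)) "u8" else "float"
  k
}

#' @export
print.mimage <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3L) d[3L] else 1L
  cat(sprintf("<mimage> %d x %d, %d channel%s, kind %s, range [%g, %g]\n",
              d[1L], d[2L], ch, if (ch > 1L) "s" else "",
              pixel_kind(x), min(x), max(x)))
  invisible(x)
}

# strip class/attrs for raw array math
img_data <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

n_channels <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) d[3L] else 1L
}

check_range_contract <- function(x) {
  k <- pixel_kind(x)
  v <- img_data(x)
  if (anyNA(v)) stop("image contains NA samples", call. = FALSE)
  if (k == "u8") {
    if (any(v < 0 | v > 255) || any(v != round(v)))
      stop("u8 contract violated: samples must be integers in 0..255",
           call. = FALSE)
  } else {
    if (any(v < 0 | v > 1))
      stop("float contract violated: samples must lie in [0, 1]",
           call. = FALSE)
  }
  invisible(x)
}

#' Convert an image to the float contract
#'
#' u8 samples v map to v/255; float input is returned unchanged.  The
#' map is monotone and bijective on the 256 u8 levels, so
#' `to_ubyte(to_float(x))` is the identity for any valid u8 image.
#'
#' @param image an image (see [as_image()]).
#' @return A `"float"` image with samples in \[0, 1\].
#' @export
to_float <- function(image) {
  image <- as_image(image, pixel_kind(image))
  if (pixel_kind(image) == "float") return(image)
  as_image(img_data(image) / 255, "float")
}

#' Convert an image to the u8 contract
#'
#' Float samples v map to round(v * 255), rounding halves away from zero
#' so that 0.5 -> 128 on every platform; u8 input is returned unchanged.
#'
#' @inheritParams to_float
#' @return A `"u8"` image with integer samples in 0..255.
#' @export
to_ubyte <- function(image) {
  image <- as_image(image, pixel_kind(image))
  if (pixel_kind(image) == "u8") return(image)
  v <- img_data(image) * 255
  as_image(array(round_half_away(v), dim(image)), "u8")
}

# base round() is round-half-even; the contract wants half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Luminance conversion of an RGB image
#'
#' Collapses a 3-channel image to gray with the ITU-R BT.601-style luma
#' weights 0.2125, 0.7154, 0.0721 (they sum to 1, so achromatic pixels
#' are preserved and the output stays inside the input's range contract).
#'
#' @param image a 3-channel image.
#' @return A single-channel image of the same kind is returned for float
#'   input; u8 input is converted to float first (the weighted sum is
#'   not integer-valued).
#' @export
rgb2gray <- function(image) {
  image <- as_image(image, pixel_kind(image))
  if (n_channels(image) != 3L)
    stop("rgb2gray expects a 3-channel image", call. = FALSE)
  image <- to_float(image)
  w <- c(0.2125, 0.7154, 0.0721)
  v <- img_data(image)
  g <- v[, , 1L] * w[1L] + v[, , 2L] * w[2L] + v[, , 3L] * w[3L]
  as_image(pmin(pmax(g, 0), 1), "float")
}

#' Replicate gray to RGB and attach a foreground alpha channel
#'
#' Channels 1..3 replicate the single-channel input; channel 4 is 1
#' where the sample differs from `background` and 0 elsewhere.  Used by
#' the panorama pipeline, whose warps mark out-of-frame pixels with the
#' sentinel value -1.
#'
#' @param image a single-channel image; the background sentinel may lie
#'   outside the usual float range, so no range contract is enforced
#'   here.
#' @param background sample value regarded as background (default -1).
#' @return rows x cols x 4 array (not range-checked: background
#'   sentinels pass through).
#' @export
add_alpha <- function(image, background = -1) {
  if (n_channels(image) != 1L)
    stop("add_alpha expects a single-channel image", call. = FALSE)
  v <- img_data(image)
  if (length(dim(v)) == 3L) dim(v) <- dim(v)[1:2]
  out <- array(0, c(dim(v), 4L))
  out[, , 1L] <- v
  out[, , 2L] <- v
  out[, , 3L] <- v
  out[, , 4L] <- as.double(v != background)
  out
}
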