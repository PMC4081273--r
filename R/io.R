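#' Read a raster image from disk
#'
#' Binary PNM is the native dialect: P5 (PGM, one channel) and P6 (PPM,
#' three channels) with maxval 255 are read bit-exactly.  Files ending
#' in `.png` are delegated to the \pkg{png} package when it is
#' installed.  16-bit PNM (maxval > 255) is rejected rather than
#' converted, keeping the u8 contract single-valued.
#'
#' @param path file path.
#' @return A u8 image ([as_image()]); PGM gives 1 channel, PPM 3.
#' @seealso [write_image()], [open_collection()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG support requires the 'png' package", call. = FALSE)
    v <- png::readPNG(path)
    v <- round_half_away(v * 255)
    if (length(dim(v)) == 3L) v <- aperm(v, c(1L, 2L, 3L))
    return(as_image(v, "u8"))
  }
  read_pnm(path)
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pos <- 0L
  read_byte <- function() {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L)
      stop(sprintf("malformed PNM '%s': unexpected end of file at byte %d",
                   path, pos), call. = FALSE)
    pos <<- pos + 1L
    b
  }
  # PNM header tokens are whitespace separated; '#' starts a comment
  next_token <- function() {
    tok <- raw(0)
    repeat {
      b <- read_byte()
      ch <- rawToChar(b)
      if (ch == "#") {
        repeat {
          b <- read_byte()
          if (rawToChar(b) %in% c("\n", "\r")) break
        }
      } else if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0L) return(rawToChar(tok))
      } else {
        tok <- c(tok, b)
      }
    }
  }
  magic <- next_token()
  if (!magic %in% c("P5", "P6"))
    stop(sprintf("unsupported PNM magic '%s' in '%s' (byte 0): only binary P5/P6",
                 magic, path), call. = FALSE)
  dims <- vapply(1:3, function(i) {
    t <- next_token()
    if (!grepl("^[0-9]+$", t))
      stop(sprintf("malformed PNM header in '%s' near byte %d: token '%s'",
                   path, pos, t), call. = FALSE)
    as.integer(t)
  }, integer(1))
  width <- dims[1L]; height <- dims[2L]; maxval <- dims[3L]
  if (maxval > 255L)
    stop(sprintf("'%s': maxval %d unsupported (only 8-bit PNM)", path, maxval),
         call. = FALSE)
  channels <- if (magic == "P5") 1L else 3L
  n <- width * height * channels
  payload <- readBin(con, "integer", n, size = 1L, signed = FALSE)
  if (length(payload) < n)
    stop(sprintf("malformed PNM '%s': raster truncated at byte %d (%d of %d samples)",
                 path, pos + length(payload), length(payload), n), call. = FALSE)
  # raster is row-major, channels interleaved fastest
  if (channels == 1L) {
    v <- matrix(payload, nrow = height, ncol = width, byrow = TRUE)
  } else {
    a <- array(payload, c(3L, width, height))   # channel, col, row
    v <- aperm(a, c(3L, 2L, 1L))
  }
  as_image(v, "u8")
}

#' Write an image as binary PNM
#'
#' Single-channel images become P5 (PGM), 3-channel images P6 (PPM),
#' both with maxval 255.  Float images are passed through [to_ubyte()]
#' first; the u8 round trip through [read_image()] is bit-exact.
#'
#' @param path destination file path.
#' @param image a 1- or 3-channel image.
#' @export
write_image <- function(path, image) {
  image <- to_ubyte(as_image(image, pixel_kind(image)))
  ch <- n_channels(image)
  if (!ch %in% c(1L, 3L))
    stop("write_image supports 1- or 3-channel images", call. = FALSE)
  d <- dim(image)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  magic <- if (ch == 1L) "P5" else "P6"
  writeChar(sprintf("%s\n%d %d\n255\n", magic, d[2L], d[1L]), con,
            eos = NULL)
  v <- img_data(image)
  if (ch == 1L) {
    payload <- as.integer(t(matrix(v, d[1L], d[2L])))
  } else {
    payload <- as.integer(aperm(array(v, d), c(3L, 2L, 1L)))
  }
  writeBin(payload, con, size = 1L)
  invisible(NULL)
}

#' Lazily loaded, ordered collection of image files
#'
#' Resolves a glob pattern to a lexicographically sorted file list.  No
#' file is opened at construction; each file is read on first index
#' access and cached, so it is opened at most once.
#'
#' @param pattern glob pattern (as understood by [Sys.glob()]), or a
#'   character vector of explicit paths.
#' @return An `image_collection`; index it with `[[` and query its
#'   size with `length()`.
#' @examples
#' \dontrun{
#' ic <- open_collection("frames/*.pgm")
#' first <- ic[[1]]
#' }
#' @export
open_collection <- function(pattern) {
  paths <- if (length(pattern) == 1L && grepl("[*?[]", pattern))
    Sys.glob(pattern) else as.character(pattern)
  paths <- sort(paths, method = "radix")
  structure(list(pattern = pattern, paths = paths,
                 cache = new.env(parent = emptyenv())),
            class = "image_collection")
}

#' @export
length.image_collection <- function(x) length(x$paths)

#' @export
`[[.image_collection` <- function(x, i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > length(x$paths))
    stop(sprintf("collection index %s out of range 1..%d", i,
                 length(x$paths)), call. = FALSE)
  key <- as.character(i)
  if (!exists(key, envir = x$cache, inherits = FALSE)) {
    assign(key, read_image(x$paths[i]), envir = x$cache)
  }
  get(key, envir = x$cache, inherits = FALSE)
}

#' @export
print.image_collection <- function(x, ...) {
  cat(sprintf("<image_collection> %d file(s)\n", length(x)))
  invisible(x)
}
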