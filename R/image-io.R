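#' Construct an image buffer
#'
#' An `image_buffer` holds an 8-bit intensity raster: a height x width matrix
#' for grayscale, or a height x width x 3 array (R, G, B) for color. All
#' intensities are integers in `[0, 255]`; the gray-level depth is fixed at
#' `L = 256` because the thresholding objectives and the metric constants
#' assume a 255 intensity peak.
#'
#' @param pixels Integer matrix (grayscale) or 3-slice array (RGB) of
#'   intensities in `[0, 255]`.
#' @return An object of class `image_buffer` with fields `pixels`, `channels`
#'   (1 or 3) and `depth` (always 256).
#' @examples
#' img <- image_buffer(matrix(c(0L, 255L, 128L, 64L), 2, 2))
#' img$channels
#' @export
image_buffer <- function(pixels) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    channels <- 3L
  } else {
    stop("`pixels` must be a matrix or a height x width x 3 array", call. = FALSE)
  }
  if (anyNA(pixels)) stop("pixel values must not be NA", call. = FALSE)
  px <- as.integer(round(pixels))
  if (any(px < 0L) || any(px > 255L)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  pixels[] <- px
  structure(
    list(pixels = pixels, channels = channels, depth = 256L),
    class = "image_buffer"
  )
}

#' @export
print.image_buffer <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_buffer> %d x %d, %s, depth %d\n",
    d[1], d[2], if (x$channels == 1L) "grayscale" else "RGB", x$depth
  ))
  invisible(x)
}

#' @export
dim.image_buffer <- function(x) dim(x$pixels)[1:2]

#' Read a raster image into an image buffer
#'
#' Reads PNG, TIFF, PGM/PPM (plain P2/P3 or raw P5/P6) and -- read-only --
#' JPEG files. Images with an alpha channel are stripped to their color
#' channels; 16-bit inputs are rescaled to 8-bit by `round(v * 255 / maxval)`.
#'
#' @param path Path to an image file.
#' @return An [image_buffer()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("JPEG support requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    pgm = ,
    ppm = ,
    pnm = return(read_pnm(path)),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  # png/tiff/jpeg return values in [0, 1]; scale back to 8-bit
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) arr <- arr[, , 1, drop = TRUE]      # gray + alpha
    else if (dim(arr)[3] >= 3L) arr <- arr[, , 1:3, drop = FALSE]
  }
  image_buffer(round(arr * 255))
}

# Minimal PNM reader: plain P2 (PGM) / P3 (PPM) and raw P5 / P6, maxval <= 65535.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok)
        stop("truncated PNM file: ", path, call. = FALSE)
      }
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("^[[:space:]]$", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  }
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(width) || is.na(height) || is.na(maxval) || width < 1L ||
      height < 1L || maxval < 1L || maxval > 65535L) {
    stop("malformed PNM header in ", path, call. = FALSE)
  }
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- width * height * nchan
  if (magic %in% c("P2", "P3")) {
    vals <- suppressWarnings(as.integer(
      scan(con, what = character(), n = nvals, quiet = TRUE, comment.char = "#")
    ))
  } else {
    bytes_per <- if (maxval > 255L) 2L else 1L
    raw_vals <- readBin(con, "integer", n = nvals, size = bytes_per,
                        signed = FALSE, endian = "big")
    vals <- as.integer(raw_vals)
  }
  if (length(vals) < nvals || anyNA(vals)) {
    stop("truncated PNM pixel data in ", path, call. = FALSE)
  }
  if (maxval != 255L) vals <- as.integer(round(vals * 255 / maxval))
  # PNM stores row-major, R fills column-major
  if (nchan == 1L) {
    px <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    px <- array(0L, dim = c(height, width, 3L))
    for (ch in 1:3) {
      px[, , ch] <- matrix(vals[seq(ch, nvals, by = 3L)],
                           nrow = height, ncol = width, byrow = TRUE)
    }
  }
  image_buffer(px)
}

#' Write an image buffer to disk
#'
#' Writes PNG, TIFF or plain-text PGM/PPM depending on the file extension.
#'
#' @param img An [image_buffer()].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_buffer"))
  ext <- tolower(tools::file_ext(path))
  arr <- img$pixels / 255
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    pgm = ,
    ppm = write_pnm(img, path),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

write_pnm <- function(img, path) {
  d <- dim(img$pixels)
  con <- file(path, "w")
  on.exit(close(con))
  if (img$channels == 1L) {
    writeLines(c("P2", paste(d[2], d[1]), "255"), con)
    write(t(img$pixels), file = con, ncolumns = min(d[2], 16L))
  } else {
    writeLines(c("P3", paste(d[2], d[1]), "255"), con)
    inter <- aperm(img$pixels, c(3L, 2L, 1L))   # channel, col, row -> row-major RGB
    write(as.vector(inter), file = con, ncolumns = 12L)
  }
  invisible(path)
}

#' Split an image into single-channel buffers
#'
#' Grayscale images return themselves in a length-1 list; RGB images return
#' three single-channel buffers in R, G, B order. Color images are thresholded
#' per channel throughout the package (no joint 3-D histogram).
#'
#' @param img An [image_buffer()].
#' @return Named list of single-channel [image_buffer()]s (`"gray"` or
#'   `"R"`, `"G"`, `"B"`).
#' @export
split_channels <- function(img) {
  stopifnot(inherits(img, "image_buffer"))
  if (img$channels == 1L) {
    return(list(gray = img))
  }
  out <- lapply(1:3, function(ch) image_buffer(img$pixels[, , ch]))
  names(out) <- c("R", "G", "B")
  out
}
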