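#' Build a 256-bin intensity histogram
#'
#' Tallies pixel intensities of a single-channel image into `L = 256` bins and
#' normalizes by the pixel count `N = M * Q`, giving the gray-level
#' probabilities `p_i = f_i / N` that both thresholding objectives consume.
#'
#' @param channel A single-channel [image_buffer()].
#' @param channel_id Label for the channel (`"gray"`, `"R"`, `"G"` or `"B"`).
#' @return An object of class `channel_histogram` with fields `counts`
#'   (length-256 integer), `probabilities` (length-256, sums to 1), `total`
#'   (pixel count) and `channel_id`.
#' @examples
#' img <- image_buffer(matrix(c(0L, 0L, 255L, 255L), 2, 2))
#' h <- compute_histogram(img)
#' h$probabilities[c(1, 256)]
#' @export
compute_histogram <- function(channel, channel_id = "gray") {
  stopifnot(inherits(channel, "image_buffer"))
  if (channel$channels != 1L) {
    stop("compute_histogram() needs a single-channel buffer; see split_channels()",
         call. = FALSE)
  }
  counts <- tabulate(as.vector(channel$pixels) + 1L, nbins = 256L)
  channel_histogram(counts, channel_id = channel_id)
}

#' Construct a histogram from raw counts
#'
#' Image histograms are always 256 bins; shorter vectors are accepted so that
#' reduced-level toy histograms can be pushed through the objectives and the
#' exhaustive oracle (where small `L` permits larger threshold counts).
#'
#' @param counts Vector of non-negative bin counts (length 256 for images).
#' @param channel_id Channel label.
#' @return A `channel_histogram`.
#' @export
channel_histogram <- function(counts, channel_id = "gray") {
  if (length(counts) < 2L) stop("`counts` must have at least 2 bins", call. = FALSE)
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("histogram must contain at least one pixel", call. = FALSE)
  structure(
    list(
      counts = as.numeric(counts),
      probabilities = as.numeric(counts) / total,
      total = total,
      channel_id = channel_id
    ),
    class = "channel_histogram"
  )
}

#' @export
print.channel_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf(
    "<channel_histogram> channel %s, %g pixels, support [%d, %d] (%d levels)\n",
    x$channel_id, x$total, min(nz) - 1L, max(nz) - 1L, length(nz)
  ))
  invisible(x)
}

#' Histograms for every channel of an image
#'
#' @param img An [image_buffer()] (grayscale or RGB).
#' @return Named list of `channel_histogram`s, one per channel.
#' @export
image_histograms <- function(img) {
  chans <- split_channels(img)
  purrr::imap(chans, function(ch, id) compute_histogram(ch, channel_id = id))
}

#' Histogram as a tibble
#'
#' @param x A `channel_histogram`.
#' @param ... Unused.
#' @return A tibble with columns `level`, `count`, `probability`.
#' @method tidy channel_histogram
#' @export
tidy.channel_histogram <- function(x, ...) {
  tibble::tibble(
    level = seq_along(x$counts) - 1L,
    count = x$counts,
    probability = x$probabilities
  )
}

#' @method autoplot channel_histogram
#' @export
autoplot.channel_histogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "gray level", y = "pixel count",
                  title = paste("Intensity histogram,", object$channel_id))
}

#' Serialize a histogram to JSON
#'
#' Schema: `{"counts": [256 integers], "channel": "gray|R|G|B"}`.
#'
#' @param h A `channel_histogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_json <- function(h, path) {
  stopifnot(inherits(h, "channel_histogram"))
  jsonlite::write_json(
    list(counts = h$counts, channel = h$channel_id),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a histogram serialized with [write_histogram_json()]
#'
#' @param path JSON file path.
#' @return A `channel_histogram`.
#' @export
read_histogram_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$counts)) stop("no 'counts' field in ", path, call. = FALSE)
  channel_histogram(obj$counts, channel_id = obj$channel %||% "gray")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
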