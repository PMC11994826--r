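#' Gaussian-mixture intensity image
#'
#' Samples each pixel's intensity from a mixture of normal components, rounds
#' and clips to `[0, 255]`. These images emulate the statistical structure the
#' thresholding objectives exploit -- multimodal intensity histograms -- not
#' the pixel content of any particular photographic or clinical image set.
#'
#' @param modes A data frame (or tibble) with columns `mean`, `sd`, `weight`;
#'   weights must sum to 1, means lie in `[0, 255]`, `sd > 0`.
#' @param shape `c(height, width)`.
#' @param seed Optional integer seed for reproducibility.
#' @return An [image_buffer()].
#' @examples
#' img <- gaussian_mixture_image(
#'   data.frame(mean = c(64, 192), sd = 10, weight = 0.5),
#'   shape = c(64, 64), seed = 1
#' )
#' @export
gaussian_mixture_image <- function(modes, shape = c(128L, 128L), seed = NULL) {
  modes <- as.data.frame(modes)
  stopifnot(all(c("mean", "sd", "weight") %in% names(modes)),
            all(modes$sd > 0), all(modes$mean >= 0), all(modes$mean <= 255))
  if (abs(sum(modes$weight) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  npix <- shape[1] * shape[2]
  comp <- sample.int(nrow(modes), npix, replace = TRUE, prob = modes$weight)
  vals <- stats::rnorm(npix, mean = modes$mean[comp], sd = modes$sd[comp])
  px <- matrix(pmin(pmax(round(vals), 0), 255), nrow = shape[1], ncol = shape[2])
  image_buffer(px)
}

#' Histogram with mass concentrated at a few levels
#'
#' @param levels Gray levels in `[0, 255]` carrying mass.
#' @param weights Probabilities per level (must sum to 1).
#' @param total Total pixel count to distribute (counts are
#'   `round(weight * total)`).
#' @param L Number of gray levels.
#' @return A [channel_histogram()].
#' @examples
#' delta_histogram(c(0, 255), c(0.5, 0.5), total = 100)
#' @export
delta_histogram <- function(levels, weights, total = 10000, L = 256L) {
  stopifnot(length(levels) == length(weights))
  levels <- as.integer(levels)
  if (any(levels < 0L) || any(levels > L - 1L)) {
    stop("levels must lie in [0, ", L - 1L, "]", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  counts <- numeric(L)
  counts[levels + 1L] <- round(weights * total)
  channel_histogram(counts)
}

#' Horizontal intensity ramp image
#'
#' Intensity increases left to right covering the full `0..255` range; a
#' width that is a multiple of 256 yields an exactly uniform histogram.
#'
#' @param shape `c(height, width)`; width of at least 256 recommended.
#' @return An [image_buffer()].
#' @examples
#' h <- compute_histogram(ramp_image(c(1L, 256L)))
#' all(h$counts == 1)
#' @export
ramp_image <- function(shape = c(4L, 256L)) {
  cols <- floor((seq_len(shape[2]) - 1L) * 256 / shape[2])
  image_buffer(matrix(rep(cols, each = shape[1]),
                      nrow = shape[1], ncol = shape[2]))
}
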