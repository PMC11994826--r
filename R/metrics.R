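#' Segment an image with a threshold vector
#'
#' Labels every pixel by the half-open class rule (`t_i <= p < t_{i+1}`) and
#' builds the class-mean reconstruction: each pixel is replaced by the rounded
#' mean intensity of its class, computed from the image itself. Class means
#' minimize the reconstruction RMSE, which makes the Otsu variance identity
#' (squared RMSE = total variance - between-class variance) exact before
#' rounding. Empty classes fall back to their class-interval midpoint.
#'
#' @param img A single-channel [image_buffer()].
#' @param t A [threshold_vector()].
#' @return An object of class `segmentation_result` with `labels` (0-based
#'   class per pixel), `reconstruction` (an [image_buffer()]), `class_means`
#'   and `thresholds`.
#' @export
apply_thresholds <- function(img, t) {
  stopifnot(inherits(img, "image_buffer"))
  if (img$channels != 1L) {
    stop("apply_thresholds() needs a single-channel buffer", call. = FALSE)
  }
  L <- img$depth
  level_class <- partition_levels(t, L)
  labels <- matrix(level_class[img$pixels + 1L], nrow = nrow(img$pixels))
  m <- length(t) + 1L
  bounds <- c(0L, as.integer(t), L)
  means <- vapply(seq_len(m), function(i) {
    sel <- labels == (i - 1L)
    if (any(sel)) {
      round(mean(img$pixels[sel]))
    } else {
      round((bounds[i] + bounds[i + 1L] - 1L) / 2)
    }
  }, numeric(1))
  recon <- matrix(means[labels + 1L], nrow = nrow(labels))
  structure(
    list(
      labels = labels,
      reconstruction = image_buffer(recon),
      class_means = means,
      thresholds = t
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d classes, thresholds: %s\n  class means: %s\n",
    length(x$thresholds) + 1L, paste(x$thresholds, collapse = ", "),
    paste(x$class_means, collapse = ", ")
  ))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "image_buffer")) x$pixels else x
}

check_same_shape <- function(I, Seg) {
  a <- as_pixels(I); b <- as_pixels(Seg)
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Root-mean-squared error between two images
#'
#' `sqrt(mean((I - Seg)^2))` over all `M x Q` pixels (all channels for color).
#'
#' @param I,Seg [image_buffer()]s (or plain matrices) of identical shape.
#' @return A non-negative scalar.
#' @export
rmse <- function(I, Seg) {
  p <- check_same_shape(I, Seg)
  sqrt(mean((as.numeric(p$a) - as.numeric(p$b))^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 * log10(255 / RMSE)`; identical images give `Inf`.
#'
#' @inheritParams rmse
#' @return PSNR in dB (`Inf` for a perfect match).
#' @export
psnr <- function(I, Seg) {
  r <- rmse(I, Seg)
  if (r == 0) Inf else 20 * log10(255 / r)
}

#' Global structural similarity index
#'
#' The single-window SSIM over the whole image with stabilizing constants
#' `C1 = 6.5025` and `C2 = 58.52252`; variances and the covariance use
#' population normalization (divide by the pixel count). Color images are
#' scored per channel and averaged.
#'
#' @inheritParams rmse
#' @return A scalar `<= 1`; 1 means identical images.
#' @export
ssim <- function(I, Seg) {
  p <- check_same_shape(I, Seg)
  a <- p$a; b <- p$b
  if (length(dim(a)) == 3L) {
    return(mean(vapply(seq_len(dim(a)[3]),
                       function(ch) ssim_global(a[, , ch], b[, , ch]),
                       numeric(1))))
  }
  ssim_global(a, b)
}

ssim_global <- function(a, b, C1 = 6.5025, C2 = 58.52252) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  var_a <- sum((a - mu_a)^2) / n
  var_b <- sum((b - mu_b)^2) / n
  cov_ab <- sum((a - mu_a) * (b - mu_b)) / n
  ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
}

#' Quality metrics of a segmentation
#'
#' Scores a class-mean reconstruction against the original image. For RGB
#' buffers each channel is segmented with its own thresholds and the metrics
#' are averaged over channels.
#'
#' @param img An [image_buffer()].
#' @param thresholds A [threshold_vector()] (grayscale), or a list of one
#'   threshold vector per channel (RGB).
#' @return A tibble with one row per channel plus, for color images, an
#'   `"average"` row: columns `channel`, `rmse`, `psnr`, `ssim`.
#' @export
segmentation_quality <- function(img, thresholds) {
  chans <- split_channels(img)
  if (inherits(thresholds, "threshold_vector")) {
    thresholds <- rep(list(thresholds), length(chans))
  }
  stopifnot(length(thresholds) == length(chans))
  rows <- purrr::imap(chans, function(ch, id) {
    seg <- apply_thresholds(ch, thresholds[[match(id, names(chans))]])
    tibble::tibble(
      channel = id,
      rmse = rmse(ch, seg$reconstruction),
      psnr = psnr(ch, seg$reconstruction),
      ssim = ssim(ch, seg$reconstruction)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 1L) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(channel = "average", rmse = mean(out$rmse),
                     psnr = mean(out$psnr), ssim = mean(out$ssim))
    )
  }
  out
}

#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$labels)),
    col = seq_len(ncol(object$labels))
  )
  df$class <- factor(as.vector(t(object$labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Segmentation label map", x = NULL, y = NULL)
}
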