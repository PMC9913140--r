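#' Median-filter noise removal
#'
#' Replaces every pixel by the median of its `window x window` neighbourhood,
#' the classic remedy for the impulse (salt-and-pepper) noise common in
#' digitised histopathology slides.  Borders are handled by reflect padding so
#' the output has the same shape as the input; RGB images are filtered per
#' channel.
#'
#' The median of an odd set is the usual middle order statistic, so every
#' output pixel is a value present in its input window.  (For completeness: an
#' even-sized set would be summarised by the mean of the two central values,
#' rounded half-up on the 8-bit scale — unreachable through this interface
#' because `window` must be odd.)
#'
#' @param image Matrix or `H x W x 3` array, either intensity scale.
#' @param window Odd positive integer window side; must not exceed the smaller
#'   image dimension.  `window = 1` is the identity.
#' @return Filtered image, same shape and scale as the input.
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 255
#' median_filter(m, 3)[2, 2]  # impulse removed -> 0
#' @export
median_filter <- function(image, window = 3) {
  validate_image(image)
  if (length(window) != 1L || !is.finite(window) || window < 1 ||
      window != as.integer(window) || window %% 2 == 0) {
    abort("`window` must be an odd positive integer.", class = "histodbn_parameter_error")
  }
  d <- dim(image)
  if (window > min(d[1], d[2])) {
    abort("`window` must not exceed the image dimensions.", class = "histodbn_parameter_error")
  }
  if (window == 1) return(image)
  r <- (window - 1L) / 2L
  k <- window * window
  f <- function(m) {
    n <- nrow(m); p <- ncol(m)
    pm <- pad_reflect(m, r)
    vals <- matrix(0, n * p, k)
    idx <- 1L
    for (di in 0:(window - 1L)) {
      for (dj in 0:(window - 1L)) {
        vals[, idx] <- as.vector(pm[di + seq_len(n), dj + seq_len(p), drop = FALSE])
        idx <- idx + 1L
      }
    }
    # row-wise sort by ordering on (row, value); median = middle column
    srt <- matrix(vals[order(row(vals), vals)], nrow = n * p, byrow = TRUE)
    matrix(srt[, (k + 1L) / 2L], n, p)
  }
  map_channels(image, f)
}

#' Contrast enhancement
#'
#' Histology images are frequently low-contrast after digitisation; this step
#' spreads the intensity histogram before feature extraction.  Two methods are
#' provided: contrast-limited adaptive histogram equalization (CLAHE, the
#' standard choice for histology, computed tile-wise via \pkg{EBImage}) and
#' plain global histogram equalization.  A constant image has no contrast to
#' stretch and is returned unchanged by either method; output intensities never
#' leave the declared range.
#'
#' Global equalization maps each intensity through the empirical CDF:
#' on the 8-bit scale `out = round_half_up(cdf * 256 - 1)` clamped to
#' `[0, 255]`; on the unit scale `out = cdf`.
#'
#' @param image Matrix or `H x W x 3` array (RGB enhanced per channel).
#' @param method `"clahe"` (default) or `"hist_eq"`.
#' @param clip_limit CLAHE clipping fraction (> 0); default 0.01.
#' @param tile CLAHE tile grid side (>= 1); default 8.
#' @return Enhanced image, same shape and scale as the input.
#' @examples
#' m <- matrix(c(10, 30, 20, 40), 2, 2)
#' enhance_contrast(m, "hist_eq")
#' @export
enhance_contrast <- function(image, method = c("clahe", "hist_eq"),
                             clip_limit = 0.01, tile = 8) {
  validate_image(image)
  if (is.character(method) && length(method) >= 1 &&
      !method[1] %in% c("clahe", "hist_eq")) {
    abort(paste0("Unknown contrast method: ", method[1]),
          class = "histodbn_parameter_error")
  }
  method <- match.arg(method)
  scale <- image_scale(image)
  if (method == "clahe" && (!is.finite(clip_limit) || clip_limit <= 0)) {
    abort("`clip_limit` must be positive.", class = "histodbn_parameter_error")
  }
  if (method == "clahe" && (!is.finite(tile) || tile < 1)) {
    abort("`tile` must be >= 1.", class = "histodbn_parameter_error")
  }
  f <- function(m) {
    if (diff(range(m)) == 0) return(m)  # constant: nothing to stretch
    if (method == "hist_eq") {
      hist_equalize(m, scale)
    } else {
      bins <- 256L
      out <- EBImage::imageData(EBImage::clahe(
        EBImage::Image(m / scale),
        nx = as.integer(tile), ny = as.integer(tile),
        bins = bins, limit = clip_limit * bins
      ))
      out <- clamp(out, 0, 1) * scale
      if (scale == 255) out <- round(out)
      out
    }
  }
  map_channels(image, f)
}

hist_equalize <- function(m, scale) {
  v <- as.vector(m)
  tab <- table(v)
  cdf <- cumsum(as.numeric(tab)) / length(v)
  lev <- as.numeric(names(tab))
  mapped <- if (scale == 255) {
    clamp(round_half_up(cdf * 256 - 1), 0, 255)
  } else {
    cdf
  }
  matrix(mapped[match(v, lev)], nrow(m), ncol(m))
}

#' Preprocess a set of images
#'
#' Convenience wrapper applying, in order: optional grayscale conversion,
#' median filtering, and contrast enhancement — the standard cleanup stage
#' ahead of feature extraction.
#'
#' @param images List of image matrices/arrays.
#' @param median_window Odd window for [median_filter()]; default 3.
#' @param contrast `"clahe"`, `"hist_eq"`, or `"none"`.
#' @param clip_limit,tile Passed to [enhance_contrast()].
#' @param grayscale Convert RGB inputs to luma first (default `TRUE`; the
#'   downstream extractor consumes single-channel input by default).
#' @return List of preprocessed images.
#' @export
preprocess_images <- function(images, median_window = 3,
                              contrast = c("clahe", "hist_eq", "none"),
                              clip_limit = 0.01, tile = 8, grayscale = TRUE) {
  contrast <- match.arg(contrast)
  purrr::map(images, function(img) {
    if (grayscale) img <- rgb_to_gray(img)
    img <- median_filter(img, median_window)
    if (contrast != "none") {
      img <- enhance_contrast(img, contrast, clip_limit = clip_limit, tile = tile)
    }
    img
  })
}
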