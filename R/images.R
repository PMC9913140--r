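#' Image containers and utilities
#'
#' Images are plain base-R objects: a numeric `height x width` matrix for a
#' single-channel image or a `height x width x 3` array for RGB.  Two intensity
#' conventions are supported and detected automatically: 8-bit integer scale
#' (values in 0--255) and unit scale (values in 0--1).  All preprocessing
#' functions preserve the convention of their input.
#'
#' @param image A numeric matrix (`H x W`) or array (`H x W x 3`).
#' @return `image_scale()` returns `255` or `1`; `validate_image()` returns the
#'   image invisibly after checking its invariants.
#' @examples
#' img <- matrix(0:24, 5, 5)
#' image_scale(img)
#' @name image-utils
NULL

#' @rdname image-utils
#' @export
image_scale <- function(image) {
  if (any(image > 1 + 1e-12)) 255 else 1
}

#' @rdname image-utils
#' @export
validate_image <- function(image) {
  if (!is.numeric(image)) {
    abort("`image` must be a numeric matrix or array.", class = "histodbn_parameter_error")
  }
  nd <- length(dim(image))
  if (!(nd == 2L || (nd == 3L && dim(image)[3] %in% c(1L, 3L)))) {
    abort("`image` must be H x W or H x W x {1,3}.", class = "histodbn_parameter_error")
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255)) {
    abort("Image intensities must be finite and within [0, 255].",
          class = "histodbn_parameter_error")
  }
  invisible(image)
}

n_channels <- function(image) {
  if (length(dim(image)) == 2L) 1L else dim(image)[3]
}

# apply f(matrix) -> matrix to every channel
map_channels <- function(image, f) {
  if (length(dim(image)) == 2L) return(f(image))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- f(image[, , ch])
  out
}

#' Convert an RGB image to grayscale (ITU-R 601 luma)
#'
#' @param image An `H x W x 3` numeric array; single-channel input is returned
#'   unchanged.
#' @return An `H x W` matrix on the same intensity scale.
#' @export
rgb_to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  if (dim(image)[3] == 1L) return(image[, , 1L])
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Bilinear image resize
#'
#' @param image Single-channel matrix or RGB array.
#' @param height,width Target size in pixels.
#' @return Resized image on the same intensity scale.
#' @export
resize_image <- function(image, height, width) {
  validate_image(image)
  scale <- image_scale(image)
  f <- function(m) {
    # EBImage maps matrix dim 1 to its x axis, so "w" receives target rows
    r <- EBImage::resize(EBImage::Image(m / scale), w = height, h = width,
                         filter = "bilinear")
    EBImage::imageData(r) * scale
  }
  out <- map_channels(image, f)
  if (scale == 255) out <- clamp(round(out), 0, 255)
  out
}

#' Read and write images
#'
#' PNG is read/written via the \pkg{png} package, TIFF via \pkg{tiff} when
#' installed.  Pixels are returned on the 8-bit 0--255 scale.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param image Image matrix/array on either intensity scale.
#' @return `read_image()` returns a matrix or `H x W x 3` array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF requires the 'tiff' package.", class = "histodbn_parameter_error")
      }
      tiff::readTIFF(path)
    },
    abort(paste0("Unsupported image format: .", ext), class = "histodbn_parameter_error")
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3] # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1L]  # gray+alpha
  round(px * 255)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  validate_image(image)
  px <- image / image_scale(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Writing TIFF requires the 'tiff' package.", class = "histodbn_parameter_error")
      }
      tiff::writeTIFF(px, path)
    },
    abort(paste0("Unsupported image format: .", ext), class = "histodbn_parameter_error")
  )
  invisible(path)
}

# reflect (symmetric) padding of a matrix by r pixels on each side
pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  n <- nrow(m); p <- ncol(m)
  if (r > n || r > p) {
    abort("Padding exceeds image size.", class = "histodbn_parameter_error")
  }
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:p, p:(p - r + 1))
  m[ri, ci, drop = FALSE]
}
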