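#' Fire-module configuration
#'
#' A fire module is the squeeze/expand building block of SqueezeNet-style
#' networks: a 1x1 "squeeze" convolution feeding parallel 1x1 and 3x3 "expand"
#' convolutions whose outputs are channel-concatenated.  Keeping the squeeze
#' width below the total expand width is what buys the parameter saving —
#' replacing a 3x3 kernel by a 1x1 kernel divides its weight count by nine.
#'
#' @param squeeze_1x1 Number of 1x1 squeeze kernels (>= 1).
#' @param expand_1x1,expand_3x3 Numbers of 1x1 and 3x3 expand kernels (>= 1).
#' @return A `fire_config` list; `expand_total` is `expand_1x1 + expand_3x3`.
#' @examples
#' fire_config(4, 8, 8)
#' @export
fire_config <- function(squeeze_1x1, expand_1x1, expand_3x3) {
  vals <- c(squeeze_1x1, expand_1x1, expand_3x3)
  if (any(vals < 1) || any(vals != as.integer(vals))) {
    abort("Fire channel counts must be positive integers.",
          class = "histodbn_parameter_error")
  }
  if (squeeze_1x1 >= expand_1x1 + expand_3x3) {
    abort("squeeze_1x1 must be < expand_1x1 + expand_3x3.",
          class = "histodbn_parameter_error")
  }
  structure(list(squeeze_1x1 = as.integer(squeeze_1x1),
                 expand_1x1 = as.integer(expand_1x1),
                 expand_3x3 = as.integer(expand_3x3),
                 expand_total = as.integer(expand_1x1 + expand_3x3)),
            class = "fire_config")
}

#' Feature-extractor topology
#'
#' Desk-scale default: 32x32 grayscale input, a 3x3 stem convolution with 8
#' channels, three fire modules (4/8/8, 8/16/16, 8/16/16) with 2x2 max-pooling
#' after the first and second, and global average pooling to a 32-dimensional
#' feature vector.  `squeezenet_v11_config()` gives the full-size topology.
#'
#' @param input_size `(height, width, channels)` of the input images.
#' @param stem_channels Channels of the 3x3 stem convolution.
#' @param fire_configs Ordered list of [fire_config()] objects.
#' @param pool_positions Indices of fire modules followed by 2x2 max-pooling;
#'   all must be `< length(fire_configs)` or equal to it (pooling after the
#'   last module is allowed but pointless before global pooling).
#' @param seed Seed for He-uniform weight initialization.
#' @return An `extractor_config`; `feature_dim` equals the expand total of the
#'   last fire module.
#' @export
extractor_config <- function(input_size = c(32, 32, 1), stem_channels = 8,
                             fire_configs = list(fire_config(4, 8, 8),
                                                 fire_config(8, 16, 16),
                                                 fire_config(8, 16, 16)),
                             pool_positions = c(1, 2), seed = 42) {
  if (length(input_size) != 3 || any(input_size < 1)) {
    abort("`input_size` must be (height, width, channels).",
          class = "histodbn_parameter_error")
  }
  if (length(fire_configs) < 1 ||
      !all(purrr::map_lgl(fire_configs, inherits, "fire_config"))) {
    abort("`fire_configs` must be a non-empty list of fire_config objects.",
          class = "histodbn_parameter_error")
  }
  if (length(pool_positions) > 0 &&
      (any(pool_positions < 1) || any(pool_positions > length(fire_configs)))) {
    abort("`pool_positions` must index fire modules.",
          class = "histodbn_parameter_error")
  }
  structure(list(
    input_size = as.integer(input_size),
    stem_channels = as.integer(stem_channels),
    fire_configs = fire_configs,
    pool_positions = as.integer(pool_positions),
    feature_dim = fire_configs[[length(fire_configs)]]$expand_total,
    seed = as.integer(seed)
  ), class = "extractor_config")
}

#' @rdname extractor_config
#' @export
squeezenet_v11_config <- function(input_size = c(224, 224, 3), seed = 42) {
  extractor_config(
    input_size = input_size, stem_channels = 64,
    fire_configs = list(
      fire_config(16, 64, 64),  fire_config(16, 64, 64),
      fire_config(32, 128, 128), fire_config(32, 128, 128),
      fire_config(48, 192, 192), fire_config(48, 192, 192),
      fire_config(64, 256, 256), fire_config(64, 256, 256)
    ),
    pool_positions = c(2, 4), seed = seed
  )
}

# ---- convolution primitives (im2col) ----

# x: C x H x W array; W: Cout x Cin x k x k; zero same-padding; returns
# Cout x H x W.  k in {1, 3}.
conv2d <- function(x, W, b = NULL) {
  dx <- dim(x); dw <- dim(W)
  if (dx[1] != dw[2]) {
    abort(sprintf("Input channels (%d) do not match kernel channels (%d).",
                  dx[1], dw[2]), class = "histodbn_structural_error")
  }
  k <- dw[3]
  H <- dx[2]; Wd <- dx[3]
  p <- (k - 1L) / 2L
  if (p > 0) {
    xp <- array(0, c(dx[1], H + 2L * p, Wd + 2L * p))
    xp[, p + seq_len(H), p + seq_len(Wd)] <- x
  } else {
    xp <- x
  }
  cols <- matrix(0, dw[2] * k * k, H * Wd)
  row0 <- 0L
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      patch <- xp[, di + seq_len(H), dj + seq_len(Wd), drop = FALSE]
      cols[row0 + seq_len(dw[2]), ] <- matrix(patch, dw[2], H * Wd)
      row0 <- row0 + dw[2]
    }
  }
  # weight layout must match patch stacking order: (di, dj) outer, channel inner
  Wm <- matrix(0, dw[1], dw[2] * k * k)
  col0 <- 0L
  for (di in 1:k) {
    for (dj in 1:k) {
      Wm[, col0 + seq_len(dw[2])] <- W[, , di, dj]
      col0 <- col0 + dw[2]
    }
  }
  out <- Wm %*% cols
  if (!is.null(b)) out <- out + b
  array(out, c(dw[1], H, Wd))
}

relu <- function(x) pmax(x, 0)

maxpool2 <- function(x) {
  d <- dim(x)
  H <- (d[2] %/% 2L) * 2L; W <- (d[3] %/% 2L) * 2L
  x <- x[, seq_len(H), seq_len(W), drop = FALSE]
  a <- pmax(x[, seq(1, H, 2), , drop = FALSE], x[, seq(2, H, 2), , drop = FALSE])
  pmax(a[, , seq(1, W, 2), drop = FALSE], a[, , seq(2, W, 2), drop = FALSE])
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}

#' Initialize extractor weights (He-uniform, seeded)
#'
#' @param config An [extractor_config()].
#' @return Nested list of weight arrays: `stem$W` (`C_out x C_in x 3 x 3`),
#'   `stem$b`, and per fire module `squeeze`/`expand1`/`expand3` each with
#'   `W` and `b`.
#' @export
init_extractor_weights <- function(config) {
  withr::with_seed(config$seed, {
    cin <- config$input_size[3]
    stem <- list(W = he_uniform(c(config$stem_channels, cin, 3, 3), cin * 9),
                 b = numeric(config$stem_channels))
    prev <- config$stem_channels
    fires <- purrr::map(config$fire_configs, function(fc) {
      s <- fc$squeeze_1x1
      w <- list(
        squeeze = list(W = he_uniform(c(s, prev, 1, 1), prev), b = numeric(s)),
        expand1 = list(W = he_uniform(c(fc$expand_1x1, s, 1, 1), s),
                       b = numeric(fc$expand_1x1)),
        expand3 = list(W = he_uniform(c(fc$expand_3x3, s, 3, 3), s * 9),
                       b = numeric(fc$expand_3x3))
      )
      prev <<- fc$expand_total
      w
    })
    list(stem = stem, fires = fires)
  })
}

#' Forward pass through one fire module
#'
#' Squeeze (1x1 convolution, ReLU), then parallel expand 1x1 and expand 3x3
#' (same padding) convolutions, channel-concatenated and passed through ReLU.
#' Spatial size is preserved; output channels equal
#' `expand_1x1 + expand_3x3`.
#'
#' @param input `C x H x W` activation array.
#' @param config A [fire_config()].
#' @param weights Module weights as produced by [init_extractor_weights()]
#'   (elements `squeeze`, `expand1`, `expand3`).
#' @return `(expand_1x1 + expand_3x3) x H x W` activation array.
#' @export
fire_forward <- function(input, config, weights) {
  if (dim(weights$squeeze$W)[1] != config$squeeze_1x1 ||
      dim(weights$expand1$W)[1] != config$expand_1x1 ||
      dim(weights$expand3$W)[1] != config$expand_3x3) {
    abort("Weights are not shaped for this fire_config.",
          class = "histodbn_structural_error")
  }
  s <- relu(conv2d(input, weights$squeeze$W, weights$squeeze$b))
  e1 <- conv2d(s, weights$expand1$W, weights$expand1$b)
  e3 <- conv2d(s, weights$expand3$W, weights$expand3$b)
  d <- dim(e1)
  out <- array(0, c(config$expand_total, d[2], d[3]))
  out[seq_len(config$expand_1x1), , ] <- e1
  out[config$expand_1x1 + seq_len(config$expand_3x3), , ] <- e3
  relu(out)
}

#' Count trainable parameters of an extractor
#'
#' Exact enumeration of weight-tensor and bias sizes, layer by layer.  The
#' canonical SqueezeNet saving is visible here: a 3x3 convolution of equal
#' channel counts carries exactly nine times the weights of its 1x1
#' substitute.
#'
#' @param config An [extractor_config()].
#' @param bias Include bias parameters (default `TRUE`).
#' @param detail If `TRUE`, return a tibble itemizing every tensor
#'   (`layer`, `tensor`, `weights`, `biases`); otherwise the total count.
#' @return Integer total, or a tibble when `detail = TRUE`.
#' @examples
#' count_parameters(extractor_config())
#' @export
count_parameters <- function(config, bias = TRUE, detail = FALSE) {
  rows <- list(tibble::tibble(
    layer = "stem", tensor = "conv3x3",
    weights = config$stem_channels * config$input_size[3] * 9L,
    biases = config$stem_channels
  ))
  prev <- config$stem_channels
  for (i in seq_along(config$fire_configs)) {
    fc <- config$fire_configs[[i]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = paste0("fire", i),
      tensor = c("squeeze1x1", "expand1x1", "expand3x3"),
      weights = c(fc$squeeze_1x1 * prev * 1L,
                  fc$expand_1x1 * fc$squeeze_1x1 * 1L,
                  fc$expand_3x3 * fc$squeeze_1x1 * 9L),
      biases = c(fc$squeeze_1x1, fc$expand_1x1, fc$expand_3x3)
    )
    prev <- fc$expand_total
  }
  tab <- dplyr::bind_rows(rows)
  if (!bias) tab$biases <- 0L
  if (detail) return(tab)
  as.integer(sum(tab$weights) + sum(tab$biases))
}

# forward pass for one image matrix (unit scale), returns feature vector
extractor_forward <- function(img, config, weights) {
  d <- dim(img)
  if (length(d) == 2L) {
    x <- array(img, c(1L, d[1], d[2]))
  } else {
    x <- aperm(img, c(3, 1, 2))
  }
  if (dim(x)[1] != config$input_size[3] ||
      dim(x)[2] != config$input_size[1] || dim(x)[3] != config$input_size[2]) {
    abort("Image size does not match extractor input_size.",
          class = "histodbn_structural_error")
  }
  a <- relu(conv2d(x, weights$stem$W, weights$stem$b))
  for (i in seq_along(config$fire_configs)) {
    a <- fire_forward(a, config$fire_configs[[i]], weights$fires[[i]])
    if (i %in% config$pool_positions) a <- maxpool2(a)
  }
  apply(a, 1, mean)  # global average pooling
}

#' Extract features from a set of images
#'
#' Runs every image through the stem convolution, the fire-module stack (with
#' max-pooling at the configured positions) and global average pooling.
#' Deterministic for fixed weights; row `i` of the result corresponds to image
#' `i`.  Images are rescaled to the unit intensity range and resized
#' (bilinear) to the extractor input size if needed.
#'
#' @param images List of image matrices/arrays.
#' @param config An [extractor_config()].
#' @param weights Extractor weights; seeded He-uniform initialization from
#'   `config$seed` when `NULL`.
#' @return Numeric matrix, `length(images) x feature_dim`.
#' @export
extract_features <- function(images, config, weights = NULL) {
  if (is.null(weights)) weights <- init_extractor_weights(config)
  h <- config$input_size[1]; w <- config$input_size[2]
  feats <- purrr::map(images, function(img) {
    if (config$input_size[3] == 1L) img <- rgb_to_gray(img)
    if (!identical(dim(img)[1:2], c(h, w))) img <- resize_image(img, h, w)
    extractor_forward(img / image_scale(img), config, weights)
  })
  out <- do.call(rbind, feats)
  dimnames(out) <- list(NULL, paste0("f", seq_len(ncol(out))))
  out
}
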