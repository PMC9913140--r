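#' Texture parameters for one synthetic tissue class
#'
#' The synthetic generator emulates the visual statistics that drive
#' benign/malignant discrimination in histopathology at low resolution:
#' darker nuclei scattered over a lighter stroma texture, with malignant
#' tissue showing a higher nuclear density.  Parameters are per 64x64 tile
#' and on the unit intensity scale.
#'
#' @param density Expected nucleus count per image (Poisson mean), > 0.
#' @param radius_mean,radius_sd Nucleus radius (pixels), mean > 0.
#' @param intensity_mean,intensity_sd Nucleus intensity in `[0, 1]` (nuclei are
#'   darker than the background).
#' @param background Background (stroma) intensity in `[0, 1]`.
#' @param correlation_length Gaussian smoothing sigma (pixels) of the stroma
#'   texture, > 0.
#' @return A `class_texture_params` list.
#' @export
class_texture_params <- function(density, radius_mean, radius_sd = 0.5,
                                 intensity_mean = 0.25, intensity_sd = 0.05,
                                 background = 0.75, correlation_length = 3) {
  if (density <= 0 || radius_mean <= 0 || correlation_length <= 0) {
    abort("density, radius_mean and correlation_length must be positive.",
          class = "histodbn_parameter_error")
  }
  if (intensity_mean < 0 || intensity_mean > 1 || background < 0 || background > 1) {
    abort("Intensity means must lie in [0, 1].", class = "histodbn_parameter_error")
  }
  structure(list(density = density, radius_mean = radius_mean,
                 radius_sd = radius_sd, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, background = background,
                 correlation_length = correlation_length),
            class = "class_texture_params")
}

#' Per-class parameter presets
#'
#' `"easy"` uses well-separated nuclear densities (for end-to-end checks of the
#' full pipeline); `"hard"` overlaps the class distributions (for robustness
#' tests).
#'
#' @param difficulty `"easy"` or `"hard"`.
#' @return List with elements `benign` and `malignant`.
#' @export
synthetic_presets <- function(difficulty = c("easy", "hard")) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "easy") {
    list(
      benign    = class_texture_params(density = 8,  radius_mean = 2.5),
      malignant = class_texture_params(density = 24, radius_mean = 2.5)
    )
  } else {
    list(
      benign    = class_texture_params(density = 12, radius_mean = 2.2,
                                       intensity_sd = 0.10),
      malignant = class_texture_params(density = 17, radius_mean = 2.5,
                                       intensity_sd = 0.10)
    )
  }
}

# separable gaussian blur with reflect padding
blur_gauss <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  pm <- pad_reflect(m, r)
  tmp <- matrix(0, n, p + 2L * r)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * pm[(i - 1L) + seq_len(n), , drop = FALSE]
  }
  out <- matrix(0, n, p)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(p), drop = FALSE]
  }
  out
}

# one synthetic tissue tile on the unit scale, before noise/contrast
render_tissue <- function(size, params) {
  stroma <- blur_gauss(matrix(rnorm(size * size), size, size),
                       params$correlation_length)
  stroma <- stroma / max(stats::sd(stroma), 1e-9) * 0.04
  img <- params$background + stroma
  n_nuc <- rpois(1, params$density)
  if (n_nuc > 0) {
    cx <- runif(n_nuc, 1, size)
    cy <- runif(n_nuc, 1, size)
    rad <- pmax(0.8, rnorm(n_nuc, params$radius_mean, params$radius_sd))
    ints <- clamp(rnorm(n_nuc, params$intensity_mean, params$intensity_sd), 0, 1)
    for (b in seq_len(n_nuc)) {
      w <- ceiling(3 * rad[b])
      ri <- max(1, floor(cx[b] - w)):min(size, ceiling(cx[b] + w))
      ci <- max(1, floor(cy[b] - w)):min(size, ceiling(cy[b] + w))
      d2 <- outer((ri - cx[b])^2, (ci - cy[b])^2, "+")
      bump <- (params$background - ints[b]) * exp(-d2 / (2 * rad[b]^2))
      img[ri, ci] <- img[ri, ci] - bump
    }
  }
  clamp(img, 0, 1)
}

apply_impulse <- function(img, rate) {
  if (rate == 0) return(img)
  npx <- length(img)
  n_noise <- round(rate * npx)
  if (n_noise == 0) return(img)
  pos <- sample.int(npx, n_noise)
  val <- ifelse(runif(n_noise) < 0.5, 0, 255)
  img[pos] <- val
  img
}

#' Generate a two-class synthetic histology dataset
#'
#' Each image is a stroma texture plus Poisson-placed Gaussian "nuclei" drawn
#' from per-class parameters, compressed in contrast (to exercise contrast
#' enhancement) and corrupted with salt-and-pepper noise (to exercise the
#' median filter).  Fully deterministic for a given seed: image `i` draws from
#' its own substream, so regeneration from the manifest is byte-identical.
#'
#' @param n_benign,n_malignant Image counts (>= 1).
#' @param size Image side in pixels (default 64).
#' @param benign_params,malignant_params [class_texture_params()] objects;
#'   defaults are the `"easy"` preset.
#' @param impulse_rate Salt-and-pepper pixel fraction in `[0, 0.2]`.
#' @param contrast_scale Intensity-range compression factor in `(0, 1]`
#'   (1 = full contrast).
#' @param seed Integer root seed.
#' @return A `histo_dataset`: list with `images` (8-bit matrices), `labels`
#'   (tibble with `image_id`, `label`), and `manifest` (seed, params, counts).
#' @examples
#' ds <- generate_dataset(3, 5, size = 32, seed = 1)
#' dplyr::count(ds$labels, label)
#' @export
generate_dataset <- function(n_benign, n_malignant, size = 64,
                             benign_params = synthetic_presets("easy")$benign,
                             malignant_params = synthetic_presets("easy")$malignant,
                             impulse_rate = 0.05, contrast_scale = 0.6,
                             seed = 1) {
  if (n_benign < 1 || n_malignant < 1) {
    abort("Class counts must be >= 1.", class = "histodbn_parameter_error")
  }
  if (impulse_rate < 0 || impulse_rate > 0.2) {
    abort("`impulse_rate` must lie in [0, 0.2].", class = "histodbn_parameter_error")
  }
  if (contrast_scale <= 0 || contrast_scale > 1) {
    abort("`contrast_scale` must lie in (0, 1].", class = "histodbn_parameter_error")
  }
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    params <- if (labels[i] == "benign") benign_params else malignant_params
    images[[i]] <- with_substream(seed, paste0("image-", i), {
      img <- render_tissue(size, params)
      img <- 0.5 + (img - 0.5) * contrast_scale
      img <- round(clamp(img, 0, 1) * 255)
      apply_impulse(img, impulse_rate)
    })
  }
  lab_tbl <- tibble::tibble(
    image_id = sprintf("img%04d", seq_along(labels)),
    label = factor(labels, levels = c("benign", "malignant"))
  )
  structure(
    list(images = images, labels = lab_tbl,
         manifest = list(seed = seed, size = size,
                         n_benign = n_benign, n_malignant = n_malignant,
                         impulse_rate = impulse_rate,
                         contrast_scale = contrast_scale,
                         benign_params = unclass(benign_params),
                         malignant_params = unclass(malignant_params))),
    class = "histo_dataset"
  )
}

#' @export
print.histo_dataset <- function(x, ...) {
  cat("<histo_dataset> ", length(x$images), " images (",
      x$manifest$n_benign, " benign / ", x$manifest$n_malignant,
      " malignant), ", x$manifest$size, "x", x$manifest$size,
      ", seed ", x$manifest$seed, "\n", sep = "")
  invisible(x)
}

# class counts of the two-magnification histopathology benchmark emulated here
benchmark_counts <- function(magnification) {
  switch(magnification,
    "100x" = c(benign = 644L, malignant = 1437L),
    "200x" = c(benign = 623L, malignant = 1390L)
  )
}

#' Generate a BreakHis-like synthetic dataset
#'
#' Reproduces the class bookkeeping of the two-magnification histopathology
#' benchmark (100x: 644 benign / 1437 malignant; 200x: 623 benign / 1390
#' malignant, an approximately 1:2.2 imbalance), optionally scaled down for
#' desk-sized runs.  Counts are `round_half_up(scale * full count)`.
#'
#' @param magnification `"100x"` or `"200x"`.
#' @param scale Factor in `(0, 1]` applied to the full class counts.
#' @param seed Integer root seed.
#' @param difficulty Preset passed to [synthetic_presets()].
#' @param size Image side in pixels.
#' @param ... Passed on to [generate_dataset()] (e.g. `impulse_rate`).
#' @return A `histo_dataset` (see [generate_dataset()]).
#' @examples
#' ds <- make_breakhis_like("100x", scale = 0.02, seed = 1)
#' nrow(ds$labels)
#' @export
make_breakhis_like <- function(magnification = c("100x", "200x"), scale = 1,
                               seed = 1, difficulty = "easy", size = 64, ...) {
  magnification <- match.arg(magnification)
  if (scale <= 0 || scale > 1) {
    abort("`scale` must lie in (0, 1].", class = "histodbn_parameter_error")
  }
  counts <- benchmark_counts(magnification)
  n <- setNames(pmax(1, round_half_up(scale * counts)), names(counts))
  preset <- synthetic_presets(difficulty)
  ds <- generate_dataset(n[["benign"]], n[["malignant"]], size = size,
                         benign_params = preset$benign,
                         malignant_params = preset$malignant,
                         seed = seed, ...)
  ds$manifest$magnification <- magnification
  ds$manifest$scale <- scale
  ds$manifest$difficulty <- difficulty
  ds
}

#' Write / read a dataset as plain files
#'
#' Images are written as 8-bit grayscale PNG, labels as `labels.csv`
#' (`path,label`), and the manifest as `manifest.json`.
#'
#' @param dataset A `histo_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_labeled_images()`
#'   returns a list with `images` and `labels`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$labels$image_id, ".png"))
  purrr::walk2(dataset$images, paths, write_image)
  write.csv(
    data.frame(path = basename(paths), label = as.character(dataset$labels$label)),
    file.path(dir, "labels.csv"), row.names = FALSE
  )
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_labeled_images <- function(dir) {
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(lab))) {
    abort("labels.csv must have columns `path` and `label`.",
          class = "histodbn_parameter_error")
  }
  images <- purrr::map(file.path(dir, lab$path), read_image)
  list(images = images,
       labels = tibble::tibble(
         image_id = tools::file_path_sans_ext(basename(lab$path)),
         label = factor(lab$label, levels = c("benign", "malignant"))
       ))
}
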