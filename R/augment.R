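#' Augmentation configuration
#'
#' Parameter ranges for the six stochastic training-time augmenters:
#' Gaussian blur (kernel SD drawn from `gauss_sd_range` pixels), average blur
#' (mask size drawn from `avg_mask_range`), flips, additive Gaussian noise
#' (SD drawn as a fraction of the image SD), pixel dropout (replacing a drawn
#' fraction of pixels with the image mean) and contrast normalization
#' (scaling around the image median). Each enabled method fires independently
#' with probability `p_apply` per image; geometric methods (flips) transform
#' the boxes identically, photometric methods leave them untouched.
#'
#' @param gauss_sd_range Gaussian blur SD range in pixels.
#' @param avg_mask_range Average-blur mask size range (integers).
#' @param dropout_frac_range Fraction of pixels replaced by the image mean.
#' @param noise_sd_frac_range Additive-noise SD as a fraction of image SD.
#' @param contrast_scale_range Multiplicative contrast constant range.
#' @param p_apply Per-method application probability.
#' @param enabled Character vector naming the active methods.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(gauss_sd_range = c(0, 3),
                                avg_mask_range = c(2, 7),
                                dropout_frac_range = c(0.01, 0.10),
                                noise_sd_frac_range = c(0.01, 0.10),
                                contrast_scale_range = c(0.5, 2.0),
                                p_apply = 0.3,
                                enabled = c("gaussian_blur", "average_blur",
                                            "flip", "noise", "dropout",
                                            "contrast")) {
  chk <- function(r, nm) if (length(r) != 2 || r[1] > r[2] || r[1] < 0)
    stop_cfg("invalid range for ", nm)
  chk(gauss_sd_range, "gauss_sd_range"); chk(avg_mask_range, "avg_mask_range")
  chk(dropout_frac_range, "dropout_frac_range")
  chk(noise_sd_frac_range, "noise_sd_frac_range")
  chk(contrast_scale_range, "contrast_scale_range")
  structure(list(gauss_sd_range = gauss_sd_range,
                 avg_mask_range = as.integer(avg_mask_range),
                 dropout_frac_range = dropout_frac_range,
                 noise_sd_frac_range = noise_sd_frac_range,
                 contrast_scale_range = contrast_scale_range,
                 p_apply = p_apply, enabled = enabled),
            class = "augmentation_config")
}

#' Gaussian blur with reflective padding
#'
#' Separable convolution with a normalized Gaussian kernel of the given SD
#' (radius 3 SD). `sd = 0` returns the input unchanged. Reflective padding
#' keeps constant images constant and preserves the image mean.
#'
#' @param img Numeric matrix.
#' @param sd Kernel standard deviation in pixels.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  cpp_sepconv_reflect(img, k / sum(k))
}

#' Average (box) blur
#'
#' Replaces each pixel with the mean of its `mask x mask` neighborhood
#' (separable uniform kernel, reflective padding; even mask sizes are biased
#' half a pixel toward the low corner).
#'
#' @param img Numeric matrix.
#' @param mask Mask side length (>= 2).
#' @return Blurred matrix.
#' @export
average_blur <- function(img, mask) {
  mask <- as.integer(mask)
  if (mask < 2) return(img)
  cpp_sepconv_reflect(img, rep(1 / mask, mask))
}

#' Mirror an image and its boxes
#'
#' @param img Numeric matrix.
#' @param boxes A [boxes_df()] data frame in the image frame.
#' @param axis `"horizontal"` mirrors x (left-right), `"vertical"` mirrors y.
#' @return `list(img, boxes)` with box centers reflected
#'   (`cx -> (width - 1) - cx` for horizontal), sizes unchanged.
#' @export
flip_image <- function(img, boxes = boxes_df(),
                       axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    boxes$cx <- (ncol(img) - 1) - boxes$cx
  } else {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    boxes$cy <- (nrow(img) - 1) - boxes$cy
  }
  list(img = img, boxes = boxes)
}

#' Additive Gaussian noise
#'
#' @param img Numeric matrix.
#' @param sd Absolute noise SD; 0 returns the input unchanged.
#' @return Noisy matrix.
#' @export
add_noise <- function(img, sd) {
  if (sd <= 0) return(img)
  img + matrix(rnorm(length(img), 0, sd), nrow(img))
}

#' Pixel dropout
#'
#' Replaces exactly `round(frac * N)` distinct pixels with the (pre-dropout)
#' image mean.
#'
#' @param img Numeric matrix.
#' @param frac Fraction of pixels to replace.
#' @return Matrix with dropped pixels.
#' @export
pixel_dropout <- function(img, frac) {
  n <- round(frac * length(img))
  if (n <= 0) return(img)
  idx <- sample.int(length(img), n)
  img[idx] <- mean(img)
  img
}

#' Contrast normalization
#'
#' `pixel' = (pixel - median) * c + median`: the median pixel is a fixed
#' point and `c = 1` is the identity.
#'
#' @param img Numeric matrix.
#' @param c_scale Multiplicative contrast constant.
#' @return Rescaled matrix.
#' @export
contrast_normalize <- function(img, c_scale) {
  med <- median(img)
  (img - med) * c_scale + med
}

#' Randomly augment a training image and its boxes
#'
#' Applies a random subset of the enabled methods (each independently with
#' probability `p_apply`), drawing parameters from the configured ranges.
#' Fully reproducible given the R RNG state (seed before calling).
#'
#' @param img Numeric matrix.
#' @param boxes A [boxes_df()] data frame.
#' @param cfg An [augmentation_config()].
#' @return `list(img, boxes, applied)` where `applied` names the methods
#'   that fired.
#' @export
augment <- function(img, boxes = boxes_df(), cfg = augmentation_config()) {
  applied <- character()
  fire <- function(nm) nm %in% cfg$enabled && runif(1) < cfg$p_apply
  if (fire("gaussian_blur")) {
    img <- gaussian_blur(img, runif(1, cfg$gauss_sd_range[1],
                                    cfg$gauss_sd_range[2]))
    applied <- c(applied, "gaussian_blur")
  }
  if (fire("average_blur")) {
    img <- average_blur(img, sample(cfg$avg_mask_range[1]:
                                    cfg$avg_mask_range[2], 1))
    applied <- c(applied, "average_blur")
  }
  if (fire("flip")) {
    if (runif(1) < 0.5) {
      r <- flip_image(img, boxes, "horizontal")
      img <- r$img; boxes <- r$boxes
    }
    if (runif(1) < 0.5) {
      r <- flip_image(img, boxes, "vertical")
      img <- r$img; boxes <- r$boxes
    }
    applied <- c(applied, "flip")
  }
  if (fire("noise")) {
    img <- add_noise(img, sd(img) * runif(1, cfg$noise_sd_frac_range[1],
                                          cfg$noise_sd_frac_range[2]))
    applied <- c(applied, "noise")
  }
  if (fire("dropout")) {
    img <- pixel_dropout(img, runif(1, cfg$dropout_frac_range[1],
                                    cfg$dropout_frac_range[2]))
    applied <- c(applied, "dropout")
  }
  if (fire("contrast")) {
    img <- contrast_normalize(img, runif(1, cfg$contrast_scale_range[1],
                                         cfg$contrast_scale_range[2]))
    applied <- c(applied, "contrast")
  }
  list(img = img, boxes = boxes, applied = applied)
}
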