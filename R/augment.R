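# Training-time augmentation: flips, rotation, shifts, brightness, zoom
# and slight Gaussian blur. Geometric transforms run on a
# reflection-padded copy so no background is invented at the borders.

#' Augmentation configuration
#'
#' Ranges follow common histology practice: "slight" blur, moderate
#' rotations and shifts. Every draw is uniform within its range; with
#' `enabled = FALSE` the transform is the identity.
#'
#' @param horizontal_flip,vertical_flip Allow flips (each with
#'   probability 0.5).
#' @param rotation_max Max absolute rotation, degrees.
#' @param width_shift,height_shift Max absolute shift, fraction of side.
#' @param brightness_range Multiplier range, e.g. `c(0.8, 1.2)`.
#' @param zoom_range Max absolute zoom, fraction (0.1 = +/-10%).
#' @param blur_sigma_max Max Gaussian blur sigma, pixels.
#' @param enabled Master switch.
#' @return An object of class `msimf_augment`.
#' @export
augment_config <- function(horizontal_flip = TRUE, vertical_flip = TRUE,
                           rotation_max = 30, width_shift = 0.1,
                           height_shift = 0.1,
                           brightness_range = c(0.8, 1.2),
                           zoom_range = 0.1, blur_sigma_max = 1.0,
                           enabled = TRUE) {
  if (rotation_max < 0 || width_shift < 0 || height_shift < 0 ||
      zoom_range < 0 || blur_sigma_max < 0) {
    stop("augmentation ranges must be non-negative")
  }
  if (length(brightness_range) != 2L || any(brightness_range <= 0) ||
      brightness_range[1L] > brightness_range[2L]) {
    stop("brightness_range must be an increasing pair of positive multipliers")
  }
  structure(list(horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 rotation_max = rotation_max,
                 width_shift = width_shift, height_shift = height_shift,
                 brightness_range = brightness_range,
                 zoom_range = zoom_range,
                 blur_sigma_max = blur_sigma_max,
                 enabled = isTRUE(enabled)),
            class = "msimf_augment")
}

pad_reflect <- function(img, p) {
  d <- dim(img)
  ix <- c(rev(seq_len(min(p, d[1L]))), seq_len(d[1L]),
          d[1L] - seq_len(min(p, d[1L])) + 1L)
  iy <- c(rev(seq_len(min(p, d[2L]))), seq_len(d[2L]),
          d[2L] - seq_len(min(p, d[2L])) + 1L)
  img[ix, iy, , drop = FALSE]
}

crop_center <- function(img, w, h) {
  d <- dim(img)
  x0 <- (d[1L] - w) %/% 2L
  y0 <- (d[2L] - h) %/% 2L
  img[x0 + seq_len(w), y0 + seq_len(h), , drop = FALSE]
}

#' Apply one random augmentation draw to a patch
#'
#' Transforms (in order): horizontal/vertical flip, rotation, width and
#' height shift, zoom, brightness, Gaussian blur. All randomness comes
#' from the R RNG, so a fixed seed reproduces the augmented patch
#' exactly; the class label is untouched by construction.
#'
#' @param patch RGB array (any square size, typically the network input).
#' @param config An [augment_config()].
#' @param seed Optional seed applied before drawing.
#' @return Augmented patch, same dimensions, clipped to `[0, 1]`.
#' @export
augment_patch <- function(patch, config = augment_config(), seed = NULL) {
  stopifnot(inherits(config, "msimf_augment"))
  assert_rgb(patch)
  if (!config$enabled) return(patch)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(patch)
  out <- patch
  if (config$horizontal_flip && runif(1) < 0.5) {
    out <- out[rev(seq_len(d[1L])), , , drop = FALSE]
  }
  if (config$vertical_flip && runif(1) < 0.5) {
    out <- out[, rev(seq_len(d[2L])), , drop = FALSE]
  }
  angle <- runif(1, -config$rotation_max, config$rotation_max)
  dx <- round(runif(1, -config$width_shift, config$width_shift) * d[1L])
  dy <- round(runif(1, -config$height_shift, config$height_shift) * d[2L])
  zoom <- 1 + runif(1, -config$zoom_range, config$zoom_range)
  needs_geom <- abs(angle) > 1e-8 || dx != 0L || dy != 0L ||
    abs(zoom - 1) > 1e-8
  if (needs_geom) {
    pad <- ceiling(max(d[1:2]) * 0.45)
    big <- pad_reflect(out, pad)
    im <- EBImage::Image(big, colormode = "Color")
    if (abs(angle) > 1e-8) {
      im <- EBImage::rotate(im, angle, output.dim = dim(big)[1:2],
                            bg.col = "black")
    }
    if (dx != 0L || dy != 0L) im <- EBImage::translate(im, c(dx, dy))
    big <- EBImage::imageData(im)
    crop_w <- max(2L, round(d[1L] / zoom))
    crop_h <- max(2L, round(d[2L] / zoom))
    out <- crop_center(big, min(crop_w, dim(big)[1L]),
                       min(crop_h, dim(big)[2L]))
    out <- resize_bilinear(out, d[1L], d[2L])
  }
  m <- runif(1, config$brightness_range[1L], config$brightness_range[2L])
  out <- out * m
  sigma <- runif(1, 0, config$blur_sigma_max)
  if (sigma > 0.2) {
    out <- EBImage::imageData(
      EBImage::gblur(EBImage::Image(out, colormode = "Color"), sigma))
  }
  clip01(out)
}
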