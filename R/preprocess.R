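# Pre-processing: H&E stain normalization, the four-scale pyramid,
# quadrant patching and assembly of the 16-patch set per image. Images
# are numeric arrays of dim (width, height, 3) in [0, 1] (EBImage
# convention); resampling is bilinear throughout.

#' Read an image file as an RGB array
#'
#' @param path PNG/TIFF/JPEG file.
#' @return Array of dim (width, height, 3), values in `[0, 1]`. A fourth
#'   (alpha) channel, if present, is dropped.
#' @export
read_rgb <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(img)
  if (length(d) == 3L && d[3L] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else {
    img
  }
}

#' Write an RGB array as PNG
#'
#' @param img (width, height, 3) array in `[0, 1]`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  EBImage::writeImage(EBImage::Image(img, colormode = "Color"), path)
  invisible(path)
}

assert_rgb <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("expected an RGB image (width x height x 3), got dims ",
         paste(d, collapse = "x"))
  }
  invisible(d)
}

resize_bilinear <- function(img, w, h) {
  out <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                         w = w, h = h, filter = "bilinear")
  EBImage::imageData(out)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Ruderman decorrelated (l-alpha-beta style) color space used for the
# simple mean/variance stain matching.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- matrix(c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3),
                     1 / sqrt(6), 1 / sqrt(6), -2 / sqrt(6),
                     1 / sqrt(2), -1 / sqrt(2), 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

rgb_to_lab <- function(img) {
  d <- dim(img)
  px <- matrix(img, ncol = 3L)           # n x 3
  lms <- px %*% t(.rgb2lms)
  lms <- log10(pmax(lms, 1e-4))
  lab <- lms %*% t(.lms2lab)
  list(lab = lab, dim = d)
}

lab_to_rgb <- function(lab, d) {
  lms <- 10^(lab %*% t(.lab2lms))
  px <- lms %*% t(.lms2rgb)
  array(clip01(px), dim = d)
}

#' Stain statistics of an image
#'
#' For the `"reinhard"` method: per-channel mean and standard deviation
#' in the decorrelated log color space. For `"macenko"`: the two stain
#' (hematoxylin/eosin) optical-density vectors estimated from the
#' leading plane of the OD cloud plus robust (99th percentile) maximum
#' concentrations.
#'
#' @param img RGB array.
#' @param method `"reinhard"` (default) or `"macenko"`.
#' @return An object of class `msimf_stain_stats`.
#' @export
stain_stats <- function(img, method = c("reinhard", "macenko")) {
  method <- match.arg(method)
  assert_rgb(img)
  if (method == "reinhard") {
    lab <- rgb_to_lab(img)$lab
    out <- list(method = method,
                mean = colMeans(lab),
                sd = apply(lab, 2L, stats::sd))
  } else {
    od <- -log10(pmax(matrix(img, ncol = 3L), 1e-4))
    keep <- rowSums(od) > 0.15
    if (sum(keep) < 10L) keep <- rep(TRUE, nrow(od))
    odk <- od[keep, , drop = FALSE]
    v <- svd(odk, nu = 0L, nv = 2L)$v             # leading OD plane
    proj <- odk %*% v
    ang <- atan2(proj[, 2L], proj[, 1L])
    a1 <- stats::quantile(ang, 0.01)
    a2 <- stats::quantile(ang, 0.99)
    s1 <- v %*% c(cos(a1), sin(a1))
    s2 <- v %*% c(cos(a2), sin(a2))
    s1 <- s1 * sign(sum(s1)); s2 <- s2 * sign(sum(s2))
    stains <- cbind(s1 / sqrt(sum(s1^2)), s2 / sqrt(sum(s2^2)))
    # hematoxylin column first (more blue absorption)
    if (stains[3L, 1L] < stains[3L, 2L]) stains <- stains[, 2:1]
    conc <- t(qr.solve(stains, t(od)))
    out <- list(method = method, stains = stains,
                max_conc = apply(conc, 2L, stats::quantile, 0.99))
  }
  class(out) <- "msimf_stain_stats"
  out
}

#' Default H&E stain reference
#'
#' A fixed reference for routine use so normalization does not depend on
#' any particular slide; values describe a typical well-stained H&E field
#' (synthetic reference, not derived from any dataset).
#'
#' @param method `"reinhard"` or `"macenko"`.
#' @return An `msimf_stain_stats`.
#' @export
default_stain_reference <- function(method = c("reinhard", "macenko")) {
  method <- match.arg(method)
  if (method == "reinhard") {
    out <- list(method = method,
                mean = c(-0.20, -0.03, 0.015),
                sd = c(0.14, 0.035, 0.02))
  } else {
    stains <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
    stains <- sweep(stains, 2L, sqrt(colSums(stains^2)), "/")
    out <- list(method = method, stains = stains,
                max_conc = c(1.0, 0.8))
  }
  class(out) <- "msimf_stain_stats"
  out
}

#' Stain-normalize an RGB image
#'
#' Matches the image's stain appearance to a reference. The default
#' method matches per-channel mean and variance in a decorrelated log
#' color space; the `"macenko"` method factorizes optical densities into
#' two stain vectors and rescales concentrations to the reference.
#'
#' @param img RGB array in `[0, 1]`.
#' @param reference An `msimf_stain_stats`; defaults to the built-in
#'   reference matching `method`.
#' @param method Used when `reference` is NULL.
#' @return Normalized RGB array, clipped to `[0, 1]`.
#' @export
normalize_stain <- function(img, reference = NULL,
                            method = c("reinhard", "macenko")) {
  method <- match.arg(method)
  assert_rgb(img)
  if (all(img == 0)) {
    warning("all-zero image; returned unchanged")
    return(img)
  }
  if (is.null(reference)) reference <- default_stain_reference(method)
  stopifnot(inherits(reference, "msimf_stain_stats"))
  method <- reference$method
  if (method == "reinhard") {
    lt <- rgb_to_lab(img)
    mu <- colMeans(lt$lab)
    sd_ <- apply(lt$lab, 2L, stats::sd)
    scale <- ifelse(sd_ > 1e-8, reference$sd / sd_, 1)
    lab <- sweep(lt$lab, 2L, mu)
    lab <- sweep(lab, 2L, scale, "*")
    lab <- sweep(lab, 2L, reference$mean, "+")
    lab_to_rgb(lab, lt$dim)
  } else {
    own <- stain_stats(img, "macenko")
    od <- -log10(pmax(matrix(img, ncol = 3L), 1e-4))
    conc <- t(qr.solve(own$stains, t(od)))
    conc <- sweep(conc, 2L,
                  reference$max_conc / pmax(own$max_conc, 1e-8), "*")
    od_new <- conc %*% t(reference$stains)
    array(clip01(10^(-od_new)), dim = dim(img))
  }
}

#' Build the four-scale pyramid
#'
#' Rescales the image to each ratio (defaults 1, 0.5, 0.33, 0.25) with
#' bilinear resampling; level sides are `round(ratio * side)` and the
#' ratio-1 level is a bit-identical copy.
#'
#' @param img RGB array.
#' @param ratios Ordered, strictly decreasing scale ratios.
#' @return An object of class `msimf_pyramid`: list with `ratios` and
#'   `images`.
#' @export
build_pyramid <- function(img, ratios = c(1, 0.5, 0.33, 0.25)) {
  d <- assert_rgb(img)
  stopifnot(length(ratios) >= 1L, all(diff(ratios) < 0))
  min_side <- min(d[1:2])
  bad <- ratios[round(min_side * ratios) < 8]
  if (length(bad) > 0L) {
    stop("image too small (min side ", min_side,
         ") for ratio ", bad[1L], ": level side would be below 8 px")
  }
  images <- lapply(ratios, function(r) {
    if (r == 1) img else resize_bilinear(img, round(d[1L] * r),
                                         round(d[2L] * r))
  })
  structure(list(ratios = ratios, images = images),
            class = "msimf_pyramid")
}

#' Cut an image into its four quadrants
#'
#' 2x2 grid of `floor(side/2)` quadrants in row-major order (top-left,
#' top-right, bottom-left, bottom-right); an odd trailing row/column is
#' dropped.
#'
#' @param img RGB array with both sides >= 2 px.
#' @return List of 4 arrays named TL, TR, BL, BR.
#' @export
quadrant_patches <- function(img) {
  d <- assert_rgb(img)
  if (d[1L] < 2L || d[2L] < 2L) stop("image sides must be at least 2 px")
  hw <- d[1L] %/% 2L
  hh <- d[2L] %/% 2L
  list(TL = img[1:hw, 1:hh, , drop = FALSE],
       TR = img[(hw + 1L):(2L * hw), 1:hh, , drop = FALSE],
       BL = img[1:hw, (hh + 1L):(2L * hh), , drop = FALSE],
       BR = img[(hw + 1L):(2L * hw), (hh + 1L):(2L * hh), , drop = FALSE])
}

#' Build the 16-patch set of one image
#'
#' Normalize (optional) -> pyramid -> quadrants per level -> resize every
#' quadrant to `out_size`. Yields 4 scales x 4 quadrants = 16 patches,
#' each carrying its (scale, quadrant) provenance and the source image's
#' label.
#'
#' @param img RGB array.
#' @param ratios Scale ratios (see [build_pyramid()]).
#' @param out_size Patch side after resizing (network input size).
#' @param normalize Apply [normalize_stain()] first.
#' @param reference Stain reference forwarded to [normalize_stain()].
#' @param label Class label inherited by every patch.
#' @return Object of class `msimf_patchset`: `patches` array
#'   `[out_size, out_size, 3, 16]`, `provenance` data.frame
#'   (scale index, scale_ratio, quadrant index, quadrant name), `label`.
#' @export
build_patchset <- function(img, ratios = c(1, 0.5, 0.33, 0.25),
                           out_size = 224L, normalize = TRUE,
                           reference = NULL, label = NA_character_) {
  assert_rgb(img)
  if (normalize) img <- normalize_stain(img, reference)
  pyr <- build_pyramid(img, ratios)
  n_lev <- length(pyr$images)
  patches <- array(NA_real_, c(out_size, out_size, 3L, 4L * n_lev))
  prov <- data.frame(scale = integer(0), scale_ratio = numeric(0),
                     quadrant = integer(0), quadrant_name = character(0))
  idx <- 0L
  for (s in seq_len(n_lev)) {
    quads <- quadrant_patches(pyr$images[[s]])
    for (q in seq_along(quads)) {
      idx <- idx + 1L
      patches[, , , idx] <- resize_bilinear(quads[[q]], out_size, out_size)
      prov <- rbind(prov, data.frame(
        scale = s, scale_ratio = pyr$ratios[s], quadrant = q,
        quadrant_name = names(quads)[q]))
    }
  }
  structure(list(patches = patches, provenance = prov, label = label),
            class = "msimf_patchset")
}

#' Extract and write patches for a set of slide records
#'
#' Runs [build_patchset()] for every record and writes each patch as a
#' PNG named `<image id>_s<scale>_q<quadrant>.png`, plus a patch manifest
#' CSV (columns `source`, `image_id`, `scale`, `scale_ratio`, `quadrant`,
#' `label`, `binary_label`, `patient_id`, `path`).
#'
#' @param records Slide records from [scan_dataset()].
#' @param out_dir Output directory (created if missing).
#' @param ratios,out_size,normalize,reference Forwarded to
#'   [build_patchset()].
#' @param binary Use the binary label instead of the subtype label.
#' @return The patch manifest data.frame, invisibly written to
#'   `file.path(out_dir, "patches.csv")`.
#' @export
prepare_patches <- function(records, out_dir,
                            ratios = c(1, 0.5, 0.33, 0.25),
                            out_size = 224L, normalize = TRUE,
                            reference = NULL, binary = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    img <- read_rgb(records$path[i])
    lab <- if (binary) records$binary_label[i] else records$label[i]
    ps <- build_patchset(img, ratios, out_size, normalize, reference,
                         label = lab)
    image_id <- tools::file_path_sans_ext(basename(records$path[i]))
    paths <- character(nrow(ps$provenance))
    for (j in seq_len(nrow(ps$provenance))) {
      paths[j] <- file.path(out_dir, sprintf(
        "%s_s%d_q%d.png", image_id, ps$provenance$scale[j],
        ps$provenance$quadrant[j]))
      write_rgb(ps$patches[, , , j], paths[j])
    }
    rows[[i]] <- data.frame(
      source = records$path[i], image_id = image_id,
      scale = ps$provenance$scale,
      scale_ratio = ps$provenance$scale_ratio,
      quadrant = ps$provenance$quadrant, label = lab,
      binary_label = records$binary_label[i],
      patient_id = records$patient_id[i], path = paths,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "patches.csv"), row.names = FALSE)
  manifest
}
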