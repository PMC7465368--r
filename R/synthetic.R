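# Seeded synthetic histology generator. Class textures are
# Poisson-scattered Gaussian "nuclei" blobs on an H&E-like tinted
# background; adjacent classes differ in blob rate by a factor of two,
# which keeps mean blob counts >= 3 sigma apart, and in background tint.
# Per-image multiplicative stain jitter exercises stain normalization.

#' Specification of a synthetic toy dataset
#'
#' Defaults describe the standard desk-scale study conditions: two
#' classes (one benign, one malignant), three patients per class, four
#' images per patient at a single 40x magnification, 256x256 px images.
#' Blob rates double between adjacent classes so mean counts stay at
#' least 3 standard deviations apart.
#'
#' @param n_classes Number of classes (up to 8 for the breakhis layout).
#' @param n_patients_per_class Patients per class.
#' @param images_per_patient Images per patient (per magnification).
#' @param image_size `c(width, height)` in pixels.
#' @param classes Class names; defaults to the first `n_classes` of the
#'   BreakHis vocabulary ordered benign-first (`A`, `DC`, `F`, `LC`, ...)
#'   for the breakhis/synthetic layouts, or the ICIAR vocabulary.
#' @param blob_rate Expected blob count per image, one per class.
#' @param tints Per-class background RGB tint (3 x n_classes matrix).
#' @param jitter Half-width of the per-image multiplicative stain jitter.
#' @param layout `"breakhis"`, `"iciar"` or `"synthetic"`.
#' @param magnifications Magnification folders to emulate.
#' @param seed RNG seed; generation is fully reproducible.
#' @return An object of class `msimf_synth_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L, n_patients_per_class = 3L,
                           images_per_patient = 4L,
                           image_size = c(256L, 256L), classes = NULL,
                           blob_rate = NULL, tints = NULL, jitter = 0.05,
                           layout = c("breakhis", "iciar", "synthetic"),
                           magnifications = 40L, seed = 1L) {
  layout <- match.arg(layout)
  if (is.null(classes)) {
    pool <- if (layout == "iciar") {
      c("Benign", "Invasive", "Normal", "InSitu")
    } else {
      c("A", "DC", "F", "LC", "TA", "MC", "PT", "PC")
    }
    stopifnot(n_classes <= length(pool))
    classes <- pool[seq_len(n_classes)]
  }
  n_classes <- length(classes)
  if (is.null(blob_rate)) blob_rate <- 40 * 2^(seq_len(n_classes) - 1L)
  stopifnot(length(blob_rate) == n_classes)
  if (is.null(tints)) {
    # interpolate from eosin pink to hematoxylin-leaning purple
    f <- if (n_classes == 1L) 0 else (seq_len(n_classes) - 1L) / (n_classes - 1L)
    tints <- rbind(0.93 - 0.13 * f, 0.78 - 0.08 * f, 0.86 + 0.06 * f)
  }
  stopifnot(ncol(tints) == n_classes)
  structure(list(classes = classes, n_classes = n_classes,
                 n_patients_per_class = n_patients_per_class,
                 images_per_patient = images_per_patient,
                 image_size = as.integer(image_size),
                 blob_rate = blob_rate, tints = tints, jitter = jitter,
                 layout = layout,
                 magnifications = as.integer(magnifications),
                 seed = as.integer(seed)),
            class = "msimf_synth_spec")
}

# one synthetic field: tinted background + Poisson-scattered dark blobs
render_synthetic_image <- function(w, h, rate, tint, jitter) {
  n_blobs <- rpois(1L, rate)
  field <- matrix(0, w, h)
  if (n_blobs > 0L) {
    cx <- runif(n_blobs, 1, w)
    cy <- runif(n_blobs, 1, h)
    rad <- runif(n_blobs, 2.5, 5)
    for (b in seq_len(n_blobs)) {
      r <- rad[b]
      x0 <- max(1L, floor(cx[b] - 3 * r)); x1 <- min(w, ceiling(cx[b] + 3 * r))
      y0 <- max(1L, floor(cy[b] - 3 * r)); y1 <- min(h, ceiling(cy[b] + 3 * r))
      xs <- x0:x1; ys <- y0:y1
      g <- exp(-(outer((xs - cx[b])^2, (ys - cy[b])^2, "+")) / (2 * r^2))
      field[xs, ys] <- field[xs, ys] + g
    }
  }
  alpha <- pmin(field, 1)
  blob_col <- c(0.36, 0.22, 0.55)          # hematoxylin-like nucleus color
  jit <- runif(3L, 1 - jitter, 1 + jitter)
  img <- array(0, c(w, h, 3L))
  for (ch in 1:3) {
    img[, , ch] <- (tint[ch] * (1 - alpha) + blob_col[ch] * alpha) * jit[ch]
  }
  img <- img + array(rnorm(w * h * 3L, sd = 0.015), c(w, h, 3L))
  list(img = clip01(img), n_blobs = n_blobs)
}

#' Generate a synthetic dataset on disk
#'
#' Writes a seeded toy histology dataset in one of the supported
#' directory layouts so [scan_dataset()] parses it unchanged, plus a
#' ground-truth manifest (`manifest.csv`) listing every file with class,
#' patient and rendered blob count.
#'
#' @param spec An [synthetic_spec()].
#' @param dir Target directory.
#' @param force Overwrite a non-empty target directory.
#' @return The manifest data.frame, invisibly; also written as CSV.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir,
                             force = FALSE) {
  stopifnot(inherits(spec, "msimf_synth_spec"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("target directory is not empty (use force = TRUE): ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  w <- spec$image_size[1L]; h <- spec$image_size[2L]
  rows <- list()
  for (k in seq_along(spec$classes)) {
    cls <- spec$classes[k]
    benign <- if (spec$layout == "iciar") {
      cls %in% c("Benign", "Normal")
    } else {
      cls %in% c("A", "F", "TA", "PT") ||
        (!cls %in% dataset_classes("breakhis") && k <= spec$n_classes / 2)
    }
    for (pt in seq_len(spec$n_patients_per_class)) {
      patient_id <- sprintf("%02d-%03d", k, pt)
      for (mag in spec$magnifications) {
        for (i in seq_len(spec$images_per_patient)) {
          rel <- synth_rel_path(spec, cls, benign, patient_id, mag, i)
          path <- file.path(dir, rel)
          dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
          ri <- render_synthetic_image(w, h, spec$blob_rate[k],
                                       spec$tints[, k], spec$jitter)
          write_rgb(ri$img, path)
          rows[[length(rows) + 1L]] <- data.frame(
            path = path, dataset = spec$layout, label = cls,
            binary_label = if (spec$layout == "iciar") {
              if (benign) "non-carcinoma" else "carcinoma"
            } else {
              if (benign) "benign" else "malignant"
            },
            patient_id = if (spec$layout == "iciar") NA_character_ else patient_id,
            magnification = if (spec$layout == "iciar") NA_integer_ else mag,
            n_blobs = ri$n_blobs, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

synth_rel_path <- function(spec, cls, benign, patient_id, mag, i) {
  if (spec$layout == "breakhis") {
    bm <- if (benign) "B" else "M"
    top <- if (benign) "benign" else "malignant"
    file.path(top, "SOB", cls,
              sprintf("SOB_%s_%s_%s", bm, cls, patient_id),
              sprintf("%dX", mag),
              sprintf("SOB_%s_%s-%s-%d-%03d.png", bm, cls, patient_id,
                      mag, i))
  } else if (spec$layout == "iciar") {
    file.path(cls, sprintf("%s_p%s_%03d.png", tolower(cls),
                           gsub("-", "", patient_id), i))
  } else {
    top <- if (benign) "benign" else "malignant"
    file.path(top, cls, patient_id, sprintf("%dX", mag),
              sprintf("%s_%s_%d_%03d.png", cls, patient_id, mag, i))
  }
}

#' Materialize a directory tree matching printed dataset structure counts
#'
#' Creates a BreakHis-shaped placeholder tree (tiny identical PNGs, valid
#' filenames) whose per-class / per-magnification file counts follow a
#' structure table, e.g. the published per-magnification totals shipped
#' in `inst/extdata/breakhis_structure.csv`. Patients are assigned by
#' spreading each subtype's images as evenly as possible over its
#' published patient count. Useful for exercising the reader and split
#' logic at full dataset scale without any image content.
#'
#' @param counts Data.frame with columns `label`, `magnification`,
#'   `n_images` and `n_patients` (patients per label).
#' @param dir Target directory.
#' @return The number of files written, invisibly.
#' @export
generate_layout_shell <- function(counts, dir) {
  stopifnot(all(c("label", "magnification", "n_images", "n_patients")
                %in% names(counts)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stub <- file.path(tempdir(), "msimf_stub.png")
  if (!file.exists(stub)) write_rgb(array(0.5, c(4L, 4L, 3L)), stub)
  fake_spec <- structure(list(layout = "breakhis"),
                         class = "msimf_synth_spec")
  total <- 0L
  for (r in seq_len(nrow(counts))) {
    lab <- counts$label[r]
    benign <- lab %in% c("A", "F", "TA", "PT")
    mag <- counts$magnification[r]
    n <- counts$n_images[r]
    n_pat <- counts$n_patients[r]
    pat_of <- rep(seq_len(n_pat), length.out = n)
    seq_in_pat <- stats::ave(pat_of, pat_of, FUN = seq_along)
    for (i in seq_len(n)) {
      patient_id <- sprintf("%02d-%03d",
                            match(lab, dataset_classes("breakhis")),
                            pat_of[i])
      rel <- synth_rel_path(fake_spec, lab, benign, patient_id, mag,
                            seq_in_pat[i])
      path <- file.path(dir, rel)
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      file.copy(stub, path)
      total <- total + 1L
    }
  }
  invisible(total)
}

#' Simple first-order features of a synthetic image
#'
#' Mean intensity and a blob count estimate (connected dark components),
#' the two statistics that make the synthetic classes linearly
#' separable. Used to verify that a depth-1 classifier already solves
#' the toy task, so pipeline-level accuracy checks are about the
#' pipeline rather than the data.
#'
#' @param img RGB array.
#' @return Named numeric vector `mean_intensity`, `blob_count`.
#' @export
synthetic_features <- function(img) {
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  dark <- EBImage::Image(gray < (mean(gray) - 1.5 * stats::sd(gray)))
  labels <- EBImage::bwlabel(dark)
  c(mean_intensity = mean(gray), blob_count = max(labels))
}
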