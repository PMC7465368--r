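# Dataset readers: BreakHis-style trees (class/patient/magnification
# encoded in SOB_* filenames), ICIAR2018-style per-class folders, and the
# synthetic layout written by generate_dataset(). Records are plain
# data.frames; splitting is patient-disjoint whenever patient ids exist.

IMG_EXT_RE <- "\\.(png|jpe?g|tiff?)$"

#' Class vocabularies and malignancy priority orders
#'
#' BreakHis distinguishes four benign subtypes (adenosis A, fibroadenoma
#' F, tubular adenoma TA, phyllodes tumor PT) and four carcinomas (ductal
#' DC, lobular LC, mucinous MC, papillary PC). ICIAR2018 has Benign,
#' Normal (non-carcinoma) and InSitu, Invasive (carcinoma). The priority
#' orders list the most malignant class first and are used to break ties
#' in patch-vote fusion.
#'
#' @param dataset `"breakhis"` or `"iciar"`.
#' @return `dataset_classes`: character vector of class names;
#'   `malignancy_priority`: the tie-break ordering.
#' @export
dataset_classes <- function(dataset = c("breakhis", "iciar")) {
  switch(match.arg(dataset),
         breakhis = c("A", "F", "TA", "PT", "DC", "LC", "MC", "PC"),
         iciar = c("Benign", "Normal", "InSitu", "Invasive"))
}

#' @rdname dataset_classes
#' @export
malignancy_priority <- function(dataset = c("breakhis", "iciar")) {
  switch(match.arg(dataset),
         breakhis = c("DC", "LC", "MC", "PC", "A", "F", "TA", "PT"),
         iciar = c("Invasive", "InSitu", "Benign", "Normal"))
}

binary_label_for <- function(label, dataset) {
  if (dataset == "iciar") {
    ifelse(label %in% c("InSitu", "Invasive"), "carcinoma", "non-carcinoma")
  } else {
    ifelse(label %in% c("DC", "LC", "MC", "PC"), "malignant", "benign")
  }
}

# Canonical BreakHis filename: SOB_<B|M>_<subtype>-<patient>-<mag>-<seq>.<ext>
# e.g. SOB_B_A-14-22549AB-40-001.png (the patient id itself may contain
# dashes; magnification and sequence are the last two dash fields).
parse_breakhis_name <- function(fname) {
  m <- regmatches(fname, regexec(
    "^SOB_([BM])_([A-Za-z]+)-(.+)-(40|100|200|400)-([0-9]+)\\.[A-Za-z]+$",
    fname))[[1]]
  if (length(m) == 0L) return(NULL)
  label <- toupper(m[3])
  if (!label %in% dataset_classes("breakhis")) return(NULL)
  list(label = label, patient_id = m[4], magnification = as.integer(m[5]))
}

normalize_iciar_class <- function(x) {
  key <- tolower(gsub("[ _-]", "", x))
  map <- c(benign = "Benign", b = "Benign",
           normal = "Normal", n = "Normal",
           insitu = "InSitu", insitucarcinoma = "InSitu", is = "InSitu",
           invasive = "Invasive", invasivecarcinoma = "Invasive",
           iv = "Invasive")
  unname(map[key])
}

#' Scan an image directory tree into slide records
#'
#' Walks `root` recursively, parses class, patient and magnification from
#' paths/filenames according to `layout`, and returns one record per
#' image in deterministic (lexicographic) order. Files that do not match
#' the layout's naming grammar are skipped with a warning; their paths
#' are kept in the `"skipped"` attribute.
#'
#' Layouts: `"breakhis"` parses `SOB_<B|M>_<subtype>-<patient>-<mag>-<seq>`
#' filenames; `"iciar"` takes the class from the parent folder name
#' (an optional top-level `train`/`test` level is recorded in the
#' `presplit` column); `"synthetic"` reads the
#' `<benign|malignant>/<class>/<patient>/<mag>X/` tree written by
#' [generate_dataset()].
#'
#' @param root Directory containing the images.
#' @param layout One of `"breakhis"`, `"iciar"`, `"synthetic"`.
#' @param read_dims Also open each file to record width/height (slow).
#' @return A data.frame with columns `path`, `dataset`, `label`,
#'   `binary_label`, `patient_id`, `magnification`, `width`, `height`,
#'   `presplit`.
#' @export
scan_dataset <- function(root, layout = c("breakhis", "iciar", "synthetic"),
                         read_dims = FALSE) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("root directory does not exist: ", root)
  files <- list.files(root, pattern = IMG_EXT_RE, recursive = TRUE,
                      full.names = FALSE, ignore.case = TRUE)
  files <- sort(files, method = "radix")
  if (length(files) == 0L) stop("no images found in ", root)

  parse_one <- function(rel) {
    parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
    fname <- parts[length(parts)]
    if (layout == "breakhis") {
      p <- parse_breakhis_name(fname)
      if (is.null(p)) return(NULL)
      c(p, list(presplit = NA_character_))
    } else if (layout == "iciar") {
      presplit <- NA_character_
      cls_dir <- if (length(parts) >= 2L) parts[length(parts) - 1L] else NA
      if (length(parts) >= 3L &&
          tolower(parts[1]) %in% c("train", "training", "test", "testing")) {
        presplit <- ifelse(tolower(parts[1]) %in% c("train", "training"),
                           "train", "test")
      }
      label <- normalize_iciar_class(cls_dir)
      if (is.na(cls_dir) || is.na(label)) return(NULL)
      list(label = label, patient_id = NA_character_,
           magnification = NA_integer_, presplit = presplit)
    } else {
      # synthetic: <benign|malignant>/<class>/<patient>/<mag>X/<file>
      if (length(parts) < 5L) return(NULL)
      n <- length(parts)
      mag <- suppressWarnings(as.integer(sub("[Xx]$", "", parts[n - 1L])))
      if (is.na(mag)) return(NULL)
      list(label = parts[n - 3L], patient_id = parts[n - 2L],
           magnification = mag, presplit = NA_character_)
    }
  }

  parsed <- lapply(files, parse_one)
  ok <- !vapply(parsed, is.null, logical(1L))
  if (any(!ok)) {
    warning(sum(!ok), " file(s) did not match the ", layout,
            " naming grammar and were skipped")
  }
  if (!any(ok)) stop("no images found in ", root)
  skipped <- files[!ok]
  files <- files[ok]
  parsed <- parsed[ok]
  dataset <- if (layout == "synthetic") "synthetic" else layout
  label <- vapply(parsed, function(p) as.character(p$label), "")
  rec <- data.frame(
    path = file.path(root, files),
    dataset = dataset,
    label = label,
    binary_label = if (layout == "synthetic") {
      ifelse(grepl("^malignant/", files), "malignant", "benign")
    } else {
      binary_label_for(label, layout)
    },
    patient_id = vapply(parsed, function(p) as.character(p$patient_id), ""),
    magnification = vapply(parsed,
                           function(p) as.integer(p$magnification),
                           integer(1L)),
    presplit = vapply(parsed, function(p) as.character(p$presplit), ""),
    width = NA_integer_, height = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (read_dims) {
    for (i in seq_len(nrow(rec))) {
      d <- dim(read_rgb(rec$path[i]))
      rec$width[i] <- d[1L]
      rec$height[i] <- d[2L]
    }
  }
  attr(rec, "skipped") <- file.path(root, skipped)
  rownames(rec) <- NULL
  rec
}

#' Patient-disjoint train/test split
#'
#' Patients are shuffled with a seeded RNG and assigned greedily to the
#' training set until the training image fraction reaches `ratio`; all
#' images of a patient land on the same side, so the split may overshoot
#' the target fraction by at most one patient's images. When no patient
#' ids exist (e.g. ICIAR), images are split individually by the same
#' greedy rule.
#'
#' @param records Slide records from [scan_dataset()].
#' @param ratio Target training fraction (0 < ratio < 1; 0.7 is the
#'   conventional 70:30 split).
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return An object of class `msimf_split`: list with `train` and
#'   `test` (record paths), `seed`, `ratio`.
#' @export
patient_split <- function(records, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  has_pat <- !all(is.na(records$patient_id) | records$patient_id == "NA")
  group <- if (has_pat) records$patient_id else records$path
  groups <- unique(group)
  if (length(groups) < 2L) {
    stop("need at least 2 ", if (has_pat) "patients" else "images",
         " to split")
  }
  n_img <- nrow(records)
  sizes <- table(group)
  ord <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(groups)
  })
  cum <- cumsum(as.numeric(sizes[ord]))
  n_train_groups <- which(cum / n_img >= ratio)[1L]
  if (is.na(n_train_groups)) n_train_groups <- length(ord)
  n_train_groups <- min(n_train_groups, length(ord) - 1L)
  train_groups <- ord[seq_len(n_train_groups)]
  in_train <- group %in% train_groups
  out <- list(train = records$path[in_train],
              test = records$path[!in_train],
              seed = seed, ratio = ratio)
  class(out) <- "msimf_split"
  out
}

#' Split from pre-assigned train/test folders
#'
#' Uses the `presplit` column recorded by [scan_dataset()] when the tree
#' already ships a train/test folder pair (the conventional 400/92
#' ICIAR division).
#'
#' @param records Slide records with a filled `presplit` column.
#' @return An `msimf_split`.
#' @export
presplit_assignment <- function(records) {
  if (all(is.na(records$presplit) | records$presplit == "NA")) {
    stop("records carry no pre-assigned train/test folders")
  }
  out <- list(train = records$path[records$presplit %in% "train"],
              test = records$path[records$presplit %in% "test"],
              seed = NA_integer_, ratio = NA_real_)
  class(out) <- "msimf_split"
  out
}

#' @export
print.msimf_split <- function(x, ...) {
  cat("msimf_split:", length(x$train), "train /", length(x$test),
      "test images (ratio", x$ratio, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Write a slide manifest as CSV
#'
#' @param records Slide records.
#' @param path Output CSV path.
#' @param split Optional `msimf_split`; adds a `split` column.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path, split = NULL) {
  out <- records[, c("path", "dataset", "label", "binary_label",
                     "patient_id", "magnification")]
  if (!is.null(split)) {
    out$split <- ifelse(records$path %in% split$train, "train",
                        ifelse(records$path %in% split$test, "test", NA))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
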