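# Dataset scanning, filename grammar and patient-disjoint splitting.

test_that("scanning the synthetic fixture recovers the generator manifest", {
  fx <- fixture_dataset()
  rec <- fx$records
  expect_equal(nrow(rec), 24L)                       # 2 x 3 x 4
  expect_equal(length(unique(rec$patient_id)), 6L)
  expect_setequal(unique(rec$label), c("A", "DC"))
  # exact round-trip against the generator's ground truth
  man <- fx$manifest[order(man_path <- fx$manifest$path), ]
  rec2 <- rec[order(rec$path), ]
  expect_equal(rec2$path, man$path)
  expect_equal(rec2$label, man$label)
  expect_equal(rec2$patient_id, man$patient_id)
  expect_equal(rec2$binary_label, man$binary_label)
  expect_equal(rec2$magnification, man$magnification)
  # deterministic lexicographic ordering
  expect_equal(rec$path, sort(rec$path, method = "radix"))
})

test_that("empty or unparseable trees are reported", {
  empty <- file.path(tempdir(), "msimf_empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(scan_dataset(empty, "breakhis"), "no images found")
  messy <- file.path(tempdir(), "msimf_messy")
  dir.create(messy, showWarnings = FALSE)
  write_rgb(array(0.5, c(4, 4, 3)),
            file.path(messy, "SOB_B_A-99-001-40-001.png"))
  write_rgb(array(0.5, c(4, 4, 3)), file.path(messy, "not_a_slide.png"))
  expect_warning(rec <- scan_dataset(messy, "breakhis"), "skipped")
  expect_equal(nrow(rec), 1L)
  expect_equal(basename(attr(rec, "skipped")), "not_a_slide.png")
})

test_that("canonical filename grammar fills label, patient and
           magnification", {
  d <- file.path(tempdir(), "msimf_names")
  dir.create(d, showWarnings = FALSE)
  f <- "SOB_M_DC-14-22549AB-100-032.png"
  write_rgb(array(0.2, c(4, 4, 3)), file.path(d, f))
  rec <- scan_dataset(d, "breakhis")
  expect_equal(rec$label, "DC")
  expect_equal(rec$binary_label, "malignant")
  expect_equal(rec$patient_id, "14-22549AB")   # dashes inside the id
  expect_equal(rec$magnification, 100L)
})

test_that("iciar layout maps folders to classes and honors presplits", {
  d <- file.path(tempdir(), "msimf_iciar")
  for (split in c("train", "test")) {
    for (cls in c("Benign", "Normal", "InSitu", "Invasive")) {
      dd <- file.path(d, split, cls)
      dir.create(dd, recursive = TRUE, showWarnings = FALSE)
      write_rgb(array(0.5, c(4, 4, 3)), file.path(dd, "img001.png"))
    }
  }
  rec <- scan_dataset(d, "iciar")
  expect_equal(nrow(rec), 8L)
  expect_setequal(rec$label, c("Benign", "Normal", "InSitu", "Invasive"))
  expect_equal(sort(unique(rec$binary_label)),
               c("carcinoma", "non-carcinoma"))
  expect_equal(rec$binary_label[rec$label == "Normal"][1], "non-carcinoma")
  expect_equal(rec$binary_label[rec$label == "InSitu"][1], "carcinoma")
  expect_true(all(is.na(rec$patient_id) | rec$patient_id == "NA"))
  sp <- presplit_assignment(rec)
  expect_equal(length(sp$train), 4L)
  expect_equal(length(sp$test), 4L)
})

test_that("patient split is disjoint by patient for many seeds", {
  fx <- fixture_dataset()
  rec <- fx$records
  for (seed in 1:100) {
    sp <- patient_split(rec, 0.7, seed)
    pt_train <- unique(rec$patient_id[rec$path %in% sp$train])
    pt_test <- unique(rec$patient_id[rec$path %in% sp$test])
    expect_length(intersect(pt_train, pt_test), 0L)
    expect_setequal(c(sp$train, sp$test), rec$path)
    expect_gt(length(sp$test), 0L)
  }
})

test_that("greedy fill hits the target exactly on single-image patients", {
  rec <- data.frame(path = sprintf("img%03d.png", 1:100),
                    patient_id = sprintf("p%03d", 1:100),
                    stringsAsFactors = FALSE)
  for (seed in c(1, 7, 99)) {
    sp <- patient_split(rec, 0.7, seed)
    expect_length(sp$train, 70L)
  }
})

test_that("splits are reproducible and refuse degenerate inputs", {
  fx <- fixture_dataset()
  s1 <- patient_split(fx$records, 0.7, 42)
  s2 <- patient_split(fx$records, 0.7, 42)
  expect_identical(s1, s2)
  one <- fx$records[fx$records$patient_id == fx$records$patient_id[1], ]
  expect_error(patient_split(one, 0.7, 1), "at least 2")
})

test_that("manifest CSV round-trips records with split labels", {
  fx <- fixture_dataset()
  path <- tempfile(fileext = ".csv")
  write_manifest(fx$records, path, fx$split)
  man <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(man), nrow(fx$records))
  expect_setequal(names(man),
                  c("path", "dataset", "label", "binary_label",
                    "patient_id", "magnification", "split"))
  expect_equal(sum(man$split == "train"), length(fx$split$train))
})
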