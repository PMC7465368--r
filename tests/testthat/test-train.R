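# Training protocol: configuration validation, determinism,
# cross-validation folds and the ablation harness.

# 25 tiny single-patch "images" from 25 distinct patients, two classes.
cv_manifest <- function() {
  if (!is.null(.fixture_cache$cv)) return(.fixture_cache$cv)
  dir <- file.path(tempdir(), "msimf_cv_patches")
  dir.create(dir, showWarnings = FALSE)
  set.seed(123)
  rows <- lapply(1:25, function(i) {
    cls <- if (i %% 2 == 0) "DC" else "A"
    tint <- if (cls == "A") c(0.9, 0.75, 0.85) else c(0.7, 0.6, 0.9)
    img <- tinted_texture(32, 32, tint = tint, seed = 1000 + i)
    path <- file.path(dir, sprintf("p%02d.png", i))
    write_rgb(img, path)
    data.frame(path = path, image_id = sprintf("i%02d", i),
               patient_id = sprintf("pt%02d", i), scale = 1L,
               quadrant = 1L, label = cls, stringsAsFactors = FALSE)
  })
  .fixture_cache$cv <- do.call(rbind, rows)
  .fixture_cache$cv
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 1L, learning_rate = 1e-3, batch_size = 8L, seed = 1L,
         augmentation = augment_config(enabled = FALSE)),
    list(...))
  do.call(train_config, args)
}

test_that("configurations are validated against the search space", {
  expect_error(train_config(optimizer = "Adagrad"), "optimizer")
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(epochs = 33, strict = TRUE), "grid")
  expect_silent(train_config(epochs = 30, learning_rate = 1e-4,
                             batch_size = 32, dropout = 0.5,
                             strict = TRUE))
  g <- hyperparameter_grid()
  expect_setequal(g$optimizer, c("SGD", "RMSprop", "Adadelta", "Adam",
                                 "Adamax", "Nadam"))
  expect_equal(g$learning_rate,
               c(1e-1, 1e-2, 1e-3, 1e-4, 5e-1, 5e-2))
})

test_that("identical seeds give identical training trajectories", {
  set.seed(77)
  x <- array(runif(32 * 32 * 3 * 20), c(32, 32, 3, 20))
  labels <- rep(c("A", "DC"), 10)
  h <- lapply(1:2, function(i) {
    set.seed(5)
    m <- build_model(tiny_spec())
    train_patchwise(m, x, labels, fast_config())$history
  })
  expect_identical(h[[1]], h[[2]])
  expect_gt(nrow(h[[1]]), 0L)
})

test_that("loss stays finite across the learning-rate grid", {
  set.seed(78)
  x <- array(runif(32 * 32 * 3 * 12), c(32, 32, 3, 12))
  labels <- rep(c("A", "DC"), 6)
  for (lr in hyperparameter_grid()$learning_rate) {
    set.seed(6)
    m <- build_model(tiny_spec())
    fit <- train_patchwise(m, x, labels,
                           fast_config(learning_rate = lr))
    expect_true(all(is.finite(fit$history$loss)), label = paste("lr", lr))
  }
})

test_that("a single-class manifest is rejected", {
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  m <- build_model(tiny_spec())
  expect_error(train_patchwise(m, x, rep("A", 4), fast_config()),
               "two classes")
})

test_that("optimizer updates change parameters for every optimizer", {
  set.seed(79)
  x <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  labels <- rep(c("A", "DC"), 4)
  for (opt in c("SGD", "RMSprop", "Adadelta", "Adam", "Adamax",
                "Nadam")) {
    set.seed(8)
    m <- build_model(tiny_spec())
    before <- m$params[["head.fc.W"]]
    train_patchwise(m, x, labels, fast_config(optimizer = opt))
    expect_false(identical(before, m$params[["head.fc.W"]]),
                 label = opt)
  }
})

test_that("cross-validation folds are disjoint, exhaustive and patient
           based", {
  man <- cv_manifest()
  fa <- msimfnet:::fold_assignment(man$patient_id, 5L, seed = 1L)
  expect_setequal(names(fa), unique(man$patient_id))
  expect_equal(as.integer(table(fa)), rep(5L, 5))  # 5 patients per fold
  expect_error(msimfnet:::fold_assignment(c("a", "b"), 5L, 1L), "folds")
  cv <- cross_validate(man, tiny_spec(), fast_config(folds = 5L))
  expect_equal(nrow(cv$fold_metrics), 5L)
  expect_true(all(cv$fold_metrics$accuracy >= 0 &
                    cv$fold_metrics$accuracy <= 1))
})

test_that("selection prefers the sane configuration over a sabotaged
           learning rate", {
  man <- cv_manifest()
  sane <- fast_config(learning_rate = 1e-3, folds = 5L)
  sabotaged <- fast_config(learning_rate = 0.5, folds = 5L)
  cv <- cross_validate(man, tiny_spec(), list(sabotaged, sane))
  expect_equal(cv$best_index, 2L)
})

test_that("the ablation harness filters scales and rebuilds taps", {
  fx <- fixture_dataset()
  tr <- fx$patches[fx$patches$split == "train", ]
  te <- fx$patches[fx$patches$split == "test", ]
  # one scale contributes exactly 4 patches per image
  one_scale <- tr[tr$scale == 1L, ]
  expect_equal(nrow(one_scale),
               4L * length(unique(tr$image_id)))
  # keep the run small: two patients per class, one scale combination
  keep <- unique(tr$patient_id)[1:4]
  tr_small <- tr[tr$patient_id %in% keep & tr$scale %in% 1:2, ]
  res <- run_ablation(tr_small, te, tiny_spec(),
                      fast_config(trials = 1L),
                      scale_subsets = list(1L, 1:2),
                      tap_subsets = list(4L, 1:4))
  expect_equal(nrow(res), 4L)
  expect_setequal(res$scales, c("1", "12"))
  expect_setequal(res$taps, c("4", "1234"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_error(run_ablation(tr_small, te, tiny_spec(), fast_config(),
                            scale_subsets = list(integer(0))),
               "non-empty")
})
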