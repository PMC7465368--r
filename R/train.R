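# Patch-wise supervised training: cross-entropy on one-hot labels, the
# published hyperparameter grid, patient-disjoint cross-validation for
# selection, repeated trials for reporting, and the scale/tap ablation
# harness.

#' The hyperparameter search space
#'
#' The grid assessed for model selection: backbone-depth presets
#' 201/205/210 (205 = the 201-layer backbone plus the 4-stage fusion
#' head, the shipped default), epochs, learning rates, batch sizes, six
#' optimizers, dropout rates and the two cross-entropy losses.
#'
#' @return Named list of candidate values.
#' @export
hyperparameter_grid <- function() {
  list(layers = c(201L, 205L, 210L),
       epochs = c(30L, 40L, 50L, 70L),
       learning_rate = c(1e-1, 1e-2, 1e-3, 1e-4, 5e-1, 5e-2),
       batch_size = c(32L, 64L, 128L),
       optimizer = optimizer_names(),
       dropout = c(0.5, 0.6, 0.7, 0.8),
       loss = c("categorical_cross_entropy", "binary_cross_entropy"))
}

#' Training configuration
#'
#' Defaults are the best selected values of the augmented scenario:
#' Adam, learning rate 1e-4, dropout 0.5, 64 epochs, batch size 32.
#' With a 2-unit softmax head the binary cross-entropy on one-hot
#' targets coincides with the categorical loss, so both names map to
#' the same computation.
#'
#' @param epochs,learning_rate,batch_size,optimizer,dropout,loss Core
#'   hyperparameters; `optimizer` is one of SGD, RMSprop, Adadelta,
#'   Adam, Adamax, Nadam.
#' @param folds Cross-validation folds (5 by convention).
#' @param trials Independent repeated runs when reporting metrics.
#' @param seed Master seed for shuffling, init and augmentation.
#' @param augmentation An [augment_config()].
#' @param class_weights `"none"` or `"inverse_frequency"`.
#' @param strict Validate every value against [hyperparameter_grid()].
#' @return An object of class `msimf_train_config`.
#' @export
train_config <- function(epochs = 64L, learning_rate = 1e-4,
                         batch_size = 32L, optimizer = "Adam",
                         dropout = 0.5,
                         loss = c("categorical_cross_entropy",
                                  "binary_cross_entropy"),
                         folds = 5L, trials = 5L, seed = 1L,
                         augmentation = augment_config(),
                         class_weights = c("none", "inverse_frequency"),
                         strict = FALSE) {
  loss <- match.arg(loss)
  class_weights <- match.arg(class_weights)
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 2L,
            dropout >= 0, dropout < 1, folds >= 2L, trials >= 1L)
  if (!optimizer %in% optimizer_names()) {
    stop("optimizer must be one of ",
         paste(optimizer_names(), collapse = ", "))
  }
  if (strict) {
    g <- hyperparameter_grid()
    if (!epochs %in% g$epochs) stop("epochs not in the search grid")
    if (!isTRUE(any(abs(learning_rate - g$learning_rate) < 1e-12))) {
      stop("learning_rate not in the search grid")
    }
    if (!batch_size %in% g$batch_size) {
      stop("batch_size not in the search grid")
    }
    if (!dropout %in% g$dropout) stop("dropout not in the search grid")
  }
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, dropout = dropout, loss = loss,
                 folds = as.integer(folds), trials = as.integer(trials),
                 seed = as.integer(seed), augmentation = augmentation,
                 class_weights = class_weights),
            class = "msimf_train_config")
}

# Load the patches of a manifest into a [side, side, 3, N] array.
load_patch_array <- function(manifest, side) {
  n <- nrow(manifest)
  x <- array(NA_real_, c(side, side, 3L, n))
  for (i in seq_len(n)) {
    img <- read_rgb(manifest$path[i])
    d <- dim(img)
    if (d[1L] != side || d[2L] != side) {
      img <- resize_bilinear(img, side, side)
    }
    x[, , , i] <- img
  }
  x
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(classes), length(labels))
  y[cbind(match(labels, classes), seq_along(labels))] <- 1
  y
}

#' Train the network patch-wise
#'
#' Minimizes the cross-entropy of one-hot patch labels with the
#' configured optimizer. Patches can be given as a patch manifest
#' (loaded and resized to the model's input side) or as an in-memory
#' array plus label vector. Training is deterministic for a fixed seed
#' under single-threaded BLAS.
#'
#' @param model An `msimf_model` from [build_model()].
#' @param patches Patch manifest data.frame (columns `path`, `label`) or
#'   a `[side, side, 3, N]` array.
#' @param labels Label vector when `patches` is an array.
#' @param config An [train_config()].
#' @param classes Class vocabulary; default sorted unique labels. Its
#'   order fixes the probability columns of later predictions.
#' @param verbose Print per-epoch loss/accuracy.
#' @return List with `model` (trained in place), `history` (data.frame
#'   `epoch`, `loss`, `accuracy`).
#' @export
train_patchwise <- function(model, patches, labels = NULL,
                            config = train_config(), classes = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "msimf_model"),
            inherits(config, "msimf_train_config"))
  side <- model$spec$input_side
  if (is.data.frame(patches)) {
    if (nrow(patches) == 0L) stop("empty patch manifest")
    labels <- patches$label
    x <- load_patch_array(patches, side)
  } else {
    x <- patches
    if (is.null(labels)) stop("labels required with an array input")
  }
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least two classes for the cross-entropy loss")
  }
  if (length(classes) != model$n_classes) {
    stop("model has ", model$n_classes, " outputs but ", length(classes),
         " classes were supplied")
  }
  model$classes <- classes
  n <- dim(x)[4L]
  y_all <- one_hot(labels, classes)
  w_class <- rep(1, length(classes))
  if (config$class_weights == "inverse_frequency") {
    freq <- tabulate(match(labels, classes), length(classes))
    w_class <- sum(freq) / (length(classes) * pmax(freq, 1L))
  }

  set.seed(config$seed)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    # fold a trailing singleton into the previous batch (normalization
    # over a batch of one is degenerate)
    if (length(starts) > 1L && (n - starts[length(starts)] + 1L) == 1L) {
      starts <- starts[-length(starts)]
    }
    ep_loss <- 0
    ep_correct <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      if (s == starts[length(starts)]) idx <- perm[s:n]
      xb <- x[, , , idx, drop = FALSE]
      if (config$augmentation$enabled) {
        for (j in seq_along(idx)) {
          xb[, , , j] <- augment_patch(xb[, , , j], config$augmentation)
        }
      }
      yb <- y_all[, idx, drop = FALSE]
      fw <- net_forward(model, xb, training = TRUE, keep = TRUE)
      wb <- w_class[apply(yb, 2L, which.max)]
      ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * length(idx)
      ep_correct <- ep_correct +
        sum(apply(fw$probs, 2L, which.max) == apply(yb, 2L, which.max))
      dlogits <- sweep(fw$probs - yb, 2L, wb, "*") / length(idx)
      grads <- net_backward(model, fw$cache, dlogits)
      apply_gradients(model, grads, config$optimizer,
                      config$learning_rate)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, accuracy %.3f", ep,
                      ep_loss / n, ep_correct / n))
    }
  }
  recalibrate_bn(model, x, config$batch_size)
  list(model = model, history = history)
}

#' Patch predictions for a manifest
#'
#' @param model Trained `msimf_model` (carries its class vocabulary).
#' @param manifest Patch manifest with `path`, `image_id`, `scale`,
#'   `quadrant`.
#' @param batch_size Forward-pass batch size.
#' @return Data.frame `image_id`, `scale`, `quadrant`, plus one
#'   probability column per class.
#' @export
predict_manifest <- function(model, manifest, batch_size = 32L) {
  if (is.null(model$classes)) {
    stop("model has no class vocabulary; train it first")
  }
  x <- load_patch_array(manifest, model$spec$input_side)
  p <- model_predict(model, x, batch_size)
  colnames(p) <- model$classes
  cbind(manifest[, intersect(c("image_id", "scale", "quadrant", "label"),
                             names(manifest)), drop = FALSE],
        as.data.frame(p))
}

#' Image-wise evaluation of patch predictions
#'
#' Fuses patch probabilities per image and scores the fused labels
#' against the image truth.
#'
#' @param pred Output of [predict_manifest()] (needs a `label` column
#'   for the truth).
#' @param method Voting rule, see [fuse_votes()].
#' @param priority Malignancy priority order; defaults to the model's
#'   class order.
#' @return List: `fused` (per-image labels), plus the
#'   [confusion_and_metrics()] fields.
#' @export
evaluate_images <- function(pred, method = "maximum", priority = NULL) {
  classes <- setdiff(names(pred),
                     c("image_id", "scale", "quadrant", "label"))
  if (is.null(priority)) priority <- classes
  # a full-vocabulary priority order may cover more classes than the
  # model was trained on; keep its relative order over the model's
  priority <- priority[priority %in% classes]
  fused <- fuse_images(pred, classes, method, priority)
  truth <- vapply(fused$image_id, function(id) {
    as.character(pred$label[pred$image_id == id][1L])
  }, "")
  c(list(fused = fused),
    confusion_and_metrics(truth, fused$label, classes))
}

fold_assignment <- function(groups, folds, seed) {
  set.seed(seed)
  g <- sample(unique(groups))
  if (length(g) < folds) {
    stop("fewer groups (", length(g), ") than folds (", folds, ")")
  }
  stats::setNames(rep(seq_len(folds), length.out = length(g)), g)
}

#' Cross-validated hyperparameter selection
#'
#' Splits the patch manifest into `folds` patient-disjoint folds (image
#' folds when no patient ids exist), trains every candidate
#' configuration on each training fold and scores patch-wise validation
#' accuracy; the configuration with the highest mean validation accuracy
#' is selected.
#'
#' @param manifest Patch manifest (columns `path`, `label`, `image_id`,
#'   optionally `patient_id`).
#' @param spec An [architecture_spec()] used for every candidate.
#' @param configs List of [train_config()] candidates.
#' @param verbose Print progress.
#' @return List: `fold_metrics` (config, fold, accuracy), `summary`
#'   (mean accuracy per config), `best_config`.
#' @export
cross_validate <- function(manifest, spec, configs, verbose = FALSE) {
  if (inherits(configs, "msimf_train_config")) configs <- list(configs)
  folds <- configs[[1L]]$folds
  groups <- if (!is.null(manifest$patient_id) &&
                !all(is.na(manifest$patient_id))) {
    manifest$patient_id
  } else {
    manifest$image_id
  }
  fa <- fold_assignment(groups, folds, configs[[1L]]$seed)
  fold_of <- fa[groups]
  classes <- sort(unique(manifest$label))
  res <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (f in seq_len(folds)) {
      tr <- manifest[fold_of != f, , drop = FALSE]
      va <- manifest[fold_of == f, , drop = FALSE]
      model <- local({
        set.seed(cfg$seed + f)
        build_model(spec, n_classes = length(classes))
      })
      fit <- train_patchwise(model, tr, config = cfg, classes = classes)
      xv <- load_patch_array(va, spec$input_side)
      pv <- model_predict(fit$model, xv, cfg$batch_size)
      acc <- mean(classes[apply(pv, 1L, which.max)] == va$label)
      res[[length(res) + 1L]] <- data.frame(config = ci, fold = f,
                                            accuracy = acc)
      if (verbose) {
        message(sprintf("config %d fold %d: accuracy %.3f", ci, f, acc))
      }
    }
  }
  fold_metrics <- do.call(rbind, res)
  summary <- stats::aggregate(accuracy ~ config, fold_metrics, mean)
  best <- summary$config[which.max(summary$accuracy)]
  list(fold_metrics = fold_metrics, summary = summary,
       best_config = configs[[best]], best_index = best)
}

#' Scale / tap ablation harness
#'
#' Re-runs training and image-wise evaluation for combinations of input
#' scales (patches filtered to the chosen pyramid levels) and
#' feature-map taps (the model fuses only the chosen blocks' pooled
#' vectors), averaging metrics over `config$trials` seeded runs —
#' the experimental design of the published ablation study at desk
#' scale.
#'
#' @param train_manifest,test_manifest Patch manifests.
#' @param spec Base [architecture_spec()] (its `taps` field is
#'   overridden per combination).
#' @param config An [train_config()].
#' @param scale_subsets List of non-empty subsets of 1:4.
#' @param tap_subsets List of non-empty subsets of 1:4.
#' @param method Voting rule for image-wise evaluation.
#' @param priority Malignancy priority order (default: class order).
#' @return Data.frame with one row per combination: `scales`, `taps`,
#'   `accuracy`, `sensitivity`, `specificity` (macro-averaged over
#'   classes, mean over trials).
#' @export
run_ablation <- function(train_manifest, test_manifest, spec, config,
                         scale_subsets = list(1:4),
                         tap_subsets = list(1:4),
                         method = "maximum", priority = NULL) {
  if (any(vapply(scale_subsets, length, 1L) == 0L) ||
      any(vapply(tap_subsets, length, 1L) == 0L)) {
    stop("scale and tap subsets must be non-empty")
  }
  classes <- sort(unique(train_manifest$label))
  out <- list()
  for (sc in scale_subsets) {
    tr <- train_manifest[train_manifest$scale %in% sc, , drop = FALSE]
    te <- test_manifest[test_manifest$scale %in% sc, , drop = FALSE]
    for (tp in tap_subsets) {
      sp <- architecture_spec(
        input_side = spec$input_side, stem_channels = spec$stem_channels,
        growth = spec$growth, block_repeats = spec$block_repeats,
        bottleneck_factor = spec$bottleneck / spec$growth,
        compression = spec$compression, taps = tp,
        n_classes = length(classes), dropout = spec$dropout,
        head_norm = spec$head_norm)
      accs <- sens <- specs <- numeric(config$trials)
      for (trial in seq_len(config$trials)) {
        cfg <- config
        cfg$seed <- config$seed + 1000L * trial
        model <- local({
          set.seed(cfg$seed)
          build_model(sp)
        })
        fit <- train_patchwise(model, tr, config = cfg, classes = classes)
        pred <- predict_manifest(fit$model, te, cfg$batch_size)
        ev <- evaluate_images(pred, method, priority)
        accs[trial] <- ev$accuracy
        sens[trial] <- mean(ev$sensitivity, na.rm = TRUE)
        specs[trial] <- mean(ev$specificity, na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        scales = paste(sc, collapse = ""),
        taps = paste(tp, collapse = ""),
        accuracy = mean(accs), sensitivity = mean(sens),
        specificity = mean(specs))
    }
  }
  do.call(rbind, out)
}
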