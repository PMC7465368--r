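# Patch-to-image probability fusion, evaluation metrics, and the
# continuity-corrected McNemar test for paired classifier comparison.

check_prob_matrix <- function(p, tol = 1e-4) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (any(p < -tol)) stop("probabilities must be non-negative")
  s <- rowSums(p)
  if (any(abs(s - 1) > tol)) {
    stop("patch probability vectors must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  }
  p
}

#' Fuse patch probabilities into one image label
#'
#' Three voting rules over the patch probability vectors of one image:
#' `"majority"` takes the most frequent patch argmax label; `"maximum"`
#' takes the label of the single highest patch probability; `"sum"` takes
#' the argmax of the summed probability vectors. Every tie — including
#' per-patch argmax ties and shared top probabilities under `"maximum"` —
#' is broken in favor of the earliest class in `priority` (most malignant
#' first).
#'
#' @param probs `n_patches x n_classes` matrix of patch probability
#'   vectors; column names are the class vocabulary (defaults to
#'   `priority` when absent).
#' @param method `"majority"`, `"maximum"` or `"sum"`.
#' @param priority Character vector: the class vocabulary ordered most
#'   malignant first (see [malignancy_priority()]).
#' @return The fused class label (character scalar).
#' @examples
#' p <- rbind(c(0.6, 0.4), c(0.2, 0.8))
#' colnames(p) <- c("B", "M")
#' fuse_votes(p, "sum", priority = c("M", "B"))  # "M": 1.2 beats 0.8
#' @export
fuse_votes <- function(probs, method = c("majority", "maximum", "sum"),
                       priority) {
  method <- match.arg(method)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (nrow(probs) < 1L) stop("no patch predictions to fuse")
  classes <- colnames(probs)
  if (is.null(classes)) {
    if (ncol(probs) != length(priority)) {
      stop("unnamed probability columns must match the priority order")
    }
    classes <- priority
  }
  if (!setequal(classes, priority)) {
    stop("priority order must be a permutation of the class vocabulary")
  }
  probs <- check_prob_matrix(probs)
  rank_of <- match(classes, priority)   # smaller = more malignant

  pick_max <- function(v) {
    # argmax over classes with priority tie-break (tolerance for float ties)
    top <- max(v)
    cand <- which(v >= top - 1e-12)
    cand[which.min(rank_of[cand])]
  }

  idx <- switch(method,
    majority = {
      votes <- apply(probs, 1L, pick_max)
      counts <- tabulate(votes, nbins = length(classes))
      pick_max(counts / sum(counts) + 0)  # counts tie-broken by priority
    },
    maximum = {
      top <- max(probs)
      cand <- which(probs >= top - 1e-12, arr.ind = TRUE)[, 2L]
      cand[which.min(rank_of[cand])]
    },
    sum = pick_max(colSums(probs))
  )
  classes[idx]
}

#' Fuse a patch prediction table image by image
#'
#' @param pred Data.frame with columns `image_id` and one probability
#'   column per class (plus anything else, ignored).
#' @param classes Class vocabulary (the probability column names).
#' @param method,priority See [fuse_votes()].
#' @return Data.frame `image_id`, `label` with one fused label per image.
#' @export
fuse_images <- function(pred, classes,
                        method = c("majority", "maximum", "sum"),
                        priority = classes) {
  method <- match.arg(method)
  stopifnot(all(classes %in% names(pred)))
  ids <- unique(pred$image_id)
  lab <- vapply(ids, function(id) {
    p <- as.matrix(pred[pred$image_id == id, classes, drop = FALSE])
    colnames(p) <- classes
    fuse_votes(p, method, priority)
  }, "")
  data.frame(image_id = ids, label = lab, stringsAsFactors = FALSE)
}

#' Confusion matrix with accuracy, sensitivity and specificity
#'
#' One-vs-rest per class: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP); accuracy is the trace over the total. Metrics whose
#' denominator is zero (e.g. a class absent from the truth) are reported
#' as `NA`, never as 0.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Class vocabulary; defaults to the sorted union.
#' @return List with `confusion` (rows = true classes), `accuracy`,
#'   `sensitivity`, `specificity` (named per class).
#' @export
confusion_and_metrics <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  sens <- spec <- stats::setNames(numeric(length(classes)), classes)
  for (c_ in classes) {
    tp <- cm[c_, c_]
    fn <- sum(cm[c_, ]) - tp
    fp <- sum(cm[, c_]) - tp
    tn <- n - tp - fn - fp
    sens[c_] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[c_] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  list(confusion = cm, accuracy = acc, sensitivity = sens,
       specificity = spec)
}

#' Paired-outcome 2x2 table of two classifiers
#'
#' @param n11 Both correct.
#' @param n12 Model A correct, model B wrong.
#' @param n21 Model A wrong, model B correct.
#' @param n22 Both wrong.
#' @return An object of class `msimf_paired_table`.
#' @export
paired_outcome_table <- function(n11, n12, n21, n22) {
  cells <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(as.list(cells), class = "msimf_paired_table")
}

#' Paired-outcome table from per-image correctness of two models
#'
#' @param truth True labels.
#' @param pred_a,pred_b Predicted labels of the two models.
#' @return An `msimf_paired_table`.
#' @export
paired_outcomes <- function(truth, pred_a, pred_b) {
  a <- pred_a == truth
  b <- pred_b == truth
  paired_outcome_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

#' Standardized (continuity-corrected) McNemar test
#'
#' Tests whether two classifiers evaluated on the same samples differ,
#' using only the discordant cells: the statistic is
#' `(|n12 - n21| - 1)^2 / (n12 + n21)`, referred to the chi-square
#' distribution with one degree of freedom (Edwards continuity
#' correction).
#'
#' @param table An [paired_outcome_table()], or `n11` given as the first
#'   of four cell counts.
#' @param n12,n21,n22 Remaining cells when counts are given directly.
#' @return List with `statistic`, `p_value`, `n_discordant`.
#' @examples
#' mcnemar_standardized(254, 14, 20, 76)$p_value   # ~0.39
#' mcnemar_standardized(773, 89, 115, 495)$p_value # ~0.08
#' @export
mcnemar_standardized <- function(table, n12 = NULL, n21 = NULL,
                                 n22 = NULL) {
  if (!inherits(table, "msimf_paired_table")) {
    table <- paired_outcome_table(table, n12, n21, n22)
  }
  d <- table$n12 + table$n21
  if (d < 1) stop("test undefined: no discordant pairs")
  stat <- (abs(table$n12 - table$n21) - 1)^2 / d
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_discordant = d)
}
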