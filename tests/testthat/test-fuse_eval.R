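# Voting fusion, metrics and the paired McNemar test.

# Independent brute-force voting oracles: scan classes in priority order
# with a strict improvement rule, so the first (most malignant) class
# wins every tie by construction.
oracle_vote <- function(probs, method, priority) {
  classes <- colnames(probs)
  ord <- match(priority, classes)        # scan order over columns
  best_of <- function(score) {
    best <- -Inf
    win <- NA_integer_
    for (j in ord) {
      if (score[j] > best + 1e-12) {
        best <- score[j]
        win <- j
      }
    }
    win
  }
  j <- switch(method,
    majority = {
      counts <- numeric(ncol(probs))
      for (i in seq_len(nrow(probs))) {
        v <- best_of(probs[i, ])
        counts[v] <- counts[v] + 1
      }
      best_of(counts)
    },
    maximum = {
      best <- -Inf
      win <- NA_integer_
      for (j2 in ord) {
        for (i in seq_len(nrow(probs))) {
          if (probs[i, j2] > best + 1e-12) {
            best <- probs[i, j2]
            win <- j2
          }
        }
      }
      win
    },
    sum = best_of(colSums(probs))
  )
  classes[j]
}

prob_grid <- function(k, step = 0.25) {
  pts <- seq(0, 1, by = step)
  g <- expand.grid(rep(list(pts), k))
  g <- g[abs(rowSums(g) - 1) < 1e-9, , drop = FALSE]
  unname(as.matrix(g))
}

test_that("worked voting examples behave as documented", {
  classes <- c("A", "DC")
  prio <- c("DC", "A")
  # patch argmax labels A, A, DC under majority -> A
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9))
  colnames(p) <- classes
  expect_equal(fuse_votes(p, "majority", prio), "A")
  # tied argmax labels DC, A -> malignant DC wins
  p2 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  colnames(p2) <- classes
  expect_equal(fuse_votes(p2, "majority", prio), "DC")
  # sum: 0.8 vs 1.2 -> class 2; maximum: single largest 0.8 -> class 2
  p3 <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  colnames(p3) <- c("c1", "c2")
  expect_equal(fuse_votes(p3, "sum", priority = c("c2", "c1")), "c2")
  expect_equal(fuse_votes(p3, "maximum", priority = c("c2", "c1")), "c2")
  expect_error(fuse_votes(p3[0, , drop = FALSE], "sum", c("c2", "c1")),
               "no patch")
  expect_error(fuse_votes(rbind(c(0.5, 0.2)), "sum", c("c1", "c2")),
               "sum to 1")
})

test_that("all three rules match exhaustive enumeration on the 0.25 grid", {
  for (k in 2:3) {
    classes <- paste0("k", seq_len(k))
    prio <- rev(classes)               # non-trivial priority order
    vecs <- prob_grid(k)
    for (n_patch in 1:3) {
      combos <- expand.grid(rep(list(seq_len(nrow(vecs))), n_patch))
      for (r in seq_len(nrow(combos))) {
        p <- vecs[unlist(combos[r, ]), , drop = FALSE]
        colnames(p) <- classes
        for (method in c("majority", "maximum", "sum")) {
          expect_identical(fuse_votes(p, method, prio),
                           oracle_vote(p, method, prio))
        }
      }
    }
  }
})

test_that("unanimous patches win under every rule", {
  classes <- c("x", "y", "z")
  for (seed in 1:20) {
    set.seed(seed)
    win <- sample(classes, 1)
    p <- t(vapply(1:4, function(i) {
      v <- runif(3, 0, 0.2)
      v[match(win, classes)] <- 1
      v / sum(v)
    }, numeric(3)))
    colnames(p) <- classes
    for (method in c("majority", "maximum", "sum")) {
      expect_equal(fuse_votes(p, method, classes), win)
    }
  }
})

test_that("confusion metrics match hand arithmetic and report NA when
           undefined", {
  # binary: TP=3, FN=1, FP=0, TN=4
  truth <- c(rep("pos", 4), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", rep("neg", 4))
  m <- confusion_and_metrics(truth, pred)
  expect_equal(unname(m$sensitivity["pos"]), 0.75)
  expect_equal(unname(m$specificity["pos"]), 1.0)
  expect_equal(m$accuracy, 7 / 8)
  # perfect predictions
  mp <- confusion_and_metrics(truth, truth)
  expect_equal(mp$accuracy, 1)
  expect_true(all(mp$sensitivity == 1) && all(mp$specificity == 1))
  # all-one-class predictor on balanced data
  ma <- confusion_and_metrics(truth, rep("pos", 8))
  expect_equal(ma$accuracy, 0.5)
  expect_equal(unname(ma$sensitivity), c(0, 1))  # neg then pos
  # class absent from both sequences -> NA, not 0
  mu <- confusion_and_metrics(truth, pred, classes = c("neg", "pos", "ghost"))
  expect_true(is.na(mu$sensitivity["ghost"]))
  # row sums of the confusion matrix account for every sample
  expect_equal(sum(mu$confusion), length(truth))
  expect_error(confusion_and_metrics(truth, pred[-1]), "equal length")
})

test_that("standardized McNemar reproduces the published p-values", {
  r1 <- mcnemar_standardized(254, 14, 20, 76)
  expect_equal(round(r1$p_value, 2), 0.39)
  expect_equal(r1$statistic, (abs(14 - 20) - 1)^2 / 34)
  r2 <- mcnemar_standardized(773, 89, 115, 495)
  expect_equal(round(r2$p_value, 2), 0.08)
  # equal discordant counts: statistic (|0|-1)^2 / 20
  r3 <- mcnemar_standardized(5, 10, 10, 5)
  expect_equal(r3$statistic, 0.05)
  expect_equal(r3$p_value, 0.823, tolerance = 1e-3)
  expect_error(mcnemar_standardized(10, 0, 0, 10), "undefined")
})

test_that("McNemar agrees with the stats oracle and is symmetric", {
  set.seed(3)
  for (i in 1:25) {
    n12 <- sample(0:60, 1)
    n21 <- sample(0:60, 1)
    if (n12 + n21 == 0) n12 <- 1
    tab <- matrix(c(30, n12, n21, 25), 2, byrow = TRUE)
    ours <- mcnemar_standardized(30, n12, n21, 25)
    ref <- stats::mcnemar.test(tab, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
    swapped <- mcnemar_standardized(30, n21, n12, 25)
    expect_equal(swapped$p_value, ours$p_value)
  }
})

test_that("paired outcome tables come straight from per-image labels", {
  truth <- c("a", "a", "b", "b", "a")
  pa <- c("a", "b", "b", "a", "a")   # correct: 1,0,1,0,1
  pb <- c("a", "a", "a", "a", "a")   # correct: 1,1,0,0,1
  t <- paired_outcomes(truth, pa, pb)
  expect_equal(unlist(t[c("n11", "n12", "n21", "n22")]),
               c(n11 = 2, n12 = 1, n21 = 1, n22 = 1))
  expect_error(paired_outcome_table(-1, 2, 3, 4), "non-negative")
})
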