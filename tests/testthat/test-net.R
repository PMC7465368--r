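# Architecture ledger, channel recursion and the network itself.

test_that("dense layer and transition closed forms match hand expansion", {
  # 4*c + 128*c + 4*128 + 9*128*32 = 132*c + 37376
  expect_equal(dense_layer_param_count(64), 132 * 64 + 37376)
  expect_equal(dense_layer_param_count(64), 45824)
  expect_equal(dense_layer_param_count(1, growth = 1, bottleneck = 2),
               4 + 2 + 8 + 18)
  expect_equal(transition_param_count(2), 10)
  expect_error(transition_param_count(3), "even")
})

test_that("channel recursion yields the published tap widths", {
  sp <- architecture_spec()
  expect_equal(sp$block_out, c(256L, 512L, 1792L, 1920L))
  expect_equal(sp$tap_widths, c(128L, 256L, 896L, 1920L))
  expect_equal(sp$fused_width, 3200L)
})

test_that("ledger reproduces every printed block count and the total", {
  led <- param_ledger(architecture_spec())
  lk <- function(b) led$params[led$block == b]
  expect_equal(lk("stem_conv"), 9408)
  expect_equal(lk("stem_bn"), 256)
  expect_equal(lk("db1"), 338304)
  expect_equal(lk("transition1"), 33792)
  expect_equal(lk("db2"), 930048)
  expect_equal(lk("transition2"), 133120)
  expect_equal(lk("db3"), 8180736)
  expect_equal(lk("transition3"), 1612800)
  expect_equal(lk("db4"), 7083520)
  expect_equal(lk("head_bn"), 12800)
  expect_equal(lk("softmax"), 25608)
  expect_equal(attr(led, "total"), 18360392)
  expect_equal(sum(led$percent), 100, tolerance = 0.02)
})

test_that("ledger equals stored parameter count for every tap subset", {
  subsets <- unlist(lapply(1:4, function(k) utils::combn(4, k, simplify = FALSE)),
                    recursive = FALSE)
  for (s in subsets) {
    sp <- tiny_spec(taps = s)
    m <- build_model(sp)
    expect_identical(model_param_count(m),
                     as.integer(attr(param_ledger(sp), "total")))
  }
})

test_that("removing a tap reduces the fused width by that tap's width", {
  full <- architecture_spec()
  for (k in 1:4) {
    sp <- architecture_spec(taps = setdiff(1:4, k))
    expect_equal(sp$fused_width, full$fused_width - full$tap_widths[k])
  }
})

test_that("forward pass returns normalized probabilities and the right
           spatial chain", {
  set.seed(11)
  sp <- tiny_spec(input_side = 64L)
  m <- build_model(sp)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  fw <- msimfnet:::net_forward(m, x)
  expect_equal(colSums(fw$probs), rep(1, 3), tolerance = 1e-5)
  expect_equal(nrow(fw$fused), sp$fused_width)
  # 64 -> 32 (stem conv) -> 16 (pool/DB1) -> 8 -> 4 -> 4
  expect_equal(vapply(fw$tap_dims, `[[`, 1L, "H"), c(8L, 4L, 2L, 2L))
  expect_error(msimfnet:::net_forward(m, array(0, c(64, 64, 1, 1))),
               "side, side, 3")
})

test_that("baseline uses only the last tap and fewer parameters", {
  sp <- tiny_spec()
  base <- build_baseline(sp)
  expect_equal(base$spec$taps, 4L)
  expect_equal(base$spec$fused_width, sp$tap_widths[4L])
  expect_false(base$spec$head_norm)
  expect_lt(model_param_count(base),
            model_param_count(build_model(sp)))
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p <- model_predict(base, x)
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-5)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  sp <- tiny_spec(n_classes = 4L)
  m <- build_model(sp)
  m$params[["head.fc.W"]] <- matrix(
    rnorm(length(m$params[["head.fc.W"]]), sd = 0.1),
    nrow(m$params[["head.fc.W"]]))
  N <- 4L
  x <- array(runif(32 * 32 * 3 * N), c(32, 32, 3, N))
  y <- msimfnet:::one_hot(sample(letters[1:4], N, TRUE), letters[1:4])
  loss_fn <- function() {
    fw <- msimfnet:::net_forward(m, x, training = TRUE, keep = FALSE)
    msimfnet:::cross_entropy(fw$probs, y)
  }
  fw <- msimfnet:::net_forward(m, x, training = TRUE, keep = TRUE)
  g <- msimfnet:::net_backward(m, fw$cache, (fw$probs - y) / N)
  eps <- 1e-6
  for (nm in c("stem.conv", "b1.l1.conv1", "b2.l2.conv3", "t1.conv",
               "b3.l1.bn1.gamma", "b4.l2.bn2.beta", "final.bn.gamma",
               "head.bn.beta", "head.fc.W", "head.fc.b", "stem.bn.gamma")) {
    w <- m$params[[nm]]
    for (i in sample(length(w), min(3L, length(w)))) {
      m$params[[nm]][i] <- w[i] + eps
      lp <- loss_fn()
      m$params[[nm]][i] <- w[i] - eps
      lm <- loss_fn()
      m$params[[nm]][i] <- w[i]
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  sp <- tiny_spec()
  m <- build_model(sp)
  m$classes <- c("A", "DC")
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$classes, c("A", "DC"))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(model_predict(m2, x), model_predict(m, x))
  # pretrained init restores from the checkpoint
  m3 <- build_model(sp, init = "pretrained", weights = path)
  expect_identical(m3$params, m$params)
  expect_error(build_model(sp, init = "pretrained"), "checkpoint")
})
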