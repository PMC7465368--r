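#' Define the network architecture from integers
#'
#' All structural choices of the multi-scale input / multi-feature fusion
#' network are integers: a 7x7 stride-2 stem to `stem_channels`, four
#' dense blocks of `block_repeats` bottleneck layers adding `growth`
#' channels each, 0.5-compression transitions with 2x2 average pooling,
#' a trailing normalization after the last block, and global-average-pool
#' taps after each block whose concatenation feeds the classifier head.
#' The shipped default reproduces the published parameter ledger exactly
#' (dense blocks of 6/12/48/32 layers, growth 32, bottleneck 128, pooled
#' tap widths 128/256/896/1920 and a fused width of 3200).
#'
#' @param input_side Network input side in pixels (square input).
#' @param stem_channels Channels produced by the stem convolution.
#' @param growth Channels added by every dense layer.
#' @param block_repeats Integer vector of 4 dense-layer counts.
#' @param bottleneck_factor Bottleneck width as a multiple of `growth`.
#' @param compression Channel compression of the transitions (0.5 halves).
#' @param taps Subset of 1:4 selecting which per-block pooled vectors are
#'   fused into the classifier descriptor.
#' @param n_classes Output classes; 2, 4 and 8 are the supported
#'   vocabularies, other values are accepted with a warning.
#' @param dropout Dropout rate applied to the fused descriptor.
#' @param head_norm Normalize the fused descriptor before the softmax.
#' @return An object of class `msimf_spec` with derived channel counts,
#'   per-tap pooled widths and the fused width.
#' @examples
#' sp <- architecture_spec()
#' sp$tap_widths   # 128 256 896 1920
#' sp$fused_width  # 3200
#' @export
architecture_spec <- function(input_side = 224L,
                              stem_channels = 64L,
                              growth = 32L,
                              block_repeats = c(6L, 12L, 48L, 32L),
                              bottleneck_factor = 4L,
                              compression = 0.5,
                              taps = 1:4,
                              n_classes = 8L,
                              dropout = 0.5,
                              head_norm = TRUE) {
  stopifnot(length(block_repeats) == 4L, all(block_repeats >= 1L),
            growth >= 1L, stem_channels >= 1L,
            compression > 0, compression <= 1)
  taps <- sort(unique(as.integer(taps)))
  if (length(taps) == 0L || !all(taps %in% 1:4)) {
    stop("taps must be a non-empty subset of 1:4")
  }
  if (input_side < 32L) {
    stop("input_side must be at least 32 px to survive four halvings")
  }
  if (!n_classes %in% c(2L, 4L, 8L)) {
    warning("n_classes ", n_classes, " is outside the usual {2, 4, 8}")
  }
  bottleneck <- as.integer(bottleneck_factor * growth)

  # channel recursion: stem -> +repeats*growth per block -> compression
  ch_in <- integer(4L)
  ch_out <- integer(4L)
  tap_widths <- integer(4L)
  c_cur <- as.integer(stem_channels)
  for (k in 1:4) {
    ch_in[k] <- c_cur
    c_cur <- c_cur + block_repeats[k] * growth
    ch_out[k] <- c_cur
    if (k < 4L) {
      c_cur <- as.integer(floor(c_cur * compression))
      if (2L * c_cur != ch_out[k]) {
        stop("block ", k, " output ", ch_out[k],
             " is not evenly compressible")
      }
      tap_widths[k] <- c_cur
    } else {
      tap_widths[k] <- c_cur
    }
  }
  spec <- list(input_side = as.integer(input_side),
               stem_channels = as.integer(stem_channels),
               growth = as.integer(growth),
               block_repeats = as.integer(block_repeats),
               bottleneck = bottleneck,
               compression = compression,
               taps = taps,
               n_classes = as.integer(n_classes),
               dropout = dropout,
               head_norm = isTRUE(head_norm),
               block_in = ch_in,
               block_out = ch_out,
               tap_widths = tap_widths,
               fused_width = sum(tap_widths[taps]))
  class(spec) <- "msimf_spec"
  spec
}

#' @export
print.msimf_spec <- function(x, ...) {
  cat("Multi-scale input / multi-feature fusion network spec\n")
  cat("  input:", x$input_side, "x", x$input_side, "x 3\n")
  cat("  blocks:", paste(x$block_repeats, collapse = "/"),
      "layers, growth", x$growth, ", bottleneck", x$bottleneck, "\n")
  cat("  tap widths:", paste(x$tap_widths, collapse = "/"),
      "-> fused", x$fused_width, "(taps",
      paste(x$taps, collapse = ","), ")\n")
  cat("  head:", x$n_classes, "classes, dropout", x$dropout,
      if (x$head_norm) ", normalized descriptor" else "", "\n")
  invisible(x)
}

#' Parameters of one dense layer
#'
#' Each dense layer is the composite BN-ReLU-conv1x1(bottleneck)-
#' BN-ReLU-conv3x3(growth). Convolutions are bias-free; a normalization
#' layer is counted at 4 accounting parameters per channel (two learned,
#' two tracked statistics), so the count is
#' `4*c_in + c_in*bottleneck + 4*bottleneck + 9*bottleneck*growth`.
#'
#' @param c_in Input channels to the layer.
#' @param growth Channels emitted by the 3x3 convolution.
#' @param bottleneck Width of the 1x1 bottleneck.
#' @return Integer parameter count.
#' @examples
#' dense_layer_param_count(64)  # 45824
#' @export
dense_layer_param_count <- function(c_in, growth = 32L, bottleneck = 128L) {
  stopifnot(all(c_in >= 1))
  4 * c_in + c_in * bottleneck + 4 * bottleneck + 9 * bottleneck * growth
}

#' Parameters of a transition layer
#'
#' BN-ReLU-conv1x1 halving the channels, followed by a parameter-free
#' 2x2 stride-2 average pool: `4*c_in + c_in*(c_in/2)`.
#'
#' @param c_in Input channels (must be even).
#' @return Integer parameter count.
#' @examples
#' transition_param_count(256)  # 33792
#' @export
transition_param_count <- function(c_in) {
  if (any(c_in %% 2 != 0)) stop("transition input channels must be even")
  4 * c_in + c_in * (c_in / 2)
}

#' Closed-form per-layer parameter ledger
#'
#' Enumerates every parameter-bearing stage of the architecture: stem
#' convolution and its normalization, the four dense blocks (the last
#' block includes the trailing normalization over its output channels),
#' the three transitions, the optional normalization of the fused
#' descriptor and the softmax classifier. For the default 8-class spec
#' this reproduces the published architecture table exactly
#' (total 18,360,392).
#'
#' @param spec An [architecture_spec()].
#' @return A data.frame with columns `block`, `params` and `percent`
#'   (share of the total to one decimal) plus a `total` attribute.
#' @export
param_ledger <- function(spec) {
  stopifnot(inherits(spec, "msimf_spec"))
  rows <- list(
    c(block = "stem_conv", params = 7 * 7 * 3 * spec$stem_channels),
    c(block = "stem_bn", params = 4 * spec$stem_channels)
  )
  for (k in 1:4) {
    c_ins <- spec$block_in[k] + spec$growth * (seq_len(spec$block_repeats[k]) - 1L)
    p <- sum(dense_layer_param_count(c_ins, spec$growth, spec$bottleneck))
    if (k == 4L) p <- p + 4 * spec$block_out[4L]  # trailing normalization
    rows[[length(rows) + 1L]] <- c(block = paste0("db", k), params = p)
    if (k < 4L) {
      rows[[length(rows) + 1L]] <-
        c(block = paste0("transition", k),
          params = transition_param_count(spec$block_out[k]))
    }
  }
  if (spec$head_norm) {
    rows[[length(rows) + 1L]] <-
      c(block = "head_bn", params = 4 * spec$fused_width)
  }
  rows[[length(rows) + 1L]] <-
    c(block = "softmax",
      params = spec$fused_width * spec$n_classes + spec$n_classes)
  ledger <- data.frame(
    block = vapply(rows, `[[`, "", "block"),
    params = as.numeric(vapply(rows, `[[`, "", "params")),
    stringsAsFactors = FALSE
  )
  total <- sum(ledger$params)
  ledger$percent <- round(100 * ledger$params / total, 1)
  attr(ledger, "total") <- total
  ledger
}

param_name_bn <- function(prefix) {
  paste0(prefix, c(".gamma", ".beta", ".rm", ".rv"))
}

init_bn <- function(params, prefix, c) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, c)
  params[[paste0(prefix, ".beta")]] <- rep(0, c)
  params[[paste0(prefix, ".rm")]] <- rep(0, c)
  params[[paste0(prefix, ".rv")]] <- rep(1, c)
  params
}

init_conv <- function(params, name, c_out, c_in, k) {
  fan_in <- k * k * c_in
  params[[name]] <- matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                           c_out, fan_in)
  params
}

#' Build the network
#'
#' Instantiates the model defined by an [architecture_spec()]: parameters
#' are allocated (He-normal convolutions, unit-gain normalizations, a
#' zero-initialized classifier) and the object carries its own running
#' statistics and optimizer state. The number of stored parameter values
#' always equals the closed-form [param_ledger()] total.
#'
#' @param spec An [architecture_spec()].
#' @param n_classes Optional override of `spec$n_classes`.
#' @param init `"random"` for fresh weights or `"pretrained"` to restore
#'   from `weights` (a file written by [save_model()]).
#' @param weights Checkpoint path used when `init = "pretrained"`.
#' @return An environment of class `msimf_model`.
#' @examples
#' m <- build_model(architecture_spec(block_repeats = c(1, 1, 1, 1)),
#'                  n_classes = 2)
#' model_param_count(m) == attr(param_ledger(m$spec), "total")
#' @export
build_model <- function(spec, n_classes = spec$n_classes,
                        init = c("random", "pretrained"), weights = NULL) {
  stopifnot(inherits(spec, "msimf_spec"))
  init <- match.arg(init)
  if (n_classes != spec$n_classes) {
    spec <- architecture_spec(
      input_side = spec$input_side, stem_channels = spec$stem_channels,
      growth = spec$growth, block_repeats = spec$block_repeats,
      bottleneck_factor = spec$bottleneck / spec$growth,
      compression = spec$compression, taps = spec$taps,
      n_classes = n_classes, dropout = spec$dropout,
      head_norm = spec$head_norm)
  }
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$n_classes <- spec$n_classes
  params <- list()
  params <- init_conv(params, "stem.conv", spec$stem_channels, 3L, 7L)
  params <- init_bn(params, "stem.bn", spec$stem_channels)
  for (k in 1:4) {
    c_in <- spec$block_in[k]
    for (i in seq_len(spec$block_repeats[k])) {
      pre <- sprintf("b%d.l%d", k, i)
      params <- init_bn(params, paste0(pre, ".bn1"), c_in)
      params <- init_conv(params, paste0(pre, ".conv1"),
                          spec$bottleneck, c_in, 1L)
      params <- init_bn(params, paste0(pre, ".bn2"), spec$bottleneck)
      params <- init_conv(params, paste0(pre, ".conv3"),
                          spec$growth, spec$bottleneck, 3L)
      c_in <- c_in + spec$growth
    }
    if (k < 4L) {
      pre <- sprintf("t%d", k)
      params <- init_bn(params, paste0(pre, ".bn"), c_in)
      params <- init_conv(params, paste0(pre, ".conv"),
                          spec$tap_widths[k], c_in, 1L)
    } else {
      params <- init_bn(params, "final.bn", c_in)
    }
  }
  if (spec$head_norm) params <- init_bn(params, "head.bn", spec$fused_width)
  params[["head.fc.W"]] <- matrix(0, spec$n_classes, spec$fused_width)
  params[["head.fc.b"]] <- rep(0, spec$n_classes)
  model$params <- params
  model$trainable <- grep("\\.(rm|rv)$", names(params),
                          value = TRUE, invert = TRUE)
  model$opt_state <- list()
  class(model) <- "msimf_model"
  if (init == "pretrained") {
    if (is.null(weights) || !file.exists(weights)) {
      stop("init = 'pretrained' requires an existing checkpoint file")
    }
    restore_model(model, weights)
  }
  model
}

#' Single-tap baseline configuration
#'
#' The comparison baseline shares the backbone but classifies from the
#' last block's pooled vector alone, with a direct softmax head (no
#' descriptor normalization).
#'
#' @inheritParams build_model
#' @return An `msimf_model`.
#' @export
build_baseline <- function(spec, n_classes = spec$n_classes) {
  stopifnot(inherits(spec, "msimf_spec"))
  base_spec <- architecture_spec(
    input_side = spec$input_side, stem_channels = spec$stem_channels,
    growth = spec$growth, block_repeats = spec$block_repeats,
    bottleneck_factor = spec$bottleneck / spec$growth,
    compression = spec$compression, taps = 4L,
    n_classes = n_classes, dropout = spec$dropout, head_norm = FALSE)
  build_model(base_spec)
}

#' Count every stored parameter value of a model
#'
#' Sums the lengths of all parameter arrays (convolution kernels,
#' normalization gains/offsets and tracked statistics, classifier weights
#' and biases). This is the "framework" count that must agree with the
#' closed-form [param_ledger()].
#'
#' @param model An `msimf_model`.
#' @return Integer total.
#' @export
model_param_count <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

#' @export
print.msimf_model <- function(x, ...) {
  cat("msimf_model:", x$n_classes, "classes,",
      format(model_param_count(x), big.mark = ","), "parameters\n")
  print(x$spec)
  invisible(x)
}

#' Save / restore model checkpoints
#'
#' @param model An `msimf_model`.
#' @param path Checkpoint file.
#' @return `save_model` returns `path` invisibly; `restore_model` returns
#'   the model with restored parameters.
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               classes = model$classes), path)
  invisible(path)
}

#' @rdname save_model
#' @export
restore_model <- function(model, path) {
  st <- readRDS(path)
  if (!identical(names(st$params), names(model$params))) {
    stop("checkpoint does not match the model architecture")
  }
  model$params <- st$params
  model$classes <- st$classes
  model
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  st <- readRDS(path)
  model <- build_model(st$spec)
  model$params <- st$params
  model$classes <- st$classes
  model
}

bn_apply <- function(model, prefix, x, training, keep,
                     momentum = NULL) {
  if (is.null(momentum)) {
    momentum <- if (is.null(model$bn_momentum)) 0.9 else model$bn_momentum
  }
  p <- model$params
  r <- bn_fwd(x, p[[paste0(prefix, ".gamma")]], p[[paste0(prefix, ".beta")]],
              p[[paste0(prefix, ".rm")]], p[[paste0(prefix, ".rv")]],
              training, momentum = momentum, keep = keep)
  if (training) {
    model$params[[paste0(prefix, ".rm")]] <- r$rm
    model$params[[paste0(prefix, ".rv")]] <- r$rv
  }
  r
}

# Forward pass. x is an [side, side, 3, N] array in [0, 1]. Returns
# logits/probs and, when keep = TRUE, the caches needed by net_backward.
net_forward <- function(model, x, training = FALSE, keep = FALSE) {
  spec <- model$spec
  p <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[3L] != 3L) {
    stop("input must be a [side, side, 3, N] array")
  }
  t <- array_to_tensor(x)
  cache <- list()

  cv <- conv_fwd(t, p[["stem.conv"]], 7L, 2L, 3L, keep = keep)
  cache$stem_conv <- cv$cache
  bn <- bn_apply(model, "stem.bn", cv$out$x, training, keep)
  rl <- relu_fwd(bn$y, keep)
  cache$stem_bn <- bn$cache; cache$stem_relu <- rl$mask
  mp <- maxpool_fwd_cpp(rl$y, cv$out$H, cv$out$W, cv$out$N, 3L, 2L, 1L)
  Ho <- conv_out_side(cv$out$H, 3L, 2L, 1L)
  Wo <- conv_out_side(cv$out$W, 3L, 2L, 1L)
  cache$stem_pool <- list(argmax = mp$argmax, in_cols = ncol(rl$y),
                          H = cv$out$H, W = cv$out$W)
  t <- new_tensor(mp$out, Ho, Wo, cv$out$N)

  tap_vecs <- vector("list", 4L)
  tap_dims <- vector("list", 4L)
  blocks <- vector("list", 4L)
  for (k in 1:4) {
    layers <- vector("list", spec$block_repeats[k])
    for (i in seq_len(spec$block_repeats[k])) {
      pre <- sprintf("b%d.l%d", k, i)
      lc <- list()
      bn1 <- bn_apply(model, paste0(pre, ".bn1"), t$x, training, keep)
      r1 <- relu_fwd(bn1$y, keep)
      c1 <- conv_fwd(new_tensor(r1$y, t$H, t$W, t$N),
                     p[[paste0(pre, ".conv1")]], 1L, 1L, 0L, keep = keep)
      bn2 <- bn_apply(model, paste0(pre, ".bn2"), c1$out$x, training, keep)
      r2 <- relu_fwd(bn2$y, keep)
      c3 <- conv_fwd(new_tensor(r2$y, t$H, t$W, t$N),
                     p[[paste0(pre, ".conv3")]], 3L, 1L, 1L, keep = keep)
      if (keep) {
        lc$bn1 <- bn1$cache; lc$r1 <- r1$mask; lc$c1 <- c1$cache
        lc$bn2 <- bn2$cache; lc$r2 <- r2$mask; lc$c3 <- c3$cache
        layers[[i]] <- lc
      }
      t <- new_tensor(rbind(t$x, c3$out$x), t$H, t$W, t$N)
    }
    bc <- list(layers = layers)
    if (k < 4L) {
      pre <- sprintf("t%d", k)
      bn <- bn_apply(model, paste0(pre, ".bn"), t$x, training, keep)
      rl <- relu_fwd(bn$y, keep)
      cv <- conv_fwd(new_tensor(rl$y, t$H, t$W, t$N),
                     p[[paste0(pre, ".conv")]], 1L, 1L, 0L, keep = keep)
      ap <- avgpool_fwd_cpp(cv$out$x, t$H, t$W, t$N, 2L, 2L)
      Hp <- (t$H - 2L) %/% 2L + 1L
      Wp <- (t$W - 2L) %/% 2L + 1L
      if (keep) {
        bc$trans <- list(bn = bn$cache, relu = rl$mask, conv = cv$cache,
                         pool_in = c(H = t$H, W = t$W, N = t$N))
      }
      t <- new_tensor(ap, Hp, Wp, t$N)
      tap_src <- t
    } else {
      bn <- bn_apply(model, "final.bn", t$x, training, keep)
      rl <- relu_fwd(bn$y, keep)
      if (keep) bc$final <- list(bn = bn$cache, relu = rl$mask)
      tap_src <- new_tensor(rl$y, t$H, t$W, t$N)
    }
    blocks[[k]] <- bc
    tap_dims[[k]] <- c(H = tap_src$H, W = tap_src$W, N = tap_src$N,
                       C = nrow(tap_src$x))
    tap_vecs[[k]] <- if (k %in% spec$taps) gap_fwd(tap_src)
  }
  cache$blocks <- blocks
  cache$tap_dims <- tap_dims

  fused <- do.call(rbind, tap_vecs[spec$taps])
  dp <- dropout_fwd(fused, spec$dropout, training)
  cache$dropout <- dp$mask
  h <- dp$y
  if (spec$head_norm) {
    bn <- bn_apply(model, "head.bn", h, training, keep)
    cache$head_bn <- bn$cache
    h <- bn$y
  }
  logits <- p[["head.fc.W"]] %*% h + p[["head.fc.b"]]
  probs <- softmax_cols(logits)
  cache$head_in <- if (keep) h
  list(logits = logits, probs = probs, fused = fused,
       tap_dims = tap_dims, cache = if (keep) cache)
}

# Backward pass from dlogits (n_classes x N); returns named gradients for
# every trainable parameter.
net_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  p <- model$params
  g <- list()

  g[["head.fc.W"]] <- dlogits %*% t(cache$head_in)
  g[["head.fc.b"]] <- rowSums(dlogits)
  dh <- crossprod(p[["head.fc.W"]], dlogits)
  if (spec$head_norm) {
    bb <- bn_bwd(dh, cache$head_bn)
    g[["head.bn.gamma"]] <- bb$dgamma
    g[["head.bn.beta"]] <- bb$dbeta
    dh <- bb$dx
  }
  if (!is.null(cache$dropout)) dh <- dh * cache$dropout

  # split fused gradient into per-tap segments
  dtap <- vector("list", 4L)
  off <- 0L
  for (k in spec$taps) {
    w <- spec$tap_widths[k]
    dtap[[k]] <- dh[(off + 1L):(off + w), , drop = FALSE]
    off <- off + w
  }

  dmain <- NULL  # gradient flowing into the output of block k's stage
  for (k in 4:1) {
    td <- cache$tap_dims[[k]]
    dstage <- if (!is.null(dtap[[k]])) {
      gap_bwd(dtap[[k]], td[["H"]], td[["W"]], td[["N"]])
    } else {
      matrix(0, td[["C"]], td[["H"]] * td[["W"]] * td[["N"]])
    }
    if (!is.null(dmain)) dstage <- dstage + dmain
    bc <- cache$blocks[[k]]

    if (k < 4L) {
      pre <- sprintf("t%d", k)
      pi <- bc$trans$pool_in
      dap <- avgpool_bwd_cpp(dstage, pi[["H"]], pi[["W"]], pi[["N"]], 2L, 2L)
      cb <- conv_bwd(dap, bc$trans$conv, p[[paste0(pre, ".conv")]])
      g[[paste0(pre, ".conv")]] <- cb$dW
      drl <- cb$dx * bc$trans$relu
      bb <- bn_bwd(drl, bc$trans$bn)
      g[[paste0(pre, ".bn.gamma")]] <- bb$dgamma
      g[[paste0(pre, ".bn.beta")]] <- bb$dbeta
      dx <- bb$dx
    } else {
      drl <- dstage * bc$final$relu
      bb <- bn_bwd(drl, bc$final$bn)
      g[["final.bn.gamma"]] <- bb$dgamma
      g[["final.bn.beta"]] <- bb$dbeta
      dx <- bb$dx
    }

    for (i in rev(seq_len(spec$block_repeats[k]))) {
      pre <- sprintf("b%d.l%d", k, i)
      lc <- bc$layers[[i]]
      c_prev <- spec$block_in[k] + spec$growth * (i - 1L)
      dprev <- dx[seq_len(c_prev), , drop = FALSE]
      dg <- dx[(c_prev + 1L):(c_prev + spec$growth), , drop = FALSE]

      cb3 <- conv_bwd(dg, lc$c3, p[[paste0(pre, ".conv3")]])
      g[[paste0(pre, ".conv3")]] <- cb3$dW
      dr2 <- cb3$dx * lc$r2
      bb2 <- bn_bwd(dr2, lc$bn2)
      g[[paste0(pre, ".bn2.gamma")]] <- bb2$dgamma
      g[[paste0(pre, ".bn2.beta")]] <- bb2$dbeta
      cb1 <- conv_bwd(bb2$dx, lc$c1, p[[paste0(pre, ".conv1")]])
      g[[paste0(pre, ".conv1")]] <- cb1$dW
      dr1 <- cb1$dx * lc$r1
      bb1 <- bn_bwd(dr1, lc$bn1)
      g[[paste0(pre, ".bn1.gamma")]] <- bb1$dgamma
      g[[paste0(pre, ".bn1.beta")]] <- bb1$dbeta
      dx <- dprev + bb1$dx
    }
    dmain <- if (k > 1L) dx else NULL
  }
  # stem
  sp <- cache$stem_pool
  dmp <- maxpool_bwd_cpp(dx, sp$argmax, sp$in_cols)
  drl <- dmp * cache$stem_relu
  bb <- bn_bwd(drl, cache$stem_bn)
  g[["stem.bn.gamma"]] <- bb$dgamma
  g[["stem.bn.beta"]] <- bb$dbeta
  cb <- conv_bwd(bb$dx, cache$stem_conv, p[["stem.conv"]])
  g[["stem.conv"]] <- cb$dW
  g
}

#' Refresh batch-normalization statistics under the current weights
#'
#' Normalization layers track running mean/variance with exponential
#' averaging; after a short training run those statistics still reflect
#' early, very different weights. This pass re-estimates them by running
#' shuffled training batches forward in training mode (weights
#' untouched) with a faster-tracking momentum, the usual "precise"
#' normalization-statistics correction. [train_patchwise()] calls this
#' automatically at the end of training.
#'
#' @param model An `msimf_model`.
#' @param x Training patches, `[side, side, 3, N]`.
#' @param batch_size Batch size for the refresh passes.
#' @param passes Number of passes over the data.
#' @return The model, invisibly (statistics updated in place).
#' @export
recalibrate_bn <- function(model, x, batch_size = 32L, passes = 3L) {
  n <- dim(x)[4L]
  model$bn_momentum <- 0.5
  on.exit(model$bn_momentum <- NULL)
  for (p in seq_len(passes)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      if (length(idx) < 2L) next
      net_forward(model, x[, , , idx, drop = FALSE], training = TRUE,
                  keep = FALSE)
    }
  }
  invisible(model)
}

#' Class probabilities for a batch of patches
#'
#' @param model An `msimf_model`.
#' @param x An `[side, side, 3, N]` array of patches in `[0, 1]`.
#' @param batch_size Patches per forward pass.
#' @return An `N x n_classes` probability matrix (rows sum to 1).
#' @export
model_predict <- function(model, x, batch_size = 32L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4L]
  out <- matrix(NA_real_, n, model$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- net_forward(model, x[, , , i:j, drop = FALSE],
                      training = FALSE, keep = FALSE)
    out[i:j, ] <- t(fw$probs)
    i <- j + 1L
  }
  out
}
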