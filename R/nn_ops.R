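# Low-level tensor ops for the network. Activations live as C x (H*W*N)
# matrices (one row per channel; columns ordered h, then w, then image)
# so channel concatenation in dense blocks is a plain rbind and the
# convolution GEMM runs through BLAS on an im2col patch matrix.

new_tensor <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

# [H, W, C, N] array (values in [0, 1]) -> internal tensor
array_to_tensor <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 4L)
  x <- aperm(a, c(3L, 1L, 2L, 4L))
  dim(x) <- c(d[3L], d[1L] * d[2L] * d[4L])
  new_tensor(x, d[1L], d[2L], d[4L])
}

conv_out_side <- function(side, k, stride, pad) {
  (side + 2L * pad - k) %/% stride + 1L
}

conv_fwd <- function(t, w, k, stride, pad, keep = TRUE) {
  cols <- im2col_cpp(t$x, t$H, t$W, t$N, k, stride, pad)
  Ho <- conv_out_side(t$H, k, stride, pad)
  Wo <- conv_out_side(t$W, k, stride, pad)
  out <- new_tensor(w %*% cols, Ho, Wo, t$N)
  cache <- if (keep) {
    list(cols = cols, H = t$H, W = t$W, N = t$N, C = nrow(t$x),
         k = k, stride = stride, pad = pad)
  }
  list(out = out, cache = cache)
}

conv_bwd <- function(dy, cache, w) {
  dW <- dy %*% t(cache$cols)
  dcols <- crossprod(w, dy)
  dx <- col2im_cpp(dcols, cache$C, cache$H, cache$W, cache$N,
                   cache$k, cache$stride, cache$pad)
  list(dx = dx, dW = dW)
}

# Batch normalization over all spatial positions and images per channel.
# Running statistics use exponential averaging (momentum 0.9); the
# accounting convention throughout the package counts 4 values per
# channel: gamma, beta and the two tracked statistics.
bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.9,
                   eps = 1e-5, keep = TRUE) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * invstd
    rm_new <- momentum * rm + (1 - momentum) * mu
    rv_new <- momentum * rv + (1 - momentum) * v
  } else {
    invstd <- 1 / sqrt(rv + eps)
    xhat <- (x - rm) * invstd
    rm_new <- rm
    rv_new <- rv
  }
  y <- gamma * xhat + beta
  cache <- if (keep) list(xhat = xhat, invstd = invstd, gamma = gamma)
  list(y = y, cache = cache, rm = rm_new, rv = rv_new)
}

bn_bwd <- function(dy, cache) {
  L <- ncol(dy)
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- (cache$invstd / L) * (L * dxhat - rowSums(dxhat) - xhat * dgamma)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x, keep = TRUE) {
  mask <- x > 0
  list(y = x * mask, mask = if (keep) mask)
}

gap_fwd <- function(t) {
  hw <- t$H * t$W
  y <- vapply(seq_len(t$N), function(n) {
    idx <- ((n - 1L) * hw + 1L):(n * hw)
    rowMeans(t$x[, idx, drop = FALSE])
  }, numeric(nrow(t$x)))
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(t$x))
  y
}

gap_bwd <- function(dy, H, W, N) {
  hw <- H * W
  dy[, rep(seq_len(N), each = hw), drop = FALSE] / hw
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- matrix(runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Mean cross-entropy over a batch; y_onehot is n_classes x N.
cross_entropy <- function(probs, y_onehot, eps = 1e-12) {
  -mean(colSums(y_onehot * log(probs + eps)))
}
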