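# The six optimizers of the tuning grid. State is kept per parameter in
# model$opt_state; all follow the conventional update rules with the
# usual default decay constants.

opt_defaults <- list(
  SGD      = list(momentum = 0.9),
  RMSprop  = list(rho = 0.9, eps = 1e-7),
  Adadelta = list(rho = 0.95, eps = 1e-7),
  Adam     = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-7),
  Adamax   = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-7),
  Nadam    = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-7)
)

optimizer_names <- function() names(opt_defaults)

apply_gradients <- function(model, grads, optimizer, lr) {
  hp <- opt_defaults[[optimizer]]
  if (is.null(hp)) stop("unknown optimizer: ", optimizer)
  st <- model$opt_state
  if (is.null(st$t)) st$t <- 0L
  st$t <- st$t + 1L
  t_ <- st$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    w <- model$params[[nm]]
    s <- st[[nm]]
    if (is.null(s)) s <- list()
    upd <- switch(optimizer,
      SGD = {
        v <- if (is.null(s$v)) 0 else s$v
        v <- hp$momentum * v - lr * gr
        s$v <- v
        v
      },
      RMSprop = {
        a <- if (is.null(s$a)) 0 else s$a
        a <- hp$rho * a + (1 - hp$rho) * gr^2
        s$a <- a
        -lr * gr / (sqrt(a) + hp$eps)
      },
      Adadelta = {
        a <- if (is.null(s$a)) 0 else s$a
        d <- if (is.null(s$d)) 0 else s$d
        a <- hp$rho * a + (1 - hp$rho) * gr^2
        step <- -sqrt(d + hp$eps) / sqrt(a + hp$eps) * gr * lr
        d <- hp$rho * d + (1 - hp$rho) * step^2
        s$a <- a; s$d <- d
        step
      },
      Adam = {
        m <- if (is.null(s$m)) 0 else s$m
        v <- if (is.null(s$v)) 0 else s$v
        m <- hp$beta1 * m + (1 - hp$beta1) * gr
        v <- hp$beta2 * v + (1 - hp$beta2) * gr^2
        s$m <- m; s$v <- v
        mhat <- m / (1 - hp$beta1^t_)
        vhat <- v / (1 - hp$beta2^t_)
        -lr * mhat / (sqrt(vhat) + hp$eps)
      },
      Adamax = {
        m <- if (is.null(s$m)) 0 else s$m
        u <- if (is.null(s$u)) 0 else s$u
        m <- hp$beta1 * m + (1 - hp$beta1) * gr
        u <- pmax(hp$beta2 * u, abs(gr))
        s$m <- m; s$u <- u
        -lr / (1 - hp$beta1^t_) * m / (u + hp$eps)
      },
      Nadam = {
        m <- if (is.null(s$m)) 0 else s$m
        v <- if (is.null(s$v)) 0 else s$v
        m <- hp$beta1 * m + (1 - hp$beta1) * gr
        v <- hp$beta2 * v + (1 - hp$beta2) * gr^2
        s$m <- m; s$v <- v
        mhat <- m / (1 - hp$beta1^(t_ + 1L))
        vhat <- v / (1 - hp$beta2^t_)
        -lr * (hp$beta1 * mhat + (1 - hp$beta1) * gr / (1 - hp$beta1^t_)) /
          (sqrt(vhat) + hp$eps)
      })
    model$params[[nm]] <- w + upd
    st[[nm]] <- s
  }
  model$opt_state <- st
  invisible(model)
}
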