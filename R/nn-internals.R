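# Small dense neural-network machinery shared by the feature-based
# importance model and the triple language model.  Full-batch training
# with Adam; everything is plain matrix algebra so runs are exactly
# reproducible for a fixed seed on a given BLAS.

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fully connected net: `hidden` ReLU layers, linear scalar output
# (sigmoid applied by the caller).  X is n x p, y in {0,1}.
mlp_train_binary <- function(X, y, hidden, epochs = 200L, lr = 0.01,
                             dropout = 0, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  with_local_seed(seed, {
    sizes <- c(ncol(X), hidden, 1L)
    L <- length(sizes) - 1L
    W <- lapply(seq_len(L), function(l) he_init(sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    params <- c(W, b)
    st <- adam_new(params)
    n <- nrow(X)
    loss_traj <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      W <- params[seq_len(L)]
      b <- params[L + seq_len(L)]
      # forward
      act <- vector("list", L + 1L)
      mask <- vector("list", L)
      act[[1]] <- X
      for (l in seq_len(L)) {
        z <- act[[l]] %*% W[[l]]
        z <- sweep(z, 2, b[[l]], "+")
        if (l < L) {
          a <- relu(z)
          if (dropout > 0) {
            m <- matrix(stats::rbinom(length(a), 1L, 1 - dropout),
                        nrow(a), ncol(a)) / (1 - dropout)
            a <- a * m
            mask[[l]] <- m
          }
          act[[l + 1]] <- a
        } else {
          act[[l + 1]] <- z
        }
      }
      p <- sigmoid(act[[L + 1]][, 1])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss_traj[ep] <- -mean(y * log(p) + (1 - y) * log(1 - p))
      # backward: d(BCE)/dz_out = (p - y)/n
      delta <- matrix((p - y) / n, ncol = 1)
      gW <- vector("list", L)
      gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(act[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          if (dropout > 0 && !is.null(mask[[l - 1]])) delta <- delta * mask[[l - 1]]
          delta <- delta * (act[[l]] > 0)
        }
      }
      upd <- adam_step(params, c(gW, gb), st, lr = lr)
      params <- upd$params
      st <- upd$state
    }
    list(W = params[seq_len(L)], b = params[L + seq_len(L)],
         sizes = sizes, loss = loss_traj)
  })
}

mlp_predict_binary <- function(net, X) {
  L <- length(net$W)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- if (l < L) relu(z) else z
  }
  sigmoid(a[, 1])
}
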