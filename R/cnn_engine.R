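# Internal CNN engine. Tensors are numeric arrays in (height, width,
# channels, batch) order. Convolutions use zero-padded "same" mode with
# stride 1, implemented by im2col + one BLAS matrix multiply; pooling is
# 2x2 average with floor semantics (a trailing odd row/column is unused).
# Nothing here is exported; fit_gait_cnn() is the public surface.

# im2col for same-padding convolution: returns (H*W*N) x (kh*kw*C) matrix
# whose column order matches the flattening of the kernel array produced by
# aperm(kernel, c(3, 1, 2, 4)) -> (C, kh, kw, F): channel fastest, then
# kernel row, then kernel column.
im2col_same <- function(X, kh, kw) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  P <- array(0, c(H + kh - 1L, W + kw - 1L, C, N))
  P[ph + seq_len(H), pw + seq_len(W), , ] <- X
  cols <- vector("list", kh * kw)
  i <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      i <- i + 1L
      S <- P[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      S <- aperm(S, c(1L, 2L, 4L, 3L))
      dim(S) <- c(H * W * N, C)
      cols[[i]] <- S
    }
  }
  do.call(cbind, cols)
}

# scatter-add inverse of im2col_same: dXcol (H*W*N) x (kh*kw*C) -> dX like X
col2im_same <- function(dXcol, dimX, kh, kw) {
  H <- dimX[1L]; W <- dimX[2L]; C <- dimX[3L]; N <- dimX[4L]
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  dP <- array(0, c(H + kh - 1L, W + kw - 1L, C, N))
  i <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      block <- dXcol[, (i * C + 1L):((i + 1L) * C), drop = FALSE]
      i <- i + 1L
      dim(block) <- c(H, W, N, C)
      block <- aperm(block, c(1L, 2L, 4L, 3L))
      ri <- di:(di + H - 1L); cj <- dj:(dj + W - 1L)
      dP[ri, cj, , ] <- dP[ri, cj, , , drop = FALSE] + block
    }
  }
  dP[ph + seq_len(H), pw + seq_len(W), , , drop = FALSE]
}

conv_forward <- function(X, kernel, bias) {
  d <- dim(X); kd <- dim(kernel)
  kh <- kd[1L]; kw <- kd[2L]; F <- kd[4L]
  Xcol <- im2col_same(X, kh, kw)
  Wmat <- aperm(kernel, c(3L, 1L, 2L, 4L))
  dim(Wmat) <- c(kh * kw * kd[3L], F)
  Y <- Xcol %*% Wmat
  Y <- sweep(Y, 2L, bias, `+`)
  dim(Y) <- c(d[1L], d[2L], d[4L], F)
  list(out = aperm(Y, c(1L, 2L, 4L, 3L)), Xcol = Xcol, Wmat = Wmat,
       dimX = d)
}

conv_backward <- function(cache, dY) {
  kd <- dim(cache$Wmat)   # (kh*kw*C) x F
  d <- dim(dY)            # (H, W, F, N)
  dYmat <- aperm(dY, c(1L, 2L, 4L, 3L))
  dim(dYmat) <- c(d[1L] * d[2L] * d[4L], d[3L])
  dWmat <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- tcrossprod(dYmat, cache$Wmat)
  list(dWmat = dWmat, db = db, dXcol = dXcol)
}

avgpool_forward <- function(X) {
  d <- dim(X)
  H2 <- d[1L] %/% 2L; W2 <- d[2L] %/% 2L
  ri <- seq.int(1L, 2L * H2, 2L); cj <- seq.int(1L, 2L * W2, 2L)
  Y <- (X[ri, cj, , , drop = FALSE] + X[ri + 1L, cj, , , drop = FALSE] +
          X[ri, cj + 1L, , , drop = FALSE] +
          X[ri + 1L, cj + 1L, , , drop = FALSE]) / 4
  list(out = Y, dimX = d)
}

avgpool_backward <- function(cache, dY) {
  d <- cache$dimX
  H2 <- dim(dY)[1L]; W2 <- dim(dY)[2L]
  ri <- seq.int(1L, 2L * H2, 2L); cj <- seq.int(1L, 2L * W2, 2L)
  dX <- array(0, d)
  g <- dY / 4
  dX[ri, cj, , ] <- g
  dX[ri + 1L, cj, , ] <- g
  dX[ri, cj + 1L, , ] <- g
  dX[ri + 1L, cj + 1L, , ] <- g
  dX
}

softmax_cols <- function(Z) {
  m <- do.call(pmax, lapply(seq_len(nrow(Z)), function(k) Z[k, ]))
  E <- exp(sweep(Z, 2L, m))
  sweep(E, 2L, colSums(E), `/`)
}

# initialize weights (He-normal) for the given architecture; returns the
# parameter list plus per-layer spatial shapes and the total parameter count
init_network <- function(config, input_shape, seed) {
  kh <- config$filter_shape[1L]; kw <- config$filter_shape[2L]
  filt <- config$filters_per_layer
  with_seed(seed, {
    H <- input_shape[1L]; W <- input_shape[2L]; C <- 1L
    conv <- vector("list", config$n_conv_layers)
    shapes <- character(0)
    for (l in seq_len(config$n_conv_layers)) {
      Fl <- filt[l]
      fan_in <- kh * kw * C
      conv[[l]] <- list(
        kernel = array(stats::rnorm(kh * kw * C * Fl, 0, sqrt(2 / fan_in)),
                       c(kh, kw, C, Fl)),
        bias = numeric(Fl))
      shapes <- c(shapes, sprintf("conv%d %dx%dx%d -> %dx%dx%d", l, H, W, C,
                                  H, W, Fl))
      C <- Fl
      if (H %/% 2L < 1L || W %/% 2L < 1L) {
        stop("input shape ", input_shape[1L], "x", input_shape[2L],
             " incompatible with pooling at layer ", l,
             ": feature map is ", H, "x", W, call. = FALSE)
      }
      H <- H %/% 2L; W <- W %/% 2L
      shapes <- c(shapes, sprintf("pool%d -> %dx%dx%d", l, H, W, C))
    }
    flat <- H * W * C
    du <- config$dense_units
    K <- config$n_classes
    dense1 <- list(W = matrix(stats::rnorm(du * flat, 0, sqrt(2 / flat)),
                              du, flat),
                   b = numeric(du))
    dense2 <- list(W = matrix(stats::rnorm(K * du, 0, sqrt(2 / du)), K, du),
                   b = numeric(K))
    n_params <- sum(vapply(conv, function(l)
      length(l$kernel) + length(l$bias), numeric(1))) +
      length(dense1$W) + du + length(dense2$W) + K
    list(conv = conv, dense1 = dense1, dense2 = dense2,
         flat_dim = flat, shapes = shapes, n_params = n_params)
  })
}

# forward pass; training = TRUE applies inverted dropout and keeps caches
net_forward <- function(net, config, X, training = FALSE, dropout_mask = NULL) {
  caches <- list()
  A <- X
  for (l in seq_along(net$conv)) {
    cf <- conv_forward(A, net$conv[[l]]$kernel, net$conv[[l]]$bias)
    relu_mask <- cf$out > 0
    A <- cf$out * relu_mask
    pf <- avgpool_forward(A)
    caches[[l]] <- list(conv = cf, relu = relu_mask, pool = pf)
    A <- pf$out
  }
  N <- dim(A)[4L]
  Aflat <- A
  dim(Aflat) <- c(net$flat_dim, N)
  Z1 <- net$dense1$W %*% Aflat + net$dense1$b
  H1 <- Z1 * (Z1 > 0)
  if (training && config$dropout_rate > 0) {
    H1 <- H1 * dropout_mask / (1 - config$dropout_rate)
  }
  Z2 <- net$dense2$W %*% H1 + net$dense2$b
  P <- softmax_cols(Z2)
  list(probs = P, caches = caches, Aflat = Aflat, Z1 = Z1, H1 = H1,
       pooled_dim = dim(A))
}

# backward pass from softmax cross-entropy; y_idx in 1..K; returns gradients
net_backward <- function(net, config, fwd, y_idx, dropout_mask = NULL) {
  N <- length(y_idx)
  dZ2 <- fwd$probs
  dZ2[cbind(y_idx, seq_len(N))] <- dZ2[cbind(y_idx, seq_len(N))] - 1
  dZ2 <- dZ2 / N
  g <- list()
  g$dense2 <- list(W = tcrossprod(dZ2, fwd$H1), b = rowSums(dZ2))
  dH1 <- crossprod(net$dense2$W, dZ2)
  if (config$dropout_rate > 0 && !is.null(dropout_mask)) {
    dH1 <- dH1 * dropout_mask / (1 - config$dropout_rate)
  }
  dZ1 <- dH1 * (fwd$Z1 > 0)
  g$dense1 <- list(W = tcrossprod(dZ1, fwd$Aflat), b = rowSums(dZ1))
  dA <- crossprod(net$dense1$W, dZ1)
  dim(dA) <- fwd$pooled_dim
  g$conv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    cache <- fwd$caches[[l]]
    dA <- avgpool_backward(cache$pool, dA)
    dA <- dA * cache$relu
    cb <- conv_backward(cache$conv, dA)
    kd <- dim(net$conv[[l]]$kernel)
    dW <- cb$dWmat
    dim(dW) <- c(kd[3L], kd[1L], kd[2L], kd[4L])
    g$conv[[l]] <- list(kernel = aperm(dW, c(2L, 3L, 1L, 4L)), b = cb$db)
    if (l > 1L) {
      dA <- col2im_same(cb$dXcol, cache$conv$dimX, kd[1L], kd[2L])
    }
  }
  g
}

# flatten parameters/gradients to a list of numeric objects for Adam
net_param_list <- function(net) {
  out <- list()
  for (l in seq_along(net$conv)) {
    out[[paste0("conv", l, ".k")]] <- net$conv[[l]]$kernel
    out[[paste0("conv", l, ".b")]] <- net$conv[[l]]$bias
  }
  out$dense1.W <- net$dense1$W; out$dense1.b <- net$dense1$b
  out$dense2.W <- net$dense2$W; out$dense2.b <- net$dense2$b
  out
}

grad_param_list <- function(g) {
  out <- list()
  for (l in seq_along(g$conv)) {
    out[[paste0("conv", l, ".k")]] <- g$conv[[l]]$kernel
    out[[paste0("conv", l, ".b")]] <- g$conv[[l]]$b
  }
  out$dense1.W <- g$dense1$W; out$dense1.b <- g$dense1$b
  out$dense2.W <- g$dense2$W; out$dense2.b <- g$dense2$b
  out
}

net_set_params <- function(net, params) {
  for (l in seq_along(net$conv)) {
    net$conv[[l]]$kernel <- params[[paste0("conv", l, ".k")]]
    net$conv[[l]]$bias <- params[[paste0("conv", l, ".b")]]
  }
  net$dense1$W <- params$dense1.W; net$dense1$b <- params$dense1.b
  net$dense2$W <- params$dense2.W; net$dense2$b <- params$dense2.b
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# cross-entropy loss and accuracy from probability columns
ce_loss_acc <- function(P, y_idx) {
  N <- length(y_idx)
  p_true <- pmax(P[cbind(y_idx, seq_len(N))], 1e-12)
  pred <- max.col(t(P), ties.method = "first")
  list(loss = -mean(log(p_true)), acc = mean(pred == y_idx))
}

# forward the whole set in chunks (no dropout); returns K x N probabilities
net_predict_probs <- function(net, config, X, chunk = 1024L) {
  N <- dim(X)[4L]
  K <- config$n_classes
  P <- matrix(0, K, N)
  for (s in seq.int(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    fwd <- net_forward(net, config, X[, , , s:e, drop = FALSE],
                       training = FALSE)
    P[, s:e] <- fwd$probs
  }
  P
}
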