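## Neural-network primitives.
##
## Minimal dense / highway-gating / LSTM / convolution layers with
## hand-derived backpropagation on base-R matrix ops (BLAS does the work).
## Batched sequence data is held as (N, T, C) arrays; because N is the
## fastest-varying index, `dim<-` reshapes between the array and the
## (N*T) x C matrix view without copying. Per-timestep quantities use the
## row grouping tidx = rep(1:T, each = N).

flat2 <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1L] * d[2L], d[3L])
  A
}

unflat2 <- function(M, N, T) {
  dim(M) <- c(N, T, ncol(M))
  M
}

slice_t <- function(A, t) matrix(A[, t, ], nrow = dim(A)[1L])

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

## ---- time-distributed dense -------------------------------------------------

init_dense <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

dense_fwd <- function(M, p, act = c("linear", "relu", "sigmoid")) {
  act <- match.arg(act)
  A <- M %*% p$W
  A <- sweep(A, 2L, p$b, "+")
  Y <- switch(act, linear = A, relu = relu(A), sigmoid = sigmoid(A))
  list(out = Y, cache = list(M = M, A = A, Y = Y, act = act))
}

dense_bwd <- function(dY, cache, p) {
  dA <- switch(cache$act,
               linear = dY,
               relu = dY * (cache$A > 0),
               sigmoid = dY * cache$Y * (1 - cache$Y))
  list(dM = dA %*% t(p$W),
       grads = list(W = crossprod(cache$M, dA), b = colSums(dA)))
}

## ---- highway gating block ---------------------------------------------------
## Per timestep t: g = sigmoid(x W_G + b_G[t]); h = relu(x W_T + b_T[t]);
## out = g*h + (1-g)*x. The biases are per-timestep (T x d) so the trainable
## count is 2*(d^2 + T*d).

init_highway <- function(d, T) {
  list(WG = glorot(d, d), BG = matrix(0, T, d),
       WT = glorot(d, d), BT = matrix(0, T, d))
}

highway_fwd <- function(M, tidx, p) {
  AG <- M %*% p$WG + p$BG[tidx, , drop = FALSE]
  G <- sigmoid(AG)
  AT <- M %*% p$WT + p$BT[tidx, , drop = FALSE]
  H <- relu(AT)
  Y <- G * H + (1 - G) * M
  list(out = Y, cache = list(M = M, G = G, H = H, mask = AT > 0, tidx = tidx))
}

highway_bwd <- function(dY, cache, p) {
  G <- cache$G; H <- cache$H; M <- cache$M
  dG <- dY * (H - M)
  dAT <- (dY * G) * cache$mask
  dAG <- dG * G * (1 - G)
  dM <- dY * (1 - G) + dAG %*% t(p$WG) + dAT %*% t(p$WT)
  list(dM = dM,
       grads = list(WG = crossprod(M, dAG), BG = rowsum(dAG, cache$tidx),
                    WT = crossprod(M, dAT), BT = rowsum(dAT, cache$tidx)))
}

## Trainable scalars in one gating block of width d over T timesteps.
highway_param_count <- function(d, T) 2 * (d^2 + T * d)

## ---- LSTM -------------------------------------------------------------------
## Standard 4-gate recurrence; gate order i, f, g, o. Forget-gate bias starts
## at 1. Trainable count = 4*u*(d_in + u + 1).

init_lstm <- function(d_in, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget bias
  list(W = glorot(d_in, 4L * units, c(d_in, 4L * units)),
       U = glorot(units, 4L * units, c(units, 4L * units)),
       b = b)
}

lstm_param_count <- function(d_in, units) 4 * units * (d_in + units + 1)

lstm_fwd <- function(A, p) {
  N <- dim(A)[1L]; T <- dim(A)[2L]
  u <- length(p$b) / 4L
  ii <- seq_len(u); fi <- u + ii; gi <- 2L * u + ii; oi <- 3L * u + ii
  h <- matrix(0, N, u); cc <- matrix(0, N, u)
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    x <- slice_t(A, t)
    Z <- x %*% p$W + h %*% p$U
    Z <- sweep(Z, 2L, p$b, "+")
    i_g <- sigmoid(Z[, ii, drop = FALSE])
    f_g <- sigmoid(Z[, fi, drop = FALSE])
    g_g <- tanh(Z[, gi, drop = FALSE])
    o_g <- sigmoid(Z[, oi, drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    cache[[t]] <- list(x = x, i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = h, cache = cache, dims = c(N = N, T = T, u = u))
}

lstm_bwd <- function(dH, fw, p) {
  N <- fw$dims[["N"]]; T <- fw$dims[["T"]]; u <- fw$dims[["u"]]
  d_in <- nrow(p$W)
  dW <- matrix(0, d_in, 4L * u); dU <- matrix(0, u, 4L * u); db <- numeric(4L * u)
  dA <- array(0, c(N, T, d_in))
  dh <- dH; dc <- matrix(0, N, u)
  for (t in rev(seq_len(T))) {
    cs <- fw$cache[[t]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    df <- dc * cs$c_prev
    dg <- dc * cs$i
    dZ <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do_ * cs$o * (1 - cs$o))
    dW <- dW + crossprod(cs$x, dZ)
    dU <- dU + crossprod(cs$h_prev, dZ)
    db <- db + colSums(dZ)
    dA[, t, ] <- dZ %*% t(p$W)
    dh <- dZ %*% t(p$U)
    dc <- dc * cs$f
  }
  list(dA = dA, grads = list(W = dW, U = dU, b = db))
}

reverse_time <- function(A) A[, rev(seq_len(dim(A)[2L])), , drop = FALSE]

## ---- 1-D and 2-D convolution (valid padding, stride 1) ----------------------

init_conv1d <- function(k, c_in, filters) {
  list(W = glorot(k * c_in, filters, c(k * c_in, filters)), b = numeric(filters),
       k = k, c_in = c_in)
}

conv1d_fwd <- function(A, p) {
  N <- dim(A)[1L]; T <- dim(A)[2L]; C <- dim(A)[3L]; k <- p$k
  T_out <- T - k + 1L
  if (T_out < 1L) stopf("sequence of length %d too short for kernel %d", T, k)
  Xcol <- array(0, c(N, T_out, k * C))
  for (j in seq_len(k))
    Xcol[, , ((j - 1L) * C + 1L):(j * C)] <- A[, j:(T_out + j - 1L), , drop = FALSE]
  M <- flat2(Xcol)
  A_pre <- sweep(M %*% p$W, 2L, p$b, "+")
  Y <- relu(A_pre)
  list(out = unflat2(Y, N, T_out),
       cache = list(M = M, mask = A_pre > 0, N = N, T = T, T_out = T_out, C = C))
}

conv1d_bwd <- function(dOut, cache, p) {
  k <- p$k; C <- cache$C
  dY <- flat2(dOut) * cache$mask
  dM <- dY %*% t(p$W)
  dXcol <- unflat2(dM, cache$N, cache$T_out)
  dA <- array(0, c(cache$N, cache$T, C))
  for (j in seq_len(k))
    dA[, j:(cache$T_out + j - 1L), ] <- dA[, j:(cache$T_out + j - 1L), ,
                                           drop = FALSE] +
      dXcol[, , ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  list(dA = dA, grads = list(W = crossprod(cache$M, dY), b = colSums(dY)))
}

init_conv2d <- function(k, c_in, filters) {
  list(W = glorot(k * k * c_in, filters, c(k * k * c_in, filters)),
       b = numeric(filters), k = k, c_in = c_in)
}

flat3 <- function(A4) {
  d <- dim(A4)
  dim(A4) <- c(d[1L] * d[2L] * d[3L], d[4L])
  A4
}

unflat3 <- function(M, N, P, Q) {
  dim(M) <- c(N, P, Q, ncol(M))
  M
}

conv2d_fwd <- function(A, p) {
  d <- dim(A); N <- d[1L]; H <- d[2L]; W_ <- d[3L]; C <- d[4L]; k <- p$k
  H_out <- H - k + 1L; W_out <- W_ - k + 1L
  if (H_out < 1L || W_out < 1L) stopf("input %dx%d too small for kernel %d", H, W_, k)
  Xcol <- array(0, c(N, H_out, W_out, k * k * C))
  s <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Xcol[, , , (s * C + 1L):((s + 1L) * C)] <-
      A[, i:(H_out + i - 1L), j:(W_out + j - 1L), , drop = FALSE]
    s <- s + 1L
  }
  M <- flat3(Xcol)
  A_pre <- sweep(M %*% p$W, 2L, p$b, "+")
  Y <- relu(A_pre)
  list(out = unflat3(Y, N, H_out, W_out),
       cache = list(M = M, mask = A_pre > 0, N = N, H = H, W = W_, C = C,
                    H_out = H_out, W_out = W_out))
}

conv2d_bwd <- function(dOut, cache, p) {
  k <- p$k; C <- cache$C
  dY <- flat3(dOut) * cache$mask
  dM <- dY %*% t(p$W)
  dXcol <- unflat3(dM, cache$N, cache$H_out, cache$W_out)
  dA <- array(0, c(cache$N, cache$H, cache$W, C))
  s <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    blk <- dXcol[, , , (s * C + 1L):((s + 1L) * C), drop = FALSE]
    dA[, i:(cache$H_out + i - 1L), j:(cache$W_out + j - 1L), ] <-
      dA[, i:(cache$H_out + i - 1L), j:(cache$W_out + j - 1L), , drop = FALSE] + blk
    s <- s + 1L
  }
  list(dA = dA, grads = list(W = crossprod(cache$M, dY), b = colSums(dY)))
}

## ---- max pooling (width 2, stride 2) ----------------------------------------

maxpool1d_fwd <- function(A) {
  T <- dim(A)[2L]; T_out <- T %/% 2L
  A1 <- A[, seq(1L, 2L * T_out, 2L), , drop = FALSE]
  A2 <- A[, seq(2L, 2L * T_out, 2L), , drop = FALSE]
  take1 <- A1 >= A2
  list(out = ifelse(take1, A1, A2), cache = list(take1 = take1, T = T, T_out = T_out))
}

maxpool1d_bwd <- function(dOut, cache) {
  d <- dim(dOut)
  dA <- array(0, c(d[1L], cache$T, d[3L]))
  dA[, seq(1L, 2L * cache$T_out, 2L), ] <- dOut * cache$take1
  dA[, seq(2L, 2L * cache$T_out, 2L), ] <- dOut * !cache$take1
  dA
}

maxpool2d_fwd <- function(A) {
  d <- dim(A)
  H_out <- d[2L] %/% 2L; W_out <- d[3L] %/% 2L
  hs <- seq(1L, 2L * H_out, 2L); ws <- seq(1L, 2L * W_out, 2L)
  cand <- list(A[, hs, ws, , drop = FALSE], A[, hs + 1L, ws, , drop = FALSE],
               A[, hs, ws + 1L, , drop = FALSE], A[, hs + 1L, ws + 1L, , drop = FALSE])
  out <- cand[[1L]]; which_max <- array(1L, dim(out))
  for (m in 2:4) {
    upd <- cand[[m]] > out
    out[upd] <- cand[[m]][upd]
    which_max[upd] <- m
  }
  list(out = out, cache = list(which_max = which_max, H = d[2L], W = d[3L],
                               H_out = H_out, W_out = W_out))
}

maxpool2d_bwd <- function(dOut, cache) {
  d <- dim(dOut)
  dA <- array(0, c(d[1L], cache$H, cache$W, d[4L]))
  hs <- seq(1L, 2L * cache$H_out, 2L); ws <- seq(1L, 2L * cache$W_out, 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (m in 1:4) {
    sel <- cache$which_max == m
    blk <- dOut * sel
    dA[, hs + offs[[m]][1L], ws + offs[[m]][2L], ] <-
      dA[, hs + offs[[m]][1L], ws + offs[[m]][2L], , drop = FALSE] + blk
  }
  dA
}

## ---- loss and optimizer -----------------------------------------------------

## Binary cross-entropy from logits; returns mean loss and d(loss)/d(logit).
bce_loss <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / length(y), prob = p)
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  ## gradients arrive in backprop order: match them to parameters by name
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)
      out <- lapply(keys, function(k) upd(p[[k]], g[[k]], m[[k]], v[[k]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

## Elementwise sum of two nested gradient lists.
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  Map(function(x, y) if (is.list(x)) grads_add(x, y) else x + y, a, b)
}
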