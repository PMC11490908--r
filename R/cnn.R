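## Six-layer convolutional per-modality baselines.
##
## Six weight-bearing layers per branch: three convolutions (2-D over the
## L x 301 text grid treated as a one-channel image; 1-D along time for the
## audio/video sequences), each followed by width-2 max pooling, then two
## rectifier affine layers and a single logistic output.

#' Build a six-layer convolutional model for one modality
#'
#' @param modality `"text"` (2-D convolutions), `"audio"` or `"video"` (1-D).
#' @param L aligned sequence length the model will consume.
#' @param n_filters convolution filters per layer (default 32).
#' @param kernel kernel size (default 3).
#' @param hidden sizes of the two affine layers (default `c(64, 32)`).
#' @param seed seed for weight initialization.
#' @return An object of class `cnn_model`.
#' @export
cnn_model <- function(modality = c("text", "audio", "video"), L,
                      n_filters = 32L, kernel = 3L, hidden = c(64L, 32L),
                      seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(length(hidden) == 2L)
  d <- MODALITY_DIMS[[modality]]
  two_d <- modality == "text"
  ## trace shapes through conv(valid)/pool(2) to size the first affine layer
  shp <- if (two_d) c(L, d) else L
  chans <- 1L
  for (i in 1:3) {
    shp <- shp - (kernel - 1L)
    if (any(shp < 1L))
      stopf("L = %d too short for three conv/pool stages with kernel %d", L, kernel)
    shp <- shp %/% 2L
    chans <- n_filters
  }
  flat_dim <- prod(shp) * chans
  if (flat_dim < 1L) stopf("L = %d too short for the convolution stack", L)
  params <- with_seed(seed, {
    p <- list()
    c_in <- if (two_d) 1L else d
    for (i in 1:3) {
      p[[paste0("conv", i)]] <- if (two_d) init_conv2d(kernel, c_in, n_filters)
                                else init_conv1d(kernel, c_in, n_filters)
      c_in <- n_filters
    }
    p$fc1 <- init_dense(flat_dim, hidden[1L])
    p$fc2 <- init_dense(hidden[1L], hidden[2L])
    p$out <- init_dense(hidden[2L], 1L)
    p
  })
  structure(list(modality = modality, L = as.integer(L), two_d = two_d,
                 n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 hidden = as.integer(hidden), flat_dim = flat_dim,
                 params = params, trained = FALSE),
            class = "cnn_model")
}

#' Number of weight-bearing layers of a CNN baseline
#' @param model a `cnn_model`.
#' @return Integer (always 6: three convolutions, two affine, one output).
#' @export
n_weight_layers <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) > 0L, logical(1L)))
}

#' @export
count_parameters.cnn_model <- function(x, ...) {
  rows <- lapply(names(x$params), function(nm) {
    p <- x$params[[nm]]
    list(layer = nm, type = if (grepl("^conv", nm)) "conv" else "dense",
         shape = "", params = length(p$W) + length(p$b))
  })
  .account(rows)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s (%s), %d weight-bearing layers, %s parameters%s\n",
              x$modality, if (x$two_d) "2-D conv" else "1-D conv",
              n_weight_layers(x),
              format(attr(count_parameters(x), "total"), big.mark = ","),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

.cnn_input <- function(model, sessions) {
  field <- paste0(model$modality, "_seq")
  N <- length(sessions)
  d <- MODALITY_DIMS[[model$modality]]
  L <- model$L
  if (model$two_d) {
    A <- array(0, c(N, L, d, 1L))
    for (n in seq_len(N)) A[n, , , 1L] <- sessions[[n]][[field]]
  } else {
    A <- array(0, c(N, L, d))
    for (n in seq_len(N)) A[n, , ] <- sessions[[n]][[field]]
  }
  A
}

cnn_forward <- function(model, A) {
  caches <- list()
  p <- model$params
  for (i in 1:3) {
    nm <- paste0("conv", i)
    fw <- if (model$two_d) conv2d_fwd(A, p[[nm]]) else conv1d_fwd(A, p[[nm]])
    caches[[nm]] <- fw$cache
    pl <- if (model$two_d) maxpool2d_fwd(fw$out) else maxpool1d_fwd(fw$out)
    caches[[paste0("pool", i)]] <- pl$cache
    A <- pl$out
  }
  N <- dim(A)[1L]
  shape_in <- dim(A)
  M <- matrix(A, N, prod(shape_in[-1L]))
  fc1 <- dense_fwd(M, p$fc1, "relu"); caches$fc1 <- fc1$cache
  fc2 <- dense_fwd(fc1$out, p$fc2, "relu"); caches$fc2 <- fc2$cache
  out <- dense_fwd(fc2$out, p$out, "linear"); caches$out <- out$cache
  list(logits = drop(out$out), caches = caches, shape_in = shape_in)
}

cnn_backward <- function(model, fwd, dlogits) {
  p <- model$params
  grads <- list()
  bo <- dense_bwd(matrix(dlogits, ncol = 1L), fwd$caches$out, p$out)
  grads$out <- bo$grads
  b2 <- dense_bwd(bo$dM, fwd$caches$fc2, p$fc2); grads$fc2 <- b2$grads
  b1 <- dense_bwd(b2$dM, fwd$caches$fc1, p$fc1); grads$fc1 <- b1$grads
  dA <- b1$dM
  dim(dA) <- fwd$shape_in
  for (i in 3:1) {
    dA <- if (model$two_d) maxpool2d_bwd(dA, fwd$caches[[paste0("pool", i)]])
          else maxpool1d_bwd(dA, fwd$caches[[paste0("pool", i)]])
    nm <- paste0("conv", i)
    bc <- if (model$two_d) conv2d_bwd(dA, fwd$caches[[nm]], p[[nm]])
          else conv1d_bwd(dA, fwd$caches[[nm]], p[[nm]])
    grads[[nm]] <- bc$grads
    dA <- bc$dA
  }
  grads
}

#' Train a convolutional per-modality baseline
#'
#' Minibatch Adam on binary cross-entropy.
#'
#' @param model a `cnn_model`.
#' @param sessions list of `aligned_session`s with `L` matching the model.
#' @param epochs,batch_size,lr,seed,verbose as in [train_fusion()].
#' @return The trained `cnn_model` with a `history` data.frame.
#' @export
train_cnn <- function(model, sessions, epochs = 20L, batch_size = 8L, lr = 1e-3,
                      seed = 1L, verbose = FALSE) {
  A_full <- .cnn_input(model, sessions)
  y <- vapply(sessions, `[[`, integer(1L), "label")
  N <- length(y)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  nd <- length(dim(A_full))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_correct <- 0
      starts <- seq(1L, N, by = batch_size)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, N)]
        A <- if (nd == 4L) A_full[idx, , , , drop = FALSE]
             else A_full[idx, , , drop = FALSE]
        fwd <- cnn_forward(model, A)
        ls <- bce_loss(fwd$logits, y[idx])
        if (!is.finite(ls$loss))
          stopf("non-finite loss at epoch %d, batch %d (lr = %g)", ep, bi, lr)
        grads <- cnn_backward(model, fwd, ls$dlogits)
        stepped <- adam_step(model$params, grads, state, lr = lr)
        model$params <- stepped$params
        state <- stepped$state
        ep_loss <- ep_loss + ls$loss * length(idx)
        ep_correct <- ep_correct + sum((ls$prob >= 0.5) == y[idx])
      }
      history[ep, ] <- list(ep, ep_loss / N, ep_correct / N)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss / N,
                        ep_correct / N))
    }
  })
  model$trained <- TRUE
  model$history <- history
  model
}

#' @export
predict.cnn_model <- function(object, sessions, threshold = 0.5, ...) {
  A <- .cnn_input(object, sessions)
  fwd <- cnn_forward(object, A)
  prob <- sigmoid(fwd$logits)
  data.frame(session_id = vapply(sessions, function(s) s$session_id %||% NA_character_,
                                 character(1L)),
             prob = prob, call = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}
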