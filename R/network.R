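## The gated fusion network.
##
## Per-modality trunks: the video stream passes through stacked highway gating
## blocks (width 388) and is projected 388 -> 200 -> 74; the audio stream
## through gating blocks (width 74) and a 74 -> 74 projection; the text stream
## (no gating) is projected 301 -> 150 -> 74. The three L x 74 sequences are
## concatenated along the TIME axis (order audio, video, text; fused length
## 3L) and consumed by a recurrent head (LSTM, 128 units) feeding a single
## logistic output. With L = 1700 the trainable-parameter account totals
## 5,907,283.

MODALITY_DIMS <- c(audio = 74L, video = 388L, text = 301L)

#' Specification of a gated fusion network
#'
#' @param L aligned sequence length per modality (default 1700).
#' @param modalities streams to include, in time-concatenation order.
#' @param n_gating stacked gating blocks on the audio and video streams
#'   (default 3; text is never gated).
#' @param recurrent `"lstm"` or `"bilstm"` head.
#' @param units recurrent units (default 128).
#' @param fusion_d common projection width (default 74).
#' @param video_proj,text_proj,audio_proj projection ladders ending at
#'   `fusion_d`.
#' @param seed seed for weight initialization.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(L = 1700L, modalities = c("audio", "video", "text"),
                         n_gating = 3L, recurrent = c("lstm", "bilstm"),
                         units = 128L, fusion_d = 74L,
                         video_proj = c(200L, fusion_d),
                         text_proj = c(150L, fusion_d),
                         audio_proj = fusion_d, seed = 1L) {
  recurrent <- match.arg(recurrent)
  modalities <- match.arg(modalities, c("audio", "video", "text"),
                          several.ok = TRUE)
  projs <- list(audio = as.integer(audio_proj), video = as.integer(video_proj),
                text = as.integer(text_proj))
  for (m in modalities) {
    ladder <- projs[[m]]
    if (ladder[length(ladder)] != fusion_d)
      stopf("%s projection must end at the fusion width %d, got %d",
            m, fusion_d, ladder[length(ladder)])
  }
  structure(list(L = as.integer(L), modalities = modalities,
                 n_gating = as.integer(n_gating), recurrent = recurrent,
                 units = as.integer(units), fusion_d = as.integer(fusion_d),
                 proj = projs, dims = MODALITY_DIMS, seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> L=%d, modalities: %s, %d gating block(s), %s(%d)\n",
              x$L, paste(x$modalities, collapse = "+"), x$n_gating,
              toupper(x$recurrent), x$units))
  invisible(x)
}

#' Build a standalone gating block
#'
#' A highway-style block over an `L x d` sequence: per timestep,
#' `g = sigmoid(x %*% W_G + b_G[t, ])`, `h = relu(x %*% W_T + b_T[t, ])`,
#' `out = g * h + (1 - g) * x`. The weight matrices are `d x d` and the biases
#' per-timestep `L x d`, so the trainable count is `2 * (d^2 + L * d)`.
#'
#' @param d feature width.
#' @param L sequence length.
#' @param seed seed for weight initialization.
#' @return An object of class `gating_block` with elements `params` (`WG`,
#'   `BG`, `WT`, `BT`), `d`, `L`.
#' @export
gating_block <- function(d, L, seed = 1L) {
  structure(list(params = with_seed(seed, init_highway(d, L)),
                 d = as.integer(d), L = as.integer(L)),
            class = "gating_block")
}

#' Apply a gating block to a sequence
#'
#' @param block a `gating_block`.
#' @param x `L x d` matrix (one sequence) or `N x L x d` array (a batch).
#' @return Output of the same shape as `x`.
#' @export
gating_forward <- function(block, x) {
  one <- is.matrix(x)
  A <- if (one) array(x, c(1L, nrow(x), ncol(x))) else x
  N <- dim(A)[1L]; T <- dim(A)[2L]
  if (T != block$L || dim(A)[3L] != block$d)
    stopf("input %d x %d does not match gating block %d x %d",
          T, dim(A)[3L], block$L, block$d)
  Y <- highway_fwd(flat2(A), rep(seq_len(T), each = N), block$params)$out
  out <- unflat2(Y, N, T)
  if (one) matrix(out[1L, , ], T, block$d) else out
}

#' @export
print.gating_block <- function(x, ...) {
  cat(sprintf("<gating_block> %d x %d, %s trainable scalars\n", x$L, x$d,
              format(highway_param_count(x$d, x$L), big.mark = ",")))
  invisible(x)
}

## Internal: the ordered layer plan for a spec — one row per layer with its
## constructor arguments; used both to initialize parameters and to count them.
.layer_plan <- function(spec) {
  plan <- list()
  add <- function(name, type, ...) {
    plan[[length(plan) + 1L]] <<- c(list(name = name, type = type), list(...))
  }
  for (m in spec$modalities) {
    d <- spec$dims[[m]]
    if (m %in% c("audio", "video") && spec$n_gating > 0L) {
      for (i in seq_len(spec$n_gating))
        add(sprintf("gating_%s_%d", m, i), "highway", d = d, L = spec$L)
    }
    ladder <- spec$proj[[m]]
    d_in <- d
    for (j in seq_along(ladder)) {
      act <- if (j < length(ladder)) "relu" else "linear"
      add(sprintf("proj_%s_%d", m, j), "dense", d_in = d_in, d_out = ladder[j],
          act = act)
      d_in <- ladder[j]
    }
  }
  add("concatenate", "concat",
      T_out = spec$L * length(spec$modalities), d = spec$fusion_d)
  if (spec$recurrent == "lstm") {
    add("recurrent", "lstm", d_in = spec$fusion_d, units = spec$units)
    head_in <- spec$units
  } else {
    add("recurrent_fwd", "lstm", d_in = spec$fusion_d, units = spec$units)
    add("recurrent_bwd", "lstm", d_in = spec$fusion_d, units = spec$units)
    head_in <- 2L * spec$units
  }
  add("output", "dense", d_in = head_in, d_out = 1L, act = "linear")
  plan
}

#' Build a gated fusion network
#'
#' Initializes all trainable parameters (variance-scaled uniform weights,
#' zero biases, forget-gate bias 1) for the layer plan implied by a
#' [network_spec()].
#'
#' @param spec a `network_spec`.
#' @param seed overrides `spec$seed` for initialization.
#' @return An object of class `fusion_network` with elements `spec`, `params`,
#'   `plan`.
#' @export
fusion_network <- function(spec = network_spec(), seed = spec$seed) {
  plan <- .layer_plan(spec)
  params <- with_seed(seed, {
    ps <- list()
    for (ly in plan) {
      ps[[ly$name]] <- switch(ly$type,
        highway = init_highway(ly$d, ly$L),
        dense = init_dense(ly$d_in, ly$d_out),
        lstm = init_lstm(ly$d_in, ly$units),
        concat = NULL)
    }
    ps
  })
  structure(list(spec = spec, params = params, plan = plan, trained = FALSE),
            class = "fusion_network")
}

#' Per-layer trainable-parameter account
#'
#' Counts the trainable scalars of each layer of a model (or of a standalone
#' gating block) from the actual parameter arrays, and reports the layer
#' output shapes. Closed forms: gating block `2*(d^2 + L*d)`, dense
#' `out*(in+1)`, LSTM `4*units*(in+units+1)`.
#'
#' @param x a `fusion_network`, `fusion_fit`, `gating_block` or `cnn_model`.
#' @param ... unused.
#' @return A `parameter_account`: data.frame with columns `layer`, `type`,
#'   `output_shape`, `params`, plus a `total` attribute.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

.account <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(layer = r$layer, type = r$type, output_shape = r$shape,
               params = r$params, stringsAsFactors = FALSE)))
  attr(df, "total") <- sum(df$params)
  class(df) <- c("parameter_account", "data.frame")
  df
}

#' @export
count_parameters.fusion_network <- function(x, ...) {
  spec <- x$spec
  rows <- list()
  for (m in spec$modalities) {
    rows[[length(rows) + 1L]] <- list(
      layer = paste0(m, "_input"), type = "input",
      shape = sprintf("(L=%d, %d)", spec$L, spec$dims[[m]]), params = 0)
  }
  for (ly in x$plan) {
    p <- x$params[[ly$name]]
    n <- if (is.null(p)) 0 else sum(vapply(p, length, numeric(1L)))
    shape <- switch(ly$type,
      highway = sprintf("(L=%d, %d)", ly$L, ly$d),
      dense = if (ly$name == "output") "(1)" else sprintf("(L=%d, %d)", spec$L, ly$d_out),
      lstm = sprintf("(%d)", ly$units),
      concat = sprintf("(%d, %d)", ly$T_out, ly$d))
    rows[[length(rows) + 1L]] <- list(layer = ly$name, type = ly$type,
                                      shape = shape, params = n)
  }
  .account(rows)
}

#' @export
count_parameters.fusion_fit <- function(x, ...) count_parameters.fusion_network(x, ...)

#' @export
count_parameters.gating_block <- function(x, ...) {
  .account(list(list(layer = "gating", type = "highway",
                     shape = sprintf("(L=%d, %d)", x$L, x$d),
                     params = sum(vapply(x$params, length, numeric(1L))))))
}

#' @export
print.parameter_account <- function(x, ...) {
  df <- as.data.frame(x)
  df$params <- format(df$params, big.mark = ",")
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %s\n",
              format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' @export
print.fusion_network <- function(x, ...) {
  cat(sprintf("<fusion_network> %s\n", if (x$trained) "(trained)" else "(untrained)"))
  print(x$spec)
  cat(sprintf("  total trainable parameters: %s\n",
              format(attr(count_parameters(x), "total"), big.mark = ",")))
  invisible(x)
}

#' @export
summary.fusion_network <- function(object, ...) count_parameters(object)

#' @export
coef.fusion_network <- function(object, ...) object$params

## ---- forward / backward ------------------------------------------------------

## Batch container: list of (N, L, d) arrays keyed by modality.
as_batch <- function(sessions) {
  N <- length(sessions)
  L <- sessions[[1L]]$L
  arr <- function(field, d) {
    A <- array(0, c(N, L, d))
    for (n in seq_len(N)) A[n, , ] <- sessions[[n]][[field]]
    A
  }
  list(audio = arr("audio_seq", AUDIO_D), video = arr("video_seq", VIDEO_D),
       text = arr("text_seq", TEXT_D),
       labels = vapply(sessions, `[[`, integer(1L), "label"), N = N, L = L)
}

net_forward <- function(net, batch) {
  spec <- net$spec
  N <- batch$N; L <- spec$L
  tidx <- rep(seq_len(L), each = N)
  caches <- list()
  streams <- list()
  for (m in spec$modalities) {
    A <- batch[[m]]
    if (dim(A)[2L] != L || dim(A)[3L] != spec$dims[[m]])
      stopf("%s input shape (%d, %d) does not match spec (%d, %d)",
            m, dim(A)[2L], dim(A)[3L], L, spec$dims[[m]])
    M <- flat2(A)
    if (m %in% c("audio", "video") && spec$n_gating > 0L) {
      for (i in seq_len(spec$n_gating)) {
        nm <- sprintf("gating_%s_%d", m, i)
        fw <- highway_fwd(M, tidx, net$params[[nm]])
        caches[[nm]] <- fw$cache
        M <- fw$out
      }
    }
    ladder <- spec$proj[[m]]
    for (j in seq_along(ladder)) {
      nm <- sprintf("proj_%s_%d", m, j)
      act <- if (j < length(ladder)) "relu" else "linear"
      fw <- dense_fwd(M, net$params[[nm]], act)
      caches[[nm]] <- fw$cache
      M <- fw$out
    }
    streams[[m]] <- unflat2(M, N, L)
  }
  T_fused <- L * length(spec$modalities)
  Fused <- array(0, c(N, T_fused, spec$fusion_d))
  for (i in seq_along(spec$modalities))
    Fused[, ((i - 1L) * L + 1L):(i * L), ] <- streams[[spec$modalities[i]]]
  if (spec$recurrent == "lstm") {
    fw <- lstm_fwd(Fused, net$params$recurrent)
    caches$recurrent <- fw
    H <- fw$out
  } else {
    fw_f <- lstm_fwd(Fused, net$params$recurrent_fwd)
    fw_b <- lstm_fwd(reverse_time(Fused), net$params$recurrent_bwd)
    caches$recurrent_fwd <- fw_f
    caches$recurrent_bwd <- fw_b
    H <- cbind(fw_f$out, fw_b$out)
  }
  out <- dense_fwd(H, net$params$output, "linear")
  caches$output <- out$cache
  list(logits = drop(out$out), caches = caches,
       fused_shape = c(T_fused, spec$fusion_d), N = N)
}

net_backward <- function(net, fwd, dlogits) {
  spec <- net$spec
  N <- fwd$N; L <- spec$L
  grads <- list()
  bo <- dense_bwd(matrix(dlogits, ncol = 1L), fwd$caches$output, net$params$output)
  grads$output <- bo$grads
  u <- spec$units
  if (spec$recurrent == "lstm") {
    br <- lstm_bwd(bo$dM, fwd$caches$recurrent, net$params$recurrent)
    grads$recurrent <- br$grads
    dFused <- br$dA
  } else {
    br_f <- lstm_bwd(bo$dM[, seq_len(u), drop = FALSE],
                     fwd$caches$recurrent_fwd, net$params$recurrent_fwd)
    br_b <- lstm_bwd(bo$dM[, u + seq_len(u), drop = FALSE],
                     fwd$caches$recurrent_bwd, net$params$recurrent_bwd)
    grads$recurrent_fwd <- br_f$grads
    grads$recurrent_bwd <- br_b$grads
    dFused <- br_f$dA + reverse_time(br_b$dA)
  }
  for (i in seq_along(spec$modalities)) {
    m <- spec$modalities[i]
    dM <- flat2(dFused[, ((i - 1L) * L + 1L):(i * L), , drop = FALSE])
    ladder <- spec$proj[[m]]
    for (j in rev(seq_along(ladder))) {
      nm <- sprintf("proj_%s_%d", m, j)
      bd <- dense_bwd(dM, fwd$caches[[nm]], net$params[[nm]])
      grads[[nm]] <- bd$grads
      dM <- bd$dM
    }
    if (m %in% c("audio", "video") && spec$n_gating > 0L) {
      for (i2 in rev(seq_len(spec$n_gating))) {
        nm <- sprintf("gating_%s_%d", m, i2)
        bh <- highway_bwd(dM, fwd$caches[[nm]], net$params[[nm]])
        grads[[nm]] <- bh$grads
        dM <- bh$dM
      }
    }
  }
  grads
}

## ---- training ----------------------------------------------------------------

#' Train a fusion network
#'
#' Minibatch Adam on binary cross-entropy, deterministic given `seed` under
#' single-threaded execution. Training aborts with diagnostics if the loss
#' turns non-finite.
#'
#' @param net a `fusion_network` (or a `network_spec`, built on the fly).
#' @param sessions list of `aligned_session`s whose `L` matches the spec.
#' @param epochs number of passes (default 30).
#' @param batch_size minibatch size (default 8).
#' @param lr Adam step size (default 1e-3).
#' @param seed seed for shuffling (weights were seeded at build time).
#' @param verbose print per-epoch loss/accuracy.
#' @param stop_accuracy optional early stop: end training after the first
#'   epoch whose training accuracy reaches this value.
#' @return A `fusion_fit`: the trained network plus a `history` data.frame
#'   (epoch, loss, accuracy).
#' @export
train_fusion <- function(net, sessions, epochs = 30L, batch_size = 8L,
                         lr = 1e-3, seed = 1L, verbose = FALSE,
                         stop_accuracy = NULL) {
  if (inherits(net, "network_spec")) net <- fusion_network(net)
  stopifnot(inherits(net, "fusion_network"))
  full <- as_batch(sessions)
  y <- full$labels
  N <- full$N
  state <- adam_init(net$params)
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_correct <- 0
      starts <- seq(1L, N, by = batch_size)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, N)]
        batch <- list(audio = full$audio[idx, , , drop = FALSE],
                      video = full$video[idx, , , drop = FALSE],
                      text = full$text[idx, , , drop = FALSE],
                      N = length(idx), L = full$L)
        fwd <- net_forward(net, batch)
        ls <- bce_loss(fwd$logits, y[idx])
        if (!is.finite(ls$loss))
          stopf("non-finite loss at epoch %d, batch %d (lr = %g); try a smaller step size",
                ep, bi, lr)
        grads <- net_backward(net, fwd, ls$dlogits)
        stepped <- adam_step(net$params, grads, state, lr = lr)
        net$params <- stepped$params
        state <- stepped$state
        ep_loss <- ep_loss + ls$loss * length(idx)
        ep_correct <- ep_correct + sum((ls$prob >= 0.5) == y[idx])
      }
      history[ep, ] <- list(ep, ep_loss / N, ep_correct / N)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss / N,
                        ep_correct / N))
      if (!is.null(stop_accuracy) && ep_correct / N >= stop_accuracy) break
    }
  })
  net$trained <- TRUE
  net$history <- history
  class(net) <- c("fusion_fit", class(net))
  net
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("<fusion_fit>\n")
  print(x$spec)
  h <- x$history
  cat(sprintf("  %d epoch(s): final loss %.4f, training accuracy %.3f\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' Predict depression probability for aligned sessions
#'
#' @param object a `fusion_network` or `fusion_fit`.
#' @param sessions list of `aligned_session`s.
#' @param threshold call threshold; a probability equal to the threshold is
#'   called positive (default 0.5).
#' @param ... unused.
#' @return data.frame with `session_id`, `prob`, `call`.
#' @export
predict.fusion_network <- function(object, sessions, threshold = 0.5, ...) {
  batch <- as_batch(sessions)
  fwd <- net_forward(object, batch)
  prob <- sigmoid(fwd$logits)
  data.frame(session_id = vapply(sessions, function(s) s$session_id %||% NA_character_,
                                 character(1L)),
             prob = prob, call = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

#' @export
predict.fusion_fit <- predict.fusion_network

#' @export
plot.fusion_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "Fusion network training", ...)
  invisible(x)
}

#' Forward pass exposing the fused sequence shape
#'
#' Runs the network on a batch and returns the probabilities together with
#' the shape of the time-concatenated stream (`3L x 74` for the default
#' three-modality network).
#'
#' @param net a `fusion_network`.
#' @param sessions list of `aligned_session`s.
#' @return List with `prob` and `fused_shape` (`c(time, width)`).
#' @export
fusion_forward_shapes <- function(net, sessions) {
  fwd <- net_forward(net, as_batch(sessions))
  list(prob = sigmoid(fwd$logits), fused_shape = fwd$fused_shape)
}
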