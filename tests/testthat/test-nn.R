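## Properties of the neural primitives: gating limits, parameter closed
## forms, and finite-difference agreement of the hand-derived gradients.

flat2 <- gatefusion:::flat2

test_that("gating block reduces to identity and transform in the gate limits", {
  set.seed(1)
  blk <- gating_block(d = 6L, L = 9L, seed = 2L)
  x <- matrix(rnorm(9 * 6), 9, 6)
  ## closed gate: g -> 0 pointwise, output = input
  blk$params$BG[] <- -1e4
  expect_lt(max(abs(gating_forward(blk, x) - x)), 1e-6)
  ## open gate: g -> 1, output = relu(x W_T + b_T)
  blk$params$BG[] <- 1e4
  h <- pmax(x %*% blk$params$WT + blk$params$BT, 0)
  expect_lt(max(abs(gating_forward(blk, x) - h)), 1e-6)
  ## shape preserved, batch input accepted
  A <- array(rnorm(2 * 9 * 6), c(2, 9, 6))
  expect_equal(dim(gating_forward(blk, A)), c(2L, 9L, 6L))
  expect_error(gating_forward(blk, matrix(0, 5, 6)), "does not match")
})

test_that("parameter closed forms hold at any size", {
  ## gating block: 2*(d^2 + L*d), counted from the actual arrays
  set.seed(3)
  for (i in 1:8) {
    d <- sample(1:40, 1); L <- sample(1:50, 1)
    blk <- gating_block(d, L)
    expect_equal(attr(count_parameters(blk), "total"), 2 * (d^2 + L * d))
  }
  expect_equal(attr(count_parameters(gating_block(1L, 1L)), "total"), 4)
  ## published widths
  expect_equal(attr(count_parameters(gating_block(388L, 1700L)), "total"),
               1620288)
  expect_equal(attr(count_parameters(gating_block(74L, 1700L)), "total"),
               262552)
  ## dense: out*(in+1); lstm: 4u(in+u+1) — via random small network specs
  for (i in 1:5) {
    u <- sample(2:20, 1); L <- sample(2:6, 1); ng <- sample(0:2, 1)
    spec <- network_spec(L = L, n_gating = ng, units = u)
    acc <- count_parameters(fusion_network(spec))
    df <- as.data.frame(acc)
    expect_equal(df$params[df$layer == "proj_video_1"], 200 * (388 + 1))
    expect_equal(df$params[df$layer == "recurrent"], 4 * u * (74 + u + 1))
    gate_rows <- df$params[df$type == "highway"]
    expect_equal(sum(gate_rows),
                 ng * (2 * (74^2 + L * 74) + 2 * (388^2 + L * 388)))
  }
})

test_that("bidirectional head doubles the recurrent parameter count", {
  uni <- count_parameters(fusion_network(network_spec(L = 4, units = 128,
                                                      recurrent = "lstm")))
  bi <- count_parameters(fusion_network(network_spec(L = 4, units = 128,
                                                     recurrent = "bilstm")))
  d_uni <- as.data.frame(uni)
  d_bi <- as.data.frame(bi)
  expect_equal(d_uni$params[d_uni$layer == "recurrent"], 103936)
  expect_equal(sum(d_bi$params[grepl("recurrent", d_bi$layer)]), 2 * 103936)
})

test_that("hand-derived gradients match finite differences", {
  g <- function(nm) getFromNamespace(nm, "gatefusion")
  set.seed(5)
  rel_err <- function(a, b) abs(a - b) / max(1e-6, abs(a), abs(b))

  ## highway
  N <- 2L; T <- 4L; d <- 3L
  M <- flat2(array(rnorm(N * T * d), c(N, T, d)))
  tidx <- rep(seq_len(T), each = N)
  p <- g("init_highway")(d, T)
  p$BG[] <- rnorm(T * d, sd = 0.3); p$BT[] <- rnorm(T * d, sd = 0.3)
  fw <- g("highway_fwd")(M, tidx, p)
  R <- matrix(rnorm(length(fw$out)), nrow(fw$out))
  bw <- g("highway_bwd")(R, fw$cache, p)
  eps <- 1e-6
  for (nm in c("WG", "BG", "WT", "BT")) {
    i <- sample(length(p[[nm]]), 1L)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (sum(g("highway_fwd")(M, tidx, pp)$out * R) -
            sum(g("highway_fwd")(M, tidx, pm)$out * R)) / (2 * eps)
    expect_lt(rel_err(num, bw$grads[[nm]][i]), 1e-4)
  }

  ## lstm, including gradient wrt the input sequence
  din <- 3L; u <- 4L; T <- 5L
  A <- array(rnorm(N * T * din), c(N, T, din))
  pl <- g("init_lstm")(din, u)
  fwl <- g("lstm_fwd")(A, pl)
  Rl <- matrix(rnorm(N * u), N, u)
  bwl <- g("lstm_bwd")(Rl, fwl, pl)
  for (nm in c("W", "U", "b")) {
    i <- sample(length(pl[[nm]]), 1L)
    pp <- pl; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- pl; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (sum(g("lstm_fwd")(A, pp)$out * Rl) -
            sum(g("lstm_fwd")(A, pm)$out * Rl)) / (2 * eps)
    expect_lt(rel_err(num, bwl$grads[[nm]][i]), 1e-4)
  }
  i <- sample(length(A), 1L)
  Ap <- A; Ap[i] <- Ap[i] + eps
  Am <- A; Am[i] <- Am[i] - eps
  num <- (sum(g("lstm_fwd")(Ap, pl)$out * Rl) -
          sum(g("lstm_fwd")(Am, pl)$out * Rl)) / (2 * eps)
  expect_lt(rel_err(num, bwl$dA[i]), 1e-4)

  ## conv1d + pool and conv2d + pool stacks
  Tc <- 9L; C <- 3L
  A1 <- array(rnorm(N * Tc * C), c(N, Tc, C))
  pc <- g("init_conv1d")(3L, C, 2L)
  o <- g("conv1d_fwd")(A1, pc)
  plo <- g("maxpool1d_fwd")(o$out)
  Rc <- array(rnorm(length(plo$out)), dim(plo$out))
  bwc <- g("conv1d_bwd")(g("maxpool1d_bwd")(Rc, plo$cache), o$cache, pc)
  i <- sample(length(pc$W), 1L)
  pp <- pc; pp$W[i] <- pp$W[i] + eps
  pm <- pc; pm$W[i] <- pm$W[i] - eps
  lossp <- sum(g("maxpool1d_fwd")(g("conv1d_fwd")(A1, pp)$out)$out * Rc)
  lossm <- sum(g("maxpool1d_fwd")(g("conv1d_fwd")(A1, pm)$out)$out * Rc)
  expect_lt(rel_err((lossp - lossm) / (2 * eps), bwc$grads$W[i]), 1e-4)

  H <- 7L; W2 <- 6L
  A2 <- array(rnorm(N * H * W2 * 2L), c(N, H, W2, 2L))
  p2 <- g("init_conv2d")(3L, 2L, 2L)
  o2 <- g("conv2d_fwd")(A2, p2)
  pl2 <- g("maxpool2d_fwd")(o2$out)
  R2 <- array(rnorm(length(pl2$out)), dim(pl2$out))
  bw2 <- g("conv2d_bwd")(g("maxpool2d_bwd")(R2, pl2$cache), o2$cache, p2)
  i <- sample(length(p2$W), 1L)
  pp <- p2; pp$W[i] <- pp$W[i] + eps
  pm <- p2; pm$W[i] <- pm$W[i] - eps
  lossp <- sum(g("maxpool2d_fwd")(g("conv2d_fwd")(A2, pp)$out)$out * R2)
  lossm <- sum(g("maxpool2d_fwd")(g("conv2d_fwd")(A2, pm)$out)$out * R2)
  expect_lt(rel_err((lossp - lossm) / (2 * eps), bw2$grads$W[i]), 1e-4)
})

test_that("the full network gradient matches finite differences", {
  g <- function(nm) getFromNamespace(nm, "gatefusion")
  set.seed(6)
  sess <- lapply(1:3, function(i) fake_aligned(3L, i %% 2L, id = paste0("g", i)))
  for (rec in c("lstm", "bilstm")) {
    spec <- network_spec(L = 3L, n_gating = 1L, recurrent = rec, units = 3L,
                         seed = 2L)
    net <- fusion_network(spec)
    batch <- g("as_batch")(sess)
    y <- batch$labels
    fwd <- g("net_forward")(net, batch)
    ls <- g("bce_loss")(fwd$logits, y)
    grads <- g("net_backward")(net, fwd, ls$dlogits)
    lossf <- function(n) g("bce_loss")(g("net_forward")(n, batch)$logits, y)$loss
    eps <- 1e-6
    for (lyr in sample(names(grads), 4L)) {
      nm <- sample(names(grads[[lyr]]), 1L)
      i <- sample(length(grads[[lyr]][[nm]]), 1L)
      np <- net; np$params[[lyr]][[nm]][i] <- np$params[[lyr]][[nm]][i] + eps
      nm2 <- net; nm2$params[[lyr]][[nm]][i] <- nm2$params[[lyr]][[nm]][i] - eps
      num <- (lossf(np) - lossf(nm2)) / (2 * eps)
      expect_lt(abs(num - grads[[lyr]][[nm]][i]) /
                  max(1e-5, abs(num), abs(grads[[lyr]][[nm]][i])), 1e-3)
    }
  }
})
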