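# Internal neural-network core: a small bidirectional LSTM with a
# condensing affine layer (back to the input feature width, enabling
# autoregressive window extension) and a two-layer regressor, with exact
# reverse-mode gradients and an Adam optimizer. Dimensions are tiny
# (feature width 5, hidden size 5), so plain batched matrix algebra in R
# is adequate. Gradients are verified against finite differences in the
# test suite.

N_FEAT <- 5L
N_HID <- 5L

sigmoid <- function(x) 1 / (1 + exp(-x))

# Parameter initialization: uniform(-1/sqrt(h), 1/sqrt(h)) per block,
# the conventional recurrent-layer default, from the current RNG state.
init_params <- function() {
  u <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  kh <- 1 / sqrt(N_HID)
  list(
    f_Wx = u(N_FEAT, 4L * N_HID, kh), f_Wh = u(N_HID, 4L * N_HID, kh),
    f_b = stats::runif(4L * N_HID, -kh, kh),
    b_Wx = u(N_FEAT, 4L * N_HID, kh), b_Wh = u(N_HID, 4L * N_HID, kh),
    b_b = stats::runif(4L * N_HID, -kh, kh),
    Wc = u(2L * N_HID, N_FEAT, 1 / sqrt(2 * N_HID)),
    # biases feeding a ReLU start slightly positive so no unit is dead at
    # initialization (the BiLSTM state varies little across windows, so a
    # negative draw here would silence a channel permanently)
    bc = stats::runif(N_FEAT, 0.05, 1 / sqrt(2 * N_HID)),
    W1 = u(N_FEAT, 2L, 1 / sqrt(N_FEAT)),
    b1 = stats::runif(2L, 0.05, 1 / sqrt(N_FEAT)),
    W2 = u(2L, 1L, 1 / sqrt(2)),
    b2 = stats::runif(1L, -1 / sqrt(2), 1 / sqrt(2))
  )
}

zero_like <- function(p) lapply(p, function(x) x * 0)

slice_t <- function(X, t) {
  matrix(X[, t, ], nrow = dim(X)[1L])
}

# One-direction LSTM over a (B, T, F) array. Returns hidden states
# (B, T, H) and the per-step cache needed for backprop.
lstm_forward <- function(X, Wx, Wh, b) {
  B <- dim(X)[1L]
  T <- dim(X)[2L]
  H <- array(0, c(B, T, N_HID))
  cache <- vector("list", T)
  h <- matrix(0, B, N_HID)
  cc <- matrix(0, B, N_HID)
  ii <- 1:N_HID
  ff <- (N_HID + 1L):(2L * N_HID)
  gg <- (2L * N_HID + 1L):(3L * N_HID)
  oo <- (3L * N_HID + 1L):(4L * N_HID)
  for (t in seq_len(T)) {
    xt <- slice_t(X, t)
    a <- xt %*% Wx + h %*% Wh
    a <- sweep(a, 2L, b, "+")
    i <- sigmoid(a[, ii, drop = FALSE])
    f <- sigmoid(a[, ff, drop = FALSE])
    g <- tanh(a[, gg, drop = FALSE])
    o <- sigmoid(a[, oo, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(
      x = xt, i = i, f = f, g = g, o = o,
      c_prev = cc, h_prev = h, c = c_new, tc = tc
    )
    h <- h_new
    cc <- c_new
    H[, t, ] <- h
  }
  list(H = H, cache = cache)
}

# Backprop through one LSTM direction. dH: (B, T, H) gradient on hidden
# states. Returns dX and parameter gradients.
lstm_backward <- function(dH, cache, Wx, Wh) {
  T <- length(cache)
  B <- nrow(cache[[1L]]$x)
  dWx <- Wx * 0
  dWh <- Wh * 0
  db <- numeric(4L * N_HID)
  dX <- array(0, c(B, T, N_FEAT))
  dh_next <- matrix(0, B, N_HID)
  dc_next <- matrix(0, B, N_HID)
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    dh <- slice_t(dH, t) + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dA <- cbind(
      di * cc$i * (1 - cc$i),
      df * cc$f * (1 - cc$f),
      dg * (1 - cc$g^2),
      do_ * cc$o * (1 - cc$o)
    )
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(Wx)
    dh_next <- dA %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# LIBC forward: BiLSTM -> ReLU -> condensing affine (2H -> F) -> ReLU.
# C is the per-step condensed output (B, T, F).
libc_fwd_ref <- function(X, p) {
  B <- dim(X)[1L]
  T <- dim(X)[2L]
  fw <- lstm_forward(X, p$f_Wx, p$f_Wh, p$f_b)
  Xr <- X[, rev(seq_len(T)), , drop = FALSE]
  bw <- lstm_forward(Xr, p$b_Wx, p$b_Wh, p$b_b)
  Hb <- bw$H[, rev(seq_len(T)), , drop = FALSE]
  Hcat <- array(0, c(B, T, 2L * N_HID))
  Hcat[, , 1:N_HID] <- fw$H
  Hcat[, , (N_HID + 1L):(2L * N_HID)] <- Hb
  R <- pmax(Hcat, 0)
  Cpre <- array(0, c(B, T, N_FEAT))
  for (t in seq_len(T)) {
    Cpre[, t, ] <- sweep(matrix(R[, t, ], nrow = B) %*% p$Wc, 2L, p$bc, "+")
  }
  C <- pmax(Cpre, 0)
  list(C = C, Cpre = Cpre, R = R, Hcat = Hcat, fw = fw, bw = bw, X = X)
}

libc_bwd_ref <- function(dC, fwd, p) {
  B <- dim(dC)[1L]
  T <- dim(dC)[2L]
  dCpre <- dC * (fwd$Cpre > 0)
  dWc <- p$Wc * 0
  dbc <- numeric(N_FEAT)
  dR <- array(0, c(B, T, 2L * N_HID))
  for (t in seq_len(T)) {
    dct <- matrix(dCpre[, t, ], nrow = B)
    rt <- matrix(fwd$R[, t, ], nrow = B)
    dWc <- dWc + crossprod(rt, dct)
    dbc <- dbc + colSums(dct)
    dR[, t, ] <- dct %*% t(p$Wc)
  }
  dHcat <- dR * (fwd$Hcat > 0)
  dHf <- dHcat[, , 1:N_HID, drop = FALSE]
  dHb <- dHcat[, , (N_HID + 1L):(2L * N_HID), drop = FALSE]
  f_b <- lstm_backward(dHf, fwd$fw$cache, p$f_Wx, p$f_Wh)
  b_b <- lstm_backward(
    dHb[, rev(seq_len(T)), , drop = FALSE],
    fwd$bw$cache, p$b_Wx, p$b_Wh
  )
  dX <- f_b$dX + b_b$dX[, rev(seq_len(T)), , drop = FALSE]
  list(
    dX = dX,
    grads = list(
      f_Wx = f_b$dWx, f_Wh = f_b$dWh, f_b = f_b$db,
      b_Wx = b_b$dWx, b_Wh = b_b$dWh, b_b = b_b$db,
      Wc = dWc, bc = dbc
    )
  )
}

# Regressor: affine F -> 2, ReLU, affine 2 -> 1.
reg_fwd <- function(V, p) {
  z1pre <- sweep(V %*% p$W1, 2L, p$b1, "+")
  z1 <- pmax(z1pre, 0)
  out <- sweep(z1 %*% p$W2, 2L, p$b2, "+")
  list(out = drop(out), z1 = z1, z1pre = z1pre, V = V)
}

reg_bwd <- function(dout, fwd, p) {
  dout <- matrix(dout, ncol = 1L)
  dW2 <- crossprod(fwd$z1, dout)
  db2 <- colSums(dout)
  dz1 <- (dout %*% t(p$W2)) * (fwd$z1pre > 0)
  dW1 <- crossprod(fwd$V, dz1)
  db1 <- colSums(dz1)
  dV <- dz1 %*% t(p$W1)
  list(dV = dV, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Autoregressive rollout over a batch with per-sample gaps. Each sample k
# receives gvec[k] + 1 passes through the LIBC; the batch is processed
# jointly to max(gvec) + 1 passes and each sample's condensed vector is
# selected at its own pass (so heterogeneous gaps share the computation).
# Appended months carry the predicted normalized value, static age/sex
# from the window, certainty 0 (predictions are estimates) and a discrete
# code recomputed from the denormalized predicted value. The discrete code
# is piecewise constant, hence carries no gradient.
rollout_fwd <- function(X0, gvec, p, marker, table, keep_steps = FALSE) {
  B <- dim(X0)[1L]
  T <- dim(X0)[2L]
  S <- max(gvec) + 1L
  emb <- matrix(0, B, N_FEAT)
  fwds <- vector("list", S)
  steps <- if (keep_steps) array(0, c(B, S, N_FEAT)) else NULL
  X <- X0
  Xs <- vector("list", S)
  for (s in seq_len(S)) {
    Xs[[s]] <- X
    fw <- libc_fwd(X, p)
    fwds[[s]] <- fw
    nxt <- matrix(fw$C[, T, ], nrow = B)
    if (keep_steps) steps[, s, ] <- nxt
    sel <- which(gvec + 1L == s)
    if (length(sel) > 0L) emb[sel, ] <- nxt[sel, , drop = FALSE]
    if (s < S) {
      newrow <- cbind(
        nxt[, 1L],
        X[, T, 2L], X[, T, 3L],
        0,
        discrete_code(denormalize_value(nxt[, 1L]), marker, table)
      )
      Xn <- array(0, c(B, T, N_FEAT))
      Xn[, seq_len(T - 1L), ] <- X[, 2L:T, , drop = FALSE]
      Xn[, T, ] <- newrow
      X <- Xn
    }
  }
  rf <- reg_fwd(emb, p)
  list(
    emb = emb, out = rf$out, reg = rf, fwds = fwds, Xs = Xs,
    gvec = gvec, S = S, steps = steps
  )
}

# Backprop through the rollout. demb: (B, F) gradient on the selected
# condensed vectors (typically from the regressor). Predicted values
# appended at pass a persist in the sliding window of later passes, so
# the value-column gradient of pass q's input row j flows back to pass
# a = q - (T - j) - 1's condensed output.
rollout_bwd <- function(roll, demb, p) {
  B <- nrow(demb)
  T <- dim(roll$Xs[[1L]])[2L]
  S <- roll$S
  acc <- zero_like(p)
  dnextval <- vector("list", S)
  for (s in seq_len(S)) dnextval[[s]] <- numeric(B)
  for (s in rev(seq_len(S))) {
    dC <- array(0, c(B, T, N_FEAT))
    sel <- which(roll$gvec + 1L == s)
    if (length(sel) > 0L) {
      dC_last <- matrix(0, B, N_FEAT)
      dC_last[sel, ] <- demb[sel, , drop = FALSE]
      dC[, T, ] <- dC_last
    }
    dC[, T, 1L] <- dC[, T, 1L] + dnextval[[s]]
    bk <- libc_bwd(dC, roll$fwds[[s]], p)
    for (nm in names(bk$grads)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
    if (s > 1L) {
      for (j in seq_len(T)) {
        a <- s - (T - j) - 1L
        if (a >= 1L) {
          dnextval[[a]] <- dnextval[[a]] + bk$dX[, j, 1L]
        }
      }
    }
  }
  acc
}

# MSE loss and full gradient for one batch of windows X (B, T, F) with
# per-sample gaps gvec and normalized targets y. Stage-1 batches are the
# gvec = 0 special case (one LIBC pass, then the regressor). The loss has
# two terms at the selected step: the regressor's prediction error and
# the condensed value channel's error against the same target — the
# latter closes the autoregressive loop (the condensed output is what
# rollout feeds back as the next month's value, so it must itself be a
# next-value prediction). Intermediate rollout steps receive no loss.
loss_and_grads <- function(X, gvec, y, p, marker, table) {
  B <- dim(X)[1L]
  roll <- rollout_fwd(X, gvec, p, marker, table)
  err <- roll$out - y
  err_v <- roll$emb[, 1L] - y
  loss <- mean(err^2) + mean(err_v^2)
  dout <- 2 * err / B
  rb <- reg_bwd(dout, roll$reg, p)
  demb <- rb$dV
  demb[, 1L] <- demb[, 1L] + 2 * err_v / B
  grads <- rollout_bwd(roll, demb, p)
  grads$W1 <- rb$grads$W1
  grads$b1 <- rb$grads$b1
  grads$W2 <- rb$grads$W2
  grads$b2 <- rb$grads$b2
  list(loss = loss, grads = grads, out = roll$out)
}

adam_init <- function(p) {
  list(m = zero_like(p), v = zero_like(p), t = 0L)
}

adam_step <- function(p, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(p = p, state = state)
}

# Compiled fast path (src/nn.cpp); numerically identical to the reference
# implementations above, which the tests use as an oracle.
libc_fwd <- function(X, p) {
  out <- cpp_libc_fwd(
    X, p$f_Wx, p$f_Wh, p$f_b, p$b_Wx, p$b_Wh, p$b_b, p$Wc, p$bc
  )
  list(C = out$C, cache = out$cache)
}

libc_bwd <- function(dC, fwd, p) {
  res <- cpp_libc_bwd(dC, fwd$cache, p$f_Wx, p$f_Wh, p$b_Wx, p$b_Wh, p$Wc)
  list(
    dX = res$dX,
    grads = list(
      f_Wx = res$f_Wx, f_Wh = res$f_Wh, f_b = as.numeric(res$f_b),
      b_Wx = res$b_Wx, b_Wh = res$b_Wh, b_b = as.numeric(res$b_b),
      Wc = res$Wc, bc = as.numeric(res$bc)
    )
  )
}

# Global gradient-norm clipping (the usual BPTT safeguard).
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) {
    return(grads)
  }
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}
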