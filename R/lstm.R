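# Minimal LSTM / bidirectional-LSTM engine: forward pass, backpropagation
# through time, and Adam. Written against the standard cell equations
#   i,f,o = sigmoid(x W + h U + b),  g = tanh(x W + h U + b)
#   c' = f*c + i*g,  h' = o * tanh(c')
# with gate blocks ordered [i | f | g | o]. Batches are arrays [n, T, F].
# Gradients are verified against numerical differentiation in the test
# suite, which is the contract the rest of the model module relies on.

sigmoid <- function(z) 1 / (1 + exp(-z))

slice_t <- function(X, t) {
  d <- dim(X)
  matrix(X[, t, ], nrow = d[1], ncol = d[3])
}

lstm_params_init <- function(input_size, hidden) {
  r <- 1 / sqrt(hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
  list(
    W = matrix(stats::runif(input_size * 4 * hidden, -r, r), input_size, 4 * hidden),
    U = matrix(stats::runif(hidden * 4 * hidden, -r, r), hidden, 4 * hidden),
    b = b
  )
}

lstm_forward <- function(p, X) {
  d <- dim(X); n <- d[1]; Tn <- d[2]
  H <- nrow(p$U)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hseq <- array(0, c(n, Tn, H))
  cache <- vector("list", Tn)
  ii <- 1:H; fi <- (H + 1):(2 * H); gi <- (2 * H + 1):(3 * H); oi <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tn)) {
    Xt <- slice_t(X, t)
    Z <- Xt %*% p$W + h %*% p$U + matrix(p$b, n, 4 * H, byrow = TRUE)
    I <- sigmoid(Z[, ii, drop = FALSE])
    F_ <- sigmoid(Z[, fi, drop = FALSE])
    G <- tanh(Z[, gi, drop = FALSE])
    O <- sigmoid(Z[, oi, drop = FALSE])
    c_prev <- cc
    cc <- F_ * c_prev + I * G
    tc <- tanh(cc)
    h_prev <- h
    h <- O * tc
    Hseq[, t, ] <- h
    cache[[t]] <- list(Xt = Xt, I = I, F_ = F_, G = G, O = O,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(H = Hseq, cache = cache)
}

lstm_backward <- function(p, X, fw, dH_seq) {
  d <- dim(X); n <- d[1]; Tn <- d[2]; Fi <- d[3]
  H <- nrow(p$U)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dX <- array(0, d)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    cache_t <- fw$cache[[t]]
    dh <- slice_t(dH_seq, t) + dh_next
    dO <- dh * cache_t$tc
    dc <- dh * cache_t$O * (1 - cache_t$tc^2) + dc_next
    dI <- dc * cache_t$G
    dG <- dc * cache_t$I
    dF <- dc * cache_t$c_prev
    dc_next <- dc * cache_t$F_
    dZ <- cbind(
      dI * cache_t$I * (1 - cache_t$I),
      dF * cache_t$F_ * (1 - cache_t$F_),
      dG * (1 - cache_t$G^2),
      dO * cache_t$O * (1 - cache_t$O)
    )
    dW <- dW + crossprod(cache_t$Xt, dZ)
    dU <- dU + crossprod(cache_t$h_prev, dZ)
    db <- db + colSums(dZ)
    dh_next <- dZ %*% t(p$U)
    dX[, t, ] <- dZ %*% t(p$W)
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db))
}

reverse_time <- function(X) {
  Tn <- dim(X)[2]
  X[, rev(seq_len(Tn)), , drop = FALSE]
}

bilstm_forward <- function(p, X) {
  fwd <- lstm_forward(p$fwd, X)
  Xr <- reverse_time(X)
  bwd <- lstm_forward(p$bwd, Xr)
  Hb <- reverse_time(bwd$H)
  d <- dim(fwd$H)
  H2 <- array(0, c(d[1], d[2], d[3] + dim(Hb)[3]))
  H2[, , seq_len(d[3])] <- fwd$H
  H2[, , d[3] + seq_len(dim(Hb)[3])] <- Hb
  list(H = H2, fwd = fwd, bwd = bwd, Xr = Xr)
}

bilstm_backward <- function(p, X, fw, dH_seq) {
  Hf <- nrow(p$fwd$U)
  dHf <- dH_seq[, , seq_len(Hf), drop = FALSE]
  dHb <- dH_seq[, , Hf + seq_len(dim(dH_seq)[3] - Hf), drop = FALSE]
  bf <- lstm_backward(p$fwd, X, fw$fwd, dHf)
  bb <- lstm_backward(p$bwd, fw$Xr, fw$bwd, reverse_time(dHb))
  list(
    dX = bf$dX + reverse_time(bb$dX),
    grads = list(fwd = bf$grads, bwd = bb$grads)
  )
}

# --- network: bilstm -> lstm stack -> fc on last timestep ------------------

net_init <- function(input_size, bilstm_units, lstm_units) {
  layers <- list()
  layers$bilstm <- list(
    fwd = lstm_params_init(input_size, bilstm_units),
    bwd = lstm_params_init(input_size, bilstm_units)
  )
  in_size <- 2 * bilstm_units
  for (j in seq_along(lstm_units)) {
    layers[[paste0("lstm", j)]] <- lstm_params_init(in_size, lstm_units[j])
    in_size <- lstm_units[j]
  }
  r <- 1 / sqrt(in_size)
  layers$fc <- list(W = matrix(stats::runif(in_size, -r, r), in_size, 1),
                    b = 0)
  layers
}

net_forward <- function(layers, X) {
  caches <- list()
  caches$bilstm <- bilstm_forward(layers$bilstm, X)
  Hcur <- caches$bilstm$H
  inputs <- list(bilstm = X)
  j <- 1
  while (!is.null(layers[[paste0("lstm", j)]])) {
    nm <- paste0("lstm", j)
    inputs[[nm]] <- Hcur
    caches[[nm]] <- lstm_forward(layers[[nm]], Hcur)
    Hcur <- caches[[nm]]$H
    j <- j + 1
  }
  Tn <- dim(Hcur)[2]
  h_last <- slice_t(Hcur, Tn)
  yhat <- as.numeric(h_last %*% layers$fc$W + layers$fc$b)
  list(yhat = yhat, caches = caches, inputs = inputs, h_last = h_last)
}

net_backward <- function(layers, fw, dyhat) {
  n <- length(dyhat)
  dy <- matrix(dyhat, n, 1)
  grads <- list()
  grads$fc <- list(W = crossprod(fw$h_last, dy), b = sum(dy))
  dh_last <- dy %*% t(layers$fc$W)
  lstm_names <- grep("^lstm", names(layers), value = TRUE)
  # seed the top layer's dH sequence: only the last timestep feeds the fc
  top <- if (length(lstm_names) > 0) lstm_names[length(lstm_names)] else "bilstm"
  top_H <- if (top == "bilstm") fw$caches$bilstm$H else fw$caches[[top]]$H
  dH <- array(0, dim(top_H))
  dH[, dim(top_H)[2], ] <- dh_last
  for (nm in rev(lstm_names)) {
    bk <- lstm_backward(layers[[nm]], fw$inputs[[nm]], fw$caches[[nm]], dH)
    grads[[nm]] <- bk$grads
    dH <- bk$dX
  }
  bk <- bilstm_backward(layers$bilstm, fw$inputs$bilstm, fw$caches$bilstm, dH)
  grads$bilstm <- bk$grads
  grads
}

mse_loss <- function(yhat, y) mean((yhat - y)^2)

# --- Adam over a nested parameter tree -------------------------------------

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (nm in names(p)) {
      r <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
    }
    out
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g^2
    mh <- m2 / (1 - b1^t)
    vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}
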