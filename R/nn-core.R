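# Minimal sequence-model engine: LSTM layers, multi-head self-attention,
# same-padded 1-D convolution, a per-frame linear head, manual reverse-mode
# gradients for all of them, and an Adam optimizer. Sequence tensors use the
# layout (T, B, F): time, batch item, feature; `tbmat()` views them as
# (T*B) x F matrices for the big matrix products.

tbmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

untbmat <- function(m, T_, B) {
  dim(m) <- c(T_, B, ncol(m))
  m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# --- LSTM -----------------------------------------------------------------

lstm_init <- function(nin, units) {
  list(Wx = glorot(nin, 4 * units),
       Wh = glorot(units, 4 * units),
       # forget-gate bias starts at 1 (standard stabilization)
       b = c(rep(0, units), rep(1, units), rep(0, 2 * units)))
}

lstm_forward <- function(p, x) {
  d <- dim(x); T_ <- d[1]; B <- d[2]
  U <- ncol(p$Wh)
  units <- U %/% 4L
  z0 <- tbmat(x) %*% p$Wx
  z0 <- sweep(z0, 2, p$b, "+")
  dim(z0) <- c(T_, B, U)
  H <- array(0, c(T_, B, units)); C <- array(0, c(T_, B, units))
  G <- array(0, c(T_, B, U))  # activated gates [i f g o]
  h <- matrix(0, B, units); cc <- matrix(0, B, units)
  ii <- 1:units; ff <- units + ii; gg <- 2 * units + ii; oo <- 3 * units + ii
  for (t in seq_len(T_)) {
    z <- z0[t, , , drop = FALSE]
    dim(z) <- c(B, U)
    z <- z + h %*% p$Wh
    gi <- sigmoid(z[, ii, drop = FALSE])
    gf <- sigmoid(z[, ff, drop = FALSE])
    gg_ <- tanh(z[, gg, drop = FALSE])
    go <- sigmoid(z[, oo, drop = FALSE])
    cc <- gf * cc + gi * gg_
    h <- go * tanh(cc)
    H[t, , ] <- h; C[t, , ] <- cc
    G[t, , ii] <- gi; G[t, , ff] <- gf; G[t, , gg] <- gg_; G[t, , oo] <- go
  }
  list(out = H, cache = list(x = x, H = H, C = C, G = G, units = units))
}

lstm_backward <- function(p, cache, dH) {
  x <- cache$x; H <- cache$H; C <- cache$C; G <- cache$G
  units <- cache$units
  d <- dim(x); T_ <- d[1]; B <- d[2]
  ii <- 1:units; ff <- units + ii; gg <- 2 * units + ii; oo <- 3 * units + ii
  dZ <- array(0, c(T_, B, 4 * units))
  dh_next <- matrix(0, B, units)
  dc_next <- matrix(0, B, units)
  dWh <- matrix(0, units, 4 * units)
  for (t in seq(T_, 1)) {
    dh <- matrix(dH[t, , ], B, units) + dh_next
    cc <- matrix(C[t, , ], B, units)
    tc <- tanh(cc)
    gi <- matrix(G[t, , ii], B, units); gf <- matrix(G[t, , ff], B, units)
    gg_ <- matrix(G[t, , gg], B, units); go <- matrix(G[t, , oo], B, units)
    dc <- dh * go * (1 - tc^2) + dc_next
    c_prev <- if (t > 1) matrix(C[t - 1, , ], B, units) else matrix(0, B, units)
    dzi <- dc * gg_ * gi * (1 - gi)
    dzf <- dc * c_prev * gf * (1 - gf)
    dzg <- dc * gi * (1 - gg_^2)
    dzo <- dh * tc * go * (1 - go)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dZ[t, , ] <- dz
    h_prev <- if (t > 1) matrix(H[t - 1, , ], B, units) else matrix(0, B, units)
    dWh <- dWh + crossprod(h_prev, dz)
    dh_next <- dz %*% t(p$Wh)
    dc_next <- dc * gf
  }
  dZm <- tbmat(dZ)
  list(grads = list(Wx = crossprod(tbmat(x), dZm), Wh = dWh, b = colSums(dZm)),
       dx = untbmat(dZm %*% t(p$Wx), T_, B))
}

# --- multi-head self-attention (residual) ---------------------------------

attention_init <- function(units, heads, key_dim) {
  hd <- heads * key_dim
  list(Wq = glorot(units, hd), Wk = glorot(units, hd), Wv = glorot(units, hd),
       Wo = glorot(hd, units))
}

attention_forward <- function(p, x, heads, key_dim) {
  d <- dim(x); T_ <- d[1]; B <- d[2]; U <- d[3]
  hd <- heads * key_dim
  out <- x
  cache <- list(x = x, Q = vector("list", B), K = vector("list", B),
                V = vector("list", B), A = vector("list", B),
                Cc = vector("list", B), heads = heads, key_dim = key_dim)
  sc <- 1 / sqrt(key_dim)
  for (b in seq_len(B)) {
    Hb <- matrix(x[, b, ], T_, U)
    Q <- Hb %*% p$Wq; K <- Hb %*% p$Wk; V <- Hb %*% p$Wv
    A <- vector("list", heads)
    Cc <- matrix(0, T_, hd)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * key_dim + seq_len(key_dim)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * sc
      S <- sweep(S, 1, apply(S, 1, max))
      E <- exp(S)
      Ah <- E / rowSums(E)
      A[[h]] <- Ah
      Cc[, cols] <- Ah %*% V[, cols, drop = FALSE]
    }
    out[, b, ] <- Hb + Cc %*% p$Wo
    cache$Q[[b]] <- Q; cache$K[[b]] <- K; cache$V[[b]] <- V
    cache$A[[b]] <- A; cache$Cc[[b]] <- Cc
  }
  list(out = out, cache = cache)
}

attention_backward <- function(p, cache, dOut) {
  x <- cache$x
  d <- dim(x); T_ <- d[1]; B <- d[2]; U <- d[3]
  heads <- cache$heads; key_dim <- cache$key_dim
  sc <- 1 / sqrt(key_dim)
  g <- list(Wq = matrix(0, U, heads * key_dim),
            Wk = matrix(0, U, heads * key_dim),
            Wv = matrix(0, U, heads * key_dim),
            Wo = matrix(0, heads * key_dim, U))
  dx <- dOut  # residual path
  for (b in seq_len(B)) {
    Hb <- matrix(x[, b, ], T_, U)
    dO <- matrix(dOut[, b, ], T_, U)
    dC <- dO %*% t(p$Wo)
    g$Wo <- g$Wo + crossprod(cache$Cc[[b]], dO)
    Q <- cache$Q[[b]]; K <- cache$K[[b]]; V <- cache$V[[b]]
    dQ <- Q * 0; dK <- K * 0; dV <- V * 0
    for (h in seq_len(heads)) {
      cols <- (h - 1) * key_dim + seq_len(key_dim)
      Ah <- cache$A[[b]][[h]]
      dCh <- dC[, cols, drop = FALSE]
      dA <- tcrossprod(dCh, V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(Ah, dCh)
      dS <- (dA - rowSums(dA * Ah)) * Ah * sc
      dQ[, cols] <- dS %*% K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, Q[, cols, drop = FALSE])
    }
    g$Wq <- g$Wq + crossprod(Hb, dQ)
    g$Wk <- g$Wk + crossprod(Hb, dK)
    g$Wv <- g$Wv + crossprod(Hb, dV)
    dx[, b, ] <- dx[, b, ] + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(grads = g, dx = dx)
}

# --- 1-D convolution over time (kernel 3, same zero padding, relu) --------

conv_init <- function(nin, filters, kernel = 3) {
  lim <- sqrt(6 / (nin * kernel + filters))  # fan-in counts all taps
  list(W = lapply(seq_len(kernel), function(k) {
    matrix(stats::runif(nin * filters, -lim, lim), nin, filters)
  }),
  b = rep(0, filters))
}

shift_time <- function(x, by) {
  # by = -1: previous frame at slot t; by = +1: next frame; zero padded
  d <- dim(x); T_ <- d[1]
  out <- array(0, d)
  if (by < 0) out[(1 - by):T_, , ] <- x[1:(T_ + by), , , drop = FALSE]
  else if (by > 0) out[1:(T_ - by), , ] <- x[(1 + by):T_, , , drop = FALSE]
  else out <- x
  out
}

conv_forward <- function(p, x) {
  kernel <- length(p$W)
  offs <- seq_len(kernel) - (kernel + 1) %/% 2
  d <- dim(x); T_ <- d[1]; B <- d[2]
  pre <- matrix(0, T_ * B, length(p$b))
  shifted <- vector("list", kernel)
  for (k in seq_len(kernel)) {
    shifted[[k]] <- shift_time(x, offs[k])
    pre <- pre + tbmat(shifted[[k]]) %*% p$W[[k]]
  }
  pre <- sweep(pre, 2, p$b, "+")
  act <- pmax(pre, 0)
  list(out = untbmat(act, T_, B),
       cache = list(shifted = shifted, mask = pre > 0, offs = offs,
                    T_ = T_, B = B, nin = d[3]))
}

conv_backward <- function(p, cache, dOut) {
  dAct <- tbmat(dOut) * cache$mask
  gW <- vector("list", length(p$W))
  dx <- array(0, c(cache$T_, cache$B, cache$nin))
  for (k in seq_along(p$W)) {
    gW[[k]] <- crossprod(tbmat(cache$shifted[[k]]), dAct)
    dxk <- untbmat(dAct %*% t(p$W[[k]]), cache$T_, cache$B)
    dx <- dx + shift_time(dxk, -cache$offs[k])
  }
  list(grads = list(W = gW, b = colSums(dAct)), dx = dx)
}

# --- layer normalization (per frame over features) ------------------------
# keeps recurrent layers downstream of the relu convolution from saturating:
# nonnegative conv outputs otherwise drift the LSTM cell state over the
# 101-step sequence until tanh pegs and gradients vanish.

layernorm_init <- function(nf) list(g = rep(1, nf), b = rep(0, nf))

layernorm_forward <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  xm <- tbmat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xn <- xc * istd
  out <- sweep(xn, 2, p$g, "*")
  out <- sweep(out, 2, p$b, "+")
  list(out = untbmat(out, d[1], d[2]),
       cache = list(xn = xn, istd = istd, T_ = d[1], B = d[2]))
}

layernorm_backward <- function(p, cache, dOut) {
  dOm <- tbmat(dOut)
  xn <- cache$xn
  nf <- ncol(xn)
  dxn <- sweep(dOm, 2, p$g, "*")
  # d/dx of (x - mu) / sd with row statistics
  dx <- (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn)) * cache$istd
  list(grads = list(g = colSums(dOm * xn), b = colSums(dOm)),
       dx = untbmat(dx, cache$T_, cache$B))
}

# --- per-frame linear head ------------------------------------------------

dense_init <- function(nin, nout) list(W = glorot(nin, nout), b = rep(0, nout))

dense_forward <- function(p, x) {
  d <- dim(x)
  out <- sweep(tbmat(x) %*% p$W, 2, p$b, "+")
  list(out = untbmat(out, d[1], d[2]), cache = list(x = x))
}

dense_backward <- function(p, cache, dOut) {
  d <- dim(cache$x)
  dOm <- tbmat(dOut)
  list(grads = list(W = crossprod(tbmat(cache$x), dOm), b = colSums(dOm)),
       dx = untbmat(dOm %*% t(p$W), d[1], d[2]))
}

# --- parameter plumbing and Adam ------------------------------------------

param_map <- function(params, f) {
  if (is.list(params)) lapply(params, param_map, f = f) else f(params)
}

param_zip <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- param_zip(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  state$m <- param_zip(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_zip(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- param_map(state$m, function(m) m / bc1)
  vh <- param_map(state$v, function(v) v / bc2)
  upd <- param_zip(mh, vh, function(m, v) lr * m / (sqrt(v) + eps))
  list(params = param_zip(params, upd, `-`), state = state)
}
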