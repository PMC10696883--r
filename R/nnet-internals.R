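# Internal neural-network engine: forward, backprop and Adam for the
# convolutional-recurrent architecture. Everything operates on batches
# (first array dimension) in double precision; per-sample computations are
# independent, which is what makes predictions batch-size invariant.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# Glorot-uniform initialisation
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# one-hot encode a character vector of equal-length sequences into B x L x 4
encode_batch <- function(seqs) {
  B <- length(seqs)
  L <- nchar(seqs[1L])
  arr <- array(0, dim = c(B, L, 4L))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = B, byrow = TRUE)
  idx <- match(chars, DNA_BASES)           # column-major over B x L
  pos <- which(!is.na(idx))
  b <- ((pos - 1L) %% B) + 1L
  l <- ((pos - 1L) %/% B) + 1L
  arr[cbind(b, l, idx[pos])] <- 1
  arr
}

init_params <- function(cfg) {
  p <- list()
  feat <- 4L
  if (cfg$use_conv) {
    k <- cfg$kernel_len
    p$Wc <- glorot(4L * k, cfg$conv_kernels)
    p$bc <- numeric(cfg$conv_kernels)
    feat <- cfg$conv_kernels
  }
  H <- cfg$rnn_units
  ngate <- if (cfg$rnn_cell == "lstm") 4L else 3L
  init_cell <- function() {
    b <- numeric(ngate * H)
    if (cfg$rnn_cell == "lstm") b[H + seq_len(H)] <- 1   # forget-gate bias 1
    list(Wx = glorot(feat, ngate * H), Wh = glorot(H, ngate * H), b = b)
  }
  p$fw <- init_cell()
  if (cfg$bidirectional) p$bw <- init_cell()
  R <- if (cfg$bidirectional) 2L * H else H
  p$Wd <- glorot(R, cfg$dense_units)
  p$bd <- numeric(cfg$dense_units)
  p$Wo <- glorot(cfg$dense_units, 1L)
  p$bo <- 0
  p
}

count_params <- function(p) {
  sum(vapply(rapply(p, identity, how = "unlist"), length, integer(1)))
}

add_bias <- function(Z, b) sweep(Z, 2L, b, "+")

# ---- convolution (via im2col) -------------------------------------------

conv_forward <- function(X, Wc, bc, k) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  T_out <- L - k + 1L
  Xc <- matrix(0, B * T_out, 4L * k)
  for (t in seq_len(T_out)) {
    Xc[(t - 1L) * B + seq_len(B), ] <- matrix(X[, t:(t + k - 1L), ,
                                                drop = FALSE], nrow = B)
  }
  Zc <- add_bias(Xc %*% Wc, bc)
  Ac <- relu(Zc)
  list(A = array(Ac, dim = c(B, T_out, ncol(Wc))), Xc = Xc, Zc = Zc,
       T_out = T_out)
}

conv_backward <- function(cache, dA) {
  B <- dim(dA)[1L]; T_out <- dim(dA)[2L]; K <- dim(dA)[3L]
  dAc <- matrix(dA, B * T_out, K)          # same b-fastest layout as forward
  dZc <- dAc * (cache$Zc > 0)
  list(dWc = crossprod(cache$Xc, dZc), dbc = colSums(dZc))
}

# ---- temporal max pooling ------------------------------------------------

pool_forward <- function(A, pool) {
  B <- dim(A)[1L]; T_out <- dim(A)[2L]; K <- dim(A)[3L]
  T_p <- T_out %/% pool
  P <- array(-Inf, dim = c(B, T_p, K))
  arg <- array(1L, dim = c(B, T_p, K))
  for (tp in seq_len(T_p)) {
    for (j in seq_len(pool)) {
      s <- A[, (tp - 1L) * pool + j, ]
      upd <- s > P[, tp, ]
      Ptp <- P[, tp, ]; atp <- arg[, tp, ]
      Ptp[upd] <- s[upd]; atp[upd] <- j
      P[, tp, ] <- Ptp; arg[, tp, ] <- atp
    }
  }
  list(P = P, arg = arg, T_out = T_out, pool = pool)
}

pool_backward <- function(cache, dP) {
  B <- dim(dP)[1L]; T_p <- dim(dP)[2L]; K <- dim(dP)[3L]
  dA <- array(0, dim = c(B, cache$T_out, K))
  for (tp in seq_len(T_p)) {
    for (j in seq_len(cache$pool)) {
      sel <- cache$arg[, tp, ] == j
      d <- dP[, tp, ]; d[!sel] <- 0
      dA[, (tp - 1L) * cache$pool + j, ] <- dA[, (tp - 1L) * cache$pool + j, ] + d
    }
  }
  dA
}

# ---- recurrent cells -----------------------------------------------------

# inputs: list over timesteps of B x F matrices; returns last hidden state
cell_forward <- function(cp, inputs, H, type) {
  B <- nrow(inputs[[1L]])
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  steps <- vector("list", length(inputs))
  for (t in seq_along(inputs)) {
    x <- inputs[[t]]
    Z <- add_bias(x %*% cp$Wx + h %*% cp$Wh, cp$b)
    if (type == "lstm") {
      i <- sigmoid(Z[, seq_len(H), drop = FALSE])
      f <- sigmoid(Z[, H + seq_len(H), drop = FALSE])
      g <- tanh(Z[, 2L * H + seq_len(H), drop = FALSE])
      o <- sigmoid(Z[, 3L * H + seq_len(H), drop = FALSE])
      c_new <- f * c + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      steps[[t]] <- list(x = x, h_prev = h, c_prev = c,
                         i = i, f = f, g = g, o = o, tc = tc)
      h <- h_new; c <- c_new
    } else {                               # gru
      # note: candidate uses r * h_prev, so Z's third block is recomputed
      zg <- sigmoid(Z[, seq_len(H), drop = FALSE])
      rg <- sigmoid(Z[, H + seq_len(H), drop = FALSE])
      Whn <- cp$Wh[, 2L * H + seq_len(H), drop = FALSE]
      n_pre <- x %*% cp$Wx[, 2L * H + seq_len(H), drop = FALSE] +
        (rg * h) %*% Whn
      n_pre <- add_bias(n_pre, cp$b[2L * H + seq_len(H)])
      ng <- tanh(n_pre)
      h_new <- (1 - zg) * ng + zg * h
      steps[[t]] <- list(x = x, h_prev = h, z = zg, r = rg, n = ng)
      h <- h_new
    }
  }
  list(h_last = h, steps = steps)
}

cell_backward <- function(cp, cache, dh_last, H, type, need_dx = TRUE) {
  steps <- cache$steps
  Tn <- length(steps)
  dWx <- matrix(0, nrow(cp$Wx), ncol(cp$Wx))
  dWh <- matrix(0, nrow(cp$Wh), ncol(cp$Wh))
  db <- numeric(length(cp$b))
  dx <- if (need_dx) vector("list", Tn) else NULL
  dh <- dh_last
  dc <- matrix(0, nrow(dh), H)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    if (type == "lstm") {
      do <- dh * st$tc
      dcc <- dc + dh * st$o * (1 - st$tc^2)
      di <- dcc * st$g
      dg <- dcc * st$i
      df <- dcc * st$c_prev
      dc <- dcc * st$f
      dZ <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      dWx <- dWx + crossprod(st$x, dZ)
      dWh <- dWh + crossprod(st$h_prev, dZ)
      db <- db + colSums(dZ)
      dh <- dZ %*% t(cp$Wh)
      if (need_dx) dx[[t]] <- dZ %*% t(cp$Wx)
    } else {
      zi <- seq_len(H); ri <- H + seq_len(H); ni <- 2L * H + seq_len(H)
      dz <- dh * (st$h_prev - st$n)
      dn <- dh * (1 - st$z)
      dh_prev <- dh * st$z
      dn_pre <- dn * (1 - st$n^2)
      dWx[, ni] <- dWx[, ni] + crossprod(st$x, dn_pre)
      dWh[, ni] <- dWh[, ni] + crossprod(st$r * st$h_prev, dn_pre)
      db[ni] <- db[ni] + colSums(dn_pre)
      drh <- dn_pre %*% t(cp$Wh[, ni, drop = FALSE])
      dr <- drh * st$h_prev
      dh_prev <- dh_prev + drh * st$r
      dz_pre <- dz * st$z * (1 - st$z)
      dr_pre <- dr * st$r * (1 - st$r)
      dWx[, zi] <- dWx[, zi] + crossprod(st$x, dz_pre)
      dWx[, ri] <- dWx[, ri] + crossprod(st$x, dr_pre)
      dWh[, zi] <- dWh[, zi] + crossprod(st$h_prev, dz_pre)
      dWh[, ri] <- dWh[, ri] + crossprod(st$h_prev, dr_pre)
      db[zi] <- db[zi] + colSums(dz_pre)
      db[ri] <- db[ri] + colSums(dr_pre)
      dh <- dh_prev + dz_pre %*% t(cp$Wh[, zi, drop = FALSE]) +
        dr_pre %*% t(cp$Wh[, ri, drop = FALSE])
      if (need_dx) {
        dx[[t]] <- dn_pre %*% t(cp$Wx[, ni, drop = FALSE]) +
          dz_pre %*% t(cp$Wx[, zi, drop = FALSE]) +
          dr_pre %*% t(cp$Wx[, ri, drop = FALSE])
      }
    }
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dx = dx)
}

# ---- full network --------------------------------------------------------

# training=TRUE draws inverted-dropout masks from the current RNG stream
net_forward <- function(params, cfg, X, training = FALSE) {
  B <- dim(X)[1L]
  cache <- list()
  if (cfg$use_conv) {
    cache$conv <- conv_forward(X, params$Wc, params$bc, cfg$kernel_len)
    cache$pool <- pool_forward(cache$conv$A, cfg$pool_size)
    feat_arr <- cache$pool$P
    if (training && cfg$conv_dropout > 0) {
      keep <- 1 - cfg$conv_dropout
      cache$conv_mask <- array(rbinom(length(feat_arr), 1L, keep) / keep,
                               dim = dim(feat_arr))
      feat_arr <- feat_arr * cache$conv_mask
    }
  } else {
    feat_arr <- X
  }
  Tn <- dim(feat_arr)[2L]
  inputs <- lapply(seq_len(Tn), function(t) feat_arr[, t, , drop = TRUE] |>
                     matrix(nrow = B))
  cache$inputs_T <- Tn
  H <- cfg$rnn_units
  cache$fw <- cell_forward(params$fw, inputs, H, cfg$rnn_cell)
  if (cfg$bidirectional) {
    cache$bw <- cell_forward(params$bw, rev(inputs), H, cfg$rnn_cell)
    Hcat <- cbind(cache$fw$h_last, cache$bw$h_last)
  } else {
    Hcat <- cache$fw$h_last
  }
  cache$Hcat <- Hcat
  cache$Zd <- add_bias(Hcat %*% params$Wd, params$bd)
  Ad <- relu(cache$Zd)
  if (training && cfg$dense_dropout > 0) {
    keep <- 1 - cfg$dense_dropout
    cache$dense_mask <- matrix(rbinom(length(Ad), 1L, keep) / keep,
                               nrow(Ad), ncol(Ad))
    Ad <- Ad * cache$dense_mask
  }
  cache$Ad <- Ad
  logits <- add_bias(Ad %*% params$Wo, params$bo)
  list(prob = as.numeric(sigmoid(logits)), cache = cache)
}

net_backward <- function(params, cfg, X, y, fwd) {
  B <- dim(X)[1L]
  cache <- fwd$cache
  g <- list()
  dlogit <- matrix((fwd$prob - y) / B, ncol = 1L)
  g$Wo <- crossprod(cache$Ad, dlogit)
  g$bo <- sum(dlogit)
  dAd <- dlogit %*% t(params$Wo)
  if (!is.null(cache$dense_mask)) dAd <- dAd * cache$dense_mask
  dZd <- dAd * (cache$Zd > 0)
  g$Wd <- crossprod(cache$Hcat, dZd)
  g$bd <- colSums(dZd)
  dHcat <- dZd %*% t(params$Wd)
  H <- cfg$rnn_units
  need_dx <- cfg$use_conv
  bk_fw <- cell_backward(params$fw, cache$fw,
                         dHcat[, seq_len(H), drop = FALSE],
                         H, cfg$rnn_cell, need_dx)
  g$fw <- bk_fw$grads
  if (cfg$bidirectional) {
    bk_bw <- cell_backward(params$bw, cache$bw,
                           dHcat[, H + seq_len(H), drop = FALSE],
                           H, cfg$rnn_cell, need_dx)
    g$bw <- bk_bw$grads
  }
  if (cfg$use_conv) {
    Tn <- cache$inputs_T
    K <- cfg$conv_kernels
    dP <- array(0, dim = c(B, Tn, K))
    for (t in seq_len(Tn)) {
      d <- bk_fw$dx[[t]]
      if (cfg$bidirectional) d <- d + bk_bw$dx[[Tn - t + 1L]]
      dP[, t, ] <- d
    }
    if (!is.null(cache$conv_mask)) dP <- dP * cache$conv_mask
    dA <- pool_backward(cache$pool, dP)
    cb <- conv_backward(cache$conv, dA)
    g$Wc <- cb$dWc
    g$bc <- cb$dbc
  }
  g
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam with per-unit max-norm projection ------------------------------

adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- lapply(names(p), function(nm) upd(p[[nm]], g[[nm]],
                                               m[[nm]], v[[nm]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tt))
}

# rescale columns (incoming weights of each unit) whose L2 norm exceeds c
max_norm_project <- function(W, c) {
  nrm <- sqrt(colSums(W^2))
  over <- nrm > c
  if (any(over)) W[, over] <- sweep(W[, over, drop = FALSE], 2L,
                                    c / nrm[over], "*")
  W
}
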