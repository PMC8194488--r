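# Layer primitives for the emotion network: each *_fwd returns its output
# plus the cache its *_bwd needs.  Tensors are plain numeric arrays laid out
# [time, frequency, channel]; reshapes to matrices rely on R's column-major
# order, so array element (i, j, c) maps to matrix row i + (j-1)*t, column c.

sigmoid <- function(x) 1 / (1 + exp(-x))

as_tf_matrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_tf_array <- function(m, t_len, f_len) {
  dim(m) <- c(t_len, f_len, ncol(m))
  m
}

# ---- convolutions ----------------------------------------------------------

# 1x1 convolution: a per-position linear map across channels.
conv1x1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- as_tf_matrix(x)
  out <- xm %*% W
  out <- sweep(out, 2, b, "+")
  list(out = as_tf_array(out, d[1], d[2]), cache = list(xm = xm, d = d))
}

conv1x1_bwd <- function(dout, W, cache) {
  dm <- as_tf_matrix(dout)
  list(
    dW = crossprod(cache$xm, dm),
    db = colSums(dm),
    dx = as_tf_array(dm %*% t(W), cache$d[1], cache$d[2])
  )
}

# 3x3 same-padded convolution, implemented as 9 shifted channel-mixing
# matrix products over a zero-padded copy of the input.
conv3x3_fwd <- function(x, W, b) {
  d <- dim(x)
  t_len <- d[1]; f_len <- d[2]; c_in <- d[3]; c_out <- dim(W)[4]
  xp <- array(0, dim = c(t_len + 2L, f_len + 2L, c_in))
  xp[2:(t_len + 1L), 2:(f_len + 1L), ] <- x
  out <- matrix(rep(b, each = t_len * f_len), t_len * f_len, c_out)
  for (di in 0:2) {
    for (dj in 0:2) {
      xs <- xp[di + seq_len(t_len), dj + seq_len(f_len), , drop = FALSE]
      dim(xs) <- c(t_len * f_len, c_in)
      wm <- matrix(W[di + 1L, dj + 1L, , ], c_in, c_out)
      out <- out + xs %*% wm
    }
  }
  list(out = as_tf_array(out, t_len, f_len), cache = list(xp = xp, d = d))
}

conv3x3_bwd <- function(dout, W, cache) {
  d <- cache$d
  t_len <- d[1]; f_len <- d[2]; c_in <- d[3]; c_out <- dim(W)[4]
  dm <- as_tf_matrix(dout)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(cache$xp))
  for (di in 0:2) {
    for (dj in 0:2) {
      xs <- cache$xp[di + seq_len(t_len), dj + seq_len(f_len), , drop = FALSE]
      dim(xs) <- c(t_len * f_len, c_in)
      wm <- matrix(W[di + 1L, dj + 1L, , ], c_in, c_out)
      dW[di + 1L, dj + 1L, , ] <- crossprod(xs, dm)
      dxs <- dm %*% t(wm)
      dim(dxs) <- c(t_len, f_len, c_in)
      dxp[di + seq_len(t_len), dj + seq_len(f_len), ] <-
        dxp[di + seq_len(t_len), dj + seq_len(f_len), , drop = FALSE] + dxs
    }
  }
  list(dW = dW, db = colSums(dm),
       dx = dxp[2:(t_len + 1L), 2:(f_len + 1L), , drop = FALSE])
}

# ---- normalization and activation ------------------------------------------

# Per-channel normalization over the time-frequency positions of one sample
# (deterministic at train and test time), with learned scale and shift.
chan_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- as_tf_matrix(x)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = as_tf_array(out, d[1], d[2]),
       cache = list(xhat = xhat, istd = istd, d = d))
}

chan_norm_bwd <- function(dout, gamma, cache) {
  dm <- as_tf_matrix(dout)
  xhat <- cache$xhat
  n <- nrow(dm)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, gamma, "*")
  dx <- sweep(
    dxhat -
      matrix(rep(colMeans(dxhat), each = n), n) -
      xhat * matrix(rep(colMeans(dxhat * xhat), each = n), n),
    2, cache$istd, "*"
  )
  list(dx = as_tf_array(dx, cache$d[1], cache$d[2]),
       dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dout, mask) dout * mask

# ---- max pooling ------------------------------------------------------------

# Non-overlapping max pooling (stride equals size).  Trailing rows/columns
# that do not fill a window are dropped (floor semantics).
maxpool_fwd <- function(x, pt = 2L, pf = 4L) {
  d <- dim(x)
  t2 <- d[1] %/% pt
  f2 <- d[2] %/% pf
  if (t2 < 1L || f2 < 1L) {
    rlang::abort(sprintf(
      "Input %d x %d too small for %d x %d pooling.", d[1], d[2], pt, pf
    ), class = "resemote_shape_error")
  }
  cc <- d[3]
  # linear indices of every window member, one window per row
  oi <- rep(seq_len(t2), times = f2 * cc)
  oj <- rep(rep(seq_len(f2), each = t2), times = cc)
  oc <- rep(seq_len(cc), each = t2 * f2)
  base <- ((oi - 1L) * pt) + ((oj - 1L) * pf) * d[1] + (oc - 1L) * d[1] * d[2]
  offs <- as.vector(outer(seq_len(pt), (seq_len(pf) - 1L) * d[1], "+"))
  idx <- outer(base, offs, "+")
  vals <- x[as.vector(idx)]
  dim(vals) <- dim(idx)
  pick <- max.col(vals, ties.method = "first")
  chosen <- idx[cbind(seq_along(pick), pick)]
  out <- x[chosen]
  dim(out) <- c(t2, f2, cc)
  list(out = out, cache = list(chosen = chosen, d = d))
}

maxpool_bwd <- function(dout, cache) {
  dx <- array(0, dim = cache$d)
  dx[cache$chosen] <- as.vector(dout)
  dx
}

# ---- LSTM -------------------------------------------------------------------

# One recurrent direction.  Gates follow the peephole-style formulation:
#   f_t = sigma(Wcf c_{t-1} + Whf h_{t-1} + Wxf x_t + bf)
#   i_t = sigma(Wci c_{t-1} + Whi h_{t-1} + Wxi x_t + bi)
#   c_t = f_t c_{t-1} + i_t tanh(Whc h_{t-1} + Wxc x_t + bc)
#   o_t = sigma(Wco c_t   + Who h_{t-1} + Wxo x_t + bo)
#   h_t = o_t tanh(c_t)
# The cell-state terms use full (not diagonal) matrices, matching the written
# form; note o_t peeks at the *current* cell state.

init_lstm_params <- function(d_in, hidden) {
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  list(
    Wxf = mk(hidden, d_in), Whf = mk(hidden, hidden), Wcf = mk(hidden, hidden),
    bf = rep(1, hidden),  # forget-gate bias starts open
    Wxi = mk(hidden, d_in), Whi = mk(hidden, hidden), Wci = mk(hidden, hidden),
    bi = rep(0, hidden),
    Wxc = mk(hidden, d_in), Whc = mk(hidden, hidden), bc = rep(0, hidden),
    Wxo = mk(hidden, d_in), Who = mk(hidden, hidden), Wco = mk(hidden, hidden),
    bo = rep(0, hidden)
  )
}

#' One LSTM step
#'
#' Applies the gated recurrence (forget, input and output gates with
#' cell-state feedback terms) for a single time step.  Exposed mainly for
#' inspection and testing; [bilstm_forward()] drives whole sequences.
#'
#' @param x_t Input vector at time `t`.
#' @param h_prev,c_prev Previous hidden state and cell state.
#' @param params Parameter list as produced inside [init_emotion_model()]
#'   (`Wxf`, `Whf`, `Wcf`, `bf`, ... `bo`).
#' @return A list with `h`, `c`, and the gate activations `f`, `i`, `o`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  p <- params
  f <- sigmoid(as.vector(p$Wcf %*% c_prev + p$Whf %*% h_prev + p$Wxf %*% x_t) + p$bf)
  i <- sigmoid(as.vector(p$Wci %*% c_prev + p$Whi %*% h_prev + p$Wxi %*% x_t) + p$bi)
  g <- tanh(as.vector(p$Whc %*% h_prev + p$Wxc %*% x_t) + p$bc)
  c_t <- f * c_prev + i * g
  o <- sigmoid(as.vector(p$Wco %*% c_t + p$Who %*% h_prev + p$Wxo %*% x_t) + p$bo)
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, o = o)
}

# Forward pass of one direction over a T x D input matrix; returns T x H
# hidden states and the per-step cache for backprop.
lstm_fwd <- function(xs, params) {
  p <- params
  T_len <- nrow(xs)
  H <- length(p$bf)
  Xf <- p$Wxf %*% t(xs); Xi <- p$Wxi %*% t(xs)
  Xg <- p$Wxc %*% t(xs); Xo <- p$Wxo %*% t(xs)
  hs <- matrix(0, H, T_len)
  Fm <- matrix(0, H, T_len); Im <- Fm; Gm <- Fm; Om <- Fm
  Cm <- Fm; TanC <- Fm
  h <- numeric(H); cst <- numeric(H)
  h_prev <- matrix(0, H, T_len)  # h_{t-1} per step
  c_prev <- matrix(0, H, T_len)  # c_{t-1} per step
  for (t in seq_len(T_len)) {
    h_prev[, t] <- h; c_prev[, t] <- cst
    f <- sigmoid(as.vector(p$Wcf %*% cst + p$Whf %*% h) + Xf[, t] + p$bf)
    i <- sigmoid(as.vector(p$Wci %*% cst + p$Whi %*% h) + Xi[, t] + p$bi)
    g <- tanh(as.vector(p$Whc %*% h) + Xg[, t] + p$bc)
    cst <- f * cst + i * g
    o <- sigmoid(as.vector(p$Wco %*% cst + p$Who %*% h) + Xo[, t] + p$bo)
    h <- o * tanh(cst)
    Fm[, t] <- f; Im[, t] <- i; Gm[, t] <- g; Om[, t] <- o
    Cm[, t] <- cst; TanC[, t] <- tanh(cst)
    hs[, t] <- h
  }
  list(hs = t(hs),
       cache = list(xs = xs, Fm = Fm, Im = Im, Gm = Gm, Om = Om, Cm = Cm,
                    TanC = TanC, h_prev = h_prev, c_prev = c_prev))
}

lstm_bwd <- function(dhs, params, cache) {
  p <- params
  T_len <- nrow(dhs)
  H <- ncol(dhs)
  dAf <- matrix(0, H, T_len); dAi <- dAf; dAg <- dAf; dAo <- dAf
  dh_next <- numeric(H)
  dc_next <- numeric(H)
  for (t in rev(seq_len(T_len))) {
    dh <- dhs[t, ] + dh_next
    o <- cache$Om[, t]; f <- cache$Fm[, t]; i <- cache$Im[, t]
    g <- cache$Gm[, t]; tc <- cache$TanC[, t]
    do <- dh * tc
    dao <- do * o * (1 - o)
    dc <- dc_next + dh * o * (1 - tc^2) + as.vector(crossprod(p$Wco, dao))
    df <- dc * cache$c_prev[, t]
    daf <- df * f * (1 - f)
    di <- dc * g
    dai <- di * i * (1 - i)
    dg <- dc * i
    dag <- dg * (1 - g^2)
    dc_next <- dc * f + as.vector(crossprod(p$Wcf, daf)) +
      as.vector(crossprod(p$Wci, dai))
    dh_next <- as.vector(crossprod(p$Whf, daf)) +
      as.vector(crossprod(p$Whi, dai)) +
      as.vector(crossprod(p$Whc, dag)) +
      as.vector(crossprod(p$Who, dao))
    dAf[, t] <- daf; dAi[, t] <- dai; dAg[, t] <- dag; dAo[, t] <- dao
  }
  xs <- cache$xs
  hp <- t(cache$h_prev); cp <- t(cache$c_prev); ct <- t(cache$Cm)
  grads <- list(
    Wxf = dAf %*% xs, Whf = dAf %*% hp, Wcf = dAf %*% cp, bf = rowSums(dAf),
    Wxi = dAi %*% xs, Whi = dAi %*% hp, Wci = dAi %*% cp, bi = rowSums(dAi),
    Wxc = dAg %*% xs, Whc = dAg %*% hp, bc = rowSums(dAg),
    Wxo = dAo %*% xs, Who = dAo %*% hp, Wco = dAo %*% ct, bo = rowSums(dAo)
  )
  dxs <- t(crossprod(p$Wxf, dAf) + crossprod(p$Wxi, dAi) +
             crossprod(p$Wxc, dAg) + crossprod(p$Wxo, dAo))
  list(grads = grads, dxs = dxs)
}

#' Bidirectional LSTM encoding of a sequence
#'
#' Runs a forward-direction and a backward-direction LSTM over the input and
#' concatenates their hidden states per step, so with `H` hidden units per
#' direction every output step has dimension `2 H` (256 with the default 128
#' units per direction).
#'
#' @param xs A `T x D` matrix, one row per time step.
#' @param params List with elements `fwd` and `bwd`, each an LSTM parameter
#'   list.
#' @param keep_cache Retain layer caches for backpropagation.
#' @return A list with `hs` (`T x 2H` matrix, forward half first) and,
#'   if requested, `cache`.
#' @export
bilstm_forward <- function(xs, params, keep_cache = FALSE) {
  if (is.null(dim(xs)) || nrow(xs) < 1L) {
    rlang::abort("Empty sequence.", class = "resemote_empty_sequence")
  }
  fw <- lstm_fwd(xs, params$fwd)
  bw <- lstm_fwd(xs[rev(seq_len(nrow(xs))), , drop = FALSE], params$bwd)
  hs <- cbind(fw$hs, bw$hs[rev(seq_len(nrow(xs))), , drop = FALSE])
  if (keep_cache) list(hs = hs, cache = list(fw = fw$cache, bw = bw$cache))
  else list(hs = hs)
}

bilstm_bwd <- function(dhs, params, cache) {
  T_len <- nrow(dhs)
  H <- ncol(dhs) / 2L
  dfw <- lstm_bwd(dhs[, seq_len(H), drop = FALSE], params$fwd, cache$fw)
  dbw <- lstm_bwd(dhs[rev(seq_len(T_len)), H + seq_len(H), drop = FALSE],
                  params$bwd, cache$bw)
  list(
    grads = list(fwd = dfw$grads, bwd = dbw$grads),
    dxs = dfw$dxs + dbw$dxs[rev(seq_len(T_len)), , drop = FALSE]
  )
}

# ---- attention pooling ------------------------------------------------------

#' Attention pooling over sequence states
#'
#' Scores each step with a scalar projection squashed by a sigmoid (or,
#' optionally, tanh), normalizes the exponentiated scores to weights summing
#' to one, and returns the weighted sum of the states.  With the sigmoid
#' squashing the exponent lies in (0, 1), so no weight can exceed `e` times
#' any other.
#'
#' @param hs `T x D` matrix of sequence states.
#' @param params List with `w1` (length-`D` projection), `b` (scalar), and
#'   optionally `score_fn` (`"sigmoid"`, the default, or `"tanh"`).
#' @param keep_cache Retain the cache for backpropagation.
#' @return List with `r` (pooled length-`D` vector), `alpha` (weights summing
#'   to one), and optionally `cache`.
#' @export
attention_pool <- function(hs, params, keep_cache = FALSE) {
  if (is.null(dim(hs)) || nrow(hs) < 1L) {
    rlang::abort("Empty sequence.", class = "resemote_empty_sequence")
  }
  score_fn <- params$score_fn %||% "sigmoid"
  s <- as.vector(hs %*% params$w1) + params$b
  z <- if (score_fn == "tanh") tanh(s) else sigmoid(s)
  e <- exp(z - max(z))
  alpha <- e / sum(e)
  r <- as.vector(crossprod(hs, alpha))
  out <- list(r = r, alpha = alpha)
  if (keep_cache) out$cache <- list(hs = hs, z = z, alpha = alpha,
                                    score_fn = score_fn)
  out
}

attention_bwd <- function(dr, params, cache) {
  hs <- cache$hs
  alpha <- cache$alpha
  da <- as.vector(hs %*% dr)
  dhs <- tcrossprod(alpha, dr)
  dz <- alpha * (da - sum(alpha * da))
  ds <- if (cache$score_fn == "tanh") dz * (1 - cache$z^2)
        else dz * cache$z * (1 - cache$z)
  dhs <- dhs + tcrossprod(ds, params$w1)
  list(dhs = dhs, dw1 = as.vector(crossprod(hs, ds)), db = sum(ds))
}

# ---- classifier head and loss ----------------------------------------------

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Classify a pooled representation
#'
#' Two affine layers with a ReLU between, followed by a softmax over emotion
#' classes.
#'
#' @param r Pooled feature vector.
#' @param params List with `W1`, `b1`, `W2`, `b2`.
#' @param keep_cache Retain the cache for backpropagation.
#' @return List with `probs` (summing to one) and `label` (argmax index,
#'   lowest index on ties).
#' @export
classify <- function(r, params, keep_cache = FALSE) {
  a1 <- as.vector(crossprod(params$W1, r)) + params$b1
  h1 <- pmax(a1, 0)
  logits <- as.vector(crossprod(params$W2, h1)) + params$b2
  probs <- softmax(logits)
  out <- list(probs = probs, label = which.max(probs))
  if (keep_cache) out$cache <- list(r = r, a1 = a1, h1 = h1, probs = probs)
  out
}

classify_bwd <- function(dlogits, params, cache) {
  dW2 <- tcrossprod(cache$h1, dlogits)
  db2 <- dlogits
  dh1 <- as.vector(params$W2 %*% dlogits)
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- tcrossprod(cache$r, da1)
  db1 <- da1
  dr <- as.vector(params$W1 %*% da1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dr = dr)
}

#' Mean cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c y_ic log(p_ic)` with the probability clipped
#' below at `floor` so a zero probability at the true class yields a large
#' finite loss rather than infinity.
#'
#' @param probs `N x C` matrix of predicted class probabilities (rows sum to
#'   one), or a single probability vector.
#' @param targets One-hot `N x C` matrix (or vector) of true labels.
#' @param floor Lower clip for probabilities inside the log.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, targets, floor = 1e-12) {
  probs <- rbind(probs)
  targets <- rbind(targets)
  stopifnot(all(dim(probs) == dim(targets)))
  -mean(rowSums(targets * log(pmax(probs, floor))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
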