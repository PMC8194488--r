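zeroed_block <- function(ch) {
  list(W1 = array(0, c(3, 3, ch, ch)), b1 = rep(0, ch),
       g1 = rep(1, ch), be1 = rep(0, ch),
       W2 = array(0, c(3, 3, ch, ch)), b2 = rep(0, ch),
       g2 = rep(1, ch), be2 = rep(0, ch))
}

test_that("residual block pools 8x16 down to 4x4 and keeps channels", {
  set.seed(1)
  ch <- 128
  x <- array(rnorm(8 * 16 * ch), c(8, 16, ch))
  blk <- zeroed_block(ch)
  blk$W1[] <- rnorm(length(blk$W1), sd = 0.05)
  blk$W2[] <- rnorm(length(blk$W2), sd = 0.05)
  out <- residual_block(x, blk)$out
  expect_identical(dim(out), c(4L, 4L, 128L))
  expect_error(residual_block(array(0, c(1, 3, 4)), zeroed_block(4)),
               class = "resemote_shape_error")
})

test_that("zeroed convolutions reduce the block to the pooled skip input", {
  set.seed(2)
  ch <- 6
  x <- array(abs(rnorm(8 * 8 * ch)), c(8, 8, ch))  # nonnegative: ReLU-transparent
  out <- residual_block(x, zeroed_block(ch))$out
  # oracle: plain 2x4 max pooling of x
  oracle <- array(0, c(4, 2, ch))
  for (i in 1:4) for (j in 1:2) for (cc in 1:ch) {
    oracle[i, j, cc] <- max(x[(2 * i - 1):(2 * i), (4 * j - 3):(4 * j), cc])
  }
  expect_equal(out, oracle)
})

test_that("3x3 convolution matches a direct triple-loop oracle", {
  set.seed(3)
  for (r in 1:3) {
    x <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
    W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
    b <- rnorm(4)
    got <- resemote:::conv3x3_fwd(x, W, b)$out
    expect_equal(got, conv3x3_oracle(x, W, b), tolerance = 1e-5)
  }
})

test_that("the conv front end reshapes to the expected sequence geometry", {
  cfg <- model_config(n_classes = 3, expand_channels = 8,
                      n_residual_blocks = 3, lstm_hidden = 4, fc_hidden = 4,
                      seed = 2)
  m <- init_emotion_model(cfg, n_mels = 64, classes = letters[1:3])
  feat <- array(rnorm(80 * 64 * 3), c(80, 64, 3))
  xs <- rescnn_forward(feat, m)$xs
  expect_identical(dim(xs), c(10L, 8L))  # 80/2^3 steps, 1 freq band x 8 ch

  cfg1 <- cfg; cfg1$n_residual_blocks <- 1L
  m1 <- init_emotion_model(cfg1, n_mels = 64, classes = letters[1:3])
  xs1 <- rescnn_forward(feat, m1)$xs
  expect_identical(nrow(xs1), 4L * nrow(xs))  # 1 block vs 3 blocks: 4:1

  expect_error(init_emotion_model(cfg, n_mels = 16),
               class = "resemote_shape_error")
})

test_that("a zero-parameter LSTM step halves everything through its gates", {
  H <- 4
  p <- lapply(resemote:::init_lstm_params(3, H), function(x) x * 0)
  st <- lstm_step(c(1, -2, 3), rep(0.3, H), rep(0.8, H), p)
  expect_equal(st$f, rep(0.5, H))
  expect_equal(st$i, rep(0.5, H))
  expect_equal(st$o, rep(0.5, H))
  expect_equal(st$c, rep(0.4, H))          # 0.5 * c_prev
  expect_equal(st$h, 0.5 * tanh(rep(0.4, H)))
})

test_that("a scalar LSTM step matches hand evaluation of the gate equations", {
  p <- list(Wxf = matrix(0.5), Whf = matrix(-0.3), Wcf = matrix(0.2), bf = 0.1,
            Wxi = matrix(-0.4), Whi = matrix(0.6), Wci = matrix(-0.1), bi = 0.2,
            Wxc = matrix(0.7), Whc = matrix(0.3), bc = -0.2,
            Wxo = matrix(0.1), Who = matrix(-0.5), Wco = matrix(0.4), bo = 0.3)
  x <- 0.9; h0 <- -0.2; c0 <- 0.5
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(0.2 * c0 - 0.3 * h0 + 0.5 * x + 0.1)
  i <- sig(-0.1 * c0 + 0.6 * h0 - 0.4 * x + 0.2)
  g <- tanh(0.3 * h0 + 0.7 * x - 0.2)
  c1 <- f * c0 + i * g
  o <- sig(0.4 * c1 - 0.5 * h0 + 0.1 * x + 0.3)
  st <- lstm_step(x, h0, c0, p)
  expect_equal(st$c, c1)
  expect_equal(st$h, o * tanh(c1))
  expect_lt(abs(st$h), 1)
})

test_that("Bi-LSTM output is 256-wide with 128 units per direction", {
  set.seed(4)
  params <- list(fwd = resemote:::init_lstm_params(10, 128),
                 bwd = resemote:::init_lstm_params(10, 128))
  hs <- bilstm_forward(matrix(rnorm(50), 5, 10), params)$hs
  expect_identical(dim(hs), c(5L, 256L))
  h1 <- bilstm_forward(matrix(rnorm(10), 1, 10), params)$hs
  expect_identical(dim(h1), c(1L, 256L))
  expect_error(bilstm_forward(matrix(0, 0, 10), params),
               class = "resemote_empty_sequence")
})

test_that("tied directions on a palindromic input give a symmetric encoding", {
  set.seed(5)
  one_dir <- resemote:::init_lstm_params(3, 4)
  params <- list(fwd = one_dir, bwd = one_dir)
  half <- matrix(rnorm(9), 3, 3)
  xs <- rbind(half, half[2, ], half[1, ])  # x1 x2 x3 x2 x1
  hs <- bilstm_forward(xs, params)$hs
  flipped <- hs[5:1, c(5:8, 1:4)]  # reverse time, swap direction halves
  expect_equal(hs, flipped, tolerance = 1e-10)
})

test_that("attention weights are a proper distribution with bounded contrast", {
  set.seed(6)
  p <- list(w1 = rnorm(8), b = 0.3)
  hs <- matrix(rnorm(48), 6, 8)
  at <- attention_pool(hs, p)
  expect_equal(sum(at$alpha), 1, tolerance = 1e-6)
  expect_equal(at$r, as.vector(crossprod(hs, at$alpha)))
  # sigmoid scores lie in (0,1), so no weight exceeds e times another
  for (r in 1:20) {
    hs2 <- matrix(rnorm(48, sd = 5), 6, 8)
    a <- attention_pool(hs2, p)$alpha
    expect_lt(max(a) / min(a), exp(1))
  }
  # identical rows: exactly uniform, pooled vector equals the row
  hs3 <- matrix(rep(rnorm(8), each = 4), 4, 8)
  at3 <- attention_pool(hs3, p)
  expect_equal(at3$alpha, rep(0.25, 4))
  expect_equal(at3$r, hs3[1, ])
  expect_error(attention_pool(matrix(0, 0, 8), p),
               class = "resemote_empty_sequence")
})

test_that("a two-step attention case matches hand evaluation", {
  p <- list(w1 = c(1, -1), b = 0.5)
  hs <- rbind(c(0.2, 0.4), c(-0.3, 0.1))
  s <- c(0.2 - 0.4 + 0.5, -0.3 - 0.1 + 0.5)
  z <- 1 / (1 + exp(-s))
  alpha <- exp(z) / sum(exp(z))
  at <- attention_pool(hs, p)
  expect_equal(at$alpha, alpha)
  expect_equal(at$r, as.vector(t(hs) %*% alpha))
})

test_that("the classifier head is softmax-correct", {
  p <- list(W1 = matrix(0, 4, 3), b1 = rep(0, 3),
            W2 = matrix(0, 3, 5), b2 = rep(0, 5))
  out <- classify(c(1, 2, 3, 4), p)
  expect_equal(out$probs, rep(0.2, 5))
  expect_identical(out$label, 1L)  # tie broken to lowest index

  set.seed(7)
  p$W1[] <- rnorm(12); p$b1 <- rnorm(3); p$W2[] <- rnorm(15); p$b2 <- rnorm(5)
  r <- rnorm(4)
  a1 <- pmax(as.vector(t(p$W1) %*% r) + p$b1, 0)
  logits <- as.vector(t(p$W2) %*% a1) + p$b2
  expect_equal(classify(r, p)$probs, softmax_oracle(logits), tolerance = 1e-6)
  # shift invariance of the softmax
  p2 <- p; p2$b2 <- p$b2 + 11.3
  expect_equal(classify(r, p2)$probs, classify(r, p)$probs, tolerance = 1e-9)
})

test_that("cross-entropy matches its closed forms and stays finite", {
  expect_equal(cross_entropy(diag(3), diag(3)), 0)
  expect_equal(cross_entropy(matrix(1 / 7, 2, 7), diag(7)[1:2, ]), log(7))
  # two hand rows: -(log .7 + log .2)/2
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.2, 0.3))
  y <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cross_entropy(probs, y), -(log(0.7) + log(0.2)) / 2)
  expect_true(is.finite(cross_entropy(rbind(c(0, 1)), rbind(c(1, 0)))))
})

test_that("every forward pass yields normalized probabilities and attention", {
  cfg <- tiny_model_cfg(n_classes = 3)
  m <- init_emotion_model(cfg, n_mels = 16, classes = letters[1:3])
  set.seed(8)
  for (r in 1:5) {
    feat <- array(rnorm(20 * 16 * 3), c(20, 16, 3))
    fw <- resemote:::model_forward(feat, m)
    expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
    expect_equal(sum(fw$alpha), 1, tolerance = 1e-6)
    expect_true(fw$label %in% 1:3)
  }
})

test_that("analytic gradients agree with central differences through the
           whole network", {
  cfg <- model_config(n_classes = 3, expand_channels = 4,
                      n_residual_blocks = 2, lstm_hidden = 5, fc_hidden = 6,
                      seed = 7)
  m <- init_emotion_model(cfg, n_mels = 16, classes = letters[1:3])
  set.seed(42)
  feat <- array(rnorm(12 * 16 * 3), c(12, 16, 3))
  y <- c(0, 1, 0)
  fw <- resemote:::model_forward(feat, m, keep_cache = TRUE)
  g <- resemote:::model_backward(fw$probs - y, m, fw$cache)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    cross_entropy(resemote:::model_forward(feat, m2)$probs, y)
  }
  leaves <- list(
    list(c("expand", "W"), 2), list(list("blocks", 1, "W1"), 5),
    list(list("blocks", 1, "g1"), 2), list(list("blocks", 2, "W2"), 17),
    list(list("blocks", 2, "be2"), 3), list(c("lstm", "fwd", "Wcf"), 7),
    list(c("lstm", "fwd", "Wco"), 3), list(c("lstm", "bwd", "Whc"), 9),
    list(c("lstm", "bwd", "bo"), 2), list(c("attn", "w1"), 3),
    list(c("attn", "b"), 1), list(c("head", "W1"), 11),
    list(c("head", "b2"), 2)
  )
  for (lf in leaves) {
    path <- as.list(lf[[1]]); idx <- lf[[2]]
    get_leaf <- function(tree) { for (k in path) tree <- tree[[k]]; tree }
    set_leaf <- function(tree, v) {
      rec <- function(tr, ks) {
        if (length(ks) == 1) { tr[[ks[[1]]]][idx] <- v; tr }
        else { tr[[ks[[1]]]] <- rec(tr[[ks[[1]]]], ks[-1]); tr }
      }
      rec(tree, path)
    }
    eps <- 1e-5
    v0 <- get_leaf(m$params)[idx]
    num <- (loss_at(set_leaf(m$params, v0 + eps)) -
              loss_at(set_leaf(m$params, v0 - eps))) / (2 * eps)
    ana <- get_leaf(g)[idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
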