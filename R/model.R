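#' Network configuration
#'
#' Hyperparameters of the emotion classifier: a 1x1 channel-expansion
#' convolution, a stack of residual blocks (two 3x3 same-padded convolutions
#' with a skip connection, then 2x4 max pooling), a bidirectional LSTM, an
#' attention pooling layer, and a two-layer softmax classifier.
#'
#' @param n_classes Number of emotion classes (>= 2).
#' @param expand_channels Channels after the 1x1 expansion and in every
#'   residual block (128 by default).
#' @param n_residual_blocks Number of residual blocks (1 to 3; 3 by default).
#' @param pool_time,pool_freq Max-pooling window (and stride) along the time
#'   and frequency axes; the 2x4 default halves time and quarters frequency
#'   per block, so 64 Mel bands collapse to 1 after three blocks.
#' @param lstm_hidden Hidden units per LSTM direction (128 by default, so the
#'   per-step bidirectional output has dimension 256).
#' @param fc_hidden Width of the classifier's hidden layer.
#' @param attention Scoring squash inside the attention exponent:
#'   `"sigmoid"` (the model's native form) or `"tanh"` (a conventional
#'   alternative, not the native formulation).
#' @param in_channels Input feature channels (3 for static + delta +
#'   delta-delta).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes, expand_channels = 128,
                         n_residual_blocks = 3, pool_time = 2, pool_freq = 4,
                         lstm_hidden = 128, fc_hidden = 64,
                         attention = c("sigmoid", "tanh"),
                         in_channels = 3, seed = 1) {
  stopifnot(n_classes >= 2, n_residual_blocks >= 1, expand_channels >= 1,
            lstm_hidden >= 1, fc_hidden >= 1, in_channels >= 1)
  attention <- match.arg(attention)
  structure(
    list(n_classes = as.integer(n_classes),
         expand_channels = as.integer(expand_channels),
         n_residual_blocks = as.integer(n_residual_blocks),
         pool_time = as.integer(pool_time),
         pool_freq = as.integer(pool_freq),
         lstm_hidden = as.integer(lstm_hidden),
         fc_hidden = as.integer(fc_hidden),
         attention = attention,
         in_channels = as.integer(in_channels),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# Frequency width entering the recurrent stage for a given Mel-band count.
freq_after_blocks <- function(n_mels, cfg) {
  f <- n_mels
  for (b in seq_len(cfg$n_residual_blocks)) f <- f %/% cfg$pool_freq
  f
}

#' Initialize an untrained emotion model
#'
#' Draws all trainable parameters (conv kernels, normalization scales, LSTM
#' gate matrices, attention projection, classifier weights) from scaled
#' Gaussians, deterministically given `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @param n_mels Number of Mel bands of the features the model will consume;
#'   fixes the width of the recurrent stage's input.
#' @param classes Character vector of class labels in prediction order.
#' @return A `ser_model` object (untrained).
#' @export
init_emotion_model <- function(cfg, n_mels, classes = NULL) {
  f_out <- freq_after_blocks(n_mels, cfg)
  if (f_out < 1L) {
    rlang::abort(sprintf(
      "%d Mel bands cannot survive %d poolings by %d.",
      n_mels, cfg$n_residual_blocks, cfg$pool_freq
    ), class = "resemote_shape_error")
  }
  if (is.null(classes)) classes <- paste0("class", seq_len(cfg$n_classes))
  stopifnot(length(classes) == cfg$n_classes)
  C <- cfg$expand_channels
  with_seed(cfg$seed, {
    mk <- function(...) {
      d <- c(...)
      array(stats::rnorm(prod(d), sd = sqrt(2 / prod(utils::head(d, -1)))),
            dim = d)
    }
    params <- list(
      expand = list(W = matrix(stats::rnorm(cfg$in_channels * C,
                                            sd = sqrt(2 / cfg$in_channels)),
                               cfg$in_channels, C),
                    b = rep(0, C)),
      blocks = lapply(seq_len(cfg$n_residual_blocks), function(b) list(
        W1 = mk(3, 3, C, C), b1 = rep(0, C),
        g1 = rep(1, C), be1 = rep(0, C),
        W2 = mk(3, 3, C, C), b2 = rep(0, C),
        g2 = rep(1, C), be2 = rep(0, C)
      )),
      lstm = list(fwd = init_lstm_params(f_out * C, cfg$lstm_hidden),
                  bwd = init_lstm_params(f_out * C, cfg$lstm_hidden)),
      attn = list(w1 = stats::rnorm(2 * cfg$lstm_hidden,
                                    sd = 1 / sqrt(2 * cfg$lstm_hidden)),
                  b = 0),
      head = list(
        W1 = matrix(stats::rnorm(2 * cfg$lstm_hidden * cfg$fc_hidden,
                                 sd = sqrt(2 / (2 * cfg$lstm_hidden))),
                    2 * cfg$lstm_hidden, cfg$fc_hidden),
        b1 = rep(0, cfg$fc_hidden),
        W2 = matrix(stats::rnorm(cfg$fc_hidden * cfg$n_classes,
                                 sd = sqrt(2 / cfg$fc_hidden)),
                    cfg$fc_hidden, cfg$n_classes),
        b2 = rep(0, cfg$n_classes)
      )
    )
    structure(
      list(params = params, config = cfg, n_mels = n_mels, classes = classes,
           loss_history = numeric(0), trained = FALSE),
      class = "ser_model"
    )
  })
}

#' @export
print.ser_model <- function(x, ...) {
  cat(sprintf(
    "<ser_model> %d classes (%s), %d residual blocks, %d conv channels, %d LSTM units/dir%s\n",
    x$config$n_classes, paste(x$classes, collapse = ", "),
    x$config$n_residual_blocks, x$config$expand_channels,
    x$config$lstm_hidden,
    if (x$trained) sprintf(", trained %d epochs", length(x$loss_history))
    else ", untrained"
  ))
  invisible(x)
}

#' Apply one residual block
#'
#' conv(3x3) -> channel norm -> ReLU -> conv(3x3) -> channel norm -> add the
#' block input -> ReLU -> 2x4 max pooling.  The skip connection adds the
#' block's input to the output of its second convolution before the final
#' activation, so zeroed convolution weights make the pre-pooling activation
#' equal the (rectified) input.
#'
#' @param x `t x f x ch` array; `ch` must equal the block's channel width.
#' @param block Parameter list for one block (`W1`, `b1`, `g1`, `be1`, `W2`,
#'   `b2`, `g2`, `be2`), e.g. `model$params$blocks[[1]]`.
#' @param pool_time,pool_freq Pooling window.
#' @param keep_cache Retain caches for backpropagation.
#' @param normalize Apply the learned channel normalization (disable to
#'   inspect the raw conv/skip arithmetic).
#' @return List with `out` (`floor(t/2) x floor(f/4) x ch` array by default)
#'   and optionally `cache`.
#' @export
residual_block <- function(x, block, pool_time = 2, pool_freq = 4,
                           keep_cache = FALSE, normalize = TRUE) {
  c1 <- conv3x3_fwd(x, block$W1, block$b1)
  n1 <- if (normalize) chan_norm_fwd(c1$out, block$g1, block$be1)
        else list(out = c1$out)
  r1 <- relu_fwd(n1$out)
  c2 <- conv3x3_fwd(r1$out, block$W2, block$b2)
  n2 <- if (normalize) chan_norm_fwd(c2$out, block$g2, block$be2)
        else list(out = c2$out)
  s <- n2$out + x
  r2 <- relu_fwd(s)
  pl <- maxpool_fwd(r2$out, pool_time, pool_freq)
  out <- list(out = pl$out)
  if (keep_cache) {
    out$cache <- list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                      c2 = c2$cache, n2 = n2$cache, r2 = r2$cache,
                      pool = pl$cache, normalize = normalize)
  }
  out
}

residual_block_bwd <- function(dout, block, cache, pool_time, pool_freq) {
  ds_r <- maxpool_bwd(dout, cache$pool)
  ds <- relu_bwd(ds_r, cache$r2)
  dskip <- ds
  if (cache$normalize) {
    nb <- chan_norm_bwd(ds, block$g2, cache$n2)
    dc2 <- nb$dx; dg2 <- nb$dgamma; dbe2 <- nb$dbeta
  } else {
    dc2 <- ds; dg2 <- block$g2 * 0; dbe2 <- dg2
  }
  cb2 <- conv3x3_bwd(dc2, block$W2, cache$c2)
  dr1 <- relu_bwd(cb2$dx, cache$r1)
  if (cache$normalize) {
    nb1 <- chan_norm_bwd(dr1, block$g1, cache$n1)
    dc1 <- nb1$dx; dg1 <- nb1$dgamma; dbe1 <- nb1$dbeta
  } else {
    dc1 <- dr1; dg1 <- block$g1 * 0; dbe1 <- dg1
  }
  cb1 <- conv3x3_bwd(dc1, block$W1, cache$c1)
  list(
    grads = list(W1 = cb1$dW, b1 = cb1$db, g1 = dg1, be1 = dbe1,
                 W2 = cb2$dW, b2 = cb2$db, g2 = dg2, be2 = dbe2),
    dx = cb1$dx + dskip
  )
}

#' Convolutional front half of the network
#'
#' 1x1 channel expansion followed by the configured residual blocks, then a
#' reshape of the remaining `t' x f' x ch` tensor into a length-`t'` sequence
#' of vectors of size `f' * ch` for the recurrent stage.
#'
#' @param feat A `t x f x c` feature array ([extract_features()] output).
#' @param model A `ser_model`.
#' @param keep_cache Retain caches for backpropagation.
#' @return List with `xs` (`t' x (f' * ch)` matrix) and optionally `cache`.
#' @export
rescnn_forward <- function(feat, model, keep_cache = FALSE) {
  cfg <- model$config
  x <- unclass(feat)
  attributes(x) <- list(dim = dim(x))
  if (dim(x)[3] != cfg$in_channels) {
    rlang::abort(sprintf("Expected %d input channels, got %d.",
                         cfg$in_channels, dim(x)[3]),
                 class = "resemote_shape_error")
  }
  ex <- conv1x1_fwd(x, model$params$expand$W, model$params$expand$b)
  h <- ex$out
  blk_caches <- vector("list", cfg$n_residual_blocks)
  for (b in seq_len(cfg$n_residual_blocks)) {
    rb <- residual_block(h, model$params$blocks[[b]],
                         cfg$pool_time, cfg$pool_freq, keep_cache = keep_cache)
    h <- rb$out
    if (keep_cache) blk_caches[[b]] <- rb$cache
  }
  d <- dim(h)
  xs <- h
  dim(xs) <- c(d[1], d[2] * d[3])
  out <- list(xs = xs)
  if (keep_cache) {
    out$cache <- list(expand = ex$cache, blocks = blk_caches, conv_dim = d)
  }
  out
}

# Full forward pass: features -> probabilities (+ caches when training).
model_forward <- function(feat, model, keep_cache = FALSE) {
  cnn <- rescnn_forward(feat, model, keep_cache = keep_cache)
  bl <- bilstm_forward(cnn$xs, model$params$lstm, keep_cache = keep_cache)
  attn_params <- model$params$attn
  attn_params$score_fn <- model$config$attention
  at <- attention_pool(bl$hs, attn_params, keep_cache = keep_cache)
  cl <- classify(at$r, model$params$head, keep_cache = keep_cache)
  out <- list(probs = cl$probs, label = cl$label, alpha = at$alpha)
  if (keep_cache) {
    out$cache <- list(cnn = cnn$cache, bilstm = bl$cache, attn = at$cache,
                      head = cl$cache, xs_dim = dim(cnn$xs))
  }
  out
}

# Backward pass for one sample given the softmax-cross-entropy logit
# gradient (probs - onehot); returns the full gradient tree.
model_backward <- function(dlogits, model, cache) {
  cfg <- model$config
  hb <- classify_bwd(dlogits, model$params$head, cache$head)
  ab <- attention_bwd(hb$dr, model$params$attn, cache$attn)
  lb <- bilstm_bwd(ab$dhs, model$params$lstm, cache$bilstm)
  dxs <- lb$dxs
  d <- cache$cnn$conv_dim
  dim(dxs) <- d
  blocks_g <- vector("list", cfg$n_residual_blocks)
  dh <- dxs
  for (b in rev(seq_len(cfg$n_residual_blocks))) {
    rb <- residual_block_bwd(dh, model$params$blocks[[b]],
                             cache$cnn$blocks[[b]], cfg$pool_time,
                             cfg$pool_freq)
    blocks_g[[b]] <- rb$grads
    dh <- rb$dx
  }
  eb <- conv1x1_bwd(dh, model$params$expand$W, cache$cnn$expand)
  list(
    expand = list(W = eb$dW, b = eb$db),
    blocks = blocks_g,
    lstm = lb$grads,
    attn = list(w1 = ab$dw1, b = ab$db),
    head = list(W1 = hb$dW1, b1 = hb$db1, W2 = hb$dW2, b2 = hb$db2)
  )
}

#' Predict emotions for extracted features
#'
#' @param object A trained (or initialized) `ser_model`.
#' @param features A single feature array or a list of them (e.g. the
#'   `features` list-column produced by [add_features()]).
#' @param ... Unused.
#' @return A tibble with one row per input: predicted label `.pred`, the
#'   per-class probabilities in columns `.prob_<class>`, and the attention
#'   entropy `attn_entropy`.
#' @export
predict.ser_model <- function(object, features, ...) {
  if (inherits(features, "log_mel_feature") ||
      (is.array(features) && length(dim(features)) == 3)) {
    features <- list(features)
  }
  rows <- purrr::map(features, function(f) {
    fw <- model_forward(f, object)
    probs <- stats::setNames(as.list(fw$probs),
                             paste0(".prob_", object$classes))
    a <- fw$alpha
    tibble::as_tibble(c(
      list(.pred = object$classes[fw$label]),
      probs,
      list(attn_entropy = -sum(a * log(pmax(a, 1e-12))))
    ))
  })
  dplyr::bind_rows(rows)
}

#' Add a feature list-column to a clip dataset
#'
#' Convenience wrapper running [extract_features()] over the `clip`
#' list-column of a dataset tibble.
#'
#' @param dataset Tibble with a `clip` list-column.
#' @param cfg A [feature_config()].
#' @return The dataset with a `features` list-column appended.
#' @export
add_features <- function(dataset, cfg = feature_config()) {
  dataset$features <- purrr::map(dataset$clip, extract_features, cfg = cfg)
  dataset
}
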