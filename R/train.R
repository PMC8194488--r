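# Parameter trees are nested lists of numeric arrays; these helpers map
# elementwise operations over one or more trees with identical shape.

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else if (is.numeric(t1)) {
    do.call(f, trees)
  } else {
    t1  # non-numeric leaves (e.g. score_fn flag) pass through
  }
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

onehot <- function(label, classes) {
  y <- numeric(length(classes))
  y[match(label, classes)] <- 1
  y
}

#' Train the emotion classifier
#'
#' Mini-batch gradient training of the full network (residual CNN, Bi-LSTM,
#' attention, classifier) with Adam, minimizing mean cross-entropy.
#' Gradients are accumulated one clip at a time within each mini-batch, so
#' clips of different lengths need no padding; the accumulated average equals
#' the padded-and-masked batch gradient.  Deterministic given `seed` (data
#' order and parameter initialization both derive from it).
#'
#' @param dataset Tibble with list-column `features` (see [add_features()])
#'   and a `label` column.
#' @param cfg A [model_config()]; its `n_classes` must match the labels
#'   present.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size (clips).
#' @param seed Seed controlling initialization and shuffling; defaults to
#'   `cfg$seed`.
#' @param on_missing_class `"error"` aborts when a configured class has no
#'   training sample; `"warn"` warns and proceeds.
#' @param log_file Optional path; per-epoch losses are appended as JSON lines.
#' @return A trained `ser_model` with `loss_history` (one mean cross-entropy
#'   value per epoch).
#' @export
train_emotion_model <- function(dataset, cfg, epochs = 50, lr = 1e-3,
                                batch_size = 32, seed = NULL,
                                on_missing_class = c("warn", "error"),
                                log_file = NULL) {
  on_missing_class <- match.arg(on_missing_class)
  stopifnot(nrow(dataset) >= 2, "features" %in% names(dataset))
  classes <- sort(unique(dataset$label))
  if (length(classes) < 2) {
    rlang::abort("Training data must contain at least 2 classes.",
                 class = "resemote_degenerate_classes")
  }
  if (length(classes) != cfg$n_classes) {
    msg <- sprintf("Configured for %d classes but %d present in the data.",
                   cfg$n_classes, length(classes))
    if (on_missing_class == "error") {
      rlang::abort(msg, class = "resemote_degenerate_classes")
    }
    rlang::warn(msg)
    cfg$n_classes <- length(classes)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  n_mels <- dim(dataset$features[[1]])[2]
  model <- init_emotion_model(cfg, n_mels, classes)
  targets <- lapply(dataset$label, onehot, classes = classes)
  opt <- adam_init(model$params)
  n <- nrow(dataset)
  loss_hist <- numeric(epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        acc <- NULL
        batch_loss <- 0
        for (i in idx) {
          fw <- model_forward(dataset$features[[i]], model, keep_cache = TRUE)
          y <- targets[[i]]
          batch_loss <- batch_loss + cross_entropy(fw$probs, y)
          g <- model_backward(fw$probs - y, model, fw$cache)
          acc <- if (is.null(acc)) g else tree_map(`+`, acc, g)
        }
        acc <- tree_map(function(x) x / length(idx), acc)
        upd <- adam_step(model$params, acc, opt, lr = lr)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + batch_loss
      }
      loss_hist[ep] <- ep_loss / n
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(list(epoch = ep, loss = loss_hist[ep]),
                             auto_unbox = TRUE, digits = NA),
            "\n", file = log_file, append = TRUE)
      }
    }
  })
  model$loss_history <- loss_hist
  model$trained <- TRUE
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON: a config header plus all parameter arrays with their
#' dimensions, so they are portable text files.
#'
#' @param model A `ser_model`.
#' @param path Output path.
#' @return `path` invisibly (`save_model`); the restored `ser_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  ser <- function(x) {
    if (is.list(x)) lapply(x, ser)
    else if (is.numeric(x)) list(dim = dim(x) %||% length(x), data = as.vector(x))
    else x
  }
  obj <- list(config = unclass(model$config), n_mels = model$n_mels,
              classes = model$classes, loss_history = model$loss_history,
              trained = model$trained, params = ser(model$params))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                            simplifyVector = FALSE)
  deser <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      d <- unlist(x$dim)
      v <- as.numeric(unlist(x$data))
      if (length(d) > 1) array(v, dim = d) else v
    } else if (is.list(x)) {
      lapply(x, deser)
    } else x
  }
  cfg <- do.call(model_config, lapply(obj$config, unlist))
  structure(
    list(params = deser(obj$params), config = cfg, n_mels = unlist(obj$n_mels),
         classes = unlist(obj$classes),
         loss_history = as.numeric(unlist(obj$loss_history)),
         trained = isTRUE(unlist(obj$trained))),
    class = "ser_model"
  )
}
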