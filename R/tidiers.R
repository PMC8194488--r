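#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per (true class, predicted class) cell of the row-normalized
#' confusion matrix, plus the per-class recall.
#'
#' @param x A `ser_eval`.
#' @param ... Unused.
#' @return A tibble with columns `truth`, `estimate`, `percent`, `count`,
#'   `recall` (recall repeated along each truth row).
#' @method tidy ser_eval
#' @export
tidy.ser_eval <- function(x, ...) {
  pct <- unclass(x$confusion)
  counts <- attr(x$confusion, "counts")
  tibble::tibble(
    truth = rep(rownames(pct), times = ncol(pct)),
    estimate = rep(colnames(pct), each = nrow(pct)),
    percent = as.vector(pct),
    count = as.vector(counts),
    recall = rep(unname(x$per_class_recall[rownames(pct)]), times = ncol(pct))
  )
}

#' @rdname tidy.ser_eval
#' @return `glance`: a one-row tibble with `uar`, `acc`, `n`, `n_classes`,
#'   and (for cross-validation reports) the mean and sd of per-fold UAR.
#' @method glance ser_eval
#' @export
glance.ser_eval <- function(x, ...) {
  tibble::tibble(
    uar = x$uar,
    acc = x$acc,
    n = nrow(x$predictions),
    n_classes = length(x$classes),
    fold_uar_mean = if (!is.null(x$fold_uar)) mean(x$fold_uar) else NA_real_,
    fold_uar_sd = if (!is.null(x$fold_uar)) stats::sd(x$fold_uar) else NA_real_
  )
}

#' Tidy a trained emotion model
#'
#' @param x A `ser_model`.
#' @param ... Unused.
#' @return `tidy`: a tibble of the loss history (`epoch`, `loss`).
#' @method tidy ser_model
#' @export
tidy.ser_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.ser_model
#' @return `glance`: one row with parameter count, epochs, final loss.
#' @method glance ser_model
#' @export
glance.ser_model <- function(x, ...) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1)))
    else if (is.numeric(p)) length(p) else 0
  }
  tibble::tibble(
    n_parameters = count(x$params),
    n_classes = x$config$n_classes,
    n_residual_blocks = x$config$n_residual_blocks,
    epochs = length(x$loss_history),
    final_loss = if (length(x$loss_history)) utils::tail(x$loss_history, 1)
                 else NA_real_
  )
}

#' Tidy an association test
#'
#' @param x A `ser_assoc`.
#' @param ... Unused.
#' @return `tidy`: one row per table cell with observed and expected counts
#'   and Pearson residuals.
#' @method tidy ser_assoc
#' @export
tidy.ser_assoc <- function(x, ...) {
  tibble::tibble(
    group = rep(rownames(x$table), times = ncol(x$table)),
    emotion = rep(colnames(x$table), each = nrow(x$table)),
    observed = as.vector(x$table),
    expected = as.vector(x$expected),
    residual = as.vector(x$residuals)
  )
}

#' @rdname tidy.ser_assoc
#' @return `glance`: one row with `statistic`, `dof`, `p_value`, `method`.
#' @method glance ser_assoc
#' @export
glance.ser_assoc <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, dof = x$dof, p_value = x$p_value,
                 method = x$method)
}

#' Tidy a contingency table
#' @param x A `ser_contingency`.
#' @param ... Unused.
#' @return A tibble with `group`, `emotion`, `count`.
#' @method tidy ser_contingency
#' @export
tidy.ser_contingency <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    group = rep(rownames(m), times = ncol(m)),
    emotion = rep(colnames(m), each = nrow(m)),
    count = as.vector(m)
  )
}
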