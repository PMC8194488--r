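#' Row-normalized confusion matrix
#'
#' Row `i`, column `j` holds the percentage of class-`i` samples predicted as
#' class `j`; every row with at least one true sample sums to 100.
#'
#' @param truth,estimate Equal-length label vectors.
#' @param classes Class labels fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return A `k x k` percentage matrix with attribute `counts` (the raw
#'   integer table).  Rows for classes absent from `truth` are `NA` and
#'   flagged with a warning.
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  stopifnot(length(truth) == length(estimate))
  if (is.null(classes)) classes <- sort(unique(c(truth, estimate)))
  counts <- table(factor(truth, levels = classes),
                  factor(estimate, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(counts)
  pct <- 100 * counts / ifelse(rs == 0, NA_real_, rs)
  if (any(rs == 0)) {
    rlang::warn(sprintf(
      "No true samples for class(es): %s; confusion rows undefined.",
      paste(classes[rs == 0], collapse = ", ")
    ))
  }
  structure(pct, counts = counts)
}

#' Per-class recall
#'
#' `recall_c = TP_c / (TP_c + FN_c)`: the fraction of class-`c` samples
#' predicted as class `c`.
#'
#' @inheritParams confusion_matrix
#' @return Named numeric vector of recalls (NA for classes with no true
#'   samples).
#' @export
per_class_recall <- function(truth, estimate, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, estimate)))
  vapply(classes, function(cl) {
    n <- sum(truth == cl)
    if (n == 0) NA_real_ else sum(truth == cl & estimate == cl) / n
  }, numeric(1))
}

#' Unweighted average recall (UAR)
#'
#' The unweighted mean of per-class recalls, robust to class imbalance: every
#' class contributes equally regardless of its sample count.
#'
#' @inheritParams confusion_matrix
#' @param na_rm Drop classes with no true samples (with a warning) instead of
#'   erroring.
#' @return A fraction in \[0, 1\].
#' @export
uar <- function(truth, estimate, classes = NULL, na_rm = FALSE) {
  rec <- per_class_recall(truth, estimate, classes)
  if (anyNA(rec)) {
    if (!na_rm) {
      rlang::abort(sprintf(
        "Class(es) %s absent from `truth`; cannot compute UAR.",
        paste(names(rec)[is.na(rec)], collapse = ", ")
      ), class = "resemote_missing_class")
    }
    rlang::warn("Dropping classes with no true samples from UAR.")
  }
  mean(rec, na.rm = na_rm)
}

#' Overall accuracy
#' @inheritParams confusion_matrix
#' @return Fraction of correct predictions.
#' @export
accuracy <- function(truth, estimate) mean(truth == estimate)

#' Build an evaluation report
#'
#' @inheritParams confusion_matrix
#' @return A `ser_eval` object: per-class recall, UAR, ACC, the
#'   row-normalized confusion matrix, and the prediction tibble.
#' @export
eval_report <- function(truth, estimate, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, estimate)))
  rec <- per_class_recall(truth, estimate, classes)
  structure(
    list(
      per_class_recall = rec,
      uar = mean(rec, na.rm = TRUE),
      acc = accuracy(truth, estimate),
      confusion = suppressWarnings(confusion_matrix(truth, estimate, classes)),
      predictions = tibble::tibble(truth = truth, estimate = estimate),
      classes = classes
    ),
    class = "ser_eval"
  )
}

#' @export
print.ser_eval <- function(x, ...) {
  cat(sprintf("<ser_eval> UAR %.3f, ACC %.3f over %d predictions\n",
              x$uar, x$acc, nrow(x$predictions)))
  cat("Per-class recall:\n")
  print(round(x$per_class_recall, 3))
  invisible(x)
}

#' Speaker-independent fold plan
#'
#' Partitions the distinct speakers into `k` disjoint test groups (with 10
#' speakers and `k = 10` this is leave-one-speaker-out); each fold trains on
#' all remaining speakers, so no speaker ever appears on both sides.
#' Deterministic given `seed`.
#'
#' @param dataset Tibble with a `speaker_id` column.
#' @param k Number of folds.
#' @param seed Seed for the speaker shuffle.
#' @return A `fold_plan` tibble with columns `fold`, `test_speakers`
#'   (list-column), `train_speakers` (list-column).
#' @export
speaker_folds <- function(dataset, k = 10, seed = 1) {
  speakers <- sort(unique(dataset$speaker_id))
  if (length(speakers) < k) {
    rlang::abort(sprintf("Need at least k = %d distinct speakers, have %d.",
                         k, length(speakers)),
                 class = "resemote_too_few_speakers")
  }
  shuffled <- with_seed(seed, sample(speakers))
  assign <- rep(seq_len(k), length.out = length(speakers))
  plan <- tibble::tibble(
    fold = seq_len(k),
    test_speakers = purrr::map(seq_len(k), ~ sort(shuffled[assign == .x])),
    train_speakers = purrr::map(seq_len(k),
                                ~ sort(shuffled[assign != .x]))
  )
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Speaker-independent cross-validation
#'
#' Trains one model per fold on the training speakers' clips and predicts the
#' held-out speakers' clips; pooled predictions over all folds form the
#' primary report, with per-fold reports attached.  Train/test speaker
#' disjointness is asserted per fold at execution time, not only at plan
#' construction.
#'
#' @param dataset Tibble with `speaker_id`, `label` and either a `features`
#'   or a `clip` list-column (features are extracted with `feature_cfg` when
#'   absent).
#' @param model_cfg A [model_config()].
#' @param plan A [speaker_folds()] plan.
#' @param feature_cfg A [feature_config()]; used when features must be
#'   extracted.
#' @param epochs,lr,batch_size Training hyperparameters per fold.
#' @param seed Base seed; fold `f` trains with `seed + f`.
#' @return A `ser_eval` report with `per_fold` (list of per-fold reports) and
#'   a pooled prediction tibble including `speaker_id` and `fold`.
#' @export
cross_validate <- function(dataset, model_cfg, plan,
                           feature_cfg = feature_config(),
                           epochs = 30, lr = 1e-3, batch_size = 16,
                           seed = 1) {
  if (!"features" %in% names(dataset)) {
    dataset <- add_features(dataset, feature_cfg)
  }
  classes <- sort(unique(dataset$label))
  pooled <- list()
  per_fold <- vector("list", nrow(plan))
  for (f in seq_len(nrow(plan))) {
    test_spk <- plan$test_speakers[[f]]
    train_spk <- plan$train_speakers[[f]]
    if (length(intersect(test_spk, train_spk)) > 0) {
      rlang::abort("Speaker leakage: a speaker is in both train and test.",
                   class = "resemote_speaker_leakage")
    }
    tr <- dataset[dataset$speaker_id %in% train_spk, ]
    te <- dataset[dataset$speaker_id %in% test_spk, ]
    if (any(te$speaker_id %in% tr$speaker_id)) {
      rlang::abort("Speaker leakage in realized split.",
                   class = "resemote_speaker_leakage")
    }
    cfg_f <- model_cfg
    cfg_f$n_classes <- length(classes)
    model <- train_emotion_model(tr, cfg_f, epochs = epochs, lr = lr,
                                 batch_size = batch_size, seed = seed + f)
    preds <- predict(model, te$features)
    fold_tbl <- tibble::tibble(
      clip_id = te$clip_id, speaker_id = te$speaker_id, fold = f,
      truth = te$label, estimate = preds$.pred
    )
    pooled[[f]] <- fold_tbl
    test_classes <- intersect(classes, unique(te$label))
    if (length(test_classes) < length(classes)) {
      rlang::warn(sprintf(
        "Fold %d: class(es) %s absent from the test split; excluded from the fold UAR.",
        f, paste(setdiff(classes, test_classes), collapse = ", ")
      ))
    }
    per_fold[[f]] <- eval_report(fold_tbl$truth, fold_tbl$estimate,
                                 test_classes)
  }
  all_pred <- dplyr::bind_rows(pooled)
  rep <- eval_report(all_pred$truth, all_pred$estimate, classes)
  rep$predictions <- all_pred
  rep$per_fold <- per_fold
  rep$fold_uar <- vapply(per_fold, `[[`, numeric(1), "uar")
  rep
}

#' Ablation experiments
#'
#' Re-runs the full speaker-independent cross-validation once per requested
#' configuration along two axes: the number of residual blocks (depth
#' ablation, a 3-row table) and the subset of feature channels retained
#' (static / delta / delta-delta combinations; all 7 non-empty subsets give a
#' 7-row table).
#'
#' @param dataset Tibble with `clip_id`, `speaker_id`, `label` and a `clip`
#'   list-column.
#' @param model_cfg,feature_cfg Base configurations; each run overrides one
#'   axis.
#' @param plan A [speaker_folds()] plan.
#' @param blocks Integer vector of residual-block counts to test, or `NULL`
#'   to skip the depth axis.
#' @param channel_subsets List of character vectors (subsets of
#'   `c("static", "delta", "delta_delta")`), `"all"` for every non-empty
#'   subset, or `NULL` to skip the channel axis.
#' @param ... Passed to [cross_validate()] (epochs, lr, seed, ...).
#' @return A tibble with columns `axis`, `configuration`, `uar`, `acc`.
#' @export
ablation <- function(dataset, model_cfg, plan,
                     feature_cfg = feature_config(),
                     blocks = NULL, channel_subsets = NULL, ...) {
  rows <- list()
  if (!is.null(blocks)) {
    feats <- add_features(dataset, feature_cfg)
    for (nb in blocks) {
      cfg <- model_cfg
      cfg$n_residual_blocks <- as.integer(nb)
      rep <- cross_validate(feats, cfg, plan, feature_cfg, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        axis = "residual_blocks",
        configuration = sprintf("%d residual block%s", nb,
                                if (nb == 1) "" else "s"),
        uar = rep$uar, acc = rep$acc
      )
    }
  }
  if (!is.null(channel_subsets)) {
    all_ch <- c("static", "delta", "delta_delta")
    if (identical(channel_subsets, "all")) {
      channel_subsets <- unlist(lapply(seq_along(all_ch), function(k) {
        utils::combn(all_ch, k, simplify = FALSE)
      }), recursive = FALSE)
    }
    for (ch in channel_subsets) {
      if (length(ch) == 0) {
        rlang::abort("Empty channel subset.", class = "resemote_bad_config")
      }
      fc <- feature_cfg
      fc$channels <- ch
      cfg <- model_cfg
      cfg$in_channels <- length(ch)
      feats <- add_features(dataset, fc)
      rep <- cross_validate(feats, cfg, plan, fc, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        axis = "feature_channels",
        configuration = paste(ch, collapse = " + "),
        uar = rep$uar, acc = rep$acc
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write an evaluation report to JSON (and the confusion matrix to CSV)
#'
#' @param report A `ser_eval`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the row-normalized confusion matrix.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, csv_path = NULL) {
  obj <- list(
    uar = report$uar, acc = report$acc,
    per_class_recall = as.list(report$per_class_recall),
    confusion_percent = apply(unclass(report$confusion), 1, as.list,
                              simplify = FALSE),
    fold_uar = report$fold_uar %||% NULL
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), json_path)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(unclass(report$confusion)), csv_path)
  }
  invisible(json_path)
}
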