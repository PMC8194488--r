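test_that("confusion matrix rows are percentages summing to 100", {
  truth <- c("a", "a", "b", "b", "b", "c")
  est <- c("a", "b", "b", "b", "c", "c")
  cm <- confusion_matrix(truth, est)
  expect_equal(unname(rowSums(cm)), rep(100, 3))
  # brute-force counting oracle on a 3-sample, 2-class case
  cm2 <- confusion_matrix(c("x", "x", "y"), c("x", "y", "y"))
  expect_equal(unname(unclass(cm2)),
               rbind(c(50, 50), c(0, 100)), ignore_attr = TRUE)
  expect_equal(unname(attr(cm2, "counts")), rbind(c(1L, 1L), c(0L, 1L)),
               ignore_attr = TRUE)
  # perfect predictions: identity pattern
  cmp <- confusion_matrix(truth, truth)
  expect_equal(unname(unclass(cmp)), diag(3) * 100, ignore_attr = TRUE)
  expect_warning(confusion_matrix(c("a", "a"), c("a", "b"), c("a", "b", "c")),
                 "No true samples")
})

test_that("UAR and ACC behave per definition", {
  expect_equal(uar(c("a", "b"), c("a", "b")), 1)
  # recalls 1.0 and 0.5 average to 0.75
  expect_equal(uar(c("a", "b", "b"), c("a", "b", "a")), 0.75)
  expect_error(uar(c("a", "a"), c("a", "b"), classes = c("a", "b")),
               class = "resemote_missing_class")
  # balanced labels: UAR equals ACC exactly
  set.seed(21)
  truth <- rep(c("a", "b", "c"), each = 10)
  est <- sample(c("a", "b", "c"), 30, replace = TRUE)
  expect_equal(uar(truth, est), accuracy(truth, est))
})

test_that("report metrics agree with confusion-matrix-derived oracles", {
  set.seed(22)
  classes <- c("a", "b", "c", "d")
  for (r in 1:5) {
    truth <- sample(classes, 40, replace = TRUE)
    while (length(unique(truth)) < 4) truth <- sample(classes, 40, TRUE)
    est <- sample(classes, 40, replace = TRUE)
    rep <- eval_report(truth, est, classes)
    counts <- attr(rep$confusion, "counts")
    expect_equal(rep$uar, mean(diag(counts) / rowSums(counts)))
    expect_equal(rep$acc, sum(diag(counts)) / sum(counts))
    expect_equal(unname(rep$per_class_recall),
                 unname(diag(counts) / rowSums(counts)))
  }
})

test_that("speaker folds partition speakers without leakage", {
  ds <- tibble::tibble(speaker_id = rep(sprintf("s%02d", 1:10), each = 3))
  plan <- speaker_folds(ds, k = 10, seed = 4)
  expect_identical(nrow(plan), 10L)
  expect_true(all(lengths(plan$test_speakers) == 1))
  expect_setequal(unlist(plan$test_speakers), unique(ds$speaker_id))
  for (f in 1:10) {
    expect_length(intersect(plan$test_speakers[[f]],
                            plan$train_speakers[[f]]), 0)
  }
  expect_identical(speaker_folds(ds, k = 10, seed = 4), plan)
  expect_error(speaker_folds(ds, k = 11),
               class = "resemote_too_few_speakers")
})

test_that("cross-validation runs end to end on a tiny fixture", {
  ds <- add_features(generate_dataset(tiny_synth_spec()), small_feature_cfg())
  plan <- speaker_folds(ds, k = 2, seed = 3)
  rep <- cross_validate(ds, tiny_model_cfg(), plan, epochs = 3,
                        batch_size = 8, seed = 1)
  expect_s3_class(rep, "ser_eval")
  expect_identical(nrow(rep$predictions), nrow(ds))
  expect_length(rep$per_fold, 2)
  expect_true(all(rep$predictions$fold %in% 1:2))
  # no test clip's speaker occurs in that fold's training speakers
  for (f in 1:2) {
    spk <- unique(rep$predictions$speaker_id[rep$predictions$fold == f])
    expect_true(all(spk %in% plan$test_speakers[[f]]))
  }
  g <- glance(rep)
  expect_true(g$uar >= 0 && g$uar <= 1)
  td <- tidy(rep)
  expect_identical(nrow(td), 4L)  # 2 classes x 2 classes
})

test_that("ablation tables have one row per configuration", {
  ds <- generate_dataset(tiny_synth_spec())
  plan <- speaker_folds(ds, k = 2, seed = 3)
  tab <- ablation(ds, tiny_model_cfg(), plan, small_feature_cfg(),
                  blocks = 1:2, epochs = 1, batch_size = 8, seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$axis, rep("residual_blocks", 2))
  tab2 <- ablation(ds, tiny_model_cfg(), plan, small_feature_cfg(),
                   channel_subsets = list("static", c("static", "delta")),
                   epochs = 1, batch_size = 8, seed = 1)
  expect_identical(tab2$configuration, c("static", "static + delta"))
  expect_error(
    ablation(ds, tiny_model_cfg(), plan, channel_subsets = list(character(0)),
             epochs = 1),
    class = "resemote_bad_config"
  )
})

test_that("evaluation reports serialize to JSON with row-stochastic rows", {
  rep <- eval_report(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$uar, rep$uar)
  expect_equal(obj$acc, 0.75)
})
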