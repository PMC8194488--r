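# Downstream annotation aggregation and group-by-emotion association:
# expert majority voting per clip, person-level emotion assignment
# (non-neutral emotions take precedence over neutral), a group x emotion
# contingency table, and a chi-square association test.  The test itself is
# an addition to the annotation protocol and is labeled as such in output.

#' Majority vote over expert labels
#'
#' A clip's label is the emotion assigned by at least `threshold` of the (up
#' to three) experts; with no such emotion the clip is `"unresolved"`.
#'
#' @param expert_labels Character vector of 1-3 expert labels (NA entries are
#'   dropped).
#' @param threshold Minimum number of agreeing experts (default 2 of 3).
#' @return The winning label, or `"unresolved"`.
#' @export
majority_vote <- function(expert_labels, threshold = 2) {
  expert_labels <- expert_labels[!is.na(expert_labels)]
  if (length(expert_labels) == 0) {
    rlang::abort("No expert labels supplied.", class = "resemote_no_labels")
  }
  if (length(expert_labels) > 3) {
    rlang::abort("At most 3 expert labels are expected.",
                 class = "resemote_bad_input")
  }
  tab <- sort(table(expert_labels), decreasing = TRUE)
  if (tab[1] >= threshold) names(tab)[1] else "unresolved"
}

#' Person-level emotion from clip-level labels
#'
#' A person expressing any non-neutral emotion is labeled with their most
#' frequent non-neutral emotion (earliest-occurring wins ties); a person
#' whose resolved clips are all neutral is labeled neutral.  Unresolved
#' clips are ignored.
#'
#' @param labels Character vector of resolved clip labels for one person.
#' @param neutral Name of the neutral category.
#' @return A single emotion label.
#' @export
person_label <- function(labels, neutral = "neutral") {
  labels <- labels[!is.na(labels) & labels != "unresolved"]
  if (length(labels) == 0) {
    rlang::abort("All of this person's clips are unresolved.",
                 class = "resemote_unresolved_person")
  }
  non_neutral <- labels[labels != neutral]
  if (length(non_neutral) == 0) return(neutral)
  counts <- table(factor(non_neutral, levels = unique(non_neutral)))
  names(counts)[which.max(counts)]  # ties: earliest occurrence
}

#' Resolve clip and person labels for an annotated record set
#'
#' Applies [majority_vote()] per clip and [person_label()] per defendant.
#'
#' @param records Tibble with `defendant_id`, `group` and `expert1`..
#'   `expert3` columns (as from [generate_trial_records()] or a manifest).
#' @param threshold Majority-vote threshold.
#' @return A tibble with one row per defendant: `defendant_id`, `group`,
#'   `label`.
#' @export
resolve_annotations <- function(records, threshold = 2) {
  records$resolved <- purrr::pmap_chr(
    records[c("expert1", "expert2", "expert3")],
    function(expert1, expert2, expert3) {
      majority_vote(c(expert1, expert2, expert3), threshold)
    }
  )
  records |>
    dplyr::group_by(.data$defendant_id, .data$group) |>
    dplyr::summarise(label = person_label(.data$resolved), .groups = "drop")
}

#' Group-by-emotion contingency table
#'
#' @param person_labels Character vector, one emotion per person.
#' @param group_flags Character vector of the same length, one group per
#'   person.
#' @param groups,emotions Optional explicit row/column orders.
#' @return A `ser_contingency` object: an integer count matrix
#'   (groups x emotions).
#' @export
build_contingency <- function(person_labels, group_flags,
                              groups = NULL, emotions = NULL) {
  stopifnot(length(person_labels) == length(group_flags))
  if (is.null(groups)) groups <- unique(group_flags)
  if (is.null(emotions)) emotions <- unique(person_labels)
  counts <- table(factor(group_flags, levels = groups),
                  factor(person_labels, levels = emotions))
  counts <- matrix(as.integer(counts), nrow = length(groups),
                   dimnames = list(group = groups, emotion = emotions))
  structure(counts, class = c("ser_contingency", "matrix", "array"))
}

#' @export
print.ser_contingency <- function(x, ...) {
  cat("<ser_contingency> group x emotion counts\n")
  print(unclass(x))
  invisible(x)
}

#' Chi-square association test on a contingency table
#'
#' Pearson chi-square without continuity correction; when any expected cell
#' count falls below 5 the p-value is computed by Monte-Carlo simulation
#' instead of the asymptotic distribution.  The test is an addition to the
#' annotation protocol (which reports counts only) and its output is flagged
#' accordingly.
#'
#' @param table A `ser_contingency` or plain count matrix (2 x k).
#' @param monte_carlo `"auto"` (simulate when any expected count < 5),
#'   `TRUE`, or `FALSE`.
#' @param B Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo draw.
#' @return A `ser_assoc` list: `statistic`, `dof`, `p_value`, `expected`,
#'   `residuals` (Pearson residuals), `method`.
#' @export
association_test <- function(table, monte_carlo = "auto", B = 10000,
                             seed = 1) {
  m <- unclass(table)
  storage.mode(m) <- "numeric"
  if (any(m < 0)) {
    rlang::abort("Counts must be nonnegative.", class = "resemote_bad_input")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("Zero-margin row or column.", class = "resemote_bad_margin")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  simulate <- isTRUE(monte_carlo) ||
    (identical(monte_carlo, "auto") && any(expected < 5))
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(m, correct = FALSE, simulate.p.value = simulate, B = B)
  ))
  structure(
    list(
      statistic = unname(res$statistic),
      dof = as.integer((nrow(m) - 1) * (ncol(m) - 1)),
      p_value = unname(res$p.value),
      expected = res$expected,
      residuals = res$residuals,
      method = if (simulate) "Pearson chi-square (Monte-Carlo p)"
               else "Pearson chi-square",
      note = "statistical test added on top of the annotation protocol",
      table = m
    ),
    class = "ser_assoc"
  )
}

#' @export
print.ser_assoc <- function(x, ...) {
  cat(sprintf("<ser_assoc> %s: X^2 = %.4g, dof = %d, p = %.4g\n",
              x$method, x$statistic, x$dof, x$p_value))
  cat("(", x$note, ")\n", sep = "")
  invisible(x)
}

#' Full association chain on an annotated record set
#'
#' Majority vote per clip, person labeling, contingency construction, and
#' the chi-square test, in one call.
#'
#' @inheritParams resolve_annotations
#' @param emotions Optional emotion order for the table columns.
#' @param ... Passed to [association_test()].
#' @return List with `persons` (tibble), `table` (`ser_contingency`) and
#'   `test` (`ser_assoc`).
#' @export
associate <- function(records, threshold = 2, emotions = NULL, ...) {
  persons <- resolve_annotations(records, threshold)
  tab <- build_contingency(persons$label, persons$group,
                           groups = unique(records$group),
                           emotions = emotions)
  list(persons = persons, table = tab, test = association_test(tab, ...))
}
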