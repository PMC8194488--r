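# Adapter for the Berlin Emotional Database (Emo-DB): 535 German utterances
# by 10 professional actors over 7 emotions, distributed as WAV files whose
# names encode speaker, text and emotion, e.g. "03a01Wa.wav" = speaker 03,
# text a01, emotion W (Wut/anger), version a.

emodb_letter_map <- c(
  W = "anger", L = "boredom", E = "disgust", A = "fear",
  F = "joy", T = "sadness", N = "neutral"
)

#' The seven Emo-DB emotion classes in their fixed one-hot order
#'
#' Alphabetical order is used throughout for one-hot encoding:
#' anger, boredom, disgust, fear, joy, neutral, sadness.
#' @return Character vector of length 7.
#' @export
emodb_classes <- function() {
  sort(unname(emodb_letter_map))
}

#' Parse an Emo-DB file name
#'
#' File names follow `SStttEv.wav`: 2-digit speaker id, 3-character text
#' code, 1-letter emotion code (W anger, L boredom, E disgust, A fear,
#' F joy, T sadness, N neutral), 1-letter version.
#'
#' @param name File name (with or without directory or `.wav` suffix).
#' @return A list with `speaker_id`, `emotion`, `text_code`, `version`.
#' @export
parse_emodb_filename <- function(name) {
  base <- sub("\\.wav$", "", basename(name), ignore.case = TRUE)
  m <- regmatches(base,
                  regexec("^([0-9]{2})([a-z][0-9]{2})([WLEAFTN])([a-z][0-9]?)$",
                          base))[[1]]
  if (length(m) == 0) {
    rlang::abort(sprintf(
      paste0("'%s' does not match the Emo-DB convention ",
             "<2-digit speaker><text code><emotion letter W/L/E/A/F/T/N>",
             "<version>.wav"), name
    ), class = "resemote_emodb_parse_error")
  }
  list(speaker_id = m[2],
       emotion = unname(emodb_letter_map[m[4]]),
       text_code = m[3],
       version = m[5])
}

#' Index a local Emo-DB directory
#'
#' Pure indexing of an already-downloaded corpus: every parseable `.wav` in
#' `root_dir` becomes one entry; unparseable files are skipped with a
#' warning count.  With the canonical corpus this yields 535 entries by 10
#' speakers over 7 emotions.
#'
#' @param root_dir Directory containing the corpus WAV files.
#' @param load_audio Also read each WAV into a `clip` list-column.
#' @return A `corpus_index`: a tibble (`path`, `clip_id`, `speaker_id`,
#'   `label`, `text_code`, `version`, optionally `clip`) with attributes
#'   `class_counts`, `speaker_counts` and `n_skipped`.
#' @export
load_emodb <- function(root_dir, load_audio = FALSE) {
  files <- list.files(root_dir, pattern = "\\.wav$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) {
    rlang::abort(sprintf("No .wav files found under '%s'.", root_dir),
                 class = "resemote_emodb_empty")
  }
  parsed <- lapply(files, function(f) {
    tryCatch(c(list(path = f), parse_emodb_filename(f)),
             resemote_emodb_parse_error = function(e) NULL)
  })
  skipped <- sum(vapply(parsed, is.null, logical(1)))
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (skipped > 0) {
    rlang::warn(sprintf("Skipped %d file(s) not matching the Emo-DB convention.",
                        skipped))
  }
  if (length(parsed) == 0) {
    rlang::abort("No parseable Emo-DB files found.",
                 class = "resemote_emodb_empty")
  }
  idx <- tibble::tibble(
    path = vapply(parsed, `[[`, character(1), "path"),
    clip_id = basename(vapply(parsed, `[[`, character(1), "path")),
    speaker_id = vapply(parsed, `[[`, character(1), "speaker_id"),
    label = vapply(parsed, `[[`, character(1), "emotion"),
    text_code = vapply(parsed, `[[`, character(1), "text_code"),
    version = vapply(parsed, `[[`, character(1), "version")
  )
  if (load_audio) {
    idx$clip <- purrr::pmap(
      list(idx$path, idx$speaker_id, idx$label, idx$clip_id),
      function(p, s, l, id) read_wav(p, speaker_id = s, label = l, clip_id = id)
    )
  }
  structure(idx,
            class_counts = table(idx$label),
            speaker_counts = table(idx$speaker_id),
            n_skipped = skipped,
            class = c("corpus_index", class(idx)))
}
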