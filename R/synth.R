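# Deterministic synthetic speech-like audio.  Emotion classes are encoded as
# band-limited amplitude-modulated multi-tones (distinct spectral signatures
# and/or modulation rates per class); speakers contribute a pitch offset and a
# noise-floor difference, giving the speaker-level nuisance variation that
# speaker-independent evaluation must be robust to.

#' Specification of a synthetic labeled-audio dataset
#'
#' Defines the emotion classes, speakers, clip geometry and noise level of a
#' fully deterministic synthetic corpus.  Class `k` is realized as a tone
#' complex centered at `class_profiles$band_center_hz[k]`, amplitude-modulated
#' at `class_profiles$mod_rate_hz[k]`; speaker `s` shifts all tone frequencies
#' by `speaker_profiles$pitch_offset_hz[s]` and adds Gaussian noise at
#' `snr_db` decibels signal-to-noise ratio.
#'
#' @param n_classes Number of emotion classes (>= 2).
#' @param n_speakers Number of speakers (>= 2).
#' @param clips_per_speaker_per_class Clips per (speaker, class) cell.
#' @param duration_s Clip duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param band_sep_hz Spacing between consecutive class band centers
#'   (the class-separability knob).
#' @param base_band_hz Band center of the first class.
#' @param mod_sep_hz Spacing between consecutive class modulation rates.
#' @param base_mod_hz Modulation rate of the first class.
#' @param discriminate Which cue distinguishes classes: `"both"` (band center
#'   and modulation rate), `"band"` (spectral content only; shared modulation)
#'   or `"modulation"` (shared spectrum; classes differ only in how their
#'   spectrum changes over time).
#' @param pitch_spread_hz Total spread of speaker pitch offsets.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` disables noise.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param class_names,speaker_names Optional label vectors.
#' @return A `synth_spec` list with resolved `class_profiles` and
#'   `speaker_profiles` tibbles.
#' @export
synth_spec <- function(n_classes = 3, n_speakers = 5,
                       clips_per_speaker_per_class = 4,
                       duration_s = 1, sample_rate = 16000,
                       band_sep_hz = 800, base_band_hz = 600,
                       mod_sep_hz = 3, base_mod_hz = 2,
                       discriminate = c("both", "band", "modulation"),
                       pitch_spread_hz = 160, snr_db = 15, seed = 1,
                       class_names = NULL, speaker_names = NULL) {
  stopifnot(n_classes >= 2, n_speakers >= 2, is.finite(seed))
  discriminate <- match.arg(discriminate)
  if (is.null(class_names)) class_names <- paste0("emo", seq_len(n_classes))
  if (is.null(speaker_names)) speaker_names <- sprintf("spk%02d", seq_len(n_speakers))
  centers <- base_band_hz + (seq_len(n_classes) - 1) * band_sep_hz
  mods <- base_mod_hz + (seq_len(n_classes) - 1) * mod_sep_hz
  if (discriminate == "band") mods <- rep(base_mod_hz, n_classes)
  if (discriminate == "modulation") {
    centers <- rep(base_band_hz + band_sep_hz, n_classes)
  }
  offsets <- (seq_len(n_speakers) - (n_speakers + 1) / 2) *
    pitch_spread_hz / max(1, n_speakers - 1)
  structure(
    list(
      n_classes = n_classes, n_speakers = n_speakers,
      clips_per_speaker_per_class = clips_per_speaker_per_class,
      duration_s = duration_s, sample_rate = sample_rate,
      snr_db = snr_db, seed = as.integer(seed),
      class_profiles = tibble::tibble(
        class = class_names, band_center_hz = centers, mod_rate_hz = mods
      ),
      speaker_profiles = tibble::tibble(
        speaker = speaker_names, pitch_offset_hz = offsets,
        noise_gain_db = seq(-2, 2, length.out = n_speakers)
      )
    ),
    class = "synth_spec"
  )
}

# Evaluate `code` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so generation never perturbs user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small deterministic per-clip seed derived from the spec seed and indices.
clip_seed <- function(seed, class_i, speaker_i, rep_i) {
  as.integer((abs(seed) * 7919 + class_i * 104729 + speaker_i * 1299709 +
                rep_i * 15485863) %% 2147483647)
}

#' Generate one synthetic clip
#'
#' @param class_id Class index or name from `spec$class_profiles`.
#' @param speaker_id Speaker index or name from `spec$speaker_profiles`.
#' @param spec A [synth_spec()].
#' @param seed Integer seed for this clip (defaults to a deterministic
#'   function of `spec$seed` and the ids).
#' @param rep_i Replicate index used in the default seed derivation.
#' @return An [audio_clip()] labeled with the class and tagged with the
#'   speaker.
#' @export
generate_clip <- function(class_id, speaker_id, spec, seed = NULL, rep_i = 1) {
  ci <- if (is.character(class_id)) {
    match(class_id, spec$class_profiles$class)
  } else as.integer(class_id)
  si <- if (is.character(speaker_id)) {
    match(speaker_id, spec$speaker_profiles$speaker)
  } else as.integer(speaker_id)
  stopifnot(!is.na(ci), ci >= 1, ci <= spec$n_classes,
            !is.na(si), si >= 1, si <= spec$n_speakers)
  if (is.null(seed)) seed <- clip_seed(spec$seed, ci, si, rep_i)
  cp <- spec$class_profiles[ci, ]
  sp <- spec$speaker_profiles[si, ]
  n <- round(spec$duration_s * spec$sample_rate)
  tt <- (seq_len(n) - 1) / spec$sample_rate
  with_seed(seed, {
    f0 <- cp$band_center_hz + sp$pitch_offset_hz
    phase <- stats::runif(3, 0, 2 * pi)
    # dominant tone plus two weaker partials keeps the spectral argmax at f0
    sig <- sin(2 * pi * f0 * tt + phase[1]) +
      0.4 * sin(2 * pi * 1.5 * f0 * tt + phase[2]) +
      0.2 * sin(2 * pi * 2.0 * f0 * tt + phase[3])
    am <- (1 + 0.8 * sin(2 * pi * cp$mod_rate_hz * tt + phase[1])) / 1.8
    sig <- sig * am
    if (is.finite(spec$snr_db)) {
      snr_lin <- 10^((spec$snr_db - sp$noise_gain_db) / 10)
      noise_sd <- sqrt(mean(sig^2) / snr_lin)
      sig <- sig + stats::rnorm(n, sd = noise_sd)
    }
    audio_clip(sig, spec$sample_rate,
               speaker_id = sp$speaker, label = cp$class,
               clip_id = sprintf("%s_%s_r%02d", cp$class, sp$speaker, rep_i))
  })
}

#' Generate a balanced synthetic dataset
#'
#' Produces `n_speakers * n_classes * clips_per_speaker_per_class` clips,
#' exactly balanced over (speaker, class) cells and fully deterministic given
#' `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with columns `clip_id`, `speaker_id`, `label` and a
#'   list-column `clip` of [audio_clip()] objects.
#' @export
generate_dataset <- function(spec) {
  grid <- tidyr::expand_grid(
    class_i = seq_len(spec$n_classes),
    speaker_i = seq_len(spec$n_speakers),
    rep_i = seq_len(spec$clips_per_speaker_per_class)
  )
  clips <- purrr::pmap(grid, function(class_i, speaker_i, rep_i) {
    generate_clip(class_i, speaker_i, spec, rep_i = rep_i)
  })
  tibble::tibble(
    clip_id = purrr::map_chr(clips, "clip_id"),
    speaker_id = purrr::map_chr(clips, "speaker_id"),
    label = purrr::map_chr(clips, "label"),
    clip = clips
  )
}

#' Generate synthetic annotated trial records
#'
#' Emulates a courtroom annotation study: two groups of defendants with
#' group-specific emotion distributions, several clips per defendant, and
#' three simulated expert labelings per clip obtained by corrupting the true
#' label independently with a stated error rate.  The defaults reproduce the
#' structure of a 27-vs-27 defendant comparison over the emotions angry,
#' neutral and fear.
#'
#' @param n_per_group Defendants per group.
#' @param groups Length-2 character vector of group names.
#' @param emotions Emotion categories.
#' @param group_probs 2 x length(emotions) matrix of person-level emotion
#'   probabilities per group (rows sum to 1).  The default plants a higher
#'   anger/fear rate in the first group.
#' @param clips_per_person Clips recorded per defendant.
#' @param p_express Probability that a clip from a non-neutral defendant
#'   expresses the defendant's emotion (other clips are neutral); the first
#'   clip always expresses it.
#' @param expert_error_rate Probability an expert mislabels a clip (uniformly
#'   to another emotion).
#' @param seed Integer seed.
#' @param audio If `TRUE`, also synthesize waveforms for each clip via
#'   [generate_clip()] (one synthetic "speaker" per defendant); default
#'   `FALSE` returns annotation records only.
#' @param spec Optional [synth_spec()] used when `audio = TRUE`.
#' @return A tibble with one row per clip: `defendant_id`, `group`,
#'   `clip_id`, `true_label`, `expert1`..`expert3`, and (if requested) a
#'   `clip` list-column.
#' @export
generate_trial_records <- function(n_per_group = 27,
                                   groups = c("addiction", "non_addiction"),
                                   emotions = c("angry", "neutral", "fear"),
                                   group_probs = rbind(
                                     c(13, 6, 8) / 27,
                                     c(5, 18, 4) / 27
                                   ),
                                   clips_per_person = 4,
                                   p_express = 0.6,
                                   expert_error_rate = 0.1,
                                   seed = 1,
                                   audio = FALSE,
                                   spec = NULL) {
  stopifnot(length(groups) == 2, nrow(group_probs) == 2,
            ncol(group_probs) == length(emotions),
            expert_error_rate >= 0, expert_error_rate <= 1)
  if (!"neutral" %in% emotions) {
    rlang::abort("`emotions` must include \"neutral\".",
                 class = "resemote_bad_config")
  }
  with_seed(seed, {
    recs <- purrr::map_dfr(1:2, function(g) {
      purrr::map_dfr(seq_len(n_per_group), function(p) {
        person_emotion <- sample(emotions, 1, prob = group_probs[g, ])
        clip_true <- if (person_emotion == "neutral") {
          rep("neutral", clips_per_person)
        } else {
          lab <- ifelse(stats::runif(clips_per_person) < p_express,
                        person_emotion, "neutral")
          lab[1] <- person_emotion
          lab
        }
        experts <- vapply(clip_true, function(tl) {
          vapply(1:3, function(e) {
            if (stats::runif(1) < expert_error_rate) {
              sample(setdiff(emotions, tl), 1)
            } else tl
          }, character(1))
        }, character(3))
        tibble::tibble(
          defendant_id = sprintf("%s_d%02d", groups[g], p),
          group = groups[g],
          clip_id = sprintf("%s_d%02d_c%02d", groups[g], p,
                            seq_len(clips_per_person)),
          true_label = clip_true,
          expert1 = unname(experts[1, ]), expert2 = unname(experts[2, ]),
          expert3 = unname(experts[3, ])
        )
      })
    })
    if (audio) {
      if (is.null(spec)) {
        spec <- synth_spec(n_classes = length(emotions),
                           n_speakers = 2 * n_per_group,
                           class_names = emotions, seed = seed)
      }
      recs$clip <- purrr::pmap(
        list(recs$true_label, recs$defendant_id, seq_len(nrow(recs))),
        function(lab, def, i) {
          generate_clip(lab, match(def, unique(recs$defendant_id)), spec,
                        rep_i = i)
        }
      )
    }
    recs
  })
}

#' Write a dataset's clips and manifest to disk
#'
#' Writes one 16-bit PCM WAV per clip plus a `manifest.csv` with the shared
#' schema (`clip_id`, `path`, `speaker_id`, `label`, `group`,
#' `expert1`..`expert3`; unused columns are `NA`).
#'
#' @param dataset A tibble with a `clip` list-column (from
#'   [generate_dataset()] or [generate_trial_records()] with `audio = TRUE`).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(dataset$clip, function(cl) {
    p <- file.path(dir, paste0(cl$clip_id, ".wav"))
    write_wav(cl, p)
    p
  })
  man <- tibble::tibble(
    clip_id = purrr::map_chr(dataset$clip, "clip_id"),
    path = paths,
    speaker_id = purrr::map_chr(dataset$clip, "speaker_id"),
    label = purrr::map_chr(dataset$clip, "label"),
    group = if ("group" %in% names(dataset)) dataset$group else NA_character_,
    expert1 = if ("expert1" %in% names(dataset)) dataset$expert1 else NA_character_,
    expert2 = if ("expert2" %in% names(dataset)) dataset$expert2 else NA_character_,
    expert3 = if ("expert3" %in% names(dataset)) dataset$expert3 else NA_character_
  )
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Read a manifest and load its clips
#'
#' @param path Path to a `manifest.csv` written by [export_dataset()] (or the
#'   Emo-DB indexer).
#' @param load_audio If `TRUE`, read each WAV into a `clip` list-column.
#' @return A tibble mirroring the manifest, optionally with clips attached.
#' @export
read_manifest <- function(path, load_audio = TRUE) {
  man <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (load_audio) {
    man$clip <- purrr::pmap(
      list(man$path, man$speaker_id, man$label, man$clip_id),
      function(p, s, l, id) read_wav(p, speaker_id = s, label = l, clip_id = id)
    )
  }
  man
}
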