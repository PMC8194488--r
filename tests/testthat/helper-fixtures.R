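# Shared fixtures, all generated in code.

# Small, quickly trainable synthetic study: 3 spectrally separable classes,
# 5 speakers, short clips at 8 kHz, 16 Mel bands so two residual blocks
# collapse the frequency axis to 1.
small_synth_spec <- function(seed = 11, ...) {
  synth_spec(n_classes = 3, n_speakers = 5, clips_per_speaker_per_class = 5,
             duration_s = 0.5, sample_rate = 8000, seed = seed, ...)
}

small_feature_cfg <- function(...) {
  feature_config(n_mels = 16, sample_rate = 8000, ...)
}

small_model_cfg <- function(n_classes = 3, ...) {
  model_config(n_classes = n_classes, expand_channels = 8,
               n_residual_blocks = 2, lstm_hidden = 16, fc_hidden = 16,
               seed = 1, ...)
}

# Even smaller scale for smoke-level checks.
tiny_synth_spec <- function(seed = 5, n_classes = 2, ...) {
  synth_spec(n_classes = n_classes, n_speakers = 4,
             clips_per_speaker_per_class = 2, duration_s = 0.4,
             sample_rate = 8000, seed = seed, ...)
}

tiny_model_cfg <- function(n_classes = 2, ...) {
  model_config(n_classes = n_classes, expand_channels = 6,
               n_residual_blocks = 2, lstm_hidden = 8, fc_hidden = 8,
               seed = 1, ...)
}

# Person-level labels reproducing the published 27-vs-27 association table:
# addiction group 13 angry / 6 neutral / 8 fear, comparison group 5 / 18 / 4.
association_fixture <- function() {
  tibble::tibble(
    group = rep(c("addiction", "non_addiction"), each = 27),
    label = c(rep(c("angry", "neutral", "fear"), c(13, 6, 8)),
              rep(c("angry", "neutral", "fear"), c(5, 18, 4)))
  )
}

# Hand-formula Pearson chi-square oracle, independent of stats::chisq.test.
chisq_oracle <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - expected)^2 / expected),
       dof = (nrow(m) - 1) * (ncol(m) - 1))
}

# Direct triple-loop 3x3 same-padded convolution oracle.
conv3x3_oracle <- function(x, W, b) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], dim(W)[4]))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (co in seq_len(dim(W)[4])) {
        acc <- b[co]
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- i + di; jj <- j + dj
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
              acc <- acc + sum(x[ii, jj, ] * W[di + 2, dj + 2, , co])
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

softmax_oracle <- function(x) exp(x) / sum(exp(x))
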