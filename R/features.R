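#' Feature extraction configuration
#'
#' Parameters of the three-channel log-Mel front end: 25 ms Hamming windows
#' with a 10 ms hop, a triangular Mel filterbank, and regression deltas with
#' half-width `delta_width = 2`.
#'
#' @param window_ms Analysis window length in milliseconds.
#' @param hop_ms Hop (frame shift) in milliseconds; must be smaller than
#'   `window_ms`.
#' @param n_mels Number of Mel bands (`f` axis).  The default 64 collapses
#'   exactly to 1 after three 4-fold frequency poolings in the network
#'   (64 -> 16 -> 4 -> 1).
#' @param delta_width Regression half-width `N` for delta features.
#' @param fft_size FFT length; `NULL` picks the next power of two at or above
#'   the window length in samples (512 at 16 kHz).
#' @param sample_rate Rate (Hz) clips are resampled to before framing.
#' @param channels Which of the three channels to keep, a subset of
#'   `c("static", "delta", "delta_delta")`.  Subsetting is used by the
#'   feature-ablation experiments; the model always receives the channels in
#'   this fixed order.
#' @param log_floor Additive floor inside the logarithm, guarding against
#'   `log(0)`.
#' @return A `feature_config` list.
#' @export
feature_config <- function(window_ms = 25, hop_ms = 10, n_mels = 64,
                           delta_width = 2, fft_size = NULL,
                           sample_rate = 16000,
                           channels = c("static", "delta", "delta_delta"),
                           log_floor = 1e-10) {
  stopifnot(window_ms > hop_ms, hop_ms > 0, delta_width >= 1, n_mels >= 8)
  if (length(channels) == 0L) {
    rlang::abort("At least one feature channel is required.",
                 class = "resemote_bad_config")
  }
  channels <- match.arg(channels, c("static", "delta", "delta_delta"),
                        several.ok = TRUE)
  structure(
    list(window_ms = window_ms, hop_ms = hop_ms, n_mels = n_mels,
         delta_width = delta_width, fft_size = fft_size,
         sample_rate = sample_rate, channels = channels,
         log_floor = log_floor),
    class = "feature_config"
  )
}

win_samples <- function(cfg) round(cfg$sample_rate * cfg$window_ms / 1000)
hop_samples <- function(cfg) round(cfg$sample_rate * cfg$hop_ms / 1000)

fft_length <- function(cfg) {
  if (!is.null(cfg$fft_size)) return(cfg$fft_size)
  2L^ceiling(log2(win_samples(cfg)))
}

#' Z-score standardization of a clip
#'
#' Centers and scales the waveform to zero mean and unit (population)
#' standard deviation, removing per-speaker level differences before
#' spectral analysis.
#'
#' @param clip An [audio_clip()].
#' @return The standardized [audio_clip()].
#' @export
standardize <- function(clip) {
  x <- clip$samples
  n <- length(x)
  mu <- mean(x)
  sd_pop <- sqrt(sum((x - mu)^2) / n)
  if (sd_pop == 0) {
    rlang::abort("Cannot standardize a constant (zero-variance) signal.",
                 class = "resemote_degenerate_signal")
  }
  clip$samples <- (x - mu) / sd_pop
  clip
}

#' Frame a clip and compute per-frame power spectra
#'
#' Splits the waveform into Hamming-windowed frames (25 ms window, 10 ms hop
#' by default) and applies the DFT to each; returns the one-sided power
#' spectrum per frame.  The number of frames is
#' `t = 1 + floor((L - win) / hop)`.
#'
#' @param clip An [audio_clip()], typically after [standardize()].
#' @param cfg A [feature_config()].
#' @return A `t x (fft_size/2 + 1)` matrix of nonnegative power values, with
#'   attribute `frame_times` (frame-center times in seconds).
#' @export
frame_power_spectrum <- function(clip, cfg = feature_config()) {
  clip <- resample_clip(clip, cfg$sample_rate)
  win <- win_samples(cfg)
  hop <- hop_samples(cfg)
  x <- clip$samples
  if (length(x) < win) {
    rlang::abort(sprintf(
      "Clip of %d samples is shorter than one %d-sample analysis window.",
      length(x), win
    ), class = "resemote_too_short")
  }
  n_frames <- 1L + floor((length(x) - win) / hop)
  nfft <- fft_length(cfg)
  w <- signal::hamming(win)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  idx <- seq_len(win)
  for (j in seq_len(n_frames)) {
    frames[idx, j] <- x[starts[j] + idx] * w
  }
  spec <- stats::mvfft(frames)
  n_bins <- nfft %/% 2L + 1L
  pow <- t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2)
  attr(pow, "frame_times") <- (starts + win / 2) / cfg$sample_rate
  pow
}

#' Triangular Mel filterbank matrix
#'
#' HTK-convention Mel scale (`mel = 2595 log10(1 + f/700)`), triangular
#' filters spanning 0 Hz to Nyquist.
#'
#' @param n_mels Number of filters.
#' @param n_bins Number of (one-sided) FFT bins.
#' @param sample_rate Sampling rate in Hz.
#' @return An `n_bins x n_mels` nonnegative matrix.
#' @export
mel_filterbank <- function(n_mels, n_bins, sample_rate) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  nfft <- 2L * (n_bins - 1L)
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                 length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (seq_len(n_bins) - 1L) * sample_rate / nfft
  fb <- matrix(0, n_bins, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Static log-Mel features from a power matrix
#'
#' Applies the Mel filterbank and takes the natural logarithm with an
#' additive floor.
#'
#' @param power A `t x n_bins` nonnegative power matrix from
#'   [frame_power_spectrum()].
#' @param cfg A [feature_config()].
#' @param filterbank Optional precomputed filterbank (`n_bins x n_mels`);
#'   built from `cfg` when `NULL`.
#' @return A `t x n_mels` matrix of log-Mel energies.
#' @export
log_mel <- function(power, cfg = feature_config(), filterbank = NULL) {
  if (any(power < 0)) {
    rlang::abort("`power` must be nonnegative.", class = "resemote_bad_input")
  }
  if (is.null(filterbank)) {
    filterbank <- mel_filterbank(cfg$n_mels, ncol(power), cfg$sample_rate)
  }
  log(power %*% filterbank + cfg$log_floor)
}

#' Regression delta of a frame-level feature matrix
#'
#' First-order regression estimate of the temporal derivative,
#' `d_i = sum_{n=1..N} n (x_{i+n} - x_{i-n}) / (2 sum_{n=1..N} n^2)`,
#' with out-of-range frames clamped to the first/last frame.
#'
#' @param x A `t x f` matrix (time in rows).
#' @param N Regression half-width (frames).
#' @return A matrix of the same shape.
#' @export
delta <- function(x, N = 2) {
  stopifnot(N >= 1)
  x <- as.matrix(x)
  t_len <- nrow(x)
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, t_len, ncol(x))
  for (n in seq_len(N)) {
    fwd <- x[pmin(seq_len(t_len) + n, t_len), , drop = FALSE]
    bwd <- x[pmax(seq_len(t_len) - n, 1L), , drop = FALSE]
    out <- out + n * (fwd - bwd)
  }
  out / denom
}

#' Extract the three-channel log-Mel representation of a clip
#'
#' The full front end: z-score standardization, Hamming framing, power
#' spectra, Mel filterbank, log compression, then delta and delta-delta
#' channels.  The result is the `t x f x 3` array the network consumes
#' (channel 1 static, channel 2 delta, channel 3 delta-delta).
#'
#' @param clip An [audio_clip()].
#' @param cfg A [feature_config()].  `cfg$channels` selects which channels are
#'   retained (in the fixed static/delta/delta-delta order).
#' @return A `log_mel_feature` object: a `t x n_mels x n_channels` array with
#'   attributes `frame_times` and `channels`.
#' @export
extract_features <- function(clip, cfg = feature_config()) {
  pow <- frame_power_spectrum(standardize(clip), cfg)
  static <- log_mel(pow, cfg)
  d1 <- delta(static, cfg$delta_width)
  d2 <- delta(d1, cfg$delta_width)
  all_ch <- list(static = static, delta = d1, delta_delta = d2)
  keep <- all_ch[cfg$channels]
  out <- array(0, dim = c(nrow(static), ncol(static), length(keep)))
  for (k in seq_along(keep)) out[, , k] <- keep[[k]]
  structure(out,
            frame_times = attr(pow, "frame_times"),
            channels = cfg$channels,
            class = c("log_mel_feature", "array"))
}

#' @export
print.log_mel_feature <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<log_mel_feature> %d frames x %d Mel bands x %d channels (%s)\n",
              d[1], d[2], d[3], paste(attr(x, "channels"), collapse = ", ")))
  invisible(x)
}
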