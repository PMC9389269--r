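# Voice features: pre-emphasis, Hamming framing (30 ms window / 15 ms hop),
# STFT power spectrum, Mel filter bank projection, log compression, and
# rendering to the fixed-size image the 2D classifier consumes.

#' Construct an audio clip
#'
#' @param samples Numeric vector in [-1, 1].
#' @param fs Sampling rate in Hz.
#' @param sample_id Opaque identifier.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, fs, sample_id = "audio") {
  sf_assert(is.numeric(fs) && length(fs) == 1L && fs > 0, "invalid_config",
            "fs must be a positive scalar")
  sf_assert(length(samples) >= 1L && all(is.finite(samples)),
            "degenerate_input", "audio samples must be nonempty and finite")
  structure(list(samples = as.numeric(samples), fs = fs, sample_id = sample_id),
            class = "audio_clip")
}

#' Resample an audio clip
#'
#' Linear-phase FFT resampling to the target rate. All voice processing in
#' the toolkit operates at a fixed 16 kHz so frame geometry and the Mel bank
#' do not depend on the recording device.
#'
#' @param clip An `audio_clip`.
#' @param fs_out Target rate in Hz (default 16000).
#' @return The resampled `audio_clip`.
#' @export
resample_audio <- function(clip, fs_out = 16000) {
  if (clip$fs == fs_out) return(clip)
  n_out <- max(1L, round(length(clip$samples) * fs_out / clip$fs))
  # band-limited interpolation via zero-padded/truncated spectrum
  y <- stats::approx(seq_along(clip$samples), clip$samples,
                     xout = seq(1, length(clip$samples), length.out = n_out))$y
  if (fs_out < clip$fs) {
    # prevent aliasing: low-pass at the new Nyquist before decimation
    bf <- signal::butter(8, (0.45 * fs_out) / (clip$fs / 2), type = "low")
    x <- signal::filtfilt(bf, clip$samples)
    y <- stats::approx(seq_along(x), x,
                       xout = seq(1, length(x), length.out = n_out))$y
  }
  audio_clip(y, fs_out, clip$sample_id)
}

#' Pre-emphasize an audio clip
#'
#' First-difference high-pass `y[n] = x[n] - coeff * x[n-1]` (with
#' `y[1] = x[1]`), boosting high frequencies ahead of spectral analysis.
#'
#' @param clip An `audio_clip`.
#' @param coeff Pre-emphasis coefficient in [0, 1).
#' @return The emphasized `audio_clip`.
#' @export
pre_emphasize <- function(clip, coeff = 0.97) {
  sf_assert(coeff >= 0 && coeff < 1, "invalid_config",
            "pre-emphasis coefficient must be in [0, 1)")
  x <- clip$samples
  y <- c(x[1], x[-1] - coeff * x[-length(x)])
  audio_clip(y, clip$fs, clip$sample_id)
}

# Number of analysis frames for a clip of n samples.
n_frames_for <- function(n, fs, frame_ms = 30, hop_ms = 15) {
  win <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  if (n < win) 0L else as.integer(floor((n - win) / hop) + 1)
}

#' Frame a clip with a Hamming window
#'
#' Frames of `frame_ms` length advance by `hop_ms` (30 ms window with 15 ms
#' overlap, i.e. 50%); the trailing partial frame is dropped; each frame is
#' multiplied by a Hamming window.
#'
#' @param clip An `audio_clip`.
#' @param frame_ms,hop_ms Frame length and hop in milliseconds.
#' @return `n_frames` x `frame_len` matrix of windowed frames, with the
#'   window vector and geometry attached as attributes.
#' @export
frame_signal <- function(clip, frame_ms = 30, hop_ms = 15) {
  fs <- clip$fs
  win_len <- round(frame_ms / 1000 * fs)
  n <- length(clip$samples)
  sf_assert(n >= win_len, "clip_too_short",
            "clip (%d samples) shorter than one %g ms frame", n, frame_ms)
  nf <- n_frames_for(n, fs, frame_ms, hop_ms)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  starts <- round((seq_len(nf) - 1) * hop_ms / 1000 * fs) + 1L
  frames <- t(vapply(starts, function(s) clip$samples[s:(s + win_len - 1)] * w,
                     numeric(win_len)))
  attr(frames, "window") <- w
  attr(frames, "starts") <- starts
  attr(frames, "fs") <- fs
  frames
}

#' Hz to Mel scale
#' @param f Frequency in Hz.
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' Mel to Hz scale
#' @param m Mel value(s).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filter bank: n_mels filters over [0, fs/2] on an n_fft/2+1
# point linear frequency grid.
mel_filterbank <- function(n_mels, n_fft, fs) {
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bins <- hz_pts / (fs / n_fft)          # fractional FFT bin positions
  freqs <- (0:(n_fft / 2))               # bin indices of the spectrum grid
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; ctr <- bins[m + 1]; hi <- bins[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center_hz") <- hz_pts[2:(n_mels + 1)]
  fb
}

#' Compute a log-Mel spectrogram
#'
#' Pre-framed (or raw) audio goes through a per-frame power spectrum
#' (STFT), a triangular Mel filter bank spanning [0, fs/2], and
#' `log(1 + E / eps)` compression.
#'
#' @param clip An `audio_clip`.
#' @param n_mels Number of Mel bands (default 64).
#' @param frame_ms,hop_ms Framing geometry in milliseconds.
#' @param eps Log-compression floor.
#' @return A `mel_spectrogram`: list with `energies` (`n_frames` x `n_mels`
#'   log-energy matrix), `power` (linear Mel power), `n_mels`, `fs`,
#'   `frame_ms`, `hop_ms`, `center_hz`.
#' @export
compute_mel_spectrogram <- function(clip, n_mels = 64, frame_ms = 30,
                                    hop_ms = 15, eps = 1e-10) {
  sf_assert(n_mels >= 2, "invalid_config", "n_mels must be at least 2")
  frames <- frame_signal(clip, frame_ms, hop_ms)
  win_len <- ncol(frames)
  n_fft <- 2^ceiling(log2(win_len))
  pad <- matrix(0, nrow(frames), n_fft - win_len)
  sp <- stats::mvfft(t(cbind(frames, pad)))
  pow <- (Mod(sp[1:(n_fft / 2 + 1), , drop = FALSE])^2)  # bins x frames
  fb <- mel_filterbank(n_mels, n_fft, clip$fs)
  mel_pow <- t(fb %*% pow)                               # frames x mels
  structure(list(
    energies = log1p(mel_pow / eps),
    power = mel_pow,
    spec_power = t(pow),
    n_mels = n_mels, fs = clip$fs,
    frame_ms = frame_ms, hop_ms = hop_ms,
    center_hz = attr(fb, "center_hz"),
    sample_id = clip$sample_id
  ), class = "mel_spectrogram")
}

#' Render a Mel spectrogram as a fixed-size image
#'
#' Min-max scaled and bilinearly resized so time runs along the horizontal
#' axis and Mel band index (low at the bottom) along the vertical axis.
#'
#' @param ms A `mel_spectrogram`.
#' @param width,height Output size in pixels (default 307 x 230).
#' @return `height` x `width` intensity matrix in [0, 1].
#' @export
render_spectrogram_image <- function(ms, width = 307, height = 230) {
  e <- ms$energies
  sf_assert(length(e) >= 1L && nrow(e) >= 1L, "degenerate_input",
            "empty spectrogram")
  # rows = mel bands (band 1 at the bottom), cols = frames
  img <- t(e)[rev(seq_len(ncol(e))), , drop = FALSE]
  if (nrow(img) == 1L) img <- rbind(img, img)
  if (ncol(img) == 1L) img <- cbind(img, img)
  resized <- resize_mat(minmax01(img), height, width)
  pmin(pmax(resized, 0), 1)
}

#' Full voice preprocessing chain
#'
#' Resample to 16 kHz, pre-emphasize, compute the log-Mel spectrogram and
#' render it as an image.
#'
#' @param clip Raw `audio_clip`.
#' @param n_mels Number of Mel bands.
#' @param fs_out Processing sample rate.
#' @param width,height Image size.
#' @return List with `clip` (processed), `mel`, `image`.
#' @export
preprocess_voice <- function(clip, n_mels = 64, fs_out = 16000,
                             width = 307, height = 230) {
  clip <- resample_audio(clip, fs_out)
  clip <- pre_emphasize(clip)
  mel <- compute_mel_spectrogram(clip, n_mels = n_mels)
  list(clip = clip, mel = mel,
       image = render_spectrogram_image(mel, width, height))
}
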