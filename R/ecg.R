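# ECG preprocessing: powerline notch, band-pass denoising, standardization,
# R-peak detection, and heartbeat relocation via short-term autocorrelation
# of the boundary regions, ending in a fixed-size trace image.

#' Construct an ECG record
#'
#' @param samples Numeric vector of single-channel ECG samples (arbitrary
#'   amplitude units).
#' @param fs Sampling rate in Hz.
#' @param sample_id Opaque identifier.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, sample_id = "ecg") {
  sf_assert(is.numeric(fs) && length(fs) == 1L && fs > 0, "invalid_config",
            "fs must be a positive scalar")
  sf_assert(all(is.finite(samples)), "degenerate_input",
            "ECG samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, sample_id = sample_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.2f s)>\n",
              x$sample_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Remove powerline interference with an IIR notch filter
#'
#' A biquad notch (quality factor `q`) at `f0`, applied forward-backward so
#' R-wave positions are not phase-shifted.
#'
#' @param record An `ecg_record`.
#' @param f0 Notch frequency in Hz (mains interference; default 50).
#' @param q Quality factor controlling notch width.
#' @return The filtered `ecg_record`, same length.
#' @export
apply_notch <- function(record, f0 = 50, q = 30) {
  fs <- record$fs
  sf_assert(fs > 2 * f0, "invalid_config",
            "sampling rate %g must exceed twice the notch frequency %g", fs, f0)
  # RBJ audio-EQ cookbook notch biquad
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  y <- signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), record$samples)
  ecg_record(y, fs, record$sample_id)
}

#' Band-pass filter an ECG record
#'
#' Zero-phase Butterworth band-pass; the default (0.5, 50) Hz band
#' suppresses baseline wander, electrode drift and muscle noise while keeping
#' the QRS energy. Realized as a 2nd-order high-pass cascaded with an
#' `order`-th low-pass, each applied forward-backward: a single
#' transfer-function band-pass with such a narrow normalized low edge
#' (0.5 Hz at 2 kHz) is numerically unstable.
#'
#' @param record An `ecg_record`.
#' @param low,high Band edges in Hz.
#' @param order Low-pass Butterworth order.
#' @return The filtered `ecg_record`, same length.
#' @export
apply_bandpass <- function(record, low = 0.5, high = 50, order = 4) {
  fs <- record$fs
  sf_assert(low > 0 && low < high && high < fs / 2, "invalid_config",
            "band (%g, %g) must satisfy 0 < low < high < fs/2 = %g", low, high, fs / 2)
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, record$samples))
  ecg_record(y, fs, record$sample_id)
}

#' Standardize an ECG record to zero mean and unit variance
#'
#' Removes amplitude scaling between recordings so that downstream
#' thresholds are scale-free.
#'
#' @param record An `ecg_record`.
#' @return The standardized `ecg_record`.
#' @export
standardize <- function(record) {
  s <- sd(record$samples)
  sf_assert(s > 0, "degenerate_input", "cannot standardize a constant series")
  ecg_record((record$samples - mean(record$samples)) / s, record$fs, record$sample_id)
}

#' Detect R waves with a thresholded sliding window
#'
#' Local maxima of the (preprocessed, standardized) signal above
#' `threshold_frac` times the global maximum are kept, then deduplicated so
#' no two peaks fall within the refractory interval (larger peak wins).
#'
#' @param record A preprocessed `ecg_record`.
#' @param window_s Sliding-window length in seconds (context for local maxima).
#' @param threshold_frac Threshold as a fraction of the global maximum.
#' @param refractory_s Minimum separation between accepted peaks in seconds;
#'   physiologically no two R waves occur within 250 ms.
#' @return An `r_peak_list` with strictly increasing `indices` (1-based) and
#'   `threshold_used`.
#' @export
detect_r_peaks <- function(record, window_s = 0.6, threshold_frac = 0.5,
                           refractory_s = 0.25) {
  x <- record$samples
  n <- length(x)
  thr <- threshold_frac * max(x)
  # interior local maxima above threshold (plateaus take their first sample)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] >= thr]
  # also admit boundary maxima of each sliding window edge case: a peak at the
  # very start/end of the record has no two-sided neighbourhood, skip it.
  if (length(cand) == 0L)
    sf_stop("empty_result",
            "no R peak found (threshold %.3g, global max %.3g)", thr, max(x))
  refr <- round(refractory_s * record$fs)
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < refr)) keep[i] <- TRUE
  }
  idx <- sort(cand[keep])
  structure(list(indices = idx, threshold_used = thr,
                 window_s = window_s, refractory_s = refractory_s),
            class = "r_peak_list")
}

#' Short-term autocorrelation of a signal window
#'
#' Computes `acf[k] = sum_n x[n] x[n+k]` for lags `0..max_lag` over the given
#' window (via FFT; exact up to floating point), normalized so `acf[0] = 1`.
#' Normalization makes the clipping thresholds scale-free.
#'
#' @param segment Numeric vector (the analysis window).
#' @param max_lag Maximum lag in samples; must be below the window length.
#' @param normalize Divide by lag-0 value (default TRUE).
#' @return An `autocorr_result` with fields `acf` (lags `0..max_lag`),
#'   `max_lag`, and placeholders for the clipped series / period.
#' @export
short_time_autocorr <- function(segment, max_lag, normalize = TRUE) {
  n <- length(segment)
  sf_assert(max_lag < n, "invalid_config",
            "max_lag %d must be below window length %d", max_lag, n)
  sf_assert(max_lag >= 1, "invalid_config", "max_lag must be at least 1")
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(segment, rep(0, nfft - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE)) / nfft
  ac <- ac[1:(max_lag + 1)]
  if (normalize) {
    sf_assert(ac[1] > 0, "degenerate_input", "zero-energy window")
    ac <- ac / ac[1]
  }
  structure(list(acf = ac, max_lag = max_lag, clipped = NULL,
                 period_samples = NULL),
            class = "autocorr_result")
}

#' Center-clip an autocorrelation series
#'
#' Piecewise shrink: values above `alpha` are reduced by `alpha`, values
#' below `beta` are raised by `beta`, values between are zeroed. Suppresses
#' the low-level ripple so only genuine harmonic peaks survive.
#'
#' @param acf Numeric vector (typically a normalized autocorrelation).
#' @param alpha Upper threshold (default 0.1).
#' @param beta Lower threshold (default -0.1).
#' @return Clipped numeric vector of the same length.
#' @export
clip_autocorr <- function(acf, alpha = 0.1, beta = -0.1) {
  sf_assert(alpha > beta, "invalid_config", "alpha must exceed beta")
  out <- numeric(length(acf))
  hi <- acf > alpha
  lo <- acf < beta
  out[hi] <- acf[hi] - alpha
  out[lo] <- acf[lo] - beta
  out
}

#' Estimate the inter-beat period from a clipped autocorrelation
#'
#' Returns the lag of the maximum of the first harmonic after the main
#' lobe around lag 0 has decayed. Positive runs are scanned in lag order
#' and the first run whose peak reaches `dominance` times the global
#' post-lobe maximum is taken; its maximum lag is the period. The
#' dominance requirement rejects weak side-lobe runs (such as the R-to-T
#' wave cross-correlation of an ECG beat, which precedes the true R-R lag
#' but is far smaller), while scanning in lag order still selects the
#' fundamental P rather than 2P when `max_lag >= 2P`.
#'
#' @param acres An `autocorr_result`, or a numeric vector taken as the
#'   clipped series over lags `0..length-1`.
#' @param alpha,beta Clipping thresholds applied if `acres` has no clipped
#'   series yet.
#' @param dominance Fraction of the global post-lobe maximum a run must
#'   reach to count as the first harmonic (default 0.5).
#' @return Integer lag in samples (`period_samples`).
#' @export
estimate_rr_interval <- function(acres, alpha = 0.1, beta = -0.1,
                                 dominance = 0.5) {
  clipped <- if (inherits(acres, "autocorr_result")) {
    if (is.null(acres$clipped)) clip_autocorr(acres$acf, alpha, beta) else acres$clipped
  } else as.numeric(acres)
  n <- length(clipped)
  # skip the main lobe: advance past leading positives from lag 0
  k <- 2L  # clipped[1] is lag 0
  while (k <= n && clipped[k] > 0) k <- k + 1L
  if (k > n || all(clipped[k:n] <= 0))
    sf_stop("period_not_found", "no positive harmonic after lag 0 in clipped series")
  global_max <- max(clipped[k:n])
  while (k <= n) {
    while (k <= n && clipped[k] <= 0) k <- k + 1L
    if (k > n) break
    run_end <- k
    while (run_end < n && clipped[run_end + 1L] > 0) run_end <- run_end + 1L
    if (max(clipped[k:run_end]) >= dominance * global_max) {
      lag <- (k:run_end)[which.max(clipped[k:run_end])] - 1L
      return(as.integer(lag))
    }
    k <- run_end + 1L
  }
  sf_stop("period_not_found", "no dominant harmonic found in clipped series")
}

# Autocorrelation-based period of the 2 s of signal adjacent to a boundary
# R wave. side = "before": window ends at the peak and is reversed; side =
# "after": window starts at the peak.
boundary_period <- function(record, peak, side = c("before", "after"),
                            context_s = 2, alpha = 0.1, beta = -0.1) {
  side <- match.arg(side)
  n_ctx <- round(context_s * record$fs)
  x <- record$samples
  if (side == "before") {
    sf_assert(peak - n_ctx >= 1, "context_too_short",
              "need %g s of signal before the first R peak", context_s)
    w <- rev(x[(peak - n_ctx):peak])
  } else {
    sf_assert(peak + n_ctx <= length(x), "context_too_short",
              "need %g s of signal after the last R peak", context_s)
    w <- x[peak:(peak + n_ctx)]
  }
  acres <- short_time_autocorr(w, max_lag = n_ctx)
  acres$clipped <- clip_autocorr(acres$acf, alpha, beta)
  acres$period_samples <- estimate_rr_interval(acres)
  acres
}

#' Relocate a heartbeat segment to inter-beat midpoints
#'
#' Re-cuts the record so it starts at the midpoint between the first
#' detected R wave and its (unobserved) predecessor, and ends at the
#' midpoint between the last R wave and its successor. The two boundary
#' periods `T1` and `T2` are estimated by the short-term autocorrelation of
#' the 2 s of signal adjacent to each boundary peak (reversed on the leading
#' side): `start = R1 - floor(T1/2)`, `end = RN + floor(T2/2)`.
#'
#' @param record A preprocessed `ecg_record`.
#' @param peaks An `r_peak_list` from [detect_r_peaks()].
#' @param context_s Boundary analysis window in seconds (default 2).
#' @param alpha,beta Autocorrelation clipping thresholds.
#' @return A `heartbeat_segment` with `samples`, `start_index`, `end_index`
#'   (1-based, inclusive), `fs`, `t1`, `t2` and the retained `r_peaks`
#'   re-indexed to the segment.
#' @export
relocate_heartbeat <- function(record, peaks, context_s = 2,
                               alpha = 0.1, beta = -0.1) {
  sf_assert(length(peaks$indices) >= 1L, "empty_result", "no R peaks supplied")
  r1 <- peaks$indices[1]
  rn <- peaks$indices[length(peaks$indices)]
  ac1 <- boundary_period(record, r1, "before", context_s, alpha, beta)
  acn <- boundary_period(record, rn, "after",  context_s, alpha, beta)
  t1 <- ac1$period_samples
  t2 <- acn$period_samples
  start_index <- r1 - floor(t1 / 2)
  end_index <- rn + floor(t2 / 2)
  sf_assert(start_index >= 1 && end_index <= length(record$samples),
            "context_too_short", "relocated segment exceeds the parent record")
  structure(list(
    samples = record$samples[start_index:end_index],
    start_index = start_index, end_index = end_index, fs = record$fs,
    t1 = t1, t2 = t2,
    r_peaks = peaks$indices - start_index + 1L,
    sample_id = record$sample_id
  ), class = "heartbeat_segment")
}

#' Render a heartbeat segment as a fixed-size trace image
#'
#' Deterministic rasterization of the amplitude-vs-time trace: amplitude is
#' min-max scaled to the vertical axis, time to the horizontal axis, and the
#' line is drawn by connecting consecutive samples.
#'
#' @param segment A `heartbeat_segment` (or any object with `$samples`).
#' @param width,height Output size in pixels; the defaults give the
#'   307 x 230 input expected by the 2D classifier.
#' @return `height` x `width` matrix with intensities in [0, 1]
#'   (1 = trace, 0 = background), oriented so larger amplitudes are higher
#'   rows from the bottom.
#' @export
render_ecg_image <- function(segment, width = 307, height = 230) {
  x <- if (is.list(segment)) segment$samples else as.numeric(segment)
  sf_assert(length(x) >= 1L, "degenerate_input", "empty segment")
  img <- matrix(0, height, width)
  n <- length(x)
  cols <- if (n == 1L) rep(1L, 2L) else round(1 + (seq_len(n) - 1) / (n - 1) * (width - 1))
  amp <- minmax01(x)
  rows <- height - round(amp * (height - 1))  # row 1 = top = max amplitude
  # draw line segments between consecutive samples
  for (i in seq_len(n - 1)) {
    c0 <- cols[i]; c1 <- cols[i + 1]; r0 <- rows[i]; r1 <- rows[i + 1]
    steps <- max(abs(c1 - c0), abs(r1 - r0)) + 1L
    cc <- round(seq(c0, c1, length.out = steps))
    rr <- round(seq(r0, r1, length.out = steps))
    img[cbind(rr, cc)] <- 1
  }
  if (n == 1L) img[rows[1], ] <- 1
  img
}

#' Full ECG preprocessing chain
#'
#' Notch, band-pass, standardize, detect R peaks, relocate, render.
#'
#' @param record Raw `ecg_record`.
#' @param notch_hz Mains frequency (NULL skips the notch).
#' @param band Band-pass edges in Hz.
#' @param width,height Image size.
#' @param threshold_frac R-peak threshold fraction.
#' @return List with `record` (preprocessed), `peaks`, `segment`, `image`.
#' @export
preprocess_ecg <- function(record, notch_hz = 50, band = c(0.5, 50),
                           width = 307, height = 230, threshold_frac = 0.5) {
  rec <- record
  if (!is.null(notch_hz)) rec <- apply_notch(rec, notch_hz)
  rec <- apply_bandpass(rec, band[1], band[2])
  rec <- standardize(rec)
  peaks <- detect_r_peaks(rec, threshold_frac = threshold_frac)
  # relocation needs 2 s of context around the boundary peaks; drop boundary
  # peaks that lack it rather than failing the whole record
  n_ctx <- round(2 * rec$fs)
  idx <- peaks$indices[peaks$indices - n_ctx >= 1 & peaks$indices + n_ctx <= length(rec$samples)]
  sf_assert(length(idx) >= 1L, "context_too_short",
            "no R peak has 2 s of context on both sides")
  peaks$indices <- idx
  segment <- relocate_heartbeat(rec, peaks)
  list(record = rec, peaks = peaks, segment = segment,
       image = render_ecg_image(segment, width, height))
}
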