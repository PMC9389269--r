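# Seeded synthetic multimodal samples with class-dependent structure and
# exact ground truth: ECG with known R positions (heart rate up and
# beat-to-beat variability up under stress), harmonic voice with higher
# fundamental and flatter spectral tilt under stress, and face videos whose
# facial sub-pattern oscillates faster and stronger under stress.

#' Synthetic dataset configuration
#'
#' Defaults encode the emulated physiology: stress-class heart rates lie
#' strictly above the calm range, stress raises beat-to-beat variability,
#' voice fundamental and high-frequency energy, and facial motion frequency
#' and amplitude. Control and experimental share the stress physiology with
#' slightly different parameters, mirroring a three-stage labeling that is
#' later collapsed to calm/stress.
#'
#' @param n_per_class Samples per stage class.
#' @param seed Master seed.
#' @param ecg,voice,video Per-modality parameter lists; see defaults.
#' @param n_folds Stratified folds precomputed in the manifest.
#' @return A `synth_config` list.
#' @export
synth_config <- function(
    n_per_class = 20, seed = 1,
    ecg = list(fs = 2000, duration_s = 10,
               hr_bpm = list(calm = c(60, 75), control = c(85, 100),
                             experimental = c(100, 120)),
               rr_sd_ms = c(calm = 20, control = 35, experimental = 45),
               noise_snr_db = 20, hum_amp = 0.02),
    voice = list(fs = 16000, duration_s = 2,
                 f0_hz = c(calm = 120, control = 180, experimental = 220),
                 tilt = c(calm = 1.5, control = 1.0, experimental = 0.8),
                 noise_snr_db = 30),
    video = list(fps = 30, n_frames = 90, frame_h = 48, frame_w = 64,
                 box = 30,
                 osc_hz = c(calm = 0.5, control = 1.5, experimental = 2.5),
                 osc_amp = c(calm = 0.2, control = 0.5, experimental = 0.7)),
    n_folds = 10) {
  sf_assert(min(ecg$hr_bpm$control[1], ecg$hr_bpm$experimental[1]) >
              max(ecg$hr_bpm$calm), "invalid_config",
            "stress-class heart rates must lie strictly above the calm range")
  sf_assert(n_per_class >= 1, "invalid_config", "need at least 1 sample per class")
  structure(list(n_per_class = n_per_class, seed = seed, ecg = ecg,
                 voice = voice, video = video, n_folds = n_folds),
            class = "synth_config")
}

gauss_bump <- function(n, center, sd, amp) {
  i <- seq_len(n)
  amp * exp(-0.5 * ((i - center) / sd)^2)
}

#' Generate a synthetic ECG record with known R positions
#'
#' Beats are a parametric template (Gaussian R wave flanked by smaller P
#' and T bumps) placed at intervals drawn from the class heart-rate range
#' with Gaussian beat-to-beat jitter, plus white noise at the configured
#' SNR and a faint mains hum. Beats are confined to the interior so at
#' least 2 s of context exists around the relocatable peaks.
#'
#' @param cfg A [synth_config()] (its `$ecg` part is used).
#' @param label Stage label: calm, control or experimental.
#' @param seed Seed.
#' @param rr_sd_ms Optional jitter override (e.g. for estimator benchmarks).
#' @param hr_bpm Optional heart-rate-range override.
#' @return List with `record` (`ecg_record`) and `truth`
#'   (`r_peaks` sample indices, `rr_ms` per-interval truth, `hr_bpm`).
#' @export
gen_ecg <- function(cfg, label, seed = 1, rr_sd_ms = NULL, hr_bpm = NULL) {
  e <- cfg$ecg
  fs <- e$fs
  n <- round(e$duration_s * fs)
  jitter_ms <- if (is.null(rr_sd_ms)) e$rr_sd_ms[[label]] else rr_sd_ms
  hr_range <- if (is.null(hr_bpm)) e$hr_bpm[[label]] else hr_bpm
  with_seed(derive_seed(seed, paste0("ecg_", label)), {
    hr <- runif(1, hr_range[1], hr_range[2])
    base_rr <- 60 / hr * fs
    # place beats from 0.25 s onward; relocation context handled downstream
    pos <- 0.25 * fs
    peaks <- numeric(0)
    while (pos < n - 0.25 * fs) {
      peaks <- c(peaks, pos)
      pos <- pos + base_rr + rnorm(1, 0, jitter_ms / 1000 * fs)
    }
    peaks <- round(peaks)
    x <- numeric(n)
    for (p in peaks) {
      x <- x + gauss_bump(n, p, 0.012 * fs, 1.0)            # R wave
      x <- x + gauss_bump(n, p - 0.17 * fs, 0.025 * fs, 0.15)  # P wave
      x <- x + gauss_bump(n, p + 0.28 * fs, 0.055 * fs, 0.3)   # T wave
    }
    sig_rms <- sqrt(mean(x^2))
    noise_sd <- sig_rms / 10^(e$noise_snr_db / 20)
    x <- x + rnorm(n, 0, noise_sd)
    if (e$hum_amp > 0)
      x <- x + e$hum_amp * sin(2 * pi * 50 * seq_len(n) / fs)
    rr <- diff(peaks)
    list(record = ecg_record(x, fs, sprintf("synthecg_%s_%d", label, seed)),
         truth = list(r_peaks = peaks, rr_ms = rr / fs * 1000, hr_bpm = hr))
  })
}

#' Generate a synthetic voice clip
#'
#' A harmonic tone at the class fundamental with harmonic amplitudes
#' `1 / h^tilt` (smaller tilt = flatter spectrum = higher spectral
#' centroid, the stress signature), slow amplitude modulation, and white
#' noise at the configured SNR.
#'
#' @param cfg A [synth_config()].
#' @param label Stage label.
#' @param seed Seed.
#' @return List with `clip` (`audio_clip`) and `truth` (`f0`, `tilt`).
#' @export
gen_audio <- function(cfg, label, seed = 1) {
  v <- cfg$voice
  n <- round(v$duration_s * v$fs)
  t <- seq_len(n) / v$fs
  f0 <- v$f0_hz[[label]]
  tilt <- v$tilt[[label]]
  with_seed(derive_seed(seed, paste0("audio_", label)), {
    n_h <- min(12L, floor((v$fs / 2 - 100) / f0))
    x <- numeric(n)
    for (h in seq_len(n_h))
      x <- x + (1 / h^tilt) * sin(2 * pi * h * f0 * t + runif(1, 0, 2 * pi))
    x <- x * (1 + 0.3 * sin(2 * pi * 3 * t))       # syllabic-rate modulation
    sig_rms <- sqrt(mean(x^2))
    x <- x + rnorm(n, 0, sig_rms / 10^(v$noise_snr_db / 20))
    x <- 0.8 * x / max(abs(x))
    list(clip = audio_clip(x, v$fs, sprintf("synthvoice_%s_%d", label, seed)),
         truth = list(f0 = f0, tilt = tilt, n_harmonics = n_h))
  })
}

#' Generate a synthetic face video with stub-detector ground truth
#'
#' Frames hold a textured square "face" patch on a smooth background; a
#' sub-pattern inside the patch (the mouth region) oscillates sinusoidally
#' at the class frequency and amplitude. The exact per-frame box is
#' emitted for the stub detector.
#'
#' @param cfg A [synth_config()].
#' @param label Stage label.
#' @param seed Seed.
#' @return List with `clip` (`video_clip`), `boxes` (n_frames x 4 matrix:
#'   top, left, height, width) and `truth` (`osc_hz`, `osc_amp`).
#' @export
gen_video <- function(cfg, label, seed = 1) {
  vd <- cfg$video
  H <- vd$frame_h; W <- vd$frame_w; B <- vd$box
  f <- vd$osc_hz[[label]]; amp <- vd$osc_amp[[label]]
  with_seed(derive_seed(seed, paste0("video_", label)), {
    top <- round(runif(1, 2, H - B - 1))
    left <- round(runif(1, 2, W - B - 1))
    bg <- outer(seq_len(H) / H, seq_len(W) / W, function(a, b) 0.2 + 0.1 * a * b)
    texture <- matrix(runif(B * B, 0.3, 0.7), B, B)
    mouth_rows <- round(0.60 * B):round(0.85 * B)
    mouth_cols <- round(0.25 * B):round(0.75 * B)
    frames <- vector("list", vd$n_frames)
    for (k in seq_len(vd$n_frames)) {
      face <- texture
      osc <- amp * sin(2 * pi * f * (k - 1) / vd$fps)
      face[mouth_rows, mouth_cols] <- pmin(pmax(
        face[mouth_rows, mouth_cols] + osc, 0), 1)
      fr <- bg
      fr[top + seq_len(B) - 1, left + seq_len(B) - 1] <- face
      frames[[k]] <- array(rep(fr, 3), c(H, W, 3))
    }
    boxes <- matrix(rep(c(top, left, B, B), each = vd$n_frames), ncol = 4)
    colnames(boxes) <- c("top", "left", "height", "width")
    list(clip = video_clip(frames, vd$fps,
                           sprintf("synthface_%s_%d", label, seed)),
         boxes = boxes,
         truth = list(osc_hz = f, osc_amp = amp, box = c(top, left, B, B)))
  })
}

# deterministic stratified fold assignment: shuffle within class, round-robin
fold_assign <- function(labels, k, seed) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- with_seed(derive_seed(seed, paste0("fold_", cl)), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Generate a full synthetic multimodal dataset
#'
#' Writes per-sample files (ECG CSV, WAV audio, PNG frame directory plus
#' stub-detector boxes), a `manifest.csv` with labels, file paths and a
#' precomputed stratified fold assignment, and a `truth.json` with the
#' generator ground truth.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly; `truth` attached as an
#'   attribute.
#' @export
gen_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truths <- list()
  i <- 0L
  for (label in stage_levels()) {
    for (j in seq_len(cfg$n_per_class)) {
      i <- i + 1L
      sid <- sprintf("s%03d_%s", i, label)
      seed_i <- derive_seed(cfg$seed, sid)
      ec <- gen_ecg(cfg, label, seed_i)
      au <- gen_audio(cfg, label, seed_i)
      vi <- gen_video(cfg, label, seed_i)
      ecg_path <- file.path(dir, paste0(sid, "_ecg.csv"))
      wav_path <- file.path(dir, paste0(sid, ".wav"))
      vid_dir <- file.path(dir, paste0(sid, "_frames"))
      write_ecg_csv(ec$record, ecg_path)
      write_wav(au$clip, wav_path)
      write_frame_dir(vi$clip, vid_dir)
      write.csv(as.data.frame(vi$boxes),
                file.path(dir, paste0(sid, "_boxes.csv")), row.names = FALSE)
      rows[[i]] <- data.frame(sample_id = sid, label = label,
                              ecg = basename(ecg_path),
                              audio = basename(wav_path),
                              video = basename(vid_dir),
                              boxes = paste0(sid, "_boxes.csv"))
      truths[[sid]] <- list(label = label, seed = seed_i,
                            r_peaks = ec$truth$r_peaks,
                            rr_ms = ec$truth$rr_ms, hr_bpm = ec$truth$hr_bpm,
                            f0 = au$truth$f0,
                            osc_hz = vi$truth$osc_hz)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$fold <- fold_assign(manifest$label,
                               min(cfg$n_folds, cfg$n_per_class), cfg$seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_json(truths, file.path(dir, "truth.json"))
  attr(manifest, "truth") <- truths
  invisible(manifest)
}
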