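# File I/O for the toolkit's exchange formats: single-column ECG CSV,
# RIFF/WAVE audio, PNG frame directories and JSON metadata.

#' Read an ECG record from CSV
#'
#' Expects a single column of samples; the sampling rate is taken from the
#' header name `samples_fs<hz>` written by [write_ecg_csv()] or passed
#' explicitly via `fs`.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; overrides any rate encoded in the header.
#' @param sample_id Identifier attached to the record.
#' @return An `ecg_record`.
#' @export
read_ecg_csv <- function(path, fs = NULL, sample_id = basename(path)) {
  d <- read.csv(path)
  if (is.null(fs)) {
    m <- regmatches(names(d)[1], regexec("fs([0-9]+)$", names(d)[1]))[[1]]
    sf_assert(length(m) == 2L, "invalid_config",
              "no sampling rate in header of %s; pass fs=", path)
    fs <- as.numeric(m[2])
  }
  ecg_record(d[[1]], fs = fs, sample_id = sample_id)
}

#' Write an ECG record to CSV
#'
#' @param record An `ecg_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  d <- data.frame(x = record$samples)
  names(d) <- sprintf("samples_fs%d", as.integer(record$fs))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports PCM 8/16/32-bit and IEEE float, taking the first channel of
#' multi-channel files. Samples are returned in [-1, 1].
#'
#' @param path WAV file path.
#' @param sample_id Identifier attached to the clip.
#' @return An `audio_clip`.
#' @export
read_wav <- function(path, sample_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  sf_assert(identical(riff, "RIFF"), "invalid_config", "%s is not RIFF", path)
  readBin(con, "integer", 1, 4, endian = "little")
  sf_assert(identical(readChar(con, 4, useBytes = TRUE), "WAVE"),
            "invalid_config", "%s is not WAVE", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        fs           = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  sf_assert(!is.null(fmt) && !is.null(data_raw), "invalid_config",
            "missing fmt/data chunk in %s", path)
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32767
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4, 4, endian = "little") / 2147483648
  } else if (fmt$bits == 8L) {
    (as.integer(data_raw) - 128) / 128
  } else sf_stop("invalid_config", "unsupported WAV bit depth %d", fmt$bits)
  if (fmt$channels > 1L) x <- x[seq(1, length(x), by = fmt$channels)]
  audio_clip(x, fs = fmt$fs, sample_id = sample_id)
}

#' Write a mono PCM16 WAV file
#'
#' @param clip An `audio_clip`; samples are clamped to [-1, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(clip$fs), con, 4, endian = "little")
  writeBin(as.integer(clip$fs) * 2L, con, 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")             # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Write an intensity image to PNG
#'
#' @param img Matrix (grayscale) or [H, W, 3] array with values in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a PNG image
#'
#' @param path PNG file path.
#' @return Matrix or array with values in [0, 1].
#' @export
read_image_png <- function(path) png::readPNG(path)

#' Read a directory of ordered frames as a video clip
#'
#' Frames are read in lexicographic filename order.
#'
#' @param dir Directory containing PNG frames.
#' @param fps Frame rate in Hz.
#' @param sample_id Identifier attached to the clip.
#' @return A `video_clip`.
#' @export
read_frame_dir <- function(dir, fps = 30, sample_id = basename(dir)) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  sf_assert(length(files) >= 1L, "degenerate_input", "no frames in %s", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  video_clip(frames, fps = fps, sample_id = sample_id)
}

#' Write a video clip as a directory of PNG frames
#'
#' @param clip A `video_clip`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_dir <- function(clip, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clip$frames)) {
    png::writePNG(pmin(pmax(clip$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  invisible(dir)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
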