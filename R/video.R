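# Face clip extraction: per-frame detection through a pluggable detector
# interface, similarity-transform alignment, fixed-length clip sampling and
# geometrically coherent train/eval augmentation.

#' Construct a video clip
#'
#' @param frames List of `[H, W, 3]` arrays with values in [0, 1]; all
#'   frames must share dimensions.
#' @param fps Frame rate in Hz.
#' @param sample_id Opaque identifier.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, fps = 30, sample_id = "video") {
  sf_assert(length(frames) >= 1L, "degenerate_input", "need at least 1 frame")
  d1 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  sf_assert(all(ok), "invalid_config", "all frames must share dimensions")
  structure(list(frames = frames, fps = fps, sample_id = sample_id),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_clip %s: %d frames of %dx%d @ %g fps>\n",
              x$sample_id, length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' Stub face detector for synthetic data
#'
#' Implements the detector contract — `detector(frame, index)` returning
#' `list(box = c(top, left, height, width), landmarks = list(left_eye,
#' right_eye))` or `NULL` — from known per-frame boxes, e.g. the ground
#' truth emitted by [gen_video()]. Landmarks default to canonical eye
#' positions inside the box.
#'
#' @param boxes Matrix with one row per frame: columns top, left, height,
#'   width (1-based pixel coordinates). Rows of `NA` simulate missed
#'   detections.
#' @return A detector function.
#' @export
stub_face_detector <- function(boxes) {
  boxes <- as.matrix(boxes)
  function(frame, index) {
    if (index > nrow(boxes) || anyNA(boxes[index, ])) return(NULL)
    b <- as.numeric(boxes[index, ])
    list(
      box = b,
      landmarks = list(
        left_eye  = c(b[1] + 0.35 * b[3], b[2] + 0.30 * b[4]),
        right_eye = c(b[1] + 0.35 * b[3], b[2] + 0.70 * b[4])
      )
    )
  }
}

#' Adapt an external face detector
#'
#' Wraps any `function(frame)` returning a box (and optionally landmarks)
#' into the per-frame detector contract used by [extract_faces()].
#'
#' @param fn External detection function.
#' @return A detector function `(frame, index)`.
#' @export
external_face_detector <- function(fn) {
  function(frame, index) fn(frame)
}

# Similarity transform mapping two source points onto two destination
# points; returns function(dst_r, dst_c) -> list(r, c) in source coords.
similarity_from_eyes <- function(src_l, src_r, dst_l, dst_r) {
  sv <- complex(real = src_r[2] - src_l[2], imaginary = src_r[1] - src_l[1])
  dv <- complex(real = dst_r[2] - dst_l[2], imaginary = dst_r[1] - dst_l[1])
  a <- sv / dv   # dst -> src rotation+scale
  s0 <- complex(real = src_l[2], imaginary = src_l[1])
  d0 <- complex(real = dst_l[2], imaginary = dst_l[1])
  function(r, c) {
    z <- (complex(real = c, imaginary = r) - d0) * a + s0
    list(r = Im(z), c = Re(z))
  }
}

crop_box <- function(frame, box, out_size) {
  rows <- seq(box[1], box[1] + box[3] - 1)
  cols <- seq(box[2], box[2] + box[4] - 1)
  rows <- pmin(pmax(round(rows), 1), dim(frame)[1])
  cols <- pmin(pmax(round(cols), 1), dim(frame)[2])
  crop <- frame[rows, cols, , drop = FALSE]
  if (dim(crop)[1] == out_size && dim(crop)[2] == out_size) crop
  else resize_mat(crop, out_size, out_size)
}

warp_to_template <- function(frame, landmarks, out_size) {
  # canonical eye template inside the output crop
  dst_l <- c(0.40 * out_size, 0.32 * out_size)
  dst_r <- c(0.40 * out_size, 0.68 * out_size)
  tr <- similarity_from_eyes(landmarks$left_eye, landmarks$right_eye,
                             dst_l, dst_r)
  grid <- expand.grid(r = seq_len(out_size), c = seq_len(out_size))
  src <- tr(grid$r, grid$c)
  out <- array(0, c(out_size, out_size, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(frame[, , ch], src$r, src$c),
                          out_size, out_size)
  out
}

#' Extract aligned face crops from a video clip
#'
#' Runs the detector on every frame. With landmarks a 2-point similarity
#' transform aligns the eyes to a canonical template; without landmarks the
#' detection box is cropped and resized. Frames with no detection reuse the
#' nearest detected frame's geometry, so the output always has one crop per
#' input frame.
#'
#' @param clip A `video_clip`.
#' @param detector A detector function (see [stub_face_detector()]).
#' @param out_size Output crop edge in pixels (default 224).
#' @param align Use landmark alignment when landmarks are available.
#' @return A `face_sequence`: list with `faces` (list of
#'   `[out_size, out_size, 3]` arrays), `out_size`, `fps`, `sample_id`.
#' @export
extract_faces <- function(clip, detector, out_size = 224, align = TRUE) {
  n <- length(clip$frames)
  dets <- lapply(seq_len(n), function(i) detector(clip$frames[[i]], i))
  have <- which(!vapply(dets, is.null, logical(1)))
  sf_assert(length(have) >= 1L, "no_face_found", "no face detected in any frame")
  faces <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dets[[if (i %in% have) i else have[which.min(abs(have - i))]]]
    faces[[i]] <- if (align && !is.null(d$landmarks))
      warp_to_template(clip$frames[[i]], d$landmarks, out_size)
    else crop_box(clip$frames[[i]], d$box, out_size)
  }
  structure(list(faces = faces, out_size = out_size, fps = clip$fps,
                 sample_id = clip$sample_id),
            class = "face_sequence")
}

face_clip_from <- function(faces, idx, seq_obj) {
  structure(list(faces = faces[idx], out_size = seq_obj$out_size,
                 t = length(idx), sample_id = seq_obj$sample_id),
            class = "face_clip")
}

#' Sample a training clip of T frames
#'
#' A contiguous window of `t` frames at a seeded-random valid offset;
#' sequences shorter than `t` are looped cyclically.
#'
#' @param faces A `face_sequence`.
#' @param t Clip length (default 64 frames).
#' @param seed Seed for the random offset.
#' @return A `face_clip` of exactly `t` frames.
#' @export
sample_training_clip <- function(faces, t = 64, seed = 1) {
  n <- length(faces$faces)
  sf_assert(n >= 1L, "degenerate_input", "empty face sequence")
  idx <- if (n >= t) {
    off <- with_seed(derive_seed(seed, "clip_offset"),
                     sample.int(n - t + 1L, 1L)) - 1L
    off + seq_len(t)
  } else {
    ((seq_len(t) - 1L) %% n) + 1L
  }
  face_clip_from(faces$faces, idx, faces)
}

#' Sample the central evaluation clip of T frames
#'
#' Deterministic: the central contiguous window (start offset
#' `floor((n - t) / 2)`); short sequences are looped cyclically.
#'
#' @param faces A `face_sequence`.
#' @param t Clip length (default 64 frames).
#' @return A `face_clip` of exactly `t` frames.
#' @export
sample_eval_clip <- function(faces, t = 64) {
  n <- length(faces$faces)
  sf_assert(n >= 1L, "degenerate_input", "empty face sequence")
  idx <- if (n >= t) floor((n - t) / 2) + seq_len(t)
  else ((seq_len(t) - 1L) %% n) + 1L
  face_clip_from(faces$faces, idx, faces)
}

#' Geometric train/eval augmentation of a face clip
#'
#' Train mode rescales every frame to `size x round(size * 270 / 224)`,
#' takes one seeded random `size x size` crop shared by all frames, and
#' flips all frames horizontally with probability 0.5. Eval mode uses the
#' deterministic center crop and never flips. The crop window is identical
#' across frames (temporal coherence).
#'
#' @param clip A `face_clip`.
#' @param mode `"train"` or `"eval"`.
#' @param seed Seed for crop offset and flip (train mode).
#' @param size Output spatial edge (default 224).
#' @return The augmented `face_clip` with `size x size` frames.
#' @export
geometric_augment <- function(clip, mode = c("train", "eval"), seed = 1,
                              size = 224) {
  mode <- match.arg(mode)
  wide <- round(size * 270 / 224)
  max_off <- wide - size
  if (mode == "train") {
    rnd <- with_seed(derive_seed(seed, "augment"),
                     c(sample.int(max_off + 1L, 1L) - 1L, runif(1)))
    off <- rnd[1]
    flip <- rnd[2] < 0.5
  } else {
    off <- floor(max_off / 2)
    flip <- FALSE
  }
  cols <- off + seq_len(size)
  faces <- lapply(clip$faces, function(f) {
    g <- resize_mat(f, size, wide)[, cols, , drop = FALSE]
    if (flip) g <- g[, rev(seq_len(size)), , drop = FALSE]
    g
  })
  structure(list(faces = faces, out_size = size, t = length(faces),
                 sample_id = clip$sample_id),
            class = "face_clip")
}

#' Convert a face clip to the network input tensor
#'
#' @param clip A `face_clip`.
#' @param size Optional spatial resize applied per frame.
#' @return Array `[size, size, 3, T]`.
#' @export
face_clip_tensor <- function(clip, size = NULL) {
  fr <- clip$faces
  if (!is.null(size) && size != dim(fr[[1]])[1])
    fr <- lapply(fr, resize_mat, height = size, width = size)
  d <- dim(fr[[1]])
  out <- array(0, c(d[1], d[2], 3, length(fr)))
  for (i in seq_along(fr)) out[, , , i] <- fr[[i]]
  out
}
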