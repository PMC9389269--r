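# Face-frame extraction, clip sampling and geometric augmentation.

make_face_video <- function(n_frames = 10, H = 40, W = 60, box = c(11, 21, 16, 16)) {
  frames <- lapply(seq_len(n_frames), function(k) {
    f <- array(0.1, c(H, W, 3))
    f[box[1]:(box[1] + box[3] - 1), box[2]:(box[2] + box[4] - 1), ] <-
      k / (n_frames + 1)   # distinct constant per frame
    f
  })
  video_clip(frames, fps = 30)
}

test_that("stub detector round-trip crops exactly the known region", {
  box <- c(11, 21, 16, 16)
  vc <- make_face_video(box = box)
  boxes <- matrix(rep(box, each = 10), ncol = 4)
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 16,
                      align = FALSE)
  expect_equal(length(fs$faces), 10L)
  for (k in c(1, 5, 10))
    expect_equal(fs$faces[[k]],
                 vc$frames[[k]][11:26, 21:36, , drop = FALSE],
                 ignore_attr = TRUE)
})

test_that("identical boxes on a static video give pixelwise equal crops", {
  vc <- video_clip(rep(list(array(with_seed(3, runif(40 * 60 * 3)),
                                  c(40, 60, 3))), 6), fps = 30)
  boxes <- matrix(rep(c(5, 7, 20, 20), each = 6), ncol = 4)
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 24)
  for (k in 2:6) expect_identical(fs$faces[[k]], fs$faces[[1]])
})

test_that("missing detections are filled from the nearest detected frame", {
  vc <- make_face_video(n_frames = 10)
  boxes <- matrix(rep(c(11, 21, 16, 16), each = 10), ncol = 4)
  boxes[4, ] <- NA  # 10% missing
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 16)
  expect_equal(length(fs$faces), 10L)
  all_na <- matrix(NA_real_, 10, 4)
  expect_error(extract_faces(vc, stub_face_detector(all_na)),
               class = "stressfuse_no_face_found")
})

test_that("training clip sampling respects offsets and the loop rule", {
  vc <- make_face_video(n_frames = 100)
  boxes <- matrix(rep(c(11, 21, 16, 16), each = 100), ncol = 4)
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 16)
  for (s in 1:10) {
    clip <- sample_training_clip(fs, t = 64, seed = s)
    expect_equal(length(clip$faces), 64L)
    first_val <- clip$faces[[1]][8, 8, 1]   # interior face pixel
    offset <- which(vapply(fs$faces, function(f) f[8, 8, 1],
                           numeric(1)) == first_val)[1] - 1
    expect_true(offset >= 0 && offset <= 36)
  }
  # exact-length sequence: identity
  fs64 <- extract_faces(make_face_video(64),
                        stub_face_detector(matrix(rep(c(11, 21, 16, 16),
                                                      each = 64), ncol = 4)),
                        out_size = 16)
  expect_identical(sample_training_clip(fs64, 64, seed = 1)$faces, fs64$faces)
  # short sequence loops cyclically
  fs40 <- extract_faces(make_face_video(40),
                        stub_face_detector(matrix(rep(c(11, 21, 16, 16),
                                                      each = 40), ncol = 4)),
                        out_size = 16)
  clip40 <- sample_training_clip(fs40, 64, seed = 1)
  expect_equal(length(clip40$faces), 64L)
  expect_identical(clip40$faces[[41]], fs40$faces[[1]])
  expect_identical(clip40$faces[[64]], fs40$faces[[24]])
})

test_that("eval clip is the deterministic central window", {
  vc <- make_face_video(n_frames = 100)
  boxes <- matrix(rep(c(11, 21, 16, 16), each = 100), ncol = 4)
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 16)
  clip <- sample_eval_clip(fs, 64)
  expect_identical(clip$faces, fs$faces[19:82])   # offset floor((100-64)/2)=18
  expect_identical(sample_eval_clip(fs, 64)$faces, clip$faces)
})

test_that("geometric augmentation is coherent across frames and seeded", {
  vc <- make_face_video(n_frames = 8)
  boxes <- matrix(rep(c(11, 21, 16, 16), each = 8), ncol = 4)
  fs <- extract_faces(vc, stub_face_detector(boxes), out_size = 64)
  clip <- sample_eval_clip(fs, 8)
  ev1 <- geometric_augment(clip, "eval")
  ev2 <- geometric_augment(clip, "eval")
  expect_identical(ev1$faces, ev2$faces)
  expect_equal(dim(ev1$faces[[1]]), c(224, 224, 3))
  tr1 <- geometric_augment(clip, "train", seed = 5)
  tr2 <- geometric_augment(clip, "train", seed = 5)
  expect_identical(tr1$faces, tr2$faces)
  expect_equal(dim(tr1$faces[[1]]), c(224, 224, 3))
  # temporal coherence: per-frame constant patches stay constant per frame,
  # so the crop window was shared across frames
  sds <- vapply(tr1$faces, function(f) sd(f[100:120, 100:120, 1]), numeric(1))
  expect_true(all(sds < 1e-6))
})

test_that("the stub-detector path is bit-deterministic under a fixed seed", {
  g <- gen_video(synth_config(), "experimental", seed = 9)
  run <- function() {
    fs <- extract_faces(g$clip, stub_face_detector(g$boxes), out_size = 42)
    face_clip_tensor(geometric_augment(sample_training_clip(fs, 64, seed = 4),
                                       "train", seed = 4, size = 32))
  }
  expect_identical(run(), run())
})
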