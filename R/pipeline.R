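# Evaluation harness: stratified k-fold plans with an inner 80/20
# train/validation split, binary calm/stress metrics, and the end-to-end
# orchestration from raw synthetic files to fused per-fold metrics.

#' Build a stratified k-fold cross-validation plan
#'
#' Folds partition the samples with per-fold class balance within one
#' sample; within the non-test portion of each fold, 80% of the data goes
#' to training and 20% to validation (stratified, seeded).
#'
#' @param manifest Data frame with a `label` column, or a vector of labels.
#' @param k Number of folds (default 10).
#' @param seed Seed.
#' @param val_frac Validation fraction of the non-test portion.
#' @return A `fold_plan`: list with `k`, `seed` and `folds`, each fold
#'   holding disjoint `train`, `val`, `test` index sets.
#' @export
make_folds <- function(manifest, k = 10, seed = 1, val_frac = 0.2) {
  labels <- if (is.data.frame(manifest)) manifest$label else as.character(manifest)
  n <- length(labels)
  counts <- table(labels)
  sf_assert(all(counts >= k), "invalid_config",
            "need at least k = %d samples per class (min is %d)", k, min(counts))
  fold_of <- fold_assign(labels, k, seed)
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    rest <- which(fold_of != f)
    val <- unlist(lapply(unique(labels), function(cl) {
      cl_idx <- rest[labels[rest] == cl]
      nv <- max(1L, round(val_frac * length(cl_idx)))
      with_seed(derive_seed(seed, paste0("val", f, cl)), sample(cl_idx, nv))
    }))
    list(train = sort(setdiff(rest, val)), val = sort(val), test = sort(test))
  })
  structure(list(k = k, seed = seed, n = n, folds = folds, fold_of = fold_of),
            class = "fold_plan")
}

#' Binary calm/stress detection metrics
#'
#' Standard binary metrics with stress as the positive class, plus the raw
#' 2x2 confusion matrix (rows = actual, columns = predicted) and its
#' column-normalized form (each predicted-label column sums to 1).
#'
#' @param decisions Character vector of predictions over calm/stress.
#' @param labels Character vector of true labels, same length.
#' @return A `metrics_report`: `accuracy`, `precision`, `recall`, `f1`,
#'   `confusion` (counts), `confusion_colnorm`, `n`.
#' @export
evaluate <- function(decisions, labels) {
  sf_assert(length(decisions) == length(labels), "invalid_config",
            "decisions and labels must have equal length")
  lv <- c("calm", "stress")
  conf <- table(factor(labels, lv), factor(decisions, lv))
  conf <- matrix(as.numeric(conf), 2, 2,
                 dimnames = list(actual = lv, predicted = lv))
  metrics_from_confusion(conf)
}

#' Recompute metrics from a stored confusion matrix
#'
#' @param conf 2x2 counts matrix, rows actual (calm, stress), columns
#'   predicted (calm, stress).
#' @return A `metrics_report` (see [evaluate()]).
#' @export
metrics_from_confusion <- function(conf) {
  tp <- conf["stress", "stress"]; tn <- conf["calm", "calm"]
  fp <- conf["calm", "stress"]; fn <- conf["stress", "calm"]
  n <- sum(conf)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  colnorm <- sweep(conf, 2, pmax(colSums(conf), 1), "/")
  structure(list(accuracy = (tp + tn) / n, precision = prec, recall = rec,
                 f1 = f1, confusion = conf, confusion_colnorm = colnorm,
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  (n=%d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$n))
  invisible(x)
}

#' End-to-end run configuration
#'
#' Desk-scale defaults: tiny backbones on 32x32 inputs, 64-frame face
#' clips, 3 folds, and short Adam schedules sized so a full run finishes in
#' minutes on one CPU.
#'
#' @param data_dir Directory holding a [gen_dataset()] output.
#' @param seed Master seed.
#' @param k Number of cross-validation folds.
#' @param input_size Spatial edge of the classifier inputs.
#' @param t_frames Face-clip length.
#' @param image_train,video_train [train_config()]s for the 2D and video
#'   nets.
#' @return An `e2e_config` list.
#' @export
e2e_config <- function(data_dir, seed = 1, k = 3, input_size = 32,
                       t_frames = 64,
                       image_train = train_config(lr = 1e-3, batch_size = 8,
                                                  epochs = 30, seed = seed),
                       video_train = train_config(lr = 0.01, batch_size = 2,
                                                  epochs = 15, seed = seed)) {
  structure(list(data_dir = data_dir, seed = seed, k = k,
                 input_size = input_size, t_frames = t_frames,
                 image_train = image_train, video_train = video_train),
            class = "e2e_config")
}

# Per-sample standardization: centering the input puts the first ReLU near
# its kink, without which the all-positive pixel range leaves the network in
# a nearly linear regime where global pooling averages the signal away.
standardize_input <- function(x) {
  s <- sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

image_to_input <- function(img, size) {
  small <- resize_mat(img, size, size)
  standardize_input(array(rep(small, 3), c(size, size, 3)))
}

# Preprocess every sample of a dataset directory into classifier inputs.
preprocess_dataset <- function(config) {
  manifest <- read.csv(file.path(config$data_dir, "manifest.csv"))
  n <- nrow(manifest)
  ecg_x <- vector("list", n); voice_x <- vector("list", n)
  faces <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- read_ecg_csv(file.path(config$data_dir, manifest$ecg[i]),
                        sample_id = manifest$sample_id[i])
    ecg_x[[i]] <- image_to_input(preprocess_ecg(rec)$image, config$input_size)
    clip <- read_wav(file.path(config$data_dir, manifest$audio[i]),
                     sample_id = manifest$sample_id[i])
    voice_x[[i]] <- image_to_input(preprocess_voice(clip)$image,
                                   config$input_size)
    vid <- read_frame_dir(file.path(config$data_dir, manifest$video[i]),
                          sample_id = manifest$sample_id[i])
    boxes <- read.csv(file.path(config$data_dir, manifest$boxes[i]))
    faces[[i]] <- extract_faces(vid, stub_face_detector(boxes),
                                out_size = round(config$input_size * 270 / 224) + 4)
  }
  list(manifest = manifest, ecg_x = ecg_x, voice_x = voice_x, faces = faces)
}

face_input <- function(face_seq, config, mode, seed) {
  clip <- if (mode == "train") sample_training_clip(face_seq, config$t_frames, seed)
  else sample_eval_clip(face_seq, config$t_frames)
  clip <- geometric_augment(clip, mode, seed = seed, size = config$input_size)
  standardize_input(face_clip_tensor(clip))
}

#' Run the full multimodal pipeline end to end
#'
#' Preprocesses every sample, trains the three tiny modality classifiers
#' per fold, fuses the per-sample posteriors with the eigenvector rule,
#' and reports pooled and per-fold calm/stress metrics. The returned
#' `report` component is fully deterministic under the config seed; wall
#' -clock timings live in the separate `timing` component.
#'
#' @param config An [e2e_config()].
#' @param out_dir Optional directory for `report.json` / `report.md`.
#' @param verbose Print progress.
#' @return List with `report` (metrics, per-sample decisions, fold plan,
#'   config echo) and `timing` (seconds per stage: preprocessing,
#'   feature_extraction, fusion).
#' @export
run_end_to_end <- function(config, out_dir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  prep <- preprocess_dataset(config)
  manifest <- prep$manifest
  labels3 <- manifest$label
  labels2 <- collapse_binary(labels3)
  t_prep <- proc.time()[["elapsed"]] - t0

  plan <- make_folds(manifest, k = config$k, seed = config$seed)
  n <- nrow(manifest)
  pred <- list(ecg = character(n), voice = character(n), face = character(n),
               fused = character(n))
  post <- list(ecg = vector("list", n), voice = vector("list", n),
               face = vector("list", n))
  t_feat <- 0; t_fuse <- 0
  fold_rows <- list()

  for (f in seq_len(config$k)) {
    fold <- plan$folds[[f]]
    tr_idx <- c(fold$train, fold$val)  # train_modality re-splits 80/20 itself
    tf0 <- proc.time()[["elapsed"]]
    seed_f <- derive_seed(config$seed, paste0("fold", f))

    img_cfg <- backbone_config("tiny", input_size = config$input_size)
    vid_cfg <- backbone_config("tiny", input_size = config$input_size,
                               t_frames = config$t_frames)
    itc <- config$image_train; itc$seed <- derive_seed(seed_f, "imgtrain")

    ecg_fit <- train_modality(
      build_image_net(img_cfg, seed = derive_seed(seed_f, "ecgnet")),
      list(x = prep$ecg_x[tr_idx], y = labels3[tr_idx]), itc)
    voice_fit <- train_modality(
      build_image_net(img_cfg, seed = derive_seed(seed_f, "voicenet")),
      list(x = prep$voice_x[tr_idx], y = labels3[tr_idx]), itc)
    face_train_x <- lapply(tr_idx, function(i)
      face_input(prep$faces[[i]], config, "train",
                 derive_seed(seed_f, paste0("clip", i))))
    vtc2 <- config$video_train; vtc2$seed <- derive_seed(seed_f, "vidtrain")
    face_fit <- train_modality(
      build_video_net(vid_cfg, seed = derive_seed(seed_f, "facenet")),
      list(x = face_train_x, y = labels3[tr_idx]), vtc2)
    t_feat <- t_feat + proc.time()[["elapsed"]] - tf0

    for (i in fold$test) {
      tf1 <- proc.time()[["elapsed"]]
      p_ecg <- predict_posteriors(ecg_fit$model, prep$ecg_x[[i]])
      p_voice <- predict_posteriors(voice_fit$model, prep$voice_x[[i]])
      p_face <- predict_posteriors(face_fit$model,
                                   face_input(prep$faces[[i]], config, "eval", 0))
      t_feat <- t_feat + proc.time()[["elapsed"]] - tf1
      tf2 <- proc.time()[["elapsed"]]
      fr <- fuse(p_voice, p_face, p_ecg)
      t_fuse <- t_fuse + proc.time()[["elapsed"]] - tf2
      post$ecg[[i]] <- p_ecg; post$voice[[i]] <- p_voice; post$face[[i]] <- p_face
      pred$ecg[i] <- posterior_binary(p_ecg)
      pred$voice[i] <- posterior_binary(p_voice)
      pred$face[i] <- posterior_binary(p_face)
      pred$fused[i] <- fr$binary
    }
    fold_rows[[f]] <- data.frame(
      fold = f,
      ecg = evaluate(pred$ecg[fold$test], labels2[fold$test])$accuracy,
      voice = evaluate(pred$voice[fold$test], labels2[fold$test])$accuracy,
      face = evaluate(pred$face[fold$test], labels2[fold$test])$accuracy,
      fused = evaluate(pred$fused[fold$test], labels2[fold$test])$accuracy)
    if (verbose)
      message(sprintf("fold %d/%d done (fused acc %.3f)", f, config$k,
                      fold_rows[[f]]$fused))
  }

  pooled <- lapply(pred, evaluate, labels = labels2)
  per_fold <- do.call(rbind, fold_rows)
  report <- list(
    pooled = pooled,
    per_fold = per_fold,
    fold_means = colMeans(per_fold[, -1, drop = FALSE]),
    decisions = data.frame(sample_id = manifest$sample_id, label = labels2,
                           ecg = pred$ecg, voice = pred$voice,
                           face = pred$face, fused = pred$fused),
    plan = plan,
    config = list(seed = config$seed, k = config$k,
                  input_size = config$input_size,
                  t_frames = config$t_frames, n = n)
  )
  timing <- list(preprocessing = t_prep, feature_extraction = t_feat,
                 fusion = t_fuse)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json(report_to_json(report), file.path(out_dir, "report.json"))
    writeLines(report_to_md(report, timing), file.path(out_dir, "report.md"))
  }
  list(report = report, timing = timing)
}

report_to_json <- function(report) {
  list(
    pooled = lapply(report$pooled, function(m)
      list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
           f1 = m$f1, confusion = as.data.frame(as.table(m$confusion)),
           confusion_colnorm = as.data.frame(as.table(m$confusion_colnorm)))),
    per_fold = report$per_fold,
    fold_means = as.list(report$fold_means),
    decisions = report$decisions,
    config = report$config
  )
}

report_to_md <- function(report, timing) {
  m <- report$pooled
  c("# Multimodal stress detection report",
    "",
    sprintf("Samples: %d, folds: %d, seed: %d", report$config$n,
            report$config$k, report$config$seed),
    "",
    "| modality | accuracy | precision | recall | F1 |",
    "|---|---|---|---|---|",
    vapply(names(m), function(nm)
      sprintf("| %s | %.3f | %.3f | %.3f | %.3f |", nm, m[[nm]]$accuracy,
              m[[nm]]$precision, m[[nm]]$recall, m[[nm]]$f1), character(1)),
    "",
    sprintf("Timing (s): preprocessing %.1f, feature extraction %.1f, fusion %.2f",
            timing$preprocessing, timing$feature_extraction, timing$fusion))
}
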