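# Classifier backbones: a residual 2D network for the ECG-trace and
# Mel-spectrogram images and a TAM-augmented inflated-3D (inception)
# network for face clips, each ending in a 3-stage softmax head.
# The `tiny` variants train in minutes on one CPU; the `full` variants
# follow the published 50-layer bottleneck / inception-v1 layouts.

#' Backbone configuration
#'
#' @param variant `"tiny"` (default; desk-scale) or `"full"`.
#' @param n_classes Number of output stages (default 3: calm, control,
#'   experimental).
#' @param tam_r TAM reduction ratio (video net).
#' @param input_size Spatial input edge expected by the tiny variants.
#' @param t_frames Temporal length expected by the video net input.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(variant = c("tiny", "full"), n_classes = 3,
                            tam_r = 4, input_size = if (variant[1] == "tiny") 32 else 224,
                            t_frames = 64) {
  variant <- match.arg(variant)
  structure(list(variant = variant, n_classes = n_classes, tam_r = tam_r,
                 input_size = input_size, t_frames = t_frames),
            class = "backbone_config")
}

conv_node <- function(name, k, cin, cout, stride = c(1L, 1L, 1L), pad = "same") {
  list(type = "conv", name = name, k = as.integer(k), cin = cin, cout = cout,
       stride = as.integer(stride), pad = pad)
}

res_block <- function(name, cin, cout, bottleneck = FALSE, stride = 1L) {
  body <- if (bottleneck) {
    mid <- cout %/% 4
    list(conv_node(paste0(name, ".c1"), c(1, 1, 1), cin, mid,
                   stride = c(stride, stride, 1L)),
         list(type = "relu", name = paste0(name, ".r1")),
         conv_node(paste0(name, ".c2"), c(3, 3, 1), mid, mid),
         list(type = "relu", name = paste0(name, ".r2")),
         conv_node(paste0(name, ".c3"), c(1, 1, 1), mid, cout))
  } else {
    list(conv_node(paste0(name, ".c1"), c(3, 3, 1), cin, cout,
                   stride = c(stride, stride, 1L)),
         list(type = "relu", name = paste0(name, ".r1")),
         conv_node(paste0(name, ".c2"), c(3, 3, 1), cout, cout))
  }
  proj <- if (cin != cout || stride != 1L)
    conv_node(paste0(name, ".proj"), c(1, 1, 1), cin, cout,
              stride = c(stride, stride, 1L))
  list(type = "residual", name = name, body = body, proj = proj)
}

incep_block <- function(name, cin, widths) {
  # widths: list(b1 = n, b3 = c(reduce, out), [b5 = c(reduce, out), pool = n])
  branches <- list(
    list(conv_node(paste0(name, ".b1"), c(1, 1, 1), cin, widths$b1)),
    list(conv_node(paste0(name, ".b3r"), c(1, 1, 1), cin, widths$b3[1]),
         list(type = "relu", name = paste0(name, ".b3rr")),
         conv_node(paste0(name, ".b3"), c(3, 3, 3), widths$b3[1], widths$b3[2]))
  )
  if (!is.null(widths$b5)) {
    branches <- c(branches, list(list(
      conv_node(paste0(name, ".b5r"), c(1, 1, 1), cin, widths$b5[1]),
      list(type = "relu", name = paste0(name, ".b5rr")),
      conv_node(paste0(name, ".b5"), c(3, 3, 3), widths$b5[1], widths$b5[2])
    )))
  }
  if (!is.null(widths$pool)) {
    branches <- c(branches, list(list(
      conv_node(paste0(name, ".poolproj"), c(1, 1, 1), cin, widths$pool)
    )))
  }
  list(type = "inception", name = name, branches = branches)
}

image_net_layout <- function(config) {
  if (config$variant == "tiny") {
    list(
      conv_node("stem", c(3, 3, 1), 3, 8),
      list(type = "relu", name = "stem.relu"),
      list(type = "avgpool", name = "pool1", f = c(2L, 2L, 1L)),
      res_block("res1", 8, 8),
      list(type = "relu", name = "res1.out"),
      list(type = "avgpool", name = "pool2", f = c(2L, 2L, 1L)),
      res_block("res2", 8, 16),
      list(type = "relu", name = "res2.out"),
      list(type = "gap", name = "gap"),
      list(type = "dense", name = "fc", din = 16, dout = config$n_classes)
    )
  } else {
    # 50-layer bottleneck configuration: stages of 3, 4, 6, 3 blocks
    widths <- c(256, 512, 1024, 2048)
    counts <- c(3, 4, 6, 3)
    nodes <- list(
      conv_node("stem", c(7, 7, 1), 3, 64, stride = c(2L, 2L, 1L)),
      list(type = "relu", name = "stem.relu"),
      list(type = "maxpool", name = "pool1", f = c(2L, 2L, 1L))
    )
    cin <- 64
    for (s in 1:4) for (b in seq_len(counts[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      nodes <- c(nodes, list(res_block(sprintf("s%d.b%d", s, b), cin,
                                       widths[s], bottleneck = TRUE,
                                       stride = stride),
                             list(type = "relu",
                                  name = sprintf("s%d.b%d.out", s, b))))
      cin <- widths[s]
    }
    c(nodes, list(list(type = "gap", name = "gap"),
                  list(type = "dense", name = "fc", din = 2048,
                       dout = config$n_classes)))
  }
}

video_net_layout <- function(config, tam = TRUE) {
  if (config$variant == "tiny") {
    t_in <- config$t_frames
    t_tam <- t_in %/% 8L   # stem pool /4, then /2
    nodes <- list(
      list(type = "avgpool", name = "stem.pool", f = c(2L, 2L, 4L)),
      conv_node("stem.conv", c(3, 3, 3), 3, 8),
      list(type = "relu", name = "stem.relu"),
      list(type = "avgpool", name = "pool1", f = c(2L, 2L, 2L))
    )
    if (tam) {
      hidden <- max(1L, as.integer(round(t_tam / config$tam_r)))
      nodes <- c(nodes, list(list(type = "tam", name = "tam", t = t_tam,
                                  hidden = hidden)))
    }
    c(nodes, list(
      incep_block("incep1", 8, list(b1 = 4, b3 = c(4, 8))),
      list(type = "relu", name = "incep1.out"),
      incep_block("incep2", 12, list(b1 = 6, b3 = c(6, 10))),
      list(type = "relu", name = "incep2.out"),
      list(type = "gap", name = "gap"),
      list(type = "dense", name = "fc", din = 16, dout = config$n_classes)
    ))
  } else {
    # inflated inception-v1: stem + 9 inception blocks (3a-3b, 4a-4e, 5a-5b)
    iw <- list(
      `3a` = list(b1 = 64,  b3 = c(96, 128),  b5 = c(16, 32),  pool = 32),
      `3b` = list(b1 = 128, b3 = c(128, 192), b5 = c(32, 96),  pool = 64),
      `4a` = list(b1 = 192, b3 = c(96, 208),  b5 = c(16, 48),  pool = 64),
      `4b` = list(b1 = 160, b3 = c(112, 224), b5 = c(24, 64),  pool = 64),
      `4c` = list(b1 = 128, b3 = c(128, 256), b5 = c(24, 64),  pool = 64),
      `4d` = list(b1 = 112, b3 = c(144, 288), b5 = c(32, 64),  pool = 64),
      `4e` = list(b1 = 256, b3 = c(160, 320), b5 = c(32, 128), pool = 128),
      `5a` = list(b1 = 256, b3 = c(160, 320), b5 = c(32, 128), pool = 128),
      `5b` = list(b1 = 384, b3 = c(192, 384), b5 = c(48, 128), pool = 128)
    )
    nodes <- list(
      conv_node("stem.conv1", c(7, 7, 7), 3, 64, stride = c(2L, 2L, 2L)),
      list(type = "relu", name = "stem.relu1"),
      list(type = "maxpool", name = "stem.pool1", f = c(2L, 2L, 1L)),
      conv_node("stem.conv2", c(1, 1, 1), 64, 64),
      list(type = "relu", name = "stem.relu2"),
      conv_node("stem.conv3", c(3, 3, 3), 64, 192),
      list(type = "relu", name = "stem.relu3"),
      list(type = "maxpool", name = "stem.pool2", f = c(2L, 2L, 1L))
    )
    if (tam) {
      t_tam <- config$t_frames %/% 2L
      hidden <- max(1L, as.integer(round(t_tam / config$tam_r)))
      nodes <- c(nodes, list(list(type = "tam", name = "tam", t = t_tam,
                                  hidden = hidden)))
    }
    cin <- 192
    pool_after <- c(`3b` = TRUE, `4e` = TRUE)
    for (nm in names(iw)) {
      nodes <- c(nodes, list(incep_block(paste0("incep", nm), cin, iw[[nm]]),
                             list(type = "relu", name = paste0("incep", nm, ".out"))))
      cin <- iw[[nm]]$b1 + iw[[nm]]$b3[2] +
        (if (!is.null(iw[[nm]]$b5)) iw[[nm]]$b5[2] else 0) +
        (if (!is.null(iw[[nm]]$pool)) iw[[nm]]$pool else 0)
      if (isTRUE(pool_after[nm]))
        nodes <- c(nodes, list(list(type = "maxpool", name = paste0("pool", nm),
                                    f = c(2L, 2L, 2L))))
    }
    c(nodes, list(list(type = "gap", name = "gap"),
                  list(type = "dense", name = "fc", din = 1024,
                       dout = config$n_classes)))
  }
}

build_net <- function(nodes, config, seed, kind) {
  params <- lapply(nodes, node_init, seed = seed)
  structure(list(nodes = nodes, params = params, config = config,
                 kind = kind, seed = seed),
            class = "stress_net")
}

#' Build the residual 2D image classifier
#'
#' Maps a `[H, W, 3]` image (ECG trace or Mel spectrogram) to a 3-stage
#' posterior. The `tiny` variant is the desk-scale default; the `full`
#' variant instantiates the published 50-layer bottleneck layout
#' (3 + 4 + 6 + 3 blocks).
#'
#' @param config A [backbone_config()].
#' @param seed Initialization seed (uniform random weights).
#' @return A `stress_net`.
#' @export
build_image_net <- function(config = backbone_config(), seed = 1) {
  build_net(image_net_layout(config), config, seed, "image")
}

#' Build the TAM-augmented inflated-3D video classifier
#'
#' Maps a `[H, W, 3, T]` face clip to a 3-stage posterior. The TAM is
#' inserted after the first convolution-and-pooling stage, before the first
#' inception block; `tam = FALSE` removes only the TAM (ablation contract:
#' every other node keeps its name, shape, and seeded initial weights).
#'
#' @param config A [backbone_config()].
#' @param tam Include the temporal attention module?
#' @param seed Initialization seed.
#' @return A `stress_net`.
#' @export
build_video_net <- function(config = backbone_config(), tam = TRUE, seed = 1) {
  build_net(video_net_layout(config, tam = tam), config, seed, "video")
}

#' Count trainable parameters of a network
#'
#' @param model A `stress_net`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) n_params(model$params)

#' @export
print.stress_net <- function(x, ...) {
  cat(sprintf("<stress_net %s/%s: %d top-level nodes, %d parameters>\n",
              x$kind, x$config$variant, length(x$nodes), count_params(x)))
  invisible(x)
}

#' Predict a 3-stage posterior
#'
#' Runs the forward pass and applies softmax to the final fully connected
#' layer; the result lies on the probability simplex.
#'
#' @param model A `stress_net`.
#' @param input `[H, W, 3]` image (image net) or `[H, W, 3, T]` clip
#'   (video net).
#' @return Named numeric vector `(calm, control, experimental)` of class
#'   `posterior_vector`.
#' @export
predict_posteriors <- function(model, input) {
  x <- input
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  sf_assert(length(dim(x)) == 4L, "invalid_config",
            "input must be [H, W, C] or [H, W, C, T]")
  p <- softmax(net_forward(model, x)$logits)
  posterior_vector(p)
}

#' Construct a simplex-valid posterior vector
#'
#' @param p Numeric vector of 3 probabilities (calm, control, experimental).
#' @return Named `posterior_vector`.
#' @export
posterior_vector <- function(p) {
  sf_assert(is_simplex(p), "invalid_posterior",
            "posterior must be 3 probabilities summing to 1")
  structure(setNames(as.numeric(p), stage_levels()), class = "posterior_vector")
}

#' Training configuration
#'
#' Defaults mirror the modality settings used at full scale: Adam with
#' learning rate 1e-4, batch size 32 and 80 epochs for the 2D nets, and
#' learning rate 0.01 with single-clip batches and 30 epochs for the video
#' net (see [train_defaults()]).
#'
#' @param lr Learning rate (> 0 or 0 for a frozen run).
#' @param batch_size Gradient-accumulation batch size.
#' @param epochs Number of passes over the training split.
#' @param seed Master seed for the split, shuffling and any augmentation.
#' @param val_frac Fraction of the data held out for validation (default
#'   0.2, i.e. the 80/20 split).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 32, epochs = 80, seed = 1,
                         val_frac = 0.2) {
  sf_assert(lr >= 0, "invalid_config", "learning rate must be nonnegative")
  structure(list(optimizer = "adam", lr = lr, batch_size = batch_size,
                 epochs = epochs, seed = seed, val_frac = val_frac),
            class = "train_config")
}

#' Per-modality default training configurations
#'
#' @param modality One of `"ecg"`, `"voice"`, `"face"`.
#' @param seed Master seed.
#' @return A [train_config()].
#' @export
train_defaults <- function(modality = c("ecg", "voice", "face"), seed = 1) {
  modality <- match.arg(modality)
  if (modality == "face") train_config(lr = 0.01, batch_size = 1, epochs = 30,
                                       seed = seed)
  else train_config(lr = 1e-4, batch_size = 32, epochs = 80, seed = seed)
}

#' Train a modality classifier
#'
#' Seeded Adam training with an internal 80/20 train/validation split;
#' returns the weights with the best validation accuracy. Optional
#' augmentation is applied to training samples only.
#'
#' @param model A `stress_net`.
#' @param dataset List with `x` (list of input arrays) and `y` (integer
#'   stage labels in 1..3 or stage names).
#' @param cfg A [train_config()].
#' @param augment_fn Optional `function(x, seed)` applied to each training
#'   sample each epoch (never to validation samples).
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best-validation weights), `history`
#'   (data.frame epoch/train_loss/val_acc) and `best_val_acc`.
#' @export
train_modality <- function(model, dataset, cfg = train_config(),
                           augment_fn = NULL, verbose = FALSE) {
  y <- dataset$y
  if (is.character(y) || is.factor(y)) y <- match(as.character(y), stage_levels())
  y <- as.integer(y)
  n <- length(dataset$x)
  sf_assert(n == length(y) && n >= 2L, "invalid_config",
            "dataset must pair inputs with labels")
  sf_assert(length(unique(y)) >= 2L, "degenerate_dataset",
            "training requires at least two classes")
  # 80/20 split, stratified per class so validation sees every class
  idx_val <- with_seed(derive_seed(cfg$seed, "split"), {
    unlist(lapply(unique(y), function(cl) {
      cl_idx <- which(y == cl)
      nv <- max(1L, round(cfg$val_frac * length(cl_idx)))
      sample(cl_idx, nv)
    }))
  })
  idx_tr <- setdiff(seq_len(n), idx_val)
  sf_assert(length(idx_tr) >= 1L, "degenerate_dataset", "empty training split")

  theta <- flatten_tree(model$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(acc = -1, theta = theta)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_acc = numeric())

  val_accuracy <- function() {
    correct <- 0L
    for (i in idx_val) {
      x <- dataset$x[[i]]
      if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
      p <- softmax(net_forward(model, x)$logits)
      if (which.max(p) == y[i]) correct <- correct + 1L
    }
    correct / length(idx_val)
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                     sample(idx_tr))
    losses <- numeric(0)
    batch_grad <- NULL; batch_n <- 0L
    for (i in ord) {
      x <- dataset$x[[i]]
      if (!is.null(augment_fn))
        x <- augment_fn(x, derive_seed(cfg$seed, paste0("aug", epoch, "_", i)))
      if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
      lg <- net_loss_grad(model, x, y[i])
      losses <- c(losses, lg$loss)
      g <- flatten_tree(lg$grads)
      batch_grad <- if (is.null(batch_grad)) g else batch_grad + g
      batch_n <- batch_n + 1L
      if (batch_n >= cfg$batch_size || i == ord[length(ord)]) {
        g <- batch_grad / batch_n
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        theta <- theta - cfg$lr * mhat / (sqrt(vhat) + eps)
        model$params <- unflatten_tree(theta, model$params)$value
        batch_grad <- NULL; batch_n <- 0L
      }
    }
    acc <- val_accuracy()
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_acc = acc))
    if (acc > best$acc) best <- list(acc = acc, theta = theta)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val_acc %.3f", epoch,
                      mean(losses), acc))
  }
  model$params <- unflatten_tree(best$theta, model$params)$value
  list(model = model, history = hist, best_val_acc = best$acc)
}

#' Save / load a trained network
#'
#' Weights and layout round-trip through R's native serialization.
#'
#' @param model A `stress_net`.
#' @param path File path.
#' @return `path` ([save_model()]) or the restored `stress_net`
#'   ([load_model()]).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
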