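# TAM algebra, backbone construction, posterior contracts and training.

test_that("TAM squeeze equals the per-frame mean over C, H, W", {
  u <- array(0, c(4, 1, 1, 1)); u[, 1, 1, 1] <- 1:4
  expect_equal(tam_squeeze(u), c(1, 2, 3, 4))
  u2 <- array(0, c(3, 2, 2, 2))
  for (t in 1:3) u2[t, , , ] <- t * 0.5
  expect_equal(tam_squeeze(u2), c(0.5, 1.0, 1.5))
  u3 <- with_seed(2, array(rnorm(5 * 3 * 4 * 4), c(5, 3, 4, 4)))
  brute <- vapply(1:5, function(t) {
    s <- 0
    for (i in 1:3) for (j in 1:4) for (k in 1:4) s <- s + u3[t, i, j, k]
    s / (3 * 4 * 4)
  }, numeric(1))
  expect_equal(tam_squeeze(u3), brute, tolerance = 1e-12)
})

test_that("TAM excite is the printed gate with sigmoid range", {
  p0 <- tam_params(6, r = 3)             # zero weights
  expect_equal(tam_excite(rnorm(6), p0), rep(0.5, 6))
  ps <- tam_params(6, r = 3, seed = 4)
  s <- tam_excite(with_seed(5, rnorm(6)), ps)
  expect_true(all(s > 0 & s < 1))
  expect_error(tam_excite(rnorm(5), ps), class = "stressfuse_invalid_config")
})

test_that("TAM composition matches the dense brute-force oracle", {
  for (trial in 1:10) {
    u <- with_seed(trial, array(rnorm(8 * 4 * 6 * 6), c(8, 4, 6, 6)))
    ps <- tam_params(8, r = 4, seed = trial + 100)
    got <- tam_apply(u, ps)
    want <- tam_brute(u, ps$W1, ps$W2)
    expect_equal(got$z, want$z, tolerance = 1e-6)
    expect_equal(got$attention, want$S, tolerance = 1e-6)
    expect_equal(got$output, want$out, tolerance = 1e-6)
    # contraction: |output| <= |input| elementwise since S < 1
    expect_true(all(abs(got$output) <= abs(u) + 1e-12))
  }
  # zero-weight case scales every frame by exactly one half
  u <- array(0, c(4, 1, 1, 1)); u[, 1, 1, 1] <- 1:4
  out <- tam_apply(u, tam_params(4, r = 4))
  expect_equal(out$attention, rep(0.5, 4))
  expect_equal(as.numeric(out$output[, 1, 1, 1]), c(0.5, 1.0, 1.5, 2.0))
})

test_that("built networks emit simplex posteriors deterministically", {
  img_net <- build_image_net(backbone_config("tiny"), seed = 3)
  x <- with_seed(4, array(rnorm(32 * 32 * 3), c(32, 32, 3)))
  p <- predict_posteriors(img_net, x)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  expect_identical(p, predict_posteriors(img_net, x))

  vid_net <- build_video_net(backbone_config("tiny", t_frames = 16), seed = 3)
  xv <- with_seed(5, array(rnorm(16 * 16 * 3 * 16), c(16, 16, 3, 16)))
  pv <- predict_posteriors(vid_net, xv)
  expect_equal(sum(pv), 1, tolerance = 1e-6)
})

test_that("posterior contracts: symmetry and saturation of the softmax head", {
  sf <- asNamespace("stressfuse")
  expect_equal(sf$softmax(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(sf$softmax(c(50, -50, -50))[1], 1, tolerance = 1e-12)
})

test_that("a zeroed residual body propagates the input exactly", {
  sf <- asNamespace("stressfuse")
  node <- sf$res_block("rb", 4, 4)
  params <- sf$node_init(node, seed = 1)
  for (i in seq_along(params$body))
    params$body[[i]] <- lapply(params$body[[i]], function(w) w * 0)
  x <- with_seed(6, array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  out <- sf$node_forward(node, params, x)$y
  expect_equal(out, x)
})

test_that("full variants match the published layer layouts", {
  sf <- asNamespace("stressfuse")
  full_img <- sf$image_net_layout(backbone_config("full"))
  res_blocks <- Filter(function(n) n$type == "residual", full_img)
  expect_equal(length(res_blocks), 3 + 4 + 6 + 3)
  # every block is a bottleneck: three convolutions in the body
  expect_true(all(vapply(res_blocks, function(b)
    sum(vapply(b$body, function(x) x$type == "conv", logical(1))) == 3,
    logical(1))))
  # 16 blocks x 3 convs + stem conv + fc = 50 weighted layers
  body_convs <- sum(vapply(res_blocks, function(b)
    sum(vapply(b$body, function(x) x$type == "conv", logical(1))),
    numeric(1)))
  expect_equal(body_convs + 2, 50)

  full_vid <- sf$video_net_layout(backbone_config("full"))
  incep <- Filter(function(n) n$type == "inception", full_vid)
  expect_equal(length(incep), 9)
  expect_true(all(vapply(incep, function(b) length(b$branches) == 4,
                         logical(1))))
})

test_that("removing the TAM changes nothing but the TAM parameters", {
  cfg <- backbone_config("tiny", t_frames = 64)
  on <- build_video_net(cfg, tam = TRUE, seed = 7)
  off <- build_video_net(cfg, tam = FALSE, seed = 7)
  t_tam <- 8; hidden <- 2
  expect_equal(count_params(on) - count_params(off),
               hidden * t_tam + t_tam * hidden)
  names_on <- vapply(on$nodes, function(n) n$name, character(1))
  names_off <- vapply(off$nodes, function(n) n$name, character(1))
  expect_equal(setdiff(names_on, names_off), "tam")
  # shared nodes have value-identical initial weights under the common seed
  for (nm in names_off) {
    i_on <- which(names_on == nm); i_off <- which(names_off == nm)
    expect_identical(on$params[[i_on]], off$params[[i_off]])
  }
})

test_that("training separates two blob classes and honors lr = 0", {
  make_blob <- function(cl, s) with_seed(s, {
    img <- array(rnorm(16 * 16 * 3, 0, 0.1), c(16, 16, 3))
    if (cl == 1) img[4:8, 4:8, ] <- img[4:8, 4:8, ] + 1
    else img[10:14, 10:14, ] <- img[10:14, 10:14, ] + 1
    img
  })
  x <- c(lapply(1:20, function(i) make_blob(1, i)),
         lapply(1:20, function(i) make_blob(2, 100 + i)))
  y <- rep(1:2, each = 20)
  cfg <- train_config(lr = 1e-3, batch_size = 8, epochs = 20, seed = 2)
  fit <- train_modality(build_image_net(backbone_config("tiny"), seed = 1),
                        list(x = x, y = y), cfg)
  expect_gte(fit$best_val_acc, 0.95)
  # determinism: identical loss curves under the same seed
  fit2 <- train_modality(build_image_net(backbone_config("tiny"), seed = 1),
                         list(x = x, y = y), cfg)
  expect_identical(fit$history, fit2$history)
  # lr = 0 leaves the weights untouched
  net0 <- build_image_net(backbone_config("tiny"), seed = 5)
  frozen <- train_modality(net0, list(x = x[1:8], y = y[c(1:4, 21:24)]),
                           train_config(lr = 0, batch_size = 4, epochs = 2,
                                        seed = 3))
  sf <- asNamespace("stressfuse")
  expect_identical(sf$flatten_tree(frozen$model$params),
                   sf$flatten_tree(net0$params))
  expect_error(train_modality(net0, list(x = x[1:4], y = rep(1L, 4)),
                              cfg),
               class = "stressfuse_degenerate_dataset")
})
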