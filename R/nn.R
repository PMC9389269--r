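# A compact, exact neural-network engine for the toolkit's classifiers.
# Tensors are arrays laid out [H, W, C, T]; 2D images are the T = 1 case so
# one convolution implementation (im2col + matrix product) serves both the
# residual 2D network and the inflated-3D video network. Everything is
# deterministic given the seeds, and gradients are analytic.

# ---- parameter trees -------------------------------------------------------

# Parameters are nested lists whose leaves are numeric arrays; flattening
# walks the tree in a fixed order so gradients and Adam state line up.
flatten_tree <- function(tree) {
  if (is.numeric(tree)) return(as.numeric(tree))
  if (is.list(tree)) return(unlist(lapply(tree, flatten_tree), use.names = FALSE))
  numeric(0)
}

unflatten_tree <- function(vec, template, pos = 1L) {
  if (is.numeric(template)) {
    n <- length(template)
    out <- vec[pos:(pos + n - 1L)]
    attributes(out) <- attributes(template)
    return(list(value = out, pos = pos + n))
  }
  if (is.list(template)) {
    res <- vector("list", length(template))
    names(res) <- names(template)
    for (i in seq_along(template)) {
      r <- unflatten_tree(vec, template[[i]], pos)
      res[[i]] <- r$value
      pos <- r$pos
    }
    return(list(value = res, pos = pos))
  }
  list(value = template, pos = pos)
}

n_params <- function(params) length(flatten_tree(params))

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# ---- convolution (3D, with 2D as kt = 1) -----------------------------------

pad_hwt <- function(x, ph, pw, pt) {
  if (ph == 0 && pw == 0 && pt == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3], d[4] + 2 * pt))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), , pt + seq_len(d[4])] <- x
  out
}

conv_fwd <- function(x, W, b, stride, pad) {
  k <- dim(W)   # kh, kw, kt, cin, cout
  xp <- pad_hwt(x, pad[1], pad[2], pad[3])
  d <- dim(xp)
  Ho <- (d[1] - k[1]) %/% stride[1] + 1L
  Wo <- (d[2] - k[2]) %/% stride[2] + 1L
  To <- (d[4] - k[3]) %/% stride[3] + 1L
  cin <- k[4]; cout <- k[5]
  X <- matrix(0, Ho * Wo * To, k[1] * k[2] * k[3] * cin)
  for (r in seq_len(k[3])) for (q in seq_len(k[2])) for (p in seq_len(k[1])) {
    slab <- xp[p + (seq_len(Ho) - 1L) * stride[1],
               q + (seq_len(Wo) - 1L) * stride[2], ,
               r + (seq_len(To) - 1L) * stride[3], drop = FALSE]
    slab <- aperm(slab, c(1, 2, 4, 3))           # H, W, T, C
    cols <- p + (q - 1L) * k[1] + (r - 1L) * k[1] * k[2] +
      (seq_len(cin) - 1L) * k[1] * k[2] * k[3]
    X[, cols] <- matrix(slab, Ho * Wo * To, cin)
  }
  Wm <- matrix(W, ncol = cout)
  Y <- X %*% Wm
  Y <- sweep(Y, 2, b, "+")
  y <- aperm(array(Y, c(Ho, Wo, To, cout)), c(1, 2, 4, 3))
  list(y = y, cache = list(X = X, xdim = dim(x), pdim = d, k = k,
                           stride = stride, pad = pad, out = c(Ho, Wo, To)))
}

conv_bwd <- function(dout, W, cache) {
  k <- cache$k; st <- cache$stride
  Ho <- cache$out[1]; Wo <- cache$out[2]; To <- cache$out[3]
  cout <- k[5]; cin <- k[4]
  dY <- matrix(aperm(dout, c(1, 2, 4, 3)), Ho * Wo * To, cout)
  dW <- array(crossprod(cache$X, dY), dim(W))
  db <- colSums(dY)
  dXc <- dY %*% t(matrix(W, ncol = cout))
  dxp <- array(0, cache$pdim)
  for (r in seq_len(k[3])) for (q in seq_len(k[2])) for (p in seq_len(k[1])) {
    cols <- p + (q - 1L) * k[1] + (r - 1L) * k[1] * k[2] +
      (seq_len(cin) - 1L) * k[1] * k[2] * k[3]
    slab <- aperm(array(dXc[, cols], c(Ho, Wo, To, cin)), c(1, 2, 4, 3))
    hi <- p + (seq_len(Ho) - 1L) * st[1]
    wi <- q + (seq_len(Wo) - 1L) * st[2]
    ti <- r + (seq_len(To) - 1L) * st[3]
    cur <- dxp[hi, wi, , ti, drop = FALSE]
    dim(slab) <- dim(cur)
    dxp[hi, wi, , ti] <- cur + slab
  }
  ph <- cache$pad[1]; pw <- cache$pad[2]; pt <- cache$pad[3]
  d0 <- cache$xdim
  dx <- dxp[ph + seq_len(d0[1]), pw + seq_len(d0[2]), , pt + seq_len(d0[4]),
            drop = FALSE]
  dim(dx) <- d0
  list(dx = dx, dW = dW, db = db)
}

# ---- pooling ---------------------------------------------------------------

avgpool_fwd <- function(x, f) {
  d <- dim(x)
  sf_assert(d[1] %% f[1] == 0 && d[2] %% f[2] == 0 && d[4] %% f[3] == 0,
            "invalid_config", "pooling factors must divide the input dims")
  Ho <- d[1] %/% f[1]; Wo <- d[2] %/% f[2]; To <- d[4] %/% f[3]
  acc <- array(0, c(Ho, Wo, d[3], To))
  for (r in seq_len(f[3])) for (q in seq_len(f[2])) for (p in seq_len(f[1])) {
    acc <- acc + x[p + (seq_len(Ho) - 1L) * f[1],
                   q + (seq_len(Wo) - 1L) * f[2], ,
                   r + (seq_len(To) - 1L) * f[3], drop = FALSE]
  }
  list(y = acc / prod(f), cache = list(f = f, xdim = d))
}

avgpool_bwd <- function(dout, cache) {
  f <- cache$f; d <- cache$xdim
  Ho <- d[1] %/% f[1]; Wo <- d[2] %/% f[2]; To <- d[4] %/% f[3]
  dx <- array(0, d)
  g <- dout / prod(f)
  for (r in seq_len(f[3])) for (q in seq_len(f[2])) for (p in seq_len(f[1])) {
    dx[p + (seq_len(Ho) - 1L) * f[1],
       q + (seq_len(Wo) - 1L) * f[2], ,
       r + (seq_len(To) - 1L) * f[3]] <- g
  }
  dx
}

maxpool_fwd <- function(x, f) {
  d <- dim(x)
  sf_assert(d[1] %% f[1] == 0 && d[2] %% f[2] == 0 && d[4] %% f[3] == 0,
            "invalid_config", "pooling factors must divide the input dims")
  Ho <- d[1] %/% f[1]; Wo <- d[2] %/% f[2]; To <- d[4] %/% f[3]
  cur <- array(-Inf, c(Ho, Wo, d[3], To))
  win <- array(0L, c(Ho, Wo, d[3], To))
  i <- 0L
  for (r in seq_len(f[3])) for (q in seq_len(f[2])) for (p in seq_len(f[1])) {
    i <- i + 1L
    slab <- x[p + (seq_len(Ho) - 1L) * f[1],
              q + (seq_len(Wo) - 1L) * f[2], ,
              r + (seq_len(To) - 1L) * f[3], drop = FALSE]
    dim(slab) <- dim(cur)
    m <- slab > cur
    cur[m] <- slab[m]
    win[m] <- i
  }
  list(y = cur, cache = list(f = f, xdim = d, win = win))
}

maxpool_bwd <- function(dout, cache) {
  f <- cache$f; d <- cache$xdim
  Ho <- d[1] %/% f[1]; Wo <- d[2] %/% f[2]; To <- d[4] %/% f[3]
  dx <- array(0, d)
  i <- 0L
  for (r in seq_len(f[3])) for (q in seq_len(f[2])) for (p in seq_len(f[1])) {
    i <- i + 1L
    mask <- cache$win == i
    g <- dout * mask
    dx[p + (seq_len(Ho) - 1L) * f[1],
       q + (seq_len(Wo) - 1L) * f[2], ,
       r + (seq_len(To) - 1L) * f[3]] <-
      dx[p + (seq_len(Ho) - 1L) * f[1],
         q + (seq_len(Wo) - 1L) * f[2], ,
         r + (seq_len(To) - 1L) * f[3], drop = FALSE] + g
  }
  dx
}

# ---- node dispatch ---------------------------------------------------------

same_pad <- function(node) {
  if (identical(node$pad, "same")) (node$k - 1L) %/% 2L else c(0L, 0L, 0L)
}

node_init <- function(node, seed) {
  with_seed(derive_seed(seed, node$name), {
    switch(node$type,
      conv = {
        k <- node$k
        fan_in <- prod(k) * node$cin
        fan_out <- prod(k) * node$cout
        list(W = glorot(c(k, node$cin, node$cout), fan_in, fan_out),
             b = numeric(node$cout))
      },
      dense = list(W = glorot(c(node$dout, node$din), node$din, node$dout),
                   b = numeric(node$dout)),
      tam = {
        h <- node$hidden
        list(W1 = glorot(c(h, node$t), node$t, h),
             W2 = glorot(c(node$t, h), h, node$t))
      },
      residual = {
        p <- list(body = lapply(node$body, node_init, seed = seed))
        if (!is.null(node$proj)) p$proj <- node_init(node$proj, seed)
        p
      },
      inception = list(branches = lapply(node$branches, function(br)
        lapply(br, node_init, seed = seed))),
      list()  # relu, avgpool, maxpool, gap: no parameters
    )
  })
}

node_forward <- function(node, params, x) {
  switch(node$type,
    conv = conv_fwd(x, params$W, params$b, node$stride, same_pad(node)),
    relu = list(y = pmax(x, 0), cache = x > 0),
    avgpool = avgpool_fwd(x, node$f),
    maxpool = maxpool_fwd(x, node$f),
    gap = {
      d <- dim(x)
      y <- apply(x, 3, mean)
      list(y = y, cache = d)
    },
    dense = list(y = as.numeric(params$W %*% x + params$b), cache = x),
    tam = {
      d <- dim(x)
      z <- apply(x, 4, mean)                       # length T
      a <- as.numeric(params$W1 %*% z)
      h <- pmax(a, 0)
      s <- 1 / (1 + exp(-as.numeric(params$W2 %*% h)))
      y <- x * rep(s, each = prod(d[1:3]))
      list(y = y, cache = list(x = x, z = z, a = a, h = h, s = s, d = d))
    },
    residual = {
      caches <- vector("list", length(node$body))
      h <- x
      for (i in seq_along(node$body)) {
        r <- node_forward(node$body[[i]], params$body[[i]], h)
        h <- r$y; caches[[i]] <- r$cache
      }
      if (!is.null(node$proj)) {
        rp <- node_forward(node$proj, params$proj, x)
        sc <- rp$y; pcache <- rp$cache
      } else {
        sc <- x; pcache <- NULL
      }
      # identity shortcut addition: y = F(x) + X (activations live inside
      # the body, so a zeroed body propagates the input exactly)
      list(y = h + sc, cache = list(body = caches, proj = pcache))
    },
    inception = {
      outs <- vector("list", length(node$branches))
      caches <- vector("list", length(node$branches))
      for (b in seq_along(node$branches)) {
        h <- x
        bc <- vector("list", length(node$branches[[b]]))
        for (i in seq_along(node$branches[[b]])) {
          r <- node_forward(node$branches[[b]][[i]], params$branches[[b]][[i]], h)
          h <- r$y; bc[[i]] <- r$cache
        }
        outs[[b]] <- h; caches[[b]] <- bc
      }
      widths <- vapply(outs, function(o) dim(o)[3], numeric(1))
      d1 <- dim(outs[[1]])
      y <- array(0, c(d1[1], d1[2], sum(widths), d1[4]))
      at <- 0L
      for (b in seq_along(outs)) {
        y[, , at + seq_len(widths[b]), ] <- outs[[b]]
        at <- at + widths[b]
      }
      list(y = y, cache = list(branches = caches, widths = widths))
    },
    sf_stop("invalid_config", "unknown node type %s", node$type)
  )
}

node_backward <- function(node, params, cache, dout) {
  switch(node$type,
    conv = {
      r <- conv_bwd(dout, params$W, cache)
      list(dx = r$dx, dparams = list(W = r$dW, b = r$db))
    },
    relu = list(dx = dout * cache, dparams = list()),
    avgpool = list(dx = avgpool_bwd(dout, cache), dparams = list()),
    maxpool = list(dx = maxpool_bwd(dout, cache), dparams = list()),
    gap = {
      d <- cache
      dx <- array(0, d)
      per <- dout / (d[1] * d[2] * d[4])
      for (ch in seq_along(per)) dx[, , ch, ] <- per[ch]
      list(dx = dx, dparams = list())
    },
    dense = list(dx = as.numeric(crossprod(params$W, dout)),
                 dparams = list(W = outer(dout, cache), b = dout)),
    tam = {
      ca <- cache; d <- ca$d
      spat <- prod(d[1:3])
      ds <- vapply(seq_len(d[4]), function(t)
        sum(dout[, , , t] * ca$x[, , , t]), numeric(1))
      dpre <- ds * ca$s * (1 - ca$s)
      dW2 <- outer(dpre, ca$h)
      dh <- as.numeric(crossprod(params$W2, dpre))
      da <- dh * (ca$a > 0)
      dW1 <- outer(da, ca$z)
      dz <- as.numeric(crossprod(params$W1, da))
      dx <- dout * rep(ca$s, each = spat) +
        array(rep(dz / spat, each = spat), d)
      list(dx = dx, dparams = list(W1 = dW1, W2 = dW2))
    },
    residual = {
      dsum <- dout
      dh <- dsum
      dbody <- vector("list", length(node$body))
      for (i in rev(seq_along(node$body))) {
        r <- node_backward(node$body[[i]], params$body[[i]], cache$body[[i]], dh)
        dh <- r$dx; dbody[[i]] <- r$dparams
      }
      dparams <- list(body = dbody)
      if (!is.null(node$proj)) {
        rp <- node_backward(node$proj, params$proj, cache$proj, dsum)
        dx <- dh + rp$dx
        dparams$proj <- rp$dparams
      } else {
        dx <- dh + dsum
      }
      list(dx = dx, dparams = dparams)
    },
    inception = {
      widths <- cache$widths
      at <- 0L
      dx <- NULL
      dbr <- vector("list", length(node$branches))
      for (b in seq_along(node$branches)) {
        dh <- dout[, , at + seq_len(widths[b]), , drop = FALSE]
        at <- at + widths[b]
        dlist <- vector("list", length(node$branches[[b]]))
        for (i in rev(seq_along(node$branches[[b]]))) {
          r <- node_backward(node$branches[[b]][[i]], params$branches[[b]][[i]],
                             cache$branches[[b]][[i]], dh)
          dh <- r$dx; dlist[[i]] <- r$dparams
        }
        dbr[[b]] <- dlist
        dx <- if (is.null(dx)) dh else dx + dh
      }
      list(dx = dx, dparams = list(branches = dbr))
    }
  )
}

# ---- model-level forward/backward ------------------------------------------

net_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$nodes)) else NULL
  h <- x
  for (i in seq_along(model$nodes)) {
    r <- node_forward(model$nodes[[i]], model$params[[i]], h)
    h <- r$y
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(logits = h, caches = caches)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Cross-entropy loss and full gradient tree for one sample.
net_loss_grad <- function(model, x, y_index) {
  fw <- net_forward(model, x, keep_cache = TRUE)
  p <- softmax(fw$logits)
  loss <- -log(max(p[y_index], 1e-12))
  dlogits <- p
  dlogits[y_index] <- dlogits[y_index] - 1
  dh <- dlogits
  grads <- vector("list", length(model$nodes))
  for (i in rev(seq_along(model$nodes))) {
    r <- node_backward(model$nodes[[i]], model$params[[i]], fw$caches[[i]], dh)
    dh <- r$dx
    grads[[i]] <- r$dparams
  }
  list(loss = loss, grads = grads, posterior = p)
}
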