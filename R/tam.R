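# Temporal Attention Module (TAM): a temporal squeeze-excitation block.
# Each frame's feature map is shrunk to a scalar by global average pooling,
# a two-layer gate produces per-frame attention in (0, 1), and the frames
# are rescaled by their attention values.

#' Construct TAM parameters
#'
#' Weight shapes follow the gate `S = sigmoid(W2 relu(W1 z))` with
#' `W1` of size `(T/r) x T` and `W2` of size `T x (T/r)`; when `T/r` is not
#' an integer the hidden size is `max(1, round(T/r))`.
#'
#' @param t Temporal length `T`.
#' @param r Reduction ratio (default 4).
#' @param seed Seed for uniform-random initialization; NULL leaves weights
#'   zero.
#' @return A `tam_params` list with `W1`, `W2`, `t`, `r`, `hidden`.
#' @export
tam_params <- function(t, r = 4, seed = NULL) {
  sf_assert(t >= 1 && r >= 1, "invalid_config", "need t >= 1 and r >= 1")
  hidden <- max(1L, as.integer(round(t / r)))
  if (is.null(seed)) {
    W1 <- matrix(0, hidden, t)
    W2 <- matrix(0, t, hidden)
  } else {
    W1 <- with_seed(derive_seed(seed, "tamW1"), glorot(c(hidden, t), t, hidden))
    W2 <- with_seed(derive_seed(seed, "tamW2"), glorot(c(t, hidden), hidden, t))
  }
  structure(list(W1 = W1, W2 = W2, t = as.integer(t), r = r, hidden = hidden),
            class = "tam_params")
}

#' TAM squeeze: per-frame global average
#'
#' Shrinks a `[T, C, H, W]` feature map to a length-`T` statistic, frame `t`
#' mapping to the arithmetic mean over its `C x H x W` values.
#'
#' @param u Numeric array `[T, C, H, W]`.
#' @return Numeric vector of length `T`.
#' @export
tam_squeeze <- function(u) {
  sf_assert(length(dim(u)) == 4L && all(dim(u) >= 1L), "invalid_config",
            "u must be a [T, C, H, W] array")
  apply(u, 1, mean)
}

#' TAM excite: gated attention map
#'
#' Computes `S = sigmoid(W2 relu(W1 z))`; every attention value is strictly
#' inside (0, 1).
#'
#' @param z Length-`T` squeeze statistic.
#' @param params A `tam_params`.
#' @return Numeric vector `S` of length `T` with values in (0, 1).
#' @export
tam_excite <- function(z, params) {
  sf_assert(length(z) == ncol(params$W1), "invalid_config",
            "z has length %d but W1 expects %d", length(z), ncol(params$W1))
  h <- pmax(as.numeric(params$W1 %*% z), 0)
  1 / (1 + exp(-as.numeric(params$W2 %*% h)))
}

#' TAM scale: rescale frames by their attention
#'
#' Frame `t` of the output is `S[t]` times frame `t` of `u`, elementwise.
#'
#' @param u Numeric array `[T, C, H, W]`.
#' @param s Attention vector of length `T`.
#' @return Array of the same shape as `u`.
#' @export
tam_scale <- function(u, s) {
  sf_assert(length(dim(u)) == 4L && dim(u)[1] == length(s), "invalid_config",
            "attention length %d does not match T = %d", length(s), dim(u)[1])
  u * as.numeric(s)   # T is the first axis, so recycling is per frame
}

#' Apply the full TAM to a feature map
#'
#' Composition of [tam_squeeze()], [tam_excite()] and [tam_scale()].
#'
#' @param u Numeric array `[T, C, H, W]`.
#' @param params A `tam_params`.
#' @return List with `output` (rescaled feature map), `attention` (S) and
#'   `z` (squeeze statistic).
#' @export
tam_apply <- function(u, params) {
  z <- tam_squeeze(u)
  s <- tam_excite(z, params)
  list(output = tam_scale(u, s), attention = s, z = z)
}
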