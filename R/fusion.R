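# Matrix-eigenvector late fusion: the three modality posteriors form the
# 3x3 stress information matrix (columns voice, face, ECG; rows calm,
# control, experimental); the Perron eigenvector of that column-stochastic
# matrix weights the stage rows, and the stage with the largest absolute
# weighted row sum is the decision.

#' Build the stress information matrix
#'
#' @param voice,face,ecg Simplex-valid 3-stage posteriors
#'   (calm, control, experimental), e.g. from [predict_posteriors()].
#' @return A 3x3 `stress_info_matrix`, columns ordered (voice, face, ecg),
#'   rows ordered (calm, control, experimental).
#' @export
build_matrix <- function(voice, face, ecg) {
  for (p in list(voice, face, ecg))
    sf_assert(is_simplex(p), "invalid_posterior",
              "each posterior must be 3 probabilities summing to 1")
  M <- cbind(voice = as.numeric(voice), face = as.numeric(face),
             ecg = as.numeric(ecg))
  rownames(M) <- stage_levels()
  structure(M, class = c("stress_info_matrix", "matrix", "array"))
}

# Power iteration from the uniform vector; used as the degenerate-case
# fallback (repeated eigenvalue) and by tests as an independent oracle.
power_iteration <- function(M, n_iter = 500, start = rep(1 / 3, 3)) {
  w <- start
  for (i in seq_len(n_iter)) {
    w2 <- as.numeric(M %*% w)
    s <- sum(abs(w2))
    if (s == 0) sf_stop("numeric", "power iteration collapsed to zero")
    w <- w2 / s
  }
  w
}

#' Principal-eigenvector fusion weights
#'
#' Returns the eigenvector of the largest-magnitude eigenvalue of the
#' stress information matrix, sign-fixed to the nonnegative orthant and
#' L1-normalized to sum 1. For a nonnegative column-stochastic matrix the
#' selected eigenvalue is 1 (Perron-Frobenius), so the weights are a fixed
#' point `M w = w`. A repeated leading eigenvalue falls back to power
#' iteration from the uniform vector, selecting the symmetric fixed point.
#'
#' @param M A 3x3 `stress_info_matrix` (nonnegative, column-stochastic).
#' @param tol Validation tolerance on nonnegativity/column sums.
#' @return A `fusion_weights` list: `w` (named length-3 weights),
#'   `eigenvalue`.
#' @export
principal_eigen_weights <- function(M, tol = 1e-6) {
  sf_assert(all(dim(M) == c(3L, 3L)), "invalid_config", "M must be 3x3")
  sf_assert(all(M >= -tol), "invalid_posterior", "M must be nonnegative")
  sf_assert(all(abs(colSums(M) - 1) <= tol), "invalid_posterior",
            "columns of M must sum to 1")
  eig <- eigen(M)
  mags <- Mod(eig$values)
  lead <- which.max(mags)
  # repeated leading eigenvalue: the eigenvector is not unique; take the
  # symmetric fixed point via power iteration from the uniform vector
  repeated <- sum(mags > mags[lead] - 1e-9) > 1L
  v <- eig$vectors[, lead]
  if (repeated || max(abs(Im(v))) > 1e-8) {
    w <- power_iteration(M)
  } else {
    w <- Re(v)
    if (sum(w) < 0) w <- -w
    sf_assert(all(w >= -1e-8), "numeric",
              "leading eigenvector has mixed signs; M is not a valid stress matrix")
    w <- pmax(w, 0)
    w <- w / sum(w)
  }
  structure(list(w = setNames(w, stage_levels()),
                 eigenvalue = Re(eig$values[lead])),
            class = "fusion_weights")
}

#' Weighted stress matrix
#'
#' Multiplies the diagonal weight matrix into the stress information
#' matrix: row i of the result is `w[i]` times row i of `M`.
#'
#' @param M A 3x3 `stress_info_matrix`.
#' @param w A `fusion_weights` (or numeric length-3 vector).
#' @return The 3x3 weighted matrix `W_global`.
#' @export
weighted_matrix <- function(M, w) {
  wv <- if (inherits(w, "fusion_weights")) w$w else as.numeric(w)
  sf_assert(length(wv) == 3L, "invalid_config", "need 3 weights")
  diag(as.numeric(wv)) %*% unclass(M)
}

#' Fusion decision from the weighted matrix
#'
#' Row scores are the row sums of `W_global`; the decision is the stage
#' with the largest absolute row score (ties broken toward the earlier
#' stage in calm, control, experimental order), and the binary label is
#' calm iff the decision is calm, else stress.
#'
#' @param Wg 3x3 weighted matrix from [weighted_matrix()].
#' @param weights Optional `fusion_weights` carried into the result.
#' @return A `fusion_result`: `row_scores`, `decision`, `binary`,
#'   `W_global`, `weights`.
#' @export
decide <- function(Wg, weights = NULL) {
  scores <- setNames(rowSums(Wg), stage_levels())
  dec <- stage_levels()[which.max(abs(scores))]  # which.max: first wins ties
  structure(list(W_global = Wg, row_scores = scores, decision = dec,
                 binary = collapse_binary(dec), weights = weights),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result: decision=%s binary=%s scores=[%s]>\n",
              x$decision, x$binary,
              paste(sprintf("%.4f", x$row_scores), collapse = ", ")))
  invisible(x)
}

#' Fuse three modality posteriors into a stress decision
#'
#' Composition of [build_matrix()], [principal_eigen_weights()],
#' [weighted_matrix()] and [decide()].
#'
#' @param voice,face,ecg 3-stage posteriors.
#' @return A `fusion_result`.
#' @export
fuse <- function(voice, face, ecg) {
  M <- build_matrix(voice, face, ecg)
  w <- principal_eigen_weights(M)
  decide(weighted_matrix(M, w), weights = w)
}

#' Collapse a 3-stage posterior to a binary prediction
#'
#' Argmax over the three stages followed by the calm/stress collapse
#' (control and experimental both count as stress) — the single-modality
#' analogue of the fused decision path.
#'
#' @param p A posterior vector.
#' @return `"calm"` or `"stress"`.
#' @export
posterior_binary <- function(p) {
  collapse_binary(stage_levels()[which.max(as.numeric(p))])
}
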