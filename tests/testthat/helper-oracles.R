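# Independent brute-force oracles used to check the package's vectorized /
# FFT / eigen implementations. Deliberately written as plain loops over
# definitions, sharing no code with the implementation.

# autocorrelation by direct summation over the definition
acf_brute <- function(x, max_lag, normalize = TRUE) {
  n <- length(x)
  ac <- vapply(0:max_lag, function(k) sum(x[1:(n - k)] * x[(1 + k):n]),
               numeric(1))
  if (normalize) ac / ac[1] else ac
}

# piecewise clipping by explicit elementwise branching
clip_brute <- function(x, alpha = 0.1, beta = -0.1) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- if (x[i] > alpha) x[i] - alpha
    else if (x[i] < beta) x[i] - beta
    else 0
  }
  out
}

# leading eigenpair of a 3x3 matrix via characteristic-polynomial roots and
# a nullspace solve (SVD), independent of base eigen()
eigen_brute <- function(M) {
  tr <- sum(diag(M))
  m2 <- (M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]) +
    (M[1, 1] * M[3, 3] - M[1, 3] * M[3, 1]) +
    (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2])
  dt <- det(M)
  roots <- polyroot(c(-dt, m2, -tr, 1))
  lam <- roots[which.max(Mod(roots))]
  sv <- svd(M - Re(lam) * diag(3))
  v <- sv$v[, 3]
  if (sum(v) < 0) v <- -v
  list(value = Re(lam), vector = v / sum(v))
}

power_iter_brute <- function(M, n_iter = 500) {
  w <- rep(1 / 3, 3)
  for (i in seq_len(n_iter)) {
    w <- as.numeric(M %*% w)
    w <- w / sum(abs(w))
  }
  w
}

# seeded random column-stochastic 3x3 matrix
random_stochastic <- function() {
  m <- matrix(runif(9), 3, 3)
  sweep(m, 2, colSums(m), "/")
}

# full fusion decision from the brute-force eigenpair
fuse_brute <- function(M) {
  w <- eigen_brute(M)$vector
  scores <- rowSums(diag(w) %*% M)
  c("calm", "control", "experimental")[which.max(abs(scores))]
}

# Mel band containing a pure tone, from the Mel-scale formula alone:
# the band whose triangular filter takes the largest value at f_hz
mel_band_brute <- function(f_hz, n_mels, fs) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(fs / 2), length.out = n_mels + 2))
  wts <- vapply(seq_len(n_mels), function(b) {
    lo <- pts[b]; ctr <- pts[b + 1]; hi <- pts[b + 2]
    max(0, min((f_hz - lo) / (ctr - lo), (hi - f_hz) / (hi - ctr)))
  }, numeric(1))
  which.max(wts)
}

# dense TAM composition by explicit loops over the printed equations
tam_brute <- function(u, W1, W2) {
  Tn <- dim(u)[1]; C <- dim(u)[2]; H <- dim(u)[3]; W <- dim(u)[4]
  z <- numeric(Tn)
  for (t in seq_len(Tn)) {
    s <- 0
    for (i in seq_len(C)) for (j in seq_len(H)) for (k in seq_len(W))
      s <- s + u[t, i, j, k]
    z[t] <- s / (C * H * W)
  }
  a <- as.numeric(W1 %*% z)
  a[a < 0] <- 0
  S <- 1 / (1 + exp(-as.numeric(W2 %*% a)))
  out <- u
  for (t in seq_len(Tn)) out[t, , , ] <- S[t] * u[t, , , ]
  list(z = z, S = S, out = out)
}

# synthetic ECG record with unit Gaussian R waves (QRS-like width ~4 ms)
peaks_record <- function(positions, n, fs = 2000, noise_sd = 0, seed = 1) {
  x <- numeric(n)
  i <- seq_len(n)
  for (p in positions) x <- x + exp(-0.5 * ((i - p) / (0.004 * fs))^2)
  if (noise_sd > 0) x <- x + stressfuse::with_seed(seed, rnorm(n, 0, noise_sd))
  stressfuse::ecg_record(x, fs)
}

rms_at_freq <- function(x, fs, f) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[1:(n %/% 2)]
  bin <- round(f * n / fs) + 1
  max(sp[max(1, bin - 2):(bin + 2)])
}
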