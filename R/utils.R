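#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif sd setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Classed conditions so callers can distinguish configuration errors from
# degenerate inputs programmatically.
sf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("stressfuse_", class), "stressfuse_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sf_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) sf_stop(class, msg, ...)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components do not perturb the global RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a label; keeps every stage's
# randomness independent but reproducible from one master seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Min-max scale to [0,1]; a constant input maps to all zeros.
minmax01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# Resize a [H, W] matrix (or [H, W, C] array, per channel) with bilinear
# interpolation.  EBImage stores images width-major, hence the transposes.
resize_mat <- function(img, height, width) {
  if (length(dim(img)) == 2L) {
    t(EBImage::resize(t(img), w = width, h = height, antialias = FALSE))
  } else {
    out <- array(0, c(height, width, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- t(EBImage::resize(t(img[, , ch]), w = width, h = height,
                                       antialias = FALSE))
    out
  }
}

# Bilinear lookup of (possibly fractional) row/col positions in a matrix.
# Positions outside the image clamp to the border.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(rows, 1), H)
  c <- pmin(pmax(cols, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

is_simplex <- function(p, tol = 1e-6) {
  is.numeric(p) && length(p) == 3L && all(is.finite(p)) &&
    all(p >= -tol) && all(p <= 1 + tol) && abs(sum(p) - 1) <= tol
}

stage_levels <- function() c("calm", "control", "experimental")

collapse_binary <- function(stage) ifelse(stage == "calm", "calm", "stress")
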