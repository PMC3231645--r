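# Internal plumbing shared across modules: reproducible RNG substreams,
# mirror-padded FFT convolution, small numeric helpers.

# Derive a 31-bit substream seed from a top-level seed and a stream index so
# that every stage (generator, weight init, shuffling) draws from its own
# deterministic stream.
derive_seed <- function(seed, stream) {
  seed <- as.double(seed %% 2147483647L)
  stream <- as.double(stream)
  as.integer((seed * 1009 + stream * 9176 + 12345) %% 2147483647)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Mirror (half-sample symmetric) padding of a matrix by `r` on every side.
mirror_pad <- function(x, r) {
  if (r == 0) return(x)
  n <- nrow(x); m <- ncol(x)
  if (r > n || r > m) stop("padding exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  x[ri, ci, drop = FALSE]
}

# FFTs of centered kernels are cached per (dimensions, kernel signature):
# convolution cost is then one forward and one inverse FFT per call.
.kernel_fft_cache <- new.env(parent = emptyenv())

kernel_fft <- function(kern, d) {
  key <- paste0(d[1], "x", d[2], ":", nrow(kern), ":",
                format(sum(kern), digits = 17), ":",
                format(kern[1, 1], digits = 17), ":",
                format(kern[(nrow(kern) + 1) %/% 2, (ncol(kern) + 1) %/% 2],
                       digits = 17))
  got <- .kernel_fft_cache[[key]]
  if (!is.null(got) && identical(attr(got, "kern"), kern)) return(got)
  kp <- matrix(0, d[1], d[2])
  r <- (nrow(kern) - 1L) %/% 2L
  kp[1:nrow(kern), 1:ncol(kern)] <- kern
  # shift so the kernel center sits at (1,1): circular convolution then
  # aligns with the unpadded image origin
  kp <- kp[c((r + 1):d[1], 1:r), c((r + 1):d[2], 1:r)]
  out <- stats::fft(kp)
  attr(out, "kern") <- kern
  .kernel_fft_cache[[key]] <- out
  out
}

# 2-D convolution with an odd-sided kernel and mirror boundary extension.
conv2_mirror <- function(x, kern) {
  stopifnot(is.matrix(x), is.matrix(kern))
  if (nrow(kern) %% 2 == 0 || ncol(kern) %% 2 == 0)
    stop("kernel sides must be odd", call. = FALSE)
  r <- (nrow(kern) - 1L) %/% 2L
  xp <- mirror_pad(x, r)
  d <- dim(xp)
  kf <- kernel_fft(kern, d)
  y <- Re(stats::fft(stats::fft(xp) * kf, inverse = TRUE)) / prod(d)
  y[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x)), drop = FALSE]
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_logical <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 8-neighborhood binary dilation by `k` steps (square structuring element).
dilate8 <- function(m, k = 1L) {
  out <- m
  for (i in seq_len(k)) {
    acc <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc | shift_logical(out, dr, dc)
    }
    out <- acc
  }
  out
}

# 8-neighborhood binary erosion by `k` steps.
erode8 <- function(m, k = 1L) {
  out <- m
  for (i in seq_len(k)) {
    acc <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc & shift_logical(out, dr, dc)
    }
    # pixels on the frame border lose their out-of-frame neighbors
    acc[c(1, nrow(m)), ] <- FALSE
    acc[, c(1, ncol(m))] <- FALSE
    out <- acc
  }
  out
}

# Pixels of `mask` having at least one 8-neighbor outside the mask
# (or lying on the image frame).
mask_boundary <- function(mask) {
  inner <- erode8(mask, 1L)
  mask & !inner
}
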