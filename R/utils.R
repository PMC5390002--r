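# Internal raster helpers: reflect-padded 2-D convolution built from matrix
# shifts, separable Gaussian smoothing, and pyramid down/upsampling. Kernels
# are small (3x3 Sobel, short Gaussians), so shift-and-add is both exact and
# fast enough for the image sizes handled here.

padReflect <- function(m, top, bottom = top, left = top, right = left) {
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(idx, n) {
    # mirror about the border pixel (no repetition), degenerate for n = 1
    if (n == 1L) return(rep(1L, length(idx)))
    period <- 2L * (n - 1L)
    k <- ((idx - 1L) %% period + period) %% period
    ifelse(k < n, k + 1L, period - k + 1L)
  }
  ri <- refl(seq.int(1L - top, nr + bottom), nr)
  ci <- refl(seq.int(1L - left, nc + right), nc)
  m[ri, ci, drop = FALSE]
}

# full 2-D convolution (correlation) with reflect padding; kernel dims odd
conv2Reflect <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  p <- padReflect(m, top = pr, bottom = pr, left = pc, right = pc)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

gaussKernel1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussBlur <- function(m, sigma) {
  k <- gaussKernel1d(sigma)
  m <- conv2Reflect(m, matrix(k, ncol = 1))
  conv2Reflect(m, matrix(k, nrow = 1))
}

# local (windowed) mean via a normalised box or Gaussian window
localMean <- function(m, sigma) gaussBlur(m, sigma)

localVar <- function(m, sigma) {
  v <- gaussBlur(m^2, sigma) - gaussBlur(m, sigma)^2
  pmax(v, 0)
}

downsample2 <- function(m) {
  m <- gaussBlur(m, 1)
  m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

# nearest-neighbour upsample back to a target shape
upsampleTo <- function(m, nr, nc) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(nr) / nr * nrow(m))))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(nc) / nc * ncol(m))))
  m[ri, ci, drop = FALSE]
}

# min-max rescale to [0, 1]; constant input maps to all zeros
rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2])))
    return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
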