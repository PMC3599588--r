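# FFT cross-correlation with mirrored (symmetric) boundary padding.
#
# All spatial filtering in the package funnels through these two helpers:
#   fft_corr_stack(): one kernel applied to many same-sized maps (kernel FFT
#     computed once, maps processed two at a time packed into one complex
#     transform), used by the surround-suppression and iteration stages.
#   fft_corr_bank(): many kernels applied to one image (image FFT computed
#     once, kernels packed pairwise), used by layer-1 feature extraction.
# Both compute cross-correlation, i.e. template matching:
#   y(i, j) = sum_u sum_v K(u, v) * x(i + u - cr, j + v - cc)
# with the kernel centre at (cr, cc) = (floor(kr/2) + 1, floor(kc/2) + 1),
# "same"-sized output, and out-of-range pixels mirrored at the border.
# For symmetric kernels (Gaussians, DoG) correlation equals convolution.

# Smallest 5-smooth integer >= n; R's mixed-radix FFT degrades on large
# prime factors, so transforms are padded up to a friendly length.
next_smooth <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Mirror-pad a matrix (symmetric padding: the edge row/column is repeated,
# reflections repeat with period 2n for pads wider than the image).
mirror_idx <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

pad_mirror <- function(x, top, bottom, left, right) {
  h <- nrow(x); w <- ncol(x)
  if (max(top, bottom) >= 8L * h || max(left, right) >= 8L * w)
    stop("kernel too large for image")
  ri <- mirror_idx(seq.int(1L - top, h + bottom), h)
  ci <- mirror_idx(seq.int(1L - left, w + right), w)
  x[ri, ci, drop = FALSE]
}

# Geometry shared by both entry points.
corr_geom <- function(h, w, kr, kc) {
  cr <- kr %/% 2L + 1L; cc <- kc %/% 2L + 1L
  list(
    cr = cr, cc = cc,
    top = cr - 1L, bottom = kr - cr, left = cc - 1L, right = kc - cc,
    pr = next_smooth(h + kr - 1L), pc = next_smooth(w + kc - 1L)
  )
}

embed_mat <- function(x, pr, pc) {
  out <- matrix(0, pr, pc)
  out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  out
}

#' @noRd
fft_corr_plan <- function(h, w, kernel, boundary = "mirror") {
  kernel <- as.matrix(kernel)
  g <- corr_geom(h, w, nrow(kernel), ncol(kernel))
  kf <- Conj(stats::fft(embed_mat(kernel, g$pr, g$pc)))
  c(g, list(kf = kf, h = h, w = w, boundary = boundary))
}

pad_any <- function(x, plan) {
  if (identical(plan$boundary, "zero")) {
    out <- matrix(0, plan$h + plan$top + plan$bottom,
                  plan$w + plan$left + plan$right)
    out[plan$top + seq_len(plan$h), plan$left + seq_len(plan$w)] <- x
    out
  } else pad_mirror(x, plan$top, plan$bottom, plan$left, plan$right)
}

fft_corr_apply_one <- function(plan, x) {
  xp <- embed_mat(pad_mirror(x, plan$top, plan$bottom, plan$left, plan$right),
                  plan$pr, plan$pc)
  y <- stats::fft(stats::fft(xp) * plan$kf, inverse = TRUE) / (plan$pr * plan$pc)
  Re(y)[seq_len(plan$h), seq_len(plan$w)]
}

# One kernel, n maps: maps are packed two per complex FFT (correlation with a
# real kernel is real-linear, so Re/Im of the packed result are the two maps).
fft_corr_stack <- function(stack, kernel, plan = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; n <- dim(stack)[3L]
  if (is.null(plan)) plan <- fft_corr_plan(h, w, kernel)
  out <- array(0, dim(stack))
  i <- 1L
  while (i <= n) {
    xa <- pad_any(stack[, , i], plan)
    if (i + 1L <= n) {
      xb <- pad_any(stack[, , i + 1L], plan)
      z <- embed_mat(xa, plan$pr, plan$pc) + 1i * embed_mat(xb, plan$pr, plan$pc)
      y <- stats::fft(stats::fft(z) * plan$kf, inverse = TRUE) / (plan$pr * plan$pc)
      out[, , i] <- Re(y)[seq_len(h), seq_len(w)]
      out[, , i + 1L] <- Im(y)[seq_len(h), seq_len(w)]
      i <- i + 2L
    } else {
      z <- embed_mat(xa, plan$pr, plan$pc)
      y <- stats::fft(stats::fft(z) * plan$kf, inverse = TRUE) / (plan$pr * plan$pc)
      out[, , i] <- Re(y)[seq_len(h), seq_len(w)]
      i <- i + 1L
    }
  }
  out
}

# Many kernels, one image: the image FFT is reused; kernels are flipped
# (turning correlation into convolution, which is complex-linear in the
# kernel) and packed two per transform.
fft_corr_bank <- function(x, kernels) {
  h <- nrow(x); w <- ncol(x)
  kr <- nrow(kernels[[1L]]); kc <- ncol(kernels[[1L]])
  for (k in kernels)
    if (nrow(k) != kr || ncol(k) != kc) stop("all kernels must share a size")
  g <- corr_geom(h, w, kr, kc)
  xp <- embed_mat(pad_mirror(x, g$top, g$bottom, g$left, g$right), g$pr, g$pc)
  xf <- stats::fft(xp)
  flip <- function(k) k[kr:1L, kc:1L, drop = FALSE]
  n <- length(kernels)
  out <- array(0, c(h, w, n))
  rows <- kr:(h + kr - 1L); cols <- kc:(w + kc - 1L)
  i <- 1L
  while (i <= n) {
    ka <- embed_mat(flip(kernels[[i]]), g$pr, g$pc)
    if (i + 1L <= n) {
      kb <- embed_mat(flip(kernels[[i + 1L]]), g$pr, g$pc)
      y <- stats::fft(xf * stats::fft(ka + 1i * kb), inverse = TRUE) / (g$pr * g$pc)
      out[, , i] <- Re(y)[rows, cols]
      out[, , i + 1L] <- Im(y)[rows, cols]
      i <- i + 2L
    } else {
      y <- stats::fft(xf * stats::fft(ka), inverse = TRUE) / (g$pr * g$pc)
      out[, , i] <- Re(y)[rows, cols]
      i <- i + 1L
    }
  }
  out
}

#' Cross-correlate a map with a kernel ("same" size, mirrored boundary)
#'
#' Template-matching correlation used throughout the model; for the symmetric
#' Gaussian and difference-of-Gaussians kernels it coincides with convolution.
#'
#' @param x Numeric matrix.
#' @param kernel Numeric matrix; any size smaller than `x`.
#' @return Matrix of the same size as `x`.
#' @export
corr2_same <- function(x, kernel) {
  fft_corr_stack(x, kernel)[, , 1L]
}
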