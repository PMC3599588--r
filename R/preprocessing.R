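#' Sample square patches from grayscale images
#'
#' Draws `n_patches` square patches uniformly at random (image index first,
#' then position, with replacement) from a list of grayscale images and
#' returns them as columns of a `patch_set`. By default the DC component
#' (per-patch mean) is removed, the standard preprocessing for ICA-style
#' basis learning on image patches.
#'
#' @param images A grayscale image matrix or a list of them, values in `[0, 1]`.
#' @param patch_side Patch side length in pixels.
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed; identical seeds give bit-identical patch sets.
#' @param dc_center Remove the per-patch mean? Default `TRUE`.
#' @return A `patch_set`: list with `data` (`patch_side^2 x n_patches` matrix,
#'   patches as column-major pixel vectors), `patch_side`, and `whitened` flag.
#' @export
sample_patches <- function(images, patch_side, n_patches, seed = 1L,
                           dc_center = TRUE) {
  if (is.matrix(images)) images <- list(images)
  usable <- vapply(images, function(im)
    nrow(im) >= patch_side && ncol(im) >= patch_side, logical(1))
  if (any(!usable))
    warning(sprintf("rejected %d image(s) smaller than patch_side = %d",
                    sum(!usable), patch_side))
  images <- images[usable]
  if (length(images) == 0L) stop("no usable image is at least patch_side in both dimensions")
  if (n_patches < 1L) stop("n_patches must be >= 1")
  d <- patch_side^2
  data <- with_seed(seed, {
    img_idx <- sample.int(length(images), n_patches, replace = TRUE)
    out <- matrix(0, d, n_patches)
    for (k in seq_len(n_patches)) {
      im <- images[[img_idx[k]]]
      r <- sample.int(nrow(im) - patch_side + 1L, 1L)
      c <- sample.int(ncol(im) - patch_side + 1L, 1L)
      out[, k] <- as.vector(im[r:(r + patch_side - 1L), c:(c + patch_side - 1L)])
    }
    out
  })
  stopifnot_finite(data, "patch data")
  if (dc_center) data <- sweep(data, 2L, colMeans(data))
  structure(list(data = data, patch_side = patch_side, whitened = FALSE),
            class = "patch_set")
}

#' Fit a PCA whitening transform to a patch set
#'
#' Centers the patches on the mean patch, eigendecomposes the empirical
#' covariance, and builds the whitening map restricted to the top
#' `retained_dim` principal components, `W = U_k^(-1/2) V_k'`, so that the
#' transformed training patches have identity covariance on the retained
#' components. Eigenvalues below `eig_floor` times the largest are treated as
#' zero (the inverse square root is singular there).
#'
#' @param patches A `patch_set` from [sample_patches()].
#' @param retained_dim Number of principal components to keep.
#' @param eig_floor Relative eigenvalue floor; default `1e-10`.
#' @return A `whitening_transform`: list with `mean_patch`, `whitening_matrix`
#'   (`retained_dim x d_raw`), `dewhitening_matrix` (`d_raw x retained_dim`),
#'   `retained_dim`, `eigenvalues`, `eigenvectors`, `patch_side`.
#' @export
fit_whitening <- function(patches, retained_dim, eig_floor = 1e-10) {
  stopifnot(inherits(patches, "patch_set"))
  X <- patches$data
  d <- nrow(X)
  if (retained_dim > d) stop("retained_dim exceeds patch dimension")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  rank <- sum(lam > eig_floor * max(lam))
  if (rank < retained_dim)
    stop(sprintf("covariance rank %d is below retained_dim %d", rank, retained_dim))
  keep <- seq_len(retained_dim)
  Vk <- e$vectors[, keep, drop = FALSE]
  sc <- 1 / sqrt(lam[keep])
  W <- sc * t(Vk)                       # U_k^(-1/2) V_k'
  DW <- Vk %*% diag(sqrt(lam[keep]), retained_dim)
  structure(list(mean_patch = mu, whitening_matrix = W, dewhitening_matrix = DW,
                 retained_dim = retained_dim, eigenvalues = lam,
                 eigenvectors = e$vectors, patch_side = patches$patch_side),
            class = "whitening_transform")
}

#' Whiten a patch set
#'
#' Applies a fitted [fit_whitening()] transform: subtracts the training mean
#' patch and projects onto the whitened principal subspace.
#'
#' @param patches A `patch_set` in raw pixel space.
#' @param tf A `whitening_transform`.
#' @return A `patch_set` with `retained_dim`-dimensional columns and
#'   `whitened = TRUE`.
#' @export
whiten <- function(patches, tf) {
  stopifnot(inherits(patches, "patch_set"), inherits(tf, "whitening_transform"))
  if (nrow(patches$data) != ncol(tf$whitening_matrix))
    stop("patch dimension does not match the whitening transform")
  structure(list(data = tf$whitening_matrix %*% (patches$data - tf$mean_patch),
                 patch_side = patches$patch_side, whitened = TRUE),
            class = "patch_set")
}

#' Map whitened patches back to pixel space
#'
#' Inverts [whiten()] up to the PCA truncation: the result is the projection
#' of the original patches onto the retained principal subspace (plus the
#' mean patch).
#'
#' @param patches A whitened `patch_set`.
#' @param tf The `whitening_transform` used to whiten them.
#' @return A `patch_set` in pixel space.
#' @export
dewhiten <- function(patches, tf) {
  stopifnot(inherits(patches, "patch_set"), inherits(tf, "whitening_transform"))
  if (nrow(patches$data) != tf$retained_dim)
    stop("patch dimension does not match the whitening transform")
  structure(list(data = tf$dewhitening_matrix %*% patches$data + tf$mean_patch,
                 patch_side = patches$patch_side, whitened = FALSE),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, dim %d (patch_side %d, %s)\n",
              ncol(x$data), nrow(x$data), x$patch_side,
              if (x$whitened) "whitened" else "pixel space"))
  invisible(x)
}

#' @export
print.whitening_transform <- function(x, ...) {
  cat(sprintf("<whitening_transform> %d -> %d dims (patch_side %d)\n",
              length(x$mean_patch), x$retained_dim, x$patch_side))
  invisible(x)
}
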