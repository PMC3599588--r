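# Layer 1: learning an (over)complete topographic basis on a torus grid.

#' Configuration for topographic basis learning
#'
#' @param n_filters Number of filters (must equal `prod(grid_shape)`).
#' @param grid_shape `c(rows, cols)` of the topographic torus grid.
#' @param neighbourhood_side Odd side length (in filters) of the torus
#'   neighbourhood used in the learning objective; tied by the model to the
#'   layer-2 pooling neighbourhood. Default 5.
#' @param step_size Initial gradient step. Default 0.1.
#' @param n_iterations Number of stochastic gradient steps. Default 500.
#' @param batch_size Patches per step. Default 1000.
#' @param step_decay,decay_every Multiply the step by `step_decay` every
#'   `decay_every` iterations. Defaults 0.5 / 100.
#' @param seed Integer seed controlling initialization and batch draws.
#' @return A `learning_config` list.
#' @export
learning_config <- function(n_filters, grid_shape,
                            neighbourhood_side = 5L, step_size = 0.1,
                            n_iterations = 500L, batch_size = 1000L,
                            step_decay = 0.5, decay_every = 100L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || prod(grid_shape) != n_filters)
    stop("grid_shape must have two entries with rows * cols = n_filters")
  if (neighbourhood_side %% 2L != 1L || neighbourhood_side > min(grid_shape))
    stop("neighbourhood_side must be odd and at most min(grid_shape)")
  structure(list(n_filters = as.integer(n_filters), grid_shape = grid_shape,
                 neighbourhood_side = as.integer(neighbourhood_side),
                 step_size = step_size, n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size), step_decay = step_decay,
                 decay_every = as.integer(decay_every), seed = as.integer(seed)),
            class = "learning_config")
}

# Grid position (row-major, 1-based) of each filter index.
grid_coords <- function(grid_shape) {
  n <- prod(grid_shape)
  idx <- seq_len(n) - 1L
  cbind(row = idx %/% grid_shape[2L] + 1L, col = idx %% grid_shape[2L] + 1L)
}

grid_index <- function(row, col, grid_shape) {
  (row - 1L) * grid_shape[2L] + col
}

# 0/1 membership matrix H: H[p, i] = 1 iff filter i lies in the torus
# neighbourhood (side s) centred on grid node p. One neighbourhood per node.
neighbourhood_matrix <- function(grid_shape, side) {
  n <- prod(grid_shape)
  h <- (side - 1L) %/% 2L
  co <- grid_coords(grid_shape)
  H <- matrix(0, n, n)
  off <- -h:h
  for (p in seq_len(n)) {
    rows <- (co[p, 1L] - 1L + off) %% grid_shape[1L] + 1L
    cols <- (co[p, 2L] - 1L + off) %% grid_shape[2L] + 1L
    H[p, as.vector(outer(rows, cols, grid_index, grid_shape = grid_shape))] <- 1
  }
  H
}

# Symmetric orthogonalization Phi <- (Phi Phi')^(-1/2) Phi (complete case).
# Overcomplete sets cannot have orthonormal rows; they are decorrelated by
# making the frame tight, Phi <- Phi (Phi' Phi)^(-1/2), with row
# renormalization. (The first-order expansion 1.5 Phi - 0.5 Phi Phi' Phi
# assumes a near-identity Gram and collapses overcomplete rows onto shared
# fixed points.)
orthogonalize_rows <- function(Phi, overcomplete) {
  if (!overcomplete) {
    e <- eigen(tcrossprod(Phi), symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    (e$vectors %*% (t(e$vectors) / sqrt(vals))) %*% Phi
  } else {
    e <- eigen(crossprod(Phi), symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    Phi <- Phi %*% (e$vectors %*% (t(e$vectors) / sqrt(vals)))
    Phi / sqrt(rowSums(Phi^2))
  }
}

#' Initialize a topographic basis set
#'
#' Draws a random Gaussian matrix under the config seed and orthogonalizes it
#' (symmetric orthogonalization when `n_filters <= d_red`; the normalized
#' quasi-orthogonalization sweep when the set is overcomplete). Rows are
#' unit-norm filters in whitened space.
#'
#' @param config A [learning_config()].
#' @param d_red Dimension of the whitened space the filters live in.
#' @return A `topo_basis` with fields `filters` (`n_filters x d_red`),
#'   `grid_shape`, `torus = TRUE`, `config`; `pixel_filters` and `patch_side`
#'   are filled in by [backproject_filters()].
#' @export
init_basis <- function(config, d_red) {
  stopifnot(inherits(config, "learning_config"))
  if (config$n_filters < 1L) stop("n_filters must be >= 1")
  Phi <- with_seed(config$seed,
                   matrix(stats::rnorm(config$n_filters * d_red),
                          config$n_filters, d_red))
  Phi <- orthogonalize_rows(Phi, overcomplete = config$n_filters > d_red)
  Phi <- Phi / sqrt(rowSums(Phi^2))
  structure(list(filters = Phi, pixel_filters = NULL,
                 grid_shape = config$grid_shape, torus = TRUE,
                 patch_side = NULL, d_red = d_red, config = config,
                 training_loss = numeric(0), response_sample = NULL,
                 whitening = NULL, pool_layout = NULL),
            class = "topo_basis")
}

#' Learn a topographic basis from whitened patches
#'
#' Stochastic gradient ascent on the topographic energy objective
#' `sum_p G(sum_{i in p} (phi_i' z)^2)` with `G(u) = -sqrt(u + eps)`, where
#' the pools `p` are torus neighbourhoods of side `neighbourhood_side`
#' centred on every grid node. Each step is followed by (quasi-)symmetric
#' orthogonalization. This is the topographic-ICA family objective that
#' yields Gabor-like filters whose orientation/frequency tuning varies
#' smoothly across the torus grid.
#'
#' @param patches A whitened `patch_set`.
#' @param config A [learning_config()].
#' @param eps Smoothing constant inside the square root. Default `1e-3`.
#' @param response_sample_size Number of training responses cached on the
#'   basis for later pool refinement (the training-ensemble similarity mode).
#'   Default 10000.
#' @return A `topo_basis`; `training_loss` holds the per-iteration batch loss
#'   `mean_z sum_p sqrt(u_p + eps)` (lower is better).
#' @export
learn_basis <- function(patches, config, eps = 1e-3,
                        response_sample_size = 10000L) {
  stopifnot(inherits(patches, "patch_set"), inherits(config, "learning_config"))
  if (!isTRUE(patches$whitened)) stop("learn_basis expects whitened patches")
  Z <- patches$data
  d <- nrow(Z); N <- ncol(Z)
  basis <- init_basis(config, d)
  Phi <- basis$filters
  H <- neighbourhood_matrix(config$grid_shape, config$neighbourhood_side)
  overcomplete <- config$n_filters > d
  loss <- numeric(config$n_iterations)
  step <- config$step_size
  with_seed(config$seed + 1L, {
    for (it in seq_len(config$n_iterations)) {
      idx <- sample.int(N, config$batch_size, replace = config$batch_size > N)
      Zb <- Z[, idx, drop = FALSE]
      Y <- Phi %*% Zb
      U <- H %*% (Y^2)
      su <- sqrt(U + eps)
      loss[it] <- sum(su) / config$batch_size
      if (!is.finite(loss[it]))
        stop(sprintf("basis learning diverged at iteration %d", it))
      G <- crossprod(H, -0.5 / su)          # r_i = sum_p H[p,i] G'(u_p)
      grad <- (2 / config$batch_size) * ((Y * G) %*% t(Zb))
      Phi <- Phi + step * grad
      Phi <- orthogonalize_rows(Phi, overcomplete)
      if (it %% config$decay_every == 0L) step <- step * config$step_decay
    }
  })
  basis$filters <- Phi / sqrt(rowSums(Phi^2))
  basis$training_loss <- loss
  m <- min(response_sample_size, N)
  basis$response_sample <- basis$filters %*% Z[, seq_len(m), drop = FALSE]
  basis
}

#' Back-project filters through the whitening transform
#'
#' Composes the whitened-space filters with the whitening matrix so that a
#' pixel filter applied to a raw patch reproduces the whitened-space inner
#' product: `pixel_filters = filters %*% W`. Needed before convolutional
#' feature extraction.
#'
#' @param basis A `topo_basis`.
#' @param tf The `whitening_transform` the training patches were whitened with.
#' @return The basis with `pixel_filters` (`n_filters x patch_side^2`) and
#'   `patch_side` set, and the transform stored for provenance.
#' @export
backproject_filters <- function(basis, tf) {
  stopifnot(inherits(basis, "topo_basis"), inherits(tf, "whitening_transform"))
  if (ncol(basis$filters) != nrow(tf$whitening_matrix))
    stop("basis dimension does not match the whitening transform")
  basis$pixel_filters <- basis$filters %*% tf$whitening_matrix
  basis$patch_side <- tf$patch_side
  basis$whitening <- tf
  basis
}

#' @export
print.topo_basis <- function(x, ...) {
  cat(sprintf("<topo_basis> %d filters on a %dx%d torus grid (d_red %d%s)\n",
              nrow(x$filters), x$grid_shape[1L], x$grid_shape[2L], x$d_red,
              if (is.null(x$pixel_filters)) ""
              else sprintf(", pixel filters %dx%d", x$patch_side, x$patch_side)))
  invisible(x)
}

#' Save / load a basis artifact
#'
#' The basis (filters, grid shape, torus flag, training config, cached
#' training responses, whitening transform, and any attached pool layout) is
#' persisted with [saveRDS()].
#'
#' @param basis A `topo_basis`.
#' @param path File path.
#' @return `save_basis` returns `path` invisibly; `load_basis` the basis.
#' @export
save_basis <- function(basis, path) {
  stopifnot(inherits(basis, "topo_basis"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  basis <- readRDS(path)
  if (!inherits(basis, "topo_basis")) stop("file does not contain a topo_basis")
  basis
}
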