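# Layer 1 responses and layer 2 invariant pooling.

new_feature_stack <- function(maps, rectified = FALSE) {
  structure(list(maps = maps, source_shape = dim(maps)[1:2],
                 rectified = rectified),
            class = "feature_stack")
}

#' Extract layer-1 feature maps by filtering an image
#'
#' Cross-correlates the image with every unit-L2-normalized pixel filter of
#' the basis ("same"-sized output, mirrored boundary), giving one simple-cell
#' response map per filter. The maps are signed; apply [rectify()] before
#' pooling.
#'
#' @param image Grayscale matrix, values in `[0, 1]`.
#' @param basis A back-projected `topo_basis` (see [backproject_filters()]).
#' @return A `feature_stack`: `maps` is an `H x W x n_filters` array.
#' @export
extract_features <- function(image, basis) {
  stopifnot(inherits(basis, "topo_basis"))
  if (is.null(basis$pixel_filters))
    stop("basis has no pixel filters; call backproject_filters() first")
  s <- basis$patch_side
  if (nrow(image) < s || ncol(image) < s)
    stop("image is smaller than the filter size")
  kernels <- lapply(seq_len(nrow(basis$pixel_filters)), function(i) {
    v <- basis$pixel_filters[i, ]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    matrix(v, s, s)
  })
  new_feature_stack(fft_corr_bank(image, kernels), rectified = FALSE)
}

#' Rectify feature maps into [0, 1)
#'
#' Applies the absolute value followed by a sigmoid. The default
#' zero-preserving form `r(x) = 2 / (1 + exp(-|x|)) - 1` maps 0 to 0 and
#' saturates at 1, so an empty background stays at zero response. The literal
#' logistic `1 / (1 + exp(-|x|))` (range `[0.5, 1)`) is available as
#' `mode = "logistic"`.
#'
#' @param stack A `feature_stack`.
#' @param mode `"zero"` (default) or `"logistic"`.
#' @return The rectified `feature_stack`.
#' @export
rectify <- function(stack, mode = c("zero", "logistic")) {
  stopifnot(inherits(stack, "feature_stack"))
  mode <- match.arg(mode)
  a <- abs(stack$maps)
  stack$maps <- if (mode == "zero") 2 / (1 + exp(-a)) - 1 else 1 / (1 + exp(-a))
  stack$rectified <- TRUE
  stack
}

#' Pool rectified feature maps into invariant maps
#'
#' Complex-cell style energy pooling: for each pool `j` with member filters
#' `Omega_j`, `CF_j(x, y) = (sum_{i in Omega_j} SF_i(x, y)^beta)^(1/beta)`
#' with the standard choice `beta = 2` (square root of the sum of squares),
#' computed pixelwise with no spatial pooling.
#'
#' @param stack A rectified `feature_stack`.
#' @param layout A `pool_layout` from [build_pools()] (refined or not).
#' @param beta Pooling exponent. Default 2.
#' @return An `invariant_stack`: `maps` is `H x W x n_pools`.
#' @export
pool_features <- function(stack, layout, beta = 2) {
  stopifnot(inherits(stack, "feature_stack"), inherits(layout, "pool_layout"))
  if (!isTRUE(stack$rectified)) stop("pool_features expects a rectified stack")
  d <- dim(stack$maps)
  M <- matrix(stack$maps, d[1L] * d[2L], d[3L])
  np <- length(layout$pools)
  out <- array(0, c(d[1L], d[2L], np))
  for (j in seq_len(np)) {
    idx <- layout$pools[[j]]
    out[, , j] <- rowSums(M[, idx, drop = FALSE]^beta)^(1 / beta)
  }
  structure(list(maps = out, source_shape = d[1:2], beta = beta,
                 layout = layout),
            class = "invariant_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<feature_stack> %d maps of %dx%d (%s)\n", d[3L], d[1L], d[2L],
              if (x$rectified) "rectified" else "signed"))
  invisible(x)
}

#' @export
print.invariant_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<invariant_stack> %d pooled maps of %dx%d (beta = %g)\n",
              d[3L], d[1L], d[2L], x$beta))
  invisible(x)
}
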