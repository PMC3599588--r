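# Within-feature competition: non-classical receptive field surround
# suppression by a difference-of-Gaussians kernel.

#' Surround-suppression parameters
#'
#' The excitation/inhibition bandwidths may be given in pixels
#' (`unit = "px"`), as multiples of the layer-1 receptive-field size
#' (`unit = "rf"`, the convention used in the parameter studies: `sigma_ex =
#' 2` means twice the filter side), or as a fraction of the image size
#' (`unit = "frac"`, relative to the larger of width and height, the
#' convention used for the composite-stimulus settings of roughly
#' 0.018-0.03). Non-pixel units are resolved by [resolve_suppression()]
#' before the kernels are built.
#'
#' @param sigma_ex Excitation bandwidth. Default 2 (in `"rf"` units).
#' @param sigma_inh Inhibition bandwidth; default `4 * sigma_ex` (the model
#'   keeps the ratio `sigma_inh / sigma_ex` fixed at 4).
#' @param alpha Suppression strength. Default 1.8.
#' @param unit Unit of the bandwidths. Default `"rf"`.
#' @param kernel_radius Truncation radius in pixels; default `ceiling(3 *
#'   sigma_inh)` once resolved (under 0.3% of the Gaussian mass is lost).
#' @param convention How the DoG becomes non-negative suppression weights:
#'   `"abs"` (default) takes `|DoG|`, so both the excitatory disc and the
#'   inhibitory annulus contribute and the weights sum to exactly 1 --
#'   the only reading under which a homogeneous texture field is fully
#'   cancelled at suppression strengths just above 1; `"center"` half-
#'   rectifies the signed DoG (central lobe only, mass about 0.5);
#'   `"annulus"` keeps the surround lobe instead.
#' @return A `suppression_params` list.
#' @export
suppression_params <- function(sigma_ex = 2, sigma_inh = 4 * sigma_ex,
                               alpha = 1.8, unit = c("rf", "px", "frac"),
                               kernel_radius = NULL,
                               convention = c("abs", "center", "annulus")) {
  unit <- match.arg(unit)
  convention <- match.arg(convention)
  if (!(sigma_inh > sigma_ex && sigma_ex > 0))
    stop("need sigma_inh > sigma_ex > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  p <- structure(list(sigma_ex = sigma_ex, sigma_inh = sigma_inh,
                      alpha = alpha, unit = unit,
                      kernel_radius = kernel_radius, convention = convention),
                 class = "suppression_params")
  if (unit == "px") p <- finalize_radius(p)
  p
}

finalize_radius <- function(p) {
  if (is.null(p$kernel_radius)) p$kernel_radius <- ceiling(3 * p$sigma_inh)
  if (p$kernel_radius < 3 * p$sigma_inh)
    stop("kernel_radius must be at least 3 * sigma_inh")
  p
}

#' Resolve suppression bandwidths to pixels
#'
#' @param params A `suppression_params`.
#' @param rf_size Layer-1 receptive-field size in pixels (filter side); needed
#'   for `unit = "rf"`.
#' @param image_shape `c(H, W)`; needed for `unit = "frac"`.
#' @return The params with `unit = "px"` and `kernel_radius` set.
#' @export
resolve_suppression <- function(params, rf_size = NULL, image_shape = NULL) {
  stopifnot(inherits(params, "suppression_params"))
  scale <- switch(params$unit,
    px = 1,
    rf = { if (is.null(rf_size)) stop("rf_size needed for unit = 'rf'"); rf_size },
    frac = { if (is.null(image_shape)) stop("image_shape needed for unit = 'frac'")
             max(image_shape) })
  params$sigma_ex <- params$sigma_ex * scale
  params$sigma_inh <- params$sigma_inh * scale
  params$unit <- "px"
  finalize_radius(params)
}

#' Difference-of-Gaussians suppression kernel
#'
#' `DoG(x, y) = G(sigma_ex) - G(sigma_inh)` with each `G` the unit-integral
#' Gaussian `exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)`, sampled on
#' the integer grid `[-r, r]^2`. Because both terms integrate to one, the
#' discrete kernel sums to approximately zero.
#'
#' @param params A pixel-unit `suppression_params` (see
#'   [resolve_suppression()]).
#' @return A `(2r + 1) x (2r + 1)` matrix.
#' @export
dog_kernel <- function(params) {
  stopifnot(inherits(params, "suppression_params"))
  if (params$unit != "px") stop("resolve_suppression() to pixel units first")
  r <- params$kernel_radius
  gauss2d(params$sigma_ex, r) - gauss2d(params$sigma_inh, r)
}

#' Non-negative, L1-normalized inhibition weights
#'
#' `omega = |DoG| / ||DoG||_L1` under the default `"abs"` convention (unit
#' mass: centre disc plus surround annulus), `max(DoG, 0) / ||DoG||_L1`
#' under `"center"`, `max(-DoG, 0) / ||DoG||_L1` under `"annulus"`.
#' Non-negative everywhere and invariant to rescaling of the DoG.
#'
#' @inheritParams dog_kernel
#' @return A non-negative kernel matrix.
#' @export
inhibition_weights <- function(params) {
  dog <- dog_kernel(params)
  l1 <- sum(abs(dog))
  if (l1 == 0) stop("degenerate DoG kernel (all zero)")
  switch(params$convention,
         abs = abs(dog) / l1,
         center = pmax(dog, 0) / l1,
         annulus = pmax(-dog, 0) / l1)
}

# The half-rectified DoG has compact support (zero beyond the radius where
# the two Gaussians cross); cropping the kernel to its non-zero bounding box
# is exact and much cheaper to convolve.
crop_kernel <- function(k) {
  nz <- which(k != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(k)
  c0 <- (dim(k) + 1L) %/% 2L
  hr <- max(abs(nz[, 1L] - c0[1L])); hc <- max(abs(nz[, 2L] - c0[2L]))
  k[(c0[1L] - hr):(c0[1L] + hr), (c0[2L] - hc):(c0[2L] + hc), drop = FALSE]
}

#' Surround-suppress one invariant feature map
#'
#' `s(x, y) = max(CF(x, y) - alpha * (CF %*% omega)(x, y), 0)`: the map minus
#' `alpha` times its correlation with the inhibition weights, half-rectified.
#' Homogeneous texture is cancelled (for constant input `C` the result is
#' `max(C (1 - alpha * sum(omega)), 0)`), while isolated structure survives.
#'
#' @param map Non-negative matrix (one invariant feature map).
#' @param params A pixel-unit `suppression_params`.
#' @return A non-negative conspicuity map, same size as `map`.
#' @export
suppress <- function(map, params) {
  w <- crop_kernel(inhibition_weights(params))
  pmax(map - params$alpha * corr2_same(map, w), 0)
}

#' Surround-suppress every map of a stack
#'
#' Applies [suppress()] to each map of an invariant (or rectified feature)
#' stack, sharing the kernel FFT across maps.
#'
#' @param inv An `invariant_stack` or `feature_stack`.
#' @param params A pixel-unit `suppression_params`.
#' @return A `conspicuity_stack` (`maps`: `H x W x n_pools`, all values >= 0).
#' @export
conspicuity_stack <- function(inv, params) {
  maps <- if (is.list(inv) && !is.null(inv$maps)) inv$maps else inv
  w <- crop_kernel(inhibition_weights(params))
  plan <- fft_corr_plan(dim(maps)[1L], dim(maps)[2L], w)
  out <- pmax(maps - params$alpha * fft_corr_stack(maps, w, plan = plan), 0)
  structure(list(maps = out, params = params), class = "conspicuity_stack")
}

#' @export
print.conspicuity_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<conspicuity_stack> %d maps of %dx%d\n", d[3L], d[1L], d[2L]))
  invisible(x)
}

#' @export
print.suppression_params <- function(x, ...) {
  cat(sprintf("<suppression_params> sigma_ex %g, sigma_inh %g (%s), alpha %g, %s lobe\n",
              x$sigma_ex, x$sigma_inh, x$unit, x$alpha, x$convention))
  invisible(x)
}
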