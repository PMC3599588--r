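# Combining conspicuity maps into one saliency map.

#' Combination-strategy parameters
#'
#' The iterative strategy repeatedly applies `s <- max(s + s %*% DoG - C_inh,
#' 0)`, strengthening the initial maximum of a map and suppressing non-maxima.
#' Its DoG is the amplitude-weighted `c_ex G(sigma_ex) - c_inh G(sigma_inh)`
#' with bandwidths given as fractions of the image width; the kernel defaults
#' (`c_ex = 0.5`, `sigma_ex = 2%`, `c_inh = 1.5`, `sigma_inh = 25%`,
#' `C_inh = 0.02`) are the canonical values of the iterative normalization
#' scheme this strategy adopts. Maps are max-normalized to `[0, 1]` before
#' iterating (`normalize = TRUE`): the iteration dynamics then depend only
#' on each map's peak structure -- a map with one dominant peak grows, a map
#' of many comparable peaks extinguishes itself -- rather than on the
#' arbitrary response scale a map inherited from its pool size and filter
#' gains.
#'
#' @param n_iterations Iterations of the sharpening update. Default 10
#'   (winner-take-all competition between distant peaks needs on the order
#'   of ten rounds to settle at these kernel scales).
#' @param c_ex,c_inh Excitatory/inhibitory amplitudes. Defaults 0.5 / 1.5.
#' @param sigma_ex_frac,sigma_inh_frac Bandwidths as fractions of image
#'   width. Defaults 0.02 / 0.25.
#' @param C_inh Constant inhibitory bias. Default 0.02.
#' @param n_clusters Number of K-means clusters for the clustered strategy.
#'   Default 8.
#' @param subsample Per-axis subsampling factor for the map-similarity
#'   matrix. Default 4.
#' @param cluster_threshold Map count at and above which the pipeline switches
#'   from plain iteration to clustered combination. Default 10.
#' @param normalize Max-normalize each map to `[0, 1]` before the iterative
#'   strategies? Default `TRUE` (see above; the sum and max baselines always
#'   normalize, as defined).
#' @param seed Seed for K-means restarts.
#' @return A `combine_params` list.
#' @export
combine_params <- function(n_iterations = 10L, c_ex = 0.5, sigma_ex_frac = 0.02,
                           c_inh = 1.5, sigma_inh_frac = 0.25, C_inh = 0.02,
                           n_clusters = 8L, subsample = 4L,
                           cluster_threshold = 10L, normalize = TRUE,
                           seed = 1L) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  if (C_inh < 0) stop("C_inh must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations), c_ex = c_ex,
                 sigma_ex_frac = sigma_ex_frac, c_inh = c_inh,
                 sigma_inh_frac = sigma_inh_frac, C_inh = C_inh,
                 n_clusters = as.integer(n_clusters),
                 subsample = as.integer(subsample),
                 cluster_threshold = as.integer(cluster_threshold),
                 normalize = isTRUE(normalize), seed = seed),
            class = "combine_params")
}

# Un-normalized DoG for the iteration update, sized from the image width.
iter_dog_kernel <- function(shape, params) {
  w <- shape[2L]
  s_ex <- max(params$sigma_ex_frac * w, 0.5)
  s_inh <- max(params$sigma_inh_frac * w, 1)
  r <- min(ceiling(3 * s_inh), min(shape) - 1L)
  params$c_ex * gauss2d(s_ex, r) - params$c_inh * gauss2d(s_inh, r)
}

# Border-corrected Gaussian smoothing: zero-padded convolution divided by
# the local kernel mass that fell inside the image, so a constant map gets a
# constant response right up to the corners. Mirror padding would reflect a
# map onto itself (up to quadrupled self-excitation in corners) and plain
# zero padding lets border pixels escape inhibition; either way border
# activity wins the competition artificially.
norm_gauss_plan <- function(h, w, sigma, radius) {
  k <- gauss2d(sigma, radius)
  plan <- fft_corr_plan(h, w, k, boundary = "zero")
  den <- fft_corr_stack(array(1, c(h, w, 1L)), k, plan = plan)[, , 1L]
  list(plan = plan, k = k, den = den)
}

norm_gauss_apply <- function(maps, ng) {
  out <- fft_corr_stack(maps, ng$k, plan = ng$plan)
  for (j in seq_len(dim(out)[3L])) out[, , j] <- out[, , j] / ng$den
  out
}

stack_maps <- function(stack) {
  m <- if (is.list(stack) && !is.null(stack$maps)) stack$maps else stack
  if (is.matrix(m)) m <- array(m, c(dim(m), 1L))
  m
}

new_saliency_map <- function(s, strategy, rf_size = NULL) {
  structure(s, class = c("saliency_map", "matrix"),
            strategy = strategy, rf_size = rf_size)
}

# Iterate a whole stack in lockstep. The DoG term is computed as the
# difference of two border-corrected Gaussian smoothings (kernel FFTs and
# border-mass denominators built once per sweep); an explicit `kernel`
# bypasses the correction.
iterate_maps <- function(maps, params, kernel = NULL) {
  h <- dim(maps)[1L]; w <- dim(maps)[2L]
  if (!is.null(kernel)) {
    plan <- fft_corr_plan(h, w, kernel, boundary = "zero")
    for (k in seq_len(params$n_iterations))
      maps <- pmax(maps + fft_corr_stack(maps, kernel, plan = plan) - params$C_inh, 0)
    return(maps)
  }
  s_ex <- max(params$sigma_ex_frac * w, 0.5)
  s_inh <- max(params$sigma_inh_frac * w, 1)
  ng_ex <- norm_gauss_plan(h, w, s_ex, min(ceiling(3 * s_ex), min(h, w) - 1L))
  ng_inh <- norm_gauss_plan(h, w, s_inh, min(ceiling(3 * s_inh), min(h, w) - 1L))
  for (k in seq_len(params$n_iterations)) {
    dog <- params$c_ex * norm_gauss_apply(maps, ng_ex) -
      params$c_inh * norm_gauss_apply(maps, ng_inh)
    maps <- pmax(maps + dog - params$C_inh, 0)
  }
  maps
}

#' Iteratively sharpen a single map
#'
#' Applies `s <- max(s + s %*% DoG - C_inh, 0)` for `n_iterations` rounds.
#' Short-range self-excitation and long-range inhibition amplify the gap
#' between a map's strongest peak and the rest.
#'
#' @param s Non-negative matrix.
#' @param params A [combine_params()].
#' @param kernel Optional explicit DoG kernel (otherwise built from `params`
#'   and the map size).
#' @return The iterated non-negative map.
#' @export
iterate_map <- function(s, params = combine_params(), kernel = NULL) {
  stopifnot_finite(s, "map")
  iterate_maps(array(s, c(dim(s), 1L)), params, kernel)[, , 1L]
}

#' Combine conspicuity maps by normalized summation
#'
#' Each map is max-normalized to `[0, 1]` and the maps are summed pixelwise.
#' Simple but fragile: a strong peak in one map is diluted by activity in the
#' others.
#'
#' @param stack A `conspicuity_stack` (or `H x W x n` array).
#' @return A `saliency_map`.
#' @export
combine_sum <- function(stack) {
  m <- stack_maps(stack)
  if (dim(m)[3L] == 0L) stop("empty conspicuity stack")
  for (j in seq_len(dim(m)[3L])) m[, , j] <- norm_peak(m[, , j])
  new_saliency_map(apply(m, c(1L, 2L), sum), "sum")
}

#' Combine conspicuity maps by a pixelwise maximum
#'
#' Takes the maximum over the max-normalized maps at every pixel. Local
#' maxima of every map survive, so cluttered stacks yield many spurious
#' peaks.
#'
#' @inheritParams combine_sum
#' @return A `saliency_map`.
#' @export
combine_max <- function(stack) {
  m <- stack_maps(stack)
  if (dim(m)[3L] == 0L) stop("empty conspicuity stack")
  for (j in seq_len(dim(m)[3L])) m[, , j] <- norm_peak(m[, , j])
  new_saliency_map(apply(m, c(1L, 2L), max), "max")
}

#' Combine conspicuity maps by iterative sharpening
#'
#' Max-normalizes each map (unless disabled), applies [iterate_map()] to
#' every map, and sums the results. Intended for small stacks; pipelines
#' switch to [combine_clustered()] at `cluster_threshold` maps.
#'
#' @inheritParams combine_sum
#' @param params A [combine_params()].
#' @return A `saliency_map`.
#' @export
combine_iterate <- function(stack, params = combine_params()) {
  m <- stack_maps(stack)
  if (dim(m)[3L] == 0L) stop("empty conspicuity stack")
  stopifnot_finite(m, "conspicuity stack")
  if (params$normalize) for (j in seq_len(dim(m)[3L])) m[, , j] <- norm_peak(m[, , j])
  m <- iterate_maps(m, params)
  new_saliency_map(apply(m, c(1L, 2L), sum), "iterate")
}

# Eq.-6 energy-correlation similarity matrix between maps, on a subsampled
# pixel grid.
map_similarity <- function(m, subsample) {
  h <- dim(m)[1L]; w <- dim(m)[2L]
  ri <- seq.int(1L, h, by = subsample); ci <- seq.int(1L, w, by = subsample)
  S <- matrix(m[ri, ci, ], length(ri) * length(ci), dim(m)[3L])^2
  v <- apply(S, 2L, stats::var)
  Cm <- suppressWarnings(stats::cor(S))
  Cm[is.na(Cm)] <- 0
  Cm[v == 0, ] <- 0; Cm[, v == 0] <- 0
  diag(Cm)[v > 0] <- 1
  Cm
}

#' Clustered combination for large stacks
#'
#' For stacks of many maps, direct iteration faces a signal-to-noise problem,
#' so the maps are first grouped: the pairwise energy-correlation similarity
#' matrix is computed on subsampled maps, K-means (10 restarts under the
#' seed) clusters its rows into `n_clusters` groups, maps within a cluster
#' are average-pooled, each cluster map is iterated, and the iterated results
#' are summed.
#'
#' @inheritParams combine_iterate
#' @return A `saliency_map`.
#' @export
combine_clustered <- function(stack, params = combine_params()) {
  m <- stack_maps(stack)
  n <- dim(m)[3L]
  if (n < params$n_clusters)
    stop("fewer maps than clusters; reduce n_clusters")
  if (params$normalize) for (j in seq_len(n)) m[, , j] <- norm_peak(m[, , j])
  # fully suppressed (all-zero) maps carry no signal and can defeat K-means
  # (identical similarity rows); cluster only the active maps
  active <- which(apply(m, 3L, max) > 0)
  if (length(active) == 0L)
    return(new_saliency_map(matrix(0, dim(m)[1L], dim(m)[2L]), "cluster_iterate"))
  m <- m[, , active, drop = FALSE]
  n <- length(active)
  k <- min(params$n_clusters, n)
  cl <- if (k == n) seq_len(n) else {
    sim <- map_similarity(m, params$subsample)
    k <- min(k, nrow(unique(sim)))
    with_seed(params$seed,
              stats::kmeans(sim, centers = k, nstart = 10L,
                            iter.max = 100L))$cluster
  }
  # canonical cluster order (by smallest member index) for stable provenance
  ord <- order(vapply(seq_len(k), function(j) min(which(cl == j)), integer(1)))
  h <- dim(m)[1L]; w <- dim(m)[2L]
  pooled <- array(0, c(h, w, k))
  for (j in seq_len(k)) {
    idx <- which(cl == ord[j])
    pooled[, , j] <- apply(m[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  pooled <- iterate_maps(pooled, params)
  new_saliency_map(apply(pooled, c(1L, 2L), sum), "cluster_iterate")
}

#' Combine a conspicuity stack with a named strategy
#'
#' `strategy = "auto"` (the pipeline default) uses plain iteration for fewer
#' than `cluster_threshold` maps and clustered combination otherwise.
#'
#' @inheritParams combine_iterate
#' @param strategy One of `"auto"`, `"iterate"`, `"sum"`, `"max"`,
#'   `"cluster_iterate"`.
#' @return A `saliency_map`.
#' @export
combine_saliency <- function(stack, strategy = "auto",
                             params = combine_params()) {
  n <- dim(stack_maps(stack))[3L]
  if (strategy == "auto")
    strategy <- if (n < params$cluster_threshold) "iterate" else "cluster_iterate"
  switch(strategy,
         iterate = combine_iterate(stack, params),
         sum = combine_sum(stack),
         max = combine_max(stack),
         cluster_iterate = combine_clustered(stack, params),
         stop(sprintf("unknown combination strategy '%s'", strategy)))
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %dx%d, strategy '%s', range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "strategy"), min(x), max(x)))
  invisible(x)
}
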