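# Comparison network architectures sharing layer 1.

#' Specify a network variant
#'
#' Four architectures share the learned layer-1 filters and differ in their
#' second layer: `invariant` pools topographic (refined) neighbourhoods;
#' `no_invariance` skips pooling (layer-2 receptive field of one filter) and
#' suppresses each rectified feature map directly; `fully_connected` pools
#' every filter into a single map (orientation-blind); `randomly_connected`
#' pools random fixed-size filter groups.
#'
#' @param kind One of `"invariant"`, `"no_invariance"`, `"fully_connected"`,
#'   `"randomly_connected"`.
#' @param random_group_size Filters per random group (randomly connected
#'   only); default: the invariant model's pool area, capped at the filter
#'   count. A group size equal to the filter count reduces the network to the
#'   fully connected one.
#' @param n_groups Number of random groups; default: the invariant model's
#'   pool count.
#' @param seed Seed for the random grouping.
#' @return A `variant_spec`.
#' @export
variant_spec <- function(kind = c("invariant", "no_invariance",
                                  "fully_connected", "randomly_connected"),
                         random_group_size = NULL, n_groups = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, random_group_size = random_group_size,
                 n_groups = n_groups, seed = as.integer(seed)),
            class = "variant_spec")
}

random_pool_layout <- function(basis, group_size, n_groups, seed) {
  n <- nrow(basis$filters)
  if (group_size > n) stop("random_group_size exceeds the filter count")
  pools <- with_seed(seed, lapply(seq_len(n_groups), function(g)
    sort(sample.int(n, group_size))))
  structure(list(pools = pools, center_index = vapply(pools, `[`, integer(1), 1L),
                 centers = NULL, pool_side = NA_integer_, stride = NA_integer_,
                 overlap = NA_integer_, grid_shape = basis$grid_shape,
                 refined = FALSE, correlation_threshold = NA_real_),
            class = "pool_layout")
}

# Default refined topographic layout for a basis (cached on the basis by the
# training pipeline; built on demand otherwise).
basis_layout <- function(basis, refine_threshold = 0.1) {
  if (!is.null(basis$pool_layout)) return(basis$pool_layout)
  layout <- build_pools(basis)
  if (!is.null(basis$response_sample))
    layout <- refine_pools(layout, basis, refine_threshold)
  layout
}

#' Run one network variant on an image
#'
#' Executes the shared layer-1 stage (filtering and rectification), the
#' variant's second layer, surround suppression, and -- except for the fully
#' connected network, whose single suppressed map is the output -- the
#' combination stage (plain iteration below `comb$cluster_threshold` maps,
#' clustered combination at or above it).
#'
#' @param image Grayscale matrix in `[0, 1]`, or a `scene`.
#' @param basis A back-projected `topo_basis`.
#' @param spec A [variant_spec()].
#' @param sup A [suppression_params()] (any unit; resolved against the basis
#'   and image here).
#' @param comb A [combine_params()].
#' @param layout Optional explicit `pool_layout` for the invariant variant.
#' @param features Optional precomputed rectified `feature_stack` (lets
#'   drivers share layer 1 across variants).
#' @return A `saliency_map` with `strategy` and `rf_size` attributes.
#' @export
run_variant <- function(image, basis, spec = variant_spec("invariant"),
                        sup = suppression_params(), comb = combine_params(),
                        layout = NULL, features = NULL) {
  stopifnot(inherits(basis, "topo_basis"), inherits(spec, "variant_spec"))
  if (inherits(image, "scene")) image <- image$image
  if (is.null(features)) features <- rectify(extract_features(image, basis))
  if (!isTRUE(features$rectified)) stop("features must be rectified")
  supx <- resolve_suppression(sup, rf_size = basis$patch_side,
                              image_shape = dim(image))
  # a single conspicuity map needs no inter-map combination and is returned
  # directly (the fully connected architecture is the canonical case)
  finish <- function(cs, strategy) {
    if (dim(cs$maps)[3L] == 1L) new_saliency_map(cs$maps[, , 1L], "single_map")
    else combine_saliency(cs, strategy, comb)
  }
  out <- switch(spec$kind,
    invariant = {
      if (is.null(layout)) layout <- basis_layout(basis)
      cs <- conspicuity_stack(pool_features(features, layout), supx)
      finish(cs, "auto")
    },
    no_invariance = {
      cs <- conspicuity_stack(features, supx)
      finish(cs, "auto")
    },
    fully_connected = {
      all_layout <- structure(list(pools = list(seq_len(nrow(basis$filters))),
                                   center_index = 1L, centers = NULL,
                                   pool_side = NA_integer_, stride = NA_integer_,
                                   overlap = NA_integer_,
                                   grid_shape = basis$grid_shape,
                                   refined = FALSE,
                                   correlation_threshold = NA_real_),
                              class = "pool_layout")
      cs <- conspicuity_stack(pool_features(features, all_layout), supx)
      new_saliency_map(cs$maps[, , 1L], "fully_connected")
    },
    randomly_connected = {
      def <- basis_layout(basis)
      gs <- spec$random_group_size
      if (is.null(gs)) gs <- min(max(lengths(def$pools)), nrow(basis$filters))
      ng <- if (is.null(spec$n_groups)) length(def$pools) else spec$n_groups
      rl <- random_pool_layout(basis, gs, ng, spec$seed)
      cs <- conspicuity_stack(pool_features(features, rl), supx)
      finish(cs, "auto")
    },
    stop(sprintf("unknown variant kind '%s'", spec$kind)))
  attr(out, "rf_size") <- basis$patch_side
  attr(out, "variant") <- spec$kind
  out
}
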