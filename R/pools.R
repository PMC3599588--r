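# Layer-2 pool layout on the topographic torus and its correlation-based
# refinement.

#' Build the layer-2 pooling layout on the torus grid
#'
#' Places square `pool_side x pool_side` neighbourhoods every
#' `pool_side - overlap` filters along each torus axis starting at the grid
#' origin, so adjacent pools share `overlap` filters per axis and the number
#' of pools per axis is `ceiling(grid_dim / stride)`. With the model's 5x5
#' pools overlapping by 2, a 10x10 grid yields 16 pools, 14x14 yields 25, and
#' 24x24 yields 64.
#'
#' @param basis A `topo_basis`, or a `c(rows, cols)` grid shape.
#' @param pool_side Odd pool side in filters. Default 5.
#' @param overlap Filters shared by adjacent pools per axis (`< pool_side`).
#'   Default 2.
#' @return A `pool_layout`: `pools` (list of filter-index vectors),
#'   `center_index` (filter index at each pool centre), `centers` (grid
#'   coordinates), `pool_side`, `stride`, `grid_shape`, `refined` flag.
#' @export
build_pools <- function(basis, pool_side = 5L, overlap = 2L) {
  grid_shape <- if (inherits(basis, "topo_basis")) basis$grid_shape
                else as.integer(basis)
  if (pool_side %% 2L != 1L) stop("pool_side must be odd")
  if (overlap >= pool_side) stop("overlap must be smaller than pool_side")
  if (pool_side > min(grid_shape)) stop("pool_side exceeds the grid dimension")
  stride <- pool_side - overlap
  h <- (pool_side - 1L) %/% 2L
  off <- -h:h
  starts_r <- seq.int(0L, grid_shape[1L] - 1L, by = stride)
  starts_c <- seq.int(0L, grid_shape[2L] - 1L, by = stride)
  pools <- list(); centers <- NULL; center_index <- integer(0)
  for (r0 in starts_r) for (c0 in starts_c) {
    rows <- (r0 + h + off) %% grid_shape[1L] + 1L
    cols <- (c0 + h + off) %% grid_shape[2L] + 1L
    members <- sort(as.vector(outer(rows, cols, grid_index,
                                    grid_shape = grid_shape)))
    cen_r <- (r0 + h) %% grid_shape[1L] + 1L
    cen_c <- (c0 + h) %% grid_shape[2L] + 1L
    pools[[length(pools) + 1L]] <- members
    centers <- rbind(centers, c(cen_r, cen_c))
    center_index <- c(center_index, grid_index(cen_r, cen_c, grid_shape))
  }
  structure(list(pools = pools, center_index = center_index, centers = centers,
                 pool_side = as.integer(pool_side), stride = stride,
                 overlap = as.integer(overlap), grid_shape = grid_shape,
                 refined = FALSE, correlation_threshold = NA_real_),
            class = "pool_layout")
}

# Squared-response matrix (observations x filters) from either a
# feature_stack (per-image ensemble) or a filter x observation response
# matrix (training ensemble cached on the basis).
squared_responses <- function(x) {
  if (inherits(x, "feature_stack")) {
    d <- dim(x$maps)
    matrix(x$maps, d[1L] * d[2L], d[3L])^2
  } else if (inherits(x, "topo_basis")) {
    if (is.null(x$response_sample))
      stop("basis carries no cached training responses")
    t(x$response_sample)^2
  } else if (is.matrix(x)) {
    t(x)^2
  } else stop("expected a feature_stack, topo_basis, or response matrix")
}

#' Energy correlation between two filters' responses
#'
#' The high-order similarity `corr(SF_i^2, SF_c^2)`: the Pearson correlation
#' of the squared responses, `[E(SF_i^2 SF_c^2) - E(SF_i^2) E(SF_c^2)] /
#' sqrt(D(SF_i^2) D(SF_c^2))`. Squaring discards phase, so the statistic
#' measures co-activation of energy -- high for filters with similar
#' orientation and frequency tuning regardless of phase.
#'
#' @param x A `feature_stack` (expectations over the image pixels), a
#'   `topo_basis` with cached training responses (expectations over the
#'   training ensemble), or a `n_filters x n_obs` response matrix.
#' @param i,c Filter indices.
#' @return Correlation in `[-1, 1]`; defined as 0 (with a warning) when
#'   either squared response has zero variance.
#' @export
pool_similarity <- function(x, i, c) {
  S <- squared_responses(x)
  if (i < 1L || c < 1L || i > ncol(S) || c > ncol(S)) stop("filter index out of range")
  vi <- stats::var(S[, i]); vc <- stats::var(S[, c])
  if (vi == 0 || vc == 0) {
    warning("zero variance of a squared response; similarity defined as 0")
    return(0)
  }
  stats::cor(S[, i], S[, c])
}

#' Refine pools by energy correlation with the pool centre
#'
#' Keeps, in each pool, the centre filter plus the members whose
#' [pool_similarity()] with the centre is at least `threshold`. Pooling on the
#' raw torus neighbourhood cannot avoid grouping a few filters with strongly
#' different tuning; pruning them makes each pool a coherent invariant
#' descriptor (similar orientation/frequency, different phases).
#'
#' @param layout An unrefined `pool_layout`.
#' @param x Response ensemble: a `topo_basis` with cached training responses
#'   (the default, filter-intrinsic mode), a `feature_stack`, or a response
#'   matrix.
#' @param threshold Correlation threshold. Default 0.1.
#' @return The refined `pool_layout`.
#' @export
refine_pools <- function(layout, x, threshold = 0.1) {
  stopifnot(inherits(layout, "pool_layout"))
  if (isTRUE(layout$refined)) stop("layout is already refined")
  S <- squared_responses(x)
  v <- apply(S, 2L, stats::var)
  Cm <- suppressWarnings(stats::cor(S))
  Cm[is.na(Cm)] <- 0
  Cm[v == 0, ] <- 0; Cm[, v == 0] <- 0
  diag(Cm)[v > 0] <- 1
  layout$pools <- lapply(seq_along(layout$pools), function(j) {
    cen <- layout$center_index[j]
    members <- layout$pools[[j]]
    keep <- members[Cm[members, cen] >= threshold]
    sort(union(cen, keep))
  })
  layout$refined <- TRUE
  layout$correlation_threshold <- threshold
  layout
}

#' @export
print.pool_layout <- function(x, ...) {
  sizes <- lengths(x$pools)
  cat(sprintf("<pool_layout> %d pools of %dx%d (stride %d) on a %dx%d torus%s; mean size %.1f\n",
              length(x$pools), x$pool_side, x$pool_side, x$stride,
              x$grid_shape[1L], x$grid_shape[2L],
              if (x$refined) sprintf(", refined at %.2g", x$correlation_threshold) else "",
              mean(sizes)))
  invisible(x)
}
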