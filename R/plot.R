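# Base-graphics display helpers.

show_gray <- function(m, main = "", ...) {
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), main = main, ...)
}

#' @export
plot.saliency_map <- function(x, ...) {
  show_gray(norm_peak(unclass(x)),
            main = sprintf("saliency (%s)", attr(x, "strategy")), ...)
  invisible(x)
}

#' @export
plot.scene <- function(x, show_target = TRUE, ...) {
  show_gray(x$image, main = x$params$kind, ...)
  if (show_target && any(x$target_mask)) {
    idx <- which(x$target_mask, arr.ind = TRUE)
    cy <- mean(idx[, 1L]); cx <- mean(idx[, 2L])
    graphics::points((cx - 1) / (ncol(x$image) - 1),
                     1 - (cy - 1) / (nrow(x$image) - 1),
                     col = "red", cex = 3)
  }
  invisible(x)
}

#' Display a basis set as a filter mosaic
#'
#' Tiles the back-projected pixel filters in their topographic grid order,
#' each tile contrast-normalized, so the emergent orientation/frequency
#' topography is visible.
#'
#' @param x A back-projected `topo_basis`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.topo_basis <- function(x, ...) {
  if (is.null(x$pixel_filters)) stop("back-project the basis first")
  s <- x$patch_side; g <- x$grid_shape
  mosaic <- matrix(0, g[1L] * (s + 1L) + 1L, g[2L] * (s + 1L) + 1L)
  for (i in seq_len(nrow(x$pixel_filters))) {
    f <- matrix(x$pixel_filters[i, ], s, s)
    rng <- max(abs(f)); if (rng > 0) f <- f / (2 * rng) + 0.5
    co <- grid_coords(g)[i, ]
    r0 <- (co[1L] - 1L) * (s + 1L) + 2L; c0 <- (co[2L] - 1L) * (s + 1L) + 2L
    mosaic[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- f
  }
  show_gray(mosaic, main = sprintf("%d filters on %dx%d torus",
                                   nrow(x$pixel_filters), g[1L], g[2L]), ...)
  invisible(x)
}
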