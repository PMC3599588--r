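# Evaluation metrics: correct detection rate, top-m segment criterion with
# its binomial chance level, and ROC area against fixation maps.

#' Detect the target of a scene from a saliency map
#'
#' A hit is scored when the global argmax of the map falls within the
#' target mask dilated by `tolerance` pixels (Euclidean). Ties at the
#' maximum are broken in row-major order with a warning; an all-zero map is
#' a miss (flagged).
#'
#' @param map A `saliency_map` (or matrix) the same size as the scene image.
#' @param scene A `scene` with a non-empty `target_mask`.
#' @param tolerance Dilation radius in pixels. Default: half the layer-1
#'   receptive-field size recorded on the map (pooling enlarges effective
#'   receptive fields, so exact-pixel argmax would under-credit), else 4.
#' @return One-row tibble: `hit`, `arg_row`, `arg_col`, `n_ties`,
#'   `all_zero`.
#' @export
detect_target <- function(map, scene, tolerance = NULL) {
  stopifnot(inherits(scene, "scene"))
  if (!any(scene$target_mask)) stop("scene has an empty target mask")
  if (is.null(tolerance)) {
    rf <- attr(map, "rf_size")
    tolerance <- if (!is.null(rf)) rf / 2 else 4
  }
  m <- unclass(map)
  if (all(m == 0)) {
    warning("all-zero saliency map; scored as a miss")
    return(tibble::tibble(hit = FALSE, arg_row = NA_integer_,
                          arg_col = NA_integer_, n_ties = 0L, all_zero = TRUE))
  }
  am <- argmax_rowmajor(m)
  if (am$n_ties > 1L)
    warning(sprintf("%d tied maxima; first in row-major order used", am$n_ties))
  tgt <- which(scene$target_mask, arr.ind = TRUE)
  d2 <- min((tgt[, 1L] - am$row)^2 + (tgt[, 2L] - am$col)^2)
  tibble::tibble(hit = d2 <= tolerance^2, arg_row = am$row, arg_col = am$col,
                 n_ties = am$n_ties, all_zero = FALSE)
}

#' Correct detection rate over a set of scenes
#'
#' Runs a model on every scene and averages [detect_target()] hits: the
#' fraction of scenes whose saliency maximum falls on the target.
#'
#' @param runner Function mapping a `scene` to a `saliency_map`.
#' @param scenes Non-empty list of `scene`s.
#' @param tolerance Passed to [detect_target()].
#' @return A `detection_result`: list with `rate` and the per-scene
#'   `records` tibble.
#' @export
detection_rate <- function(runner, scenes, tolerance = NULL) {
  if (length(scenes) == 0L) stop("no scenes supplied")
  records <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    rec <- detect_target(runner(scenes[[i]]), scenes[[i]], tolerance)
    rec$scene <- i
    rec
  }))
  structure(list(rate = mean(records$hit), records = records),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> rate %.3f over %d scenes\n",
              x$rate, nrow(x$records)))
  invisible(x)
}

#' Top-m segment detection criterion
#'
#' Scores every labelled segment by its saliency (maximum over the segment's
#' pixels by default), ranks all `m + n` segments, and declares a correct
#' detection when at least `ceiling(fraction_required * m)` of the `m`
#' top-ranked segments are object segments, where `m` is the scene's object
#' segment count. Rank ties are broken by lower segment id.
#'
#' @param map Saliency map matrix.
#' @param scene A `scene` with labelled segments.
#' @param fraction_required Required object fraction of the top-m. Default
#'   0.7.
#' @param score `"max"` (default) or `"mean"` segment saliency.
#' @return Logical: correct detection or not.
#' @export
topm_detection <- function(map, scene, fraction_required = 0.7,
                           score = c("max", "mean")) {
  stopifnot(inherits(scene, "scene"))
  score <- match.arg(score)
  segs <- scene$segments
  ids <- unique(segs$id)
  m_obj <- length(unique(segs$id[segs$is_object]))
  if (m_obj == 0L) stop("scene has no object segments")
  v <- as.vector(unclass(map))
  lab <- as.vector(scene$segment_labels)
  sal <- vapply(ids, function(id) {
    px <- v[lab == id]
    if (length(px) == 0L) return(-Inf)   # fully occluded segment
    if (score == "max") max(px) else mean(px)
  }, numeric(1))
  is_obj <- vapply(ids, function(id) any(segs$is_object[segs$id == id]), logical(1))
  top <- order(-sal, ids)[seq_len(m_obj)]
  sum(is_obj[top]) >= ceiling(fraction_required * m_obj)
}

#' Chance probability of the top-m criterion under random ranking
#'
#' The binomial chance model for scoring at least 7 object segments among the
#' 10 top-ranked ones when ranks are uniformly random:
#' `C(10, 7) * (m / (m + n))^7 * (n / (m + n))^3`, with `m` object and `n`
#' background segments. (Sampling without replacement would make this
#' hypergeometric; the binomial form is the conventional approximation and
#' the one evaluated here.)
#'
#' @param m Object segment count (> 0).
#' @param n Background segment count (> 0).
#' @return The chance probability.
#' @export
random_detection_probability <- function(m, n) {
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  p <- m / (m + n)
  choose(10, 7) * p^7 * (1 - p)^3
}

#' ROC area of a saliency map against fixations
#'
#' Area under the ROC curve for classifying fixated vs non-fixated pixels by
#' thresholding the saliency map (computed as the Mann-Whitney statistic via
#' \pkg{pROC}). Fixations may be a logical matrix, a fixation-density matrix
#' (binarized at `density_quantile`), or an `(x, y)` coordinate table.
#'
#' @param map Saliency map matrix.
#' @param fixations Logical matrix, numeric density matrix, or a two-column
#'   matrix/data frame of `(x, y)` pixel coordinates.
#' @param density_quantile Quantile at which a density is binarized. Default
#'   0.95.
#' @return AUC in `[0, 1]`.
#' @export
roc_area <- function(map, fixations, density_quantile = 0.95) {
  m <- unclass(map)
  if (is.matrix(fixations) && !is.logical(fixations) &&
      ncol(fixations) == 2L && !all(dim(fixations) == dim(m))) {
    fixations <- as.data.frame(fixations)
  }
  if (is.data.frame(fixations)) {
    fm <- matrix(FALSE, nrow(m), ncol(m))
    fm[cbind(round(fixations[[2L]]), round(fixations[[1L]]))] <- TRUE
    fixations <- fm
  }
  if (!is.logical(fixations)) {
    thr <- stats::quantile(fixations, density_quantile)
    fixations <- fixations > thr
  }
  if (!any(fixations) || all(fixations))
    stop("fixation map must contain both fixated and non-fixated pixels")
  as.numeric(pROC::auc(pROC::roc(response = as.vector(fixations),
                                 predictor = as.vector(m),
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}
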