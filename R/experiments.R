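# Experiment drivers tying stimuli, variants, and evaluation together.

#' Pop-out detection rates across orientation noise and network variants
#'
#' Generates `n_scenes` orientation-singleton arrays per noise level, shares
#' the layer-1 features of each scene across all requested variants, and
#' scores each variant's correct detection rate.
#'
#' @param basis A back-projected `topo_basis`.
#' @param delta_thetas Orientation-noise half-widths in degrees. Default
#'   `c(0, 10, 20, 30, 45)`.
#' @param variants Character vector of [variant_spec()] kinds.
#' @param n_scenes Scenes per noise level. Default 20.
#' @param sup,comb Suppression / combination parameters.
#' @param seed Base seed; scene `i` at noise level `j` is seeded
#'   deterministically from it.
#' @param ... Passed to [gen_orientation_array()].
#' @return A tibble: `delta_theta`, `variant`, `rate`, `n_scenes`.
#' @export
popout_experiment <- function(basis, delta_thetas = c(0, 10, 20, 30, 45),
                              variants = c("invariant", "no_invariance",
                                           "fully_connected",
                                           "randomly_connected"),
                              n_scenes = 20L, sup = suppression_params(),
                              comb = combine_params(), seed = 1L, ...) {
  layout <- basis_layout(basis)
  rows <- list()
  for (j in seq_along(delta_thetas)) {
    hits <- stats::setNames(numeric(length(variants)), variants)
    for (i in seq_len(n_scenes)) {
      scene <- gen_orientation_array(noise_halfwidth = delta_thetas[j],
                                     seed = seed + 1000L * j + i, ...)
      feats <- rectify(extract_features(scene$image, basis))
      for (v in variants) {
        map <- run_variant(scene$image, basis, variant_spec(v, seed = seed),
                           sup, comb, layout = layout, features = feats)
        hit <- suppressWarnings(detect_target(map, scene)$hit)
        hits[v] <- hits[v] + hit
      }
    }
    for (v in variants)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        delta_theta = delta_thetas[j], variant = v,
        rate = unname(hits[v]) / n_scenes, n_scenes = n_scenes)
  }
  do.call(rbind, rows)
}

#' Top-m detection rate across segment SNRs
#'
#' For every SNR ratio, builds one object-in-texture scene per
#' object x texture pair (3 x 6 = 18 by default), runs the invariant model,
#' and scores the top-m criterion.
#'
#' @param basis A back-projected `topo_basis`.
#' @param snr_ratios Background-per-object segment ratios. Default
#'   `c(2, 2.5, 3, 3.5, 4)` (SNRs 1:2 to 1:4).
#' @param objects,textures Stimulus kinds crossed to form the scene set.
#' @param sup Suppression parameters; the default uses image-fraction units
#'   (2.5% of the image size) with a strong suppression coefficient
#'   (`alpha = 3.5`), the regime used for cluttered edge and contour
#'   stimuli, where the texture must cancel itself completely for the
#'   object contour to dominate the segment ranking.
#' @param comb Combination parameters.
#' @param seed Base seed.
#' @param ... Passed to [gen_object_in_texture()].
#' @return A tibble: `snr_ratio`, `rate`, `n_scenes`, plus per-scene records
#'   in `attr(, "records")`.
#' @export
snr_experiment <- function(basis, snr_ratios = c(2, 2.5, 3, 3.5, 4),
                           objects = c("pear", "banana", "onion"),
                           textures = c("brick", "wave", "diag", "cross",
                                        "arc", "rand"),
                           sup = suppression_params(sigma_ex = 0.025,
                                                    alpha = 3.5,
                                                    unit = "frac"),
                           comb = combine_params(), seed = 1L, ...) {
  layout <- basis_layout(basis)
  spec <- variant_spec("invariant")
  rows <- list(); recs <- list()
  for (j in seq_along(snr_ratios)) {
    correct <- 0L; ns <- 0L
    for (ob in objects) for (tx in textures) {
      ns <- ns + 1L
      scene <- gen_object_in_texture(ob, tx, snr_ratio = snr_ratios[j],
                                     seed = seed + 1000L * j + ns, ...)
      map <- run_variant(scene$image, basis, spec, sup, comb, layout = layout)
      ok <- topm_detection(map, scene)
      correct <- correct + ok
      recs[[length(recs) + 1L]] <- tibble::tibble(
        snr_ratio = snr_ratios[j], object = ob, texture = tx, correct = ok)
    }
    rows[[j]] <- tibble::tibble(snr_ratio = snr_ratios[j],
                                rate = correct / ns, n_scenes = ns)
  }
  out <- do.call(rbind, rows)
  attr(out, "records") <- do.call(rbind, recs)
  out
}

#' Contour-structure suite
#'
#' Runs a variant on the solid, illusory, and noisy s-curve scenes and
#' summarizes how much saliency falls on the contour: the ratio of mean
#' saliency on object-segment pixels to mean saliency elsewhere.
#'
#' @param basis A back-projected `topo_basis`.
#' @param variant Variant kind. Default `"invariant"`.
#' @param sup,comb Parameters; the default suppression uses image-fraction
#'   units (3% of image size), the regime quoted for contour stimuli.
#' @param seed Integer seed.
#' @param ... Passed to [gen_contour_scene()].
#' @return A tibble (`kind`, `on_contour`, `off_contour`, `contrast`) with
#'   the maps in `attr(, "maps")`.
#' @export
contour_experiment <- function(basis, variant = "invariant",
                               sup = suppression_params(sigma_ex = 0.03,
                                                        unit = "frac"),
                               comb = combine_params(), seed = 1L, ...) {
  layout <- basis_layout(basis)
  kinds <- c("solid_s", "illusory_s", "noisy_s")
  maps <- list(); rows <- list()
  for (k in kinds) {
    scene <- gen_contour_scene(k, seed = seed, ...)
    map <- run_variant(scene$image, basis, variant_spec(variant), sup, comb,
                       layout = layout)
    on <- mean(map[scene$target_mask])
    off <- mean(map[!scene$target_mask])
    maps[[k]] <- map
    rows[[k]] <- tibble::tibble(kind = k, on_contour = on, off_contour = off,
                                contrast = if (off > 0) on / off else Inf)
  }
  out <- do.call(rbind, rows)
  attr(out, "maps") <- maps
  out
}

#' Compare combination strategies on one conspicuity stack
#'
#' Applies the iterate, sum, and max strategies to the same stack and
#' reports each result's activation sparsity (fraction of pixels above 10%
#' of the map maximum) and local-maximum count.
#'
#' @param stack A `conspicuity_stack` (or `H x W x n` array).
#' @param comb A [combine_params()].
#' @return A tibble (`strategy`, `active_fraction`, `n_local_maxima`) with
#'   the maps in `attr(, "maps")`.
#' @export
combine_compare <- function(stack, comb = combine_params()) {
  strategies <- c("iterate", "sum", "max")
  maps <- list(); rows <- list()
  for (s in strategies) {
    map <- combine_saliency(stack, s, comb)
    maps[[s]] <- map
    rows[[s]] <- tibble::tibble(
      strategy = s,
      active_fraction = mean(map > 0.1 * max(map)),
      n_local_maxima = count_local_maxima(unclass(map)))
  }
  out <- do.call(rbind, rows)
  attr(out, "maps") <- maps
  out
}
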