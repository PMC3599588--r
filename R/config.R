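# Reproducible run configuration and the command-style entry points.

#' Build a run configuration
#'
#' A serializable record of everything a training or saliency run needs;
#' written/read as YAML so a run can be re-executed bit-identically.
#'
#' @param basis_path Path to a saved basis (output of [cmd_train()]).
#' @param image_dir Directory of training images (PNG/TIFF/PGM); `NULL`
#'   falls back to the procedural training textures.
#' @param patch_side,n_patches,retained_dim Preprocessing settings.
#' @param n_filters,grid_shape,n_iterations,batch_size,step_size,decay_every
#'   Learning settings (see [learning_config()]).
#' @param variant Variant kind for saliency runs.
#' @param sigma_ex,sigma_unit,alpha Suppression settings.
#' @param refine_threshold Pool-refinement correlation threshold.
#' @param seed Master seed.
#' @param output_dir Where artifacts are written.
#' @return A `run_config` list.
#' @export
run_config <- function(basis_path = NULL, image_dir = NULL,
                       patch_side = 16L, n_patches = 50000L,
                       retained_dim = 196L, n_filters = 196L,
                       grid_shape = c(14L, 14L), n_iterations = 500L,
                       batch_size = 1000L, step_size = 0.1,
                       decay_every = 100L, variant = "invariant",
                       sigma_ex = 2, sigma_unit = "rf", alpha = 1.8,
                       refine_threshold = 0.1, seed = 1L,
                       output_dir = ".") {
  structure(list(basis_path = basis_path, image_dir = image_dir,
                 patch_side = as.integer(patch_side),
                 n_patches = as.integer(n_patches),
                 retained_dim = as.integer(retained_dim),
                 n_filters = as.integer(n_filters),
                 grid_shape = as.integer(grid_shape),
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size), step_size = step_size,
                 decay_every = as.integer(decay_every), variant = variant,
                 sigma_ex = sigma_ex, sigma_unit = sigma_unit, alpha = alpha,
                 refine_threshold = refine_threshold, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for `write_config`).
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Train and persist a basis set
#'
#' Runs the full training protocol: sample patches from the training images
#' (or the procedural textures), whiten with PCA reduction, learn the
#' topographic basis, back-project to pixel filters, build and refine the
#' layer-2 pool layout on the training ensemble, and save the artifact
#' (with its training-loss log and config hash) under `output_dir`.
#'
#' @param config A [run_config()].
#' @return The trained `topo_basis`, invisibly; saved to
#'   `file.path(config$output_dir, "basis.rds")`.
#' @export
cmd_train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  images <- if (is.null(config$image_dir)) {
    gen_texture_images(seed = config$seed)
  } else {
    if (!dir.exists(config$image_dir))
      stop(sprintf("image directory '%s' not found", config$image_dir))
    files <- list.files(config$image_dir, "\\.(png|tif|tiff|pgm)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0L) stop("no readable images in image_dir")
    lapply(files, read_gray_image)
  }
  patches <- sample_patches(images, config$patch_side, config$n_patches,
                            seed = config$seed)
  tf <- fit_whitening(patches, config$retained_dim)
  white <- whiten(patches, tf)
  ns <- min(5L, min(config$grid_shape))
  if (ns %% 2L == 0L) ns <- ns - 1L
  lc <- learning_config(config$n_filters, config$grid_shape,
                        neighbourhood_side = ns,
                        step_size = config$step_size,
                        n_iterations = config$n_iterations,
                        batch_size = config$batch_size,
                        decay_every = config$decay_every, seed = config$seed)
  basis <- learn_basis(white, lc)
  basis <- backproject_filters(basis, tf)
  ps <- min(5L, min(config$grid_shape))
  if (ps %% 2L == 0L) ps <- ps - 1L
  layout <- build_pools(basis, pool_side = ps, overlap = min(2L, ps - 1L))
  basis$pool_layout <- refine_pools(layout, basis, config$refine_threshold)
  basis$config_hash <- config_hash(config)
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  save_basis(basis, file.path(config$output_dir, "basis.rds"))
  utils::write.csv(
    data.frame(iteration = seq_along(basis$training_loss),
               loss = basis$training_loss),
    file.path(config$output_dir, "training_log.csv"), row.names = FALSE)
  invisible(basis)
}

#' Compute and write a saliency map for an image
#'
#' Loads the basis named by the config, runs the configured variant, and
#' writes the map as PNG plus a JSON provenance sidecar (variant,
#' parameters, config hash).
#'
#' @param image_path Input image (PNG/TIFF/PGM).
#' @param config A [run_config()] with `basis_path` set.
#' @return The `saliency_map`, invisibly.
#' @export
cmd_saliency <- function(image_path, config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(image_path)) stop(sprintf("cannot read '%s'", image_path))
  basis <- load_basis(config$basis_path)
  image <- read_gray_image(image_path)
  sup <- suppression_params(sigma_ex = config$sigma_ex, alpha = config$alpha,
                            unit = config$sigma_unit)
  map <- run_variant(image, basis, variant_spec(config$variant), sup,
                     combine_params(seed = config$seed))
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  stem <- file.path(config$output_dir,
                    paste0(tools::file_path_sans_ext(basename(image_path)),
                           "_saliency"))
  write_map_png(map, paste0(stem, ".png"), raw_path = paste0(stem, ".rds"))
  jsonlite::write_json(
    list(image = image_path, variant = config$variant,
         sigma_ex = config$sigma_ex, sigma_unit = config$sigma_unit,
         alpha = config$alpha, seed = config$seed,
         config_hash = config_hash(config)),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(map)
}

#' Run a named experiment protocol
#'
#' Drives the stimulus generators, variants, and metrics over a named
#' protocol grid and writes the summary as CSV + JSON under `output_dir`.
#'
#' @param name One of `"popout_sweep"`, `"snr_curve"`, `"contour_suite"`,
#'   `"combine_compare"`.
#' @param config A [run_config()] with `basis_path` set.
#' @param ... Passed to the underlying experiment driver.
#' @return The summary tibble, invisibly.
#' @export
cmd_experiment <- function(name, config, ...) {
  stopifnot(inherits(config, "run_config"))
  basis <- load_basis(config$basis_path)
  res <- switch(name,
    popout_sweep = popout_experiment(basis, seed = config$seed, ...),
    snr_curve = snr_experiment(basis, seed = config$seed, ...),
    contour_suite = contour_experiment(basis, seed = config$seed, ...),
    combine_compare = {
      scene <- gen_orientation_array(noise_halfwidth = 30, seed = config$seed)
      feats <- rectify(extract_features(scene$image, basis))
      supx <- resolve_suppression(
        suppression_params(sigma_ex = config$sigma_ex, alpha = config$alpha,
                           unit = config$sigma_unit),
        rf_size = basis$patch_side, image_shape = dim(scene$image))
      cs <- conspicuity_stack(pool_features(feats, basis_layout(basis)), supx)
      combine_compare(cs, combine_params(seed = config$seed), ...)
    },
    stop(sprintf("unknown experiment '%s'", name)))
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  utils::write.csv(res, file.path(config$output_dir, paste0(name, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(list(experiment = name, seed = config$seed,
                            config_hash = config_hash(config),
                            summary = res),
                       file.path(config$output_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
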