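# Synthetic psychophysical stimuli with machine-readable ground truth.
#
# A scene is an anti-aliased grayscale image in [0, 1] (background 0,
# foreground 1) plus a target mask, an integer segment-label map, and a
# per-segment table flagging object vs background segments. All generators
# are pure functions of their parameters and seed.

new_scene <- function(image, target_mask, segment_labels, segments, params,
                      seed) {
  structure(list(image = image, target_mask = target_mask,
                 segment_labels = segment_labels, segments = segments,
                 params = params, seed = seed),
            class = "scene")
}

# Render a table of bar segments (cx, cy in pixel coordinates, theta in
# degrees measured from the x/column axis, length, width) onto a canvas.
# Anti-aliased coverage; labels take the id of the last segment covering a
# pixel with coverage > 0.5 (later rows overwrite earlier ones).
render_segments <- function(segs, shape, value = 1) {
  img <- matrix(0, shape[1L], shape[2L])
  labels <- matrix(0L, shape[1L], shape[2L])
  for (k in seq_len(nrow(segs))) {
    th <- deg2rad(segs$theta[k])
    hl <- segs$length[k] / 2; hw <- segs$width[k] / 2
    rad <- ceiling(sqrt(hl^2 + hw^2)) + 1L
    r0 <- max(1L, floor(segs$cy[k] - rad)); r1 <- min(shape[1L], ceiling(segs$cy[k] + rad))
    c0 <- max(1L, floor(segs$cx[k] - rad)); c1 <- min(shape[2L], ceiling(segs$cx[k] + rad))
    if (r0 > r1 || c0 > c1) next
    dy <- (r0:r1) - segs$cy[k]; dx <- (c0:c1) - segs$cx[k]
    u <- outer(dy * sin(th), dx * cos(th), "+")       # along the bar axis
    v <- outer(dy * cos(th), -dx * sin(th), "+")      # across the bar
    cov <- pmin(pmax(hl + 0.5 - abs(u), 0), 1) * pmin(pmax(hw + 0.5 - abs(v), 0), 1)
    blk <- img[r0:r1, c0:c1]
    img[r0:r1, c0:c1] <- pmax(blk, cov * value)
    lab <- labels[r0:r1, c0:c1]
    lab[cov > 0.5] <- segs$id[k]
    labels[r0:r1, c0:c1] <- lab
  }
  list(image = img, labels = labels)
}

segments_tbl <- function(id, is_object, cx, cy, theta, length, width, ...) {
  tibble::tibble(id = as.integer(id), is_object = is_object, cx = cx, cy = cy,
                 theta = theta %% 180, length = length, width = width, ...)
}

#' Orientation-singleton search array
#'
#' A grid of bars: one target at a random cell with random orientation
#' `theta_t`, distractors orthogonal to it plus uniform orientation noise in
#' `[-noise_halfwidth, +noise_halfwidth]` degrees. Positions are jittered
#' within cells. The classic pop-out stimulus: with zero noise the singleton
#' pops out; noise makes the task harder for models without orientation
#' invariance.
#'
#' @param grid `c(rows, cols)` of array elements. Default `c(8, 8)`.
#' @param spacing Cell size in pixels (canvas is `grid * spacing`). Default 32.
#' @param bar_length,bar_width Bar geometry in pixels. Defaults 16 / 3.
#' @param noise_halfwidth Orientation-noise half-range in degrees, at most
#'   45. Default 0.
#' @param seed Integer seed.
#' @return A `scene`.
#' @export
gen_orientation_array <- function(grid = c(8L, 8L), spacing = 32L,
                                  bar_length = 16, bar_width = 3,
                                  noise_halfwidth = 0, seed = 1L) {
  if (noise_halfwidth > 45) stop("noise_halfwidth must not exceed 45 degrees")
  jit <- spacing / 2 - bar_length / 2 - 1
  if (jit < 0) stop("bars would overlap at the given spacing")
  shape <- as.integer(grid) * as.integer(spacing)
  n <- prod(grid)
  segs <- with_seed(seed, {
    tgt <- sample.int(n, 1L)
    theta_t <- stats::runif(1, 0, 180)
    theta <- theta_t + 90 + stats::runif(n, -noise_halfwidth, noise_halfwidth)
    theta[tgt] <- theta_t
    cells <- expand.grid(row = seq_len(grid[1L]), col = seq_len(grid[2L]))
    segments_tbl(id = seq_len(n), is_object = seq_len(n) == tgt,
                 cx = (cells$col - 0.5) * spacing + stats::runif(n, -jit, jit),
                 cy = (cells$row - 0.5) * spacing + stats::runif(n, -jit, jit),
                 theta = theta, length = bar_length, width = bar_width)
  })
  rend <- render_segments(segs, shape)
  new_scene(rend$image, rend$labels == which(segs$is_object), rend$labels, segs,
            list(kind = "orientation_array", grid = grid, spacing = spacing,
                 bar_length = bar_length, bar_width = bar_width,
                 noise_halfwidth = noise_halfwidth,
                 theta_target = segs$theta[segs$is_object]),
            seed)
}

#' Composite-element search array
#'
#' A grid of identical multi-bar composite elements with `n_deviant` elements
#' deviating in their internal configuration. Templates give each bar of an
#' element as an orientation offset `dtheta` (degrees, relative to the
#' scene's base orientation) and a perpendicular offset `dv` (pixels) from
#' the element centre; the defaults are a parallel bar pair for the
#' background and an orthogonal (crossed) pair for the deviant. The template
#' geometry approximates the composite-stimulus class rather than any
#' specific printed figure.
#'
#' @inheritParams gen_orientation_array
#' @param bar_length,bar_width Per-bar geometry. Defaults 12 / 2.
#' @param n_deviant Number of deviating elements. Default 1; 0 gives a
#'   target-free scene (`target_mask` empty, flagged in `params`).
#' @param templates List with `background` and `deviant` data frames
#'   (`dtheta`, `dv`).
#' @return A `scene`; all bars of a deviant element share its segment id.
#' @export
gen_composite_array <- function(grid = c(8L, 8L), spacing = 32L,
                                bar_length = 12, bar_width = 2,
                                n_deviant = 1L, seed = 1L,
                                templates = list(
                                  background = data.frame(dtheta = c(0, 0),
                                                          dv = c(-3.5, 3.5)),
                                  deviant = data.frame(dtheta = c(0, 90),
                                                       dv = c(-3.5, 3.5)))) {
  shape <- as.integer(grid) * as.integer(spacing)
  n <- prod(grid)
  if (n_deviant > n) stop("more deviants than array elements")
  jit <- spacing / 2 - bar_length / 2 - max(abs(c(templates$background$dv,
                                                  templates$deviant$dv))) - 1
  if (jit < 0) stop("composite elements would overlap at the given spacing")
  out <- with_seed(seed, {
    dev <- if (n_deviant > 0L) sample.int(n, n_deviant) else integer(0)
    theta0 <- stats::runif(1, 0, 180)
    cells <- expand.grid(row = seq_len(grid[1L]), col = seq_len(grid[2L]))
    ex <- (cells$col - 0.5) * spacing + stats::runif(n, -jit, jit)
    ey <- (cells$row - 0.5) * spacing + stats::runif(n, -jit, jit)
    rows <- lapply(seq_len(n), function(e) {
      tpl <- if (e %in% dev) templates$deviant else templates$background
      th <- deg2rad(theta0)
      segments_tbl(id = rep(e, nrow(tpl)), is_object = rep(e %in% dev, nrow(tpl)),
                   cx = ex[e] - tpl$dv * sin(th), cy = ey[e] + tpl$dv * cos(th),
                   theta = theta0 + tpl$dtheta,
                   length = bar_length, width = bar_width)
    })
    list(segs = do.call(rbind, rows), dev = dev, theta0 = theta0)
  })
  rend <- render_segments(out$segs, shape)
  new_scene(rend$image, matrix(rend$labels %in% out$dev, shape[1L], shape[2L]),
            rend$labels, out$segs,
            list(kind = "composite_array", grid = grid, spacing = spacing,
                 n_deviant = n_deviant, has_target = n_deviant > 0L,
                 theta0 = out$theta0),
            seed)
}

# The s-shaped path and its analytic tangent (degrees from the x axis).
s_path <- function(t, shape, margin = 32) {
  h <- shape[1L]; w <- shape[2L]
  amp <- (w - 2 * margin) / 2.5
  list(x = w / 2 + amp * sin(2 * pi * t),
       y = margin + (h - 2 * margin) * t,
       theta = atan2(h - 2 * margin, amp * 2 * pi * cos(2 * pi * t)) * 180 / pi)
}

#' Contour scenes: solid, illusory, and noisy s-curves
#'
#' `solid_s` renders a continuous s-shaped curve; `illusory_s` places
#' `n_elements` short collinear bars along the same path, tangent-aligned,
#' separated by `gap` pixels; `noisy_s` adds randomly placed and oriented
#' background bars at `background_density` bars per pixel. Contour elements
#' are labelled as object segments. These probe Gestalt good-continuation
#' saliency rather than singleton pop-out.
#'
#' @param kind One of `"solid_s"`, `"illusory_s"`, `"noisy_s"`.
#' @param n_elements Bars along the contour. Default 14.
#' @param gap Gap between successive contour bars in pixels. Default 4.
#' @param background_density Background bars per pixel (`noisy_s`). Default
#'   `8e-4`.
#' @param shape Canvas `c(H, W)`. Default `c(256, 256)`.
#' @param bar_width Bar width. Default 2.
#' @param seed Integer seed.
#' @return A `scene`; object segments carry their path parameter `t`.
#' @export
gen_contour_scene <- function(kind = c("solid_s", "illusory_s", "noisy_s"),
                              n_elements = 14L, gap = 4, background_density = 8e-4,
                              shape = c(256L, 256L), bar_width = 2, seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (kind == "solid_s") {
    t <- seq(0, 1, length.out = 8L * n_elements)
    p <- s_path(t, shape)
    step <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    segs <- segments_tbl(id = rep(1L, length(t) - 1L), is_object = TRUE,
                         cx = (p$x[-1] + p$x[-length(t)]) / 2,
                         cy = (p$y[-1] + p$y[-length(t)]) / 2,
                         theta = atan2(diff(p$y), diff(p$x)) * 180 / pi,
                         length = step + 1, width = bar_width,
                         t = (t[-1] + t[-length(t)]) / 2)
  } else {
    t <- seq(0, 1, length.out = n_elements)
    p <- s_path(t, shape)
    chord <- mean(sqrt(diff(p$x)^2 + diff(p$y)^2))
    len <- max(2, chord - gap)
    segs <- segments_tbl(id = seq_len(n_elements), is_object = TRUE,
                         cx = p$x, cy = p$y, theta = p$theta,
                         length = len, width = bar_width, t = t)
    if (kind == "noisy_s") {
      n_bg <- round(background_density * prod(shape))
      bg <- with_seed(seed, segments_tbl(
        id = n_elements + seq_len(n_bg), is_object = FALSE,
        cx = stats::runif(n_bg, 4, shape[2L] - 4),
        cy = stats::runif(n_bg, 4, shape[1L] - 4),
        theta = stats::runif(n_bg, 0, 180),
        length = len, width = bar_width, t = NA_real_))
      segs <- rbind(bg, segs)   # contour drawn on top
    }
  }
  rend <- render_segments(segs, shape)
  obj_ids <- segs$id[segs$is_object]
  new_scene(rend$image, matrix(rend$labels %in% obj_ids, shape[1L], shape[2L]),
            rend$labels, segs,
            list(kind = kind, n_elements = n_elements, gap = gap,
                 background_density = if (kind == "noisy_s") background_density else 0),
            seed)
}

# Closed/open outline points for the procedural "fruit-like" objects
# (synthetic stand-ins for real object edge images).
object_outline <- function(object, n_segments) {
  phi <- seq(0, 2 * pi, length.out = n_segments + 1L)
  switch(object,
    pear = {
      r <- 10 * (1 + 0.25 * sin(phi) + 0.08 * sin(2 * phi))
      list(x = r * cos(phi), y = r * sin(phi), closed = TRUE)
    },
    onion = {
      r <- 10.5 * (1 + 0.12 * sin(3 * phi))
      list(x = r * cos(phi), y = r * sin(phi), closed = TRUE)
    },
    banana = {
      # crescent: outer and inner arcs sharing endpoints
      n_out <- ceiling((n_segments + 1L) / 2); n_in <- n_segments + 2L - n_out
      ao <- seq(deg2rad(15), deg2rad(255), length.out = n_out)
      ai <- seq(deg2rad(255), deg2rad(15), length.out = n_in)
      list(x = c(13 * cos(ao), 9 * cos(ai)),
           y = c(13 * sin(ao), 9 * sin(ai)), closed = TRUE)
    },
    stop(sprintf("unknown object '%s'", object)))
}

# Candidate background segments for the procedural textures; each returns a
# data frame (cx, cy, theta, length) with well over 120 candidates on a
# 64 x 64 canvas.
texture_candidates <- function(texture, shape) {
  h <- shape[1L]; w <- shape[2L]
  grid_segs <- function(step, theta, len) {
    pos <- seq(3, max(h, w) - 3, by = step)
    along <- seq(3, max(h, w) - 3, by = len + 2)
    do.call(rbind, lapply(pos, function(p)
      data.frame(cx = if (theta == 0) along else p,
                 cy = if (theta == 0) p else along,
                 theta = theta, length = len)))
  }
  segs <- switch(texture,
    brick = {
      horiz <- grid_segs(5, 0, 5)
      joints <- do.call(rbind, lapply(seq_along(seq(3, h - 3, by = 5)), function(i) {
        y <- seq(3, h - 3, by = 5)[i]
        xs <- seq(if (i %% 2 == 0) 4 else 8, w - 3, by = 7)
        data.frame(cx = xs, cy = y + 2.5, theta = 90, length = 3.5)
      }))
      rbind(horiz, joints)
    },
    wave = {
      rows <- seq(3, h - 3, by = 4)
      do.call(rbind, lapply(rows, function(y0) {
        xs <- seq(3, w - 3, by = 4)
        yc <- y0 + 2.5 * sin(2 * pi * xs / 20)
        th <- atan2(2.5 * (2 * pi / 20) * cos(2 * pi * xs / 20), 1) * 180 / pi
        data.frame(cx = xs, cy = yc, theta = th, length = 4)
      }))
    },
    diag = {
      offs <- seq(-h, w, by = 3)
      do.call(rbind, lapply(offs, function(o) {
        xs <- seq(3, w - 3, by = 4)
        ys <- xs - o
        ok <- ys > 3 & ys < h - 3
        if (!any(ok)) return(NULL)
        data.frame(cx = xs[ok], cy = ys[ok], theta = 45, length = 4)
      }))
    },
    cross = rbind(grid_segs(5, 0, 4), grid_segs(5, 90, 4)),
    arc = {
      radii <- seq(5, sqrt(h^2 + w^2) - 4, by = 4)
      do.call(rbind, lapply(radii, function(r) {
        n <- max(4L, round(pi * r / 6))
        a <- seq(0, pi / 2, length.out = n)
        x <- r * cos(a); y <- r * sin(a)
        ok <- x > 3 & x < w - 3 & y > 3 & y < h - 3
        if (!any(ok)) return(NULL)
        data.frame(cx = x[ok], cy = y[ok], theta = (a[ok] * 180 / pi) + 90,
                   length = 4.5)
      }))
    },
    rand = {
      n <- 320L
      data.frame(cx = stats::runif(n, 3, w - 3), cy = stats::runif(n, 3, h - 3),
                 theta = stats::runif(n, 0, 180), length = 5)
    },
    stop(sprintf("unknown texture '%s'", texture)))
  segs[segs$cx > 2 & segs$cx < w - 2 & segs$cy > 2 & segs$cy < h - 2, ]
}

#' Object-in-texture scene at a given segment SNR
#'
#' Builds an edge-image style scene: a procedural closed-contour object of
#' about `n_object_segments` short segments placed in the centre region of
#' the canvas, over a procedural texture whose candidate segments are
#' subsampled to `n = round(m * snr_ratio)` background segments (an SNR of
#' `m:n`, e.g. `snr_ratio = 3` gives 1:3). The objects and textures are
#' synthetic stand-ins for object/texture edge photographs.
#'
#' @param object `"pear"`, `"banana"`, or `"onion"`.
#' @param texture `"brick"`, `"wave"`, `"diag"`, `"cross"`, `"arc"`, `"rand"`.
#' @param snr_ratio Background segments per object segment. Default 3.
#' @param shape Canvas `c(H, W)`. Default `c(64, 64)`; the object occupies
#'   the central half-sized region.
#' @param n_object_segments Approximate object segment count. Default 30.
#' @param segment_width Rendered segment width. Default 1.
#' @param seed Integer seed (object rotation, texture jitter, subsampling).
#' @return A `scene`; `params` records `m` and `n`.
#' @export
gen_object_in_texture <- function(object = c("pear", "banana", "onion"),
                                  texture = c("brick", "wave", "diag",
                                              "cross", "arc", "rand"),
                                  snr_ratio = 3, shape = c(64L, 64L),
                                  n_object_segments = 30L, segment_width = 1,
                                  seed = 1L) {
  object <- match.arg(object); texture <- match.arg(texture)
  shape <- as.integer(shape)
  out <- with_seed(seed, {
    ol <- object_outline(object, n_object_segments)
    rot <- stats::runif(1, 0, 2 * pi)
    x <- ol$x * cos(rot) - ol$y * sin(rot)
    y <- ol$x * sin(rot) + ol$y * cos(rot)
    half <- min(shape) / 4
    sc <- (half - 2) / max(abs(c(x, y)))   # object fits the central region
    x <- x * sc + shape[2L] / 2; y <- y * sc + shape[1L] / 2
    np <- length(x)
    obj <- segments_tbl(id = seq_len(np - 1L), is_object = TRUE,
                        cx = (x[-1] + x[-np]) / 2, cy = (y[-1] + y[-np]) / 2,
                        theta = atan2(diff(y), diff(x)) * 180 / pi,
                        length = pmax(sqrt(diff(x)^2 + diff(y)^2), 1.5),
                        width = segment_width)
    m <- nrow(obj)
    n_bg <- round(m * snr_ratio)
    cand <- texture_candidates(texture, shape)
    cand$cx <- cand$cx + stats::runif(nrow(cand), -0.5, 0.5)
    cand$cy <- cand$cy + stats::runif(nrow(cand), -0.5, 0.5)
    # the object edge image replaces the central region: texture segments
    # whose extent reaches into it are removed before subsampling
    ch <- shape[1L] / 2; cw <- shape[2L] / 2
    margin <- cand$length / 2 + 1
    inside <- abs(cand$cx - cw) < cw / 2 + margin &
      abs(cand$cy - ch) < ch / 2 + margin
    cand <- cand[!inside, ]
    if (n_bg > nrow(cand))
      stop(sprintf("requested %d background segments but texture '%s' offers %d",
                   n_bg, texture, nrow(cand)))
    pick <- cand[sample.int(nrow(cand), n_bg), ]
    bg <- segments_tbl(id = m + seq_len(n_bg), is_object = FALSE,
                       cx = pick$cx, cy = pick$cy, theta = pick$theta,
                       length = pick$length, width = segment_width)
    list(segs = rbind(bg, obj), m = m, n = n_bg)   # object drawn on top
  })
  rend <- render_segments(out$segs, shape)
  obj_ids <- out$segs$id[out$segs$is_object]
  new_scene(rend$image, matrix(rend$labels %in% obj_ids, shape[1L], shape[2L]),
            rend$labels, out$segs,
            list(kind = "object_in_texture", object = object, texture = texture,
                 snr_ratio = snr_ratio, m = out$m, n = out$n),
            seed)
}

#' Procedural naturalistic training textures
#'
#' Block-structured oriented line fields: each image is tiled into blocks of
#' locally parallel bars at a random orientation per block, so sampled
#' patches see oriented structure at all orientations -- enough statistical
#' structure for the basis learner to develop oriented, topographically
#' organized filters without any external image corpus.
#'
#' @param n_images Number of images. Default 6.
#' @param size Image side in pixels. Default 128.
#' @param block Block side in pixels. Default 32.
#' @param bar_spacing Spacing of parallel bars within a block. Default 5.
#' @param seed Integer seed.
#' @return A list of `size x size` matrices in `[0, 1]`.
#' @export
gen_texture_images <- function(n_images = 6L, size = 128L, block = 32L,
                               bar_spacing = 5, seed = 1L) {
  with_seed(seed, lapply(seq_len(n_images), function(i) {
    nb <- ceiling(size / block)
    # stratified orientations: every image covers [0, 180) evenly, so the
    # learned basis has no sampling gaps in its orientation tuning
    ths <- sample((seq_len(nb^2) - stats::runif(nb^2)) / nb^2 * 180)
    segs <- do.call(rbind, lapply(seq_len(nb^2), function(b) {
      br <- (b - 1L) %/% nb; bc <- (b - 1L) %% nb
      th <- ths[b]
      nlines <- ceiling(block * 1.5 / bar_spacing)
      offs <- (seq_len(nlines) - (nlines + 1) / 2) * bar_spacing
      cx0 <- bc * block + block / 2; cy0 <- br * block + block / 2
      thr <- deg2rad(th)
      segments_tbl(id = rep(0L, nlines), is_object = FALSE,
                   cx = cx0 - offs * sin(thr), cy = cy0 + offs * cos(thr),
                   theta = th, length = block * 1.2, width = 1.5)
    }))
    segs$id <- seq_len(nrow(segs))
    render_segments(segs, c(size, size))$image
  }))
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s, %dx%d, %d segments (%d object), target pixels %d\n",
              x$params$kind, nrow(x$image), ncol(x$image), nrow(x$segments),
              sum(x$segments$is_object), sum(x$target_mask)))
  invisible(x)
}
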