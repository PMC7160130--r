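#' Composition configuration
#'
#' Parameters of the domain-randomized scene generator.  Defaults follow the
#' study conditions: a 1024 px virtual canvas center-cropped to 768 px,
#' placements rejected when more than a 0.25 fraction of the candidate
#' sprite would cover already-placed seeds, at most 70 pasting trials per
#' scene, and a 1 px-sigma Gaussian blur of the pasted perimeter.
#'
#' @param canvas_size virtual canvas side (px).
#' @param out_size final image side after border cropping (px).
#' @param overlap_threshold maximum tolerated overlap fraction in [0, 1].
#' @param max_trials pasting trials per scene; a rejected placement consumes
#'   a trial.
#' @param blur_sigma Gaussian sigma (px) for the perimeter blur; 0 disables.
#' @param rng_seed default seed used by [generate_scene()] when none is given.
#' @return A `compose_config` list.
#' @export
compose_config <- function(canvas_size = 1024L, out_size = 768L,
                           overlap_threshold = 0.25, max_trials = 70L,
                           blur_sigma = 1.0, rng_seed = NULL) {
  if (out_size > canvas_size)
    stop_seedpheno("out_size must be <= canvas_size", "config_error")
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stop_seedpheno("overlap_threshold must lie in [0, 1]", "config_error")
  if (max_trials < 0) stop_seedpheno("max_trials must be >= 0", "config_error")
  structure(list(canvas_size = as.integer(canvas_size),
                 out_size = as.integer(out_size),
                 overlap_threshold = overlap_threshold,
                 max_trials = as.integer(max_trials),
                 blur_sigma = blur_sigma, rng_seed = rng_seed),
            class = "compose_config")
}

#' Fraction of a candidate mask already covered by existing seeds
#'
#' The placement-acceptance statistic: |candidate intersect occupancy| /
#' |candidate|.  The denominator is the candidate sprite's own support, so
#' one scalar decides each trial.
#'
#' @param candidate_mask,occupancy logical matrices of equal shape.
#' @return Overlap fraction in [0, 1].
#' @export
overlap_fraction <- function(candidate_mask, occupancy) {
  stopifnot(all(dim(candidate_mask) == dim(occupancy)))
  n <- sum(candidate_mask)
  if (n == 0L)
    stop_seedpheno("candidate mask is empty: overlap fraction undefined",
                   "undefined_fraction")
  sum(candidate_mask & occupancy) / n
}

# Bilinear rotation of an H x W x C stack about its center, output raster
# expanded to hold the rotated image, zero fill outside the source.
.rot_bilinear <- function(stack, angle) {
  th <- angle * pi / 180
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; nc <- dim(stack)[3L]
  ct <- cos(th); st <- sin(th)
  wout <- ceiling(abs(w * ct) + abs(h * st))
  hout <- ceiling(abs(w * st) + abs(h * ct))
  X <- rep(seq_len(wout) - (wout + 1) / 2, each = hout)
  Y <- rep(seq_len(hout) - (hout + 1) / 2, times = wout)
  xs <- ct * X + st * Y + (w + 1) / 2
  ys <- -st * X + ct * Y + (h + 1) / 2
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  # corner linear indices (clamped; out-of-bounds weights zeroed), one
  # gather per corner shared across all channels
  corner <- function(yi, xi, wgt) {
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    li <- (pmin.int(pmax.int(xi, 1), w) - 1) * h + pmin.int(pmax.int(yi, 1), h)
    list(li = li, wgt = wgt * ok)
  }
  c00 <- corner(y0, x0, (1 - fx) * (1 - fy))
  c10 <- corner(y0, x0 + 1, fx * (1 - fy))
  c01 <- corner(y0 + 1, x0, (1 - fx) * fy)
  c11 <- corner(y0 + 1, x0 + 1, fx * fy)
  sm <- matrix(stack, h * w, nc)
  v <- sm[c00$li, , drop = FALSE] * c00$wgt +
       sm[c10$li, , drop = FALSE] * c10$wgt +
       sm[c01$li, , drop = FALSE] * c01$wgt +
       sm[c11$li, , drop = FALSE] * c11$wgt
  array(v, dim = c(hout, wout, nc))
}

# Separable Gaussian blur with zero padding at the borders.
.gblur2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pass <- function(mat, along_rows) {
    h <- nrow(mat); w <- ncol(mat)
    acc <- matrix(0, h, w)
    for (o in -r:r) {
      ki <- k[o + r + 1L]
      if (along_rows) {  # shift vertically (within columns)
        src <- max(1L, 1L - o):min(h, h - o)
        acc[src + o, ] <- acc[src + o, , drop = FALSE] +
          ki * mat[src, , drop = FALSE]
      } else {
        src <- max(1L, 1L - o):min(w, w - o)
        acc[, src + o] <- acc[, src + o, drop = FALSE] +
          ki * mat[, src, drop = FALSE]
      }
    }
    acc
  }
  pass(pass(m, TRUE), FALSE)
}

# Rotate a sprite by `angle` degrees (bilinear, raster expanded), returning
# pixels + fractional alpha cropped to the tight support bbox.
rotate_sprite <- function(sprite, angle) {
  if (angle %% 360 == 0)
    return(list(pixels = sprite$pixels, alpha = sprite$alpha))
  stack <- array(0, dim = c(dim(sprite$alpha), 4L))
  stack[, , 1:3] <- sprite$pixels; stack[, , 4L] <- sprite$alpha
  rot <- .rot_bilinear(stack, angle)
  alpha <- rot[, , 4L]
  alpha[alpha < 0] <- 0
  alpha[alpha > 1] <- 1
  bb <- mask_bbox(alpha > 0.5)
  if (is.null(bb)) bb <- mask_bbox(alpha > 0)
  rows <- (bb["y0"] + 1L):bb["y1"]; cols <- (bb["x0"] + 1L):bb["x1"]
  list(pixels = rot[rows, cols, 1:3, drop = FALSE],
       alpha = alpha[rows, cols, drop = FALSE])
}

# Gaussian-blur the alpha channel inside a band around the support
# boundary, leaving the interior fully opaque and the far exterior fully
# transparent.
blur_alpha_perimeter <- function(alpha, sigma) {
  if (sigma <= 0) return(alpha)
  bl <- .gblur2d(alpha, sigma)
  # restrict to the band the Gaussian actually reaches (~3 sigma around
  # the support boundary); interior and far exterior stay untouched
  inband <- abs(bl - alpha) > 1e-3
  if (!any(inband)) return(alpha)
  out <- alpha
  out[inband] <- pmin(1, pmax(0, bl[inband]))
  out
}

# Alpha-composite sprite pixels over a canvas patch.
.blend_patch <- function(patch, pixels, alpha) {
  for (ch in 1:3)
    patch[, , ch] <- alpha * pixels[, , ch] + (1 - alpha) * patch[, , ch]
  patch
}

# Mutable scene accumulator used during composition.  An environment so
# that repeated pastes update the canvas in place instead of copying it.
new_scene_state <- function(background) {
  n <- nrow(background)
  state <- new.env(parent = emptyenv())
  state$canvas <- background
  state$label_map <- matrix(0L, n, n)
  state$instances <- list()
  class(state) <- "scene_state"
  state
}

#' Paste a rotated sprite onto a scene state
#'
#' Alpha-composites the sprite over the canvas at the given top-left corner
#' after blurring its perimeter opacity, and writes the new instance id into
#' the label map wherever the sprite's support lands (foreground
#' replacement: earlier instances lose those pixels).
#'
#' @param state scene state from `new_scene_state()` or a previous paste.
#' @param rot rotated sprite: list with `pixels` and `alpha`.
#' @param x,y 0-based top-left canvas coordinates of the sprite raster.
#' @param blur_sigma perimeter blur sigma (px).
#' @param cultivar tag recorded on the instance.
#' @return Updated scene state.
#' @export
paste_sprite <- function(state, rot, x, y, blur_sigma = 1.0,
                         cultivar = "unknown") {
  h <- nrow(rot$alpha); w <- ncol(rot$alpha)
  H <- nrow(state$label_map); W <- ncol(state$label_map)
  if (x < 0 || y < 0 || x + w > W || y + h > H)
    stop_seedpheno("placement outside canvas", "contract_violation")
  alpha <- blur_alpha_perimeter(rot$alpha, blur_sigma)
  rows <- (y + 1L):(y + h); cols <- (x + 1L):(x + w)
  patch <- state$canvas[rows, cols, , drop = FALSE]
  patch <- .blend_patch(patch, rot$pixels, alpha)
  state$canvas[rows, cols, ] <- patch
  supp <- alpha > 0.5
  id <- length(state$instances) + 1L
  win <- state$label_map[rows, cols]
  win[supp] <- id
  state$label_map[rows, cols] <- win
  state$instances[[id]] <- list(instance_id = id, cultivar = cultivar,
                                pasted_area_px = sum(supp),
                                window = c(x, y, x + w, y + h))
  state
}

#' Generate one domain-randomized scene
#'
#' Pastes a random background tile onto the canvas, then runs up to
#' `max_trials` pasting trials.  Each trial holds a randomly drawn sprite
#' rotated by a uniform random angle; a random in-canvas position is drawn
#' and the placement is accepted iff the fraction of the sprite's support
#' falling on already-placed seeds is at most `overlap_threshold`.  A
#' rejected position consumes the trial and the next trial redraws only the
#' position for the same rotated sprite.  Finally the borders are cropped
#' to `out_size`.
#'
#' @param pool a `sprite_pool`.
#' @param config a [compose_config()].
#' @param rng_seed seed for this scene; falls back to `config$rng_seed`.
#' @return A `seed_scene`: list with `image` (out RGB array), `label_map`
#'   (integer matrix, 0 = background), `instances` (per-instance id,
#'   cultivar, bbox, visible area, local mask), `config`, `rng_seed`.
#' @export
generate_scene <- function(pool, config = compose_config(), rng_seed = NULL) {
  if (length(pool$sprites) == 0L || length(pool$backgrounds) == 0L)
    stop_seedpheno("sprite pool and background pool must be non-empty",
                   "config_error")
  seed <- rng_seed %||% config$rng_seed %||%
    stop_seedpheno("no rng_seed given", "config_error")
  with_seed(seed, {
    bg <- pool$backgrounds[[sample.int(length(pool$backgrounds), 1L)]]
    if (nrow(bg) != config$canvas_size)
      stop_seedpheno("background tile does not match canvas size",
                     "config_error")
    # Local canvas/label_map so window assignments update in place; the
    # paste arithmetic is shared with paste_sprite() via the helpers.
    canvas <- bg + 0
    W <- config$canvas_size
    label_map <- matrix(0L, W, W)
    instances <- list()
    pending <- NULL
    trials <- 0L
    while (trials < config$max_trials) {
      trials <- trials + 1L
      if (is.null(pending)) {
        sp <- pool$sprites[[sample.int(length(pool$sprites), 1L)]]
        angle <- stats::runif(1, 0, 360)
        pending <- rotate_sprite(sp, angle)
        pending$cultivar <- sp$cultivar
        pending$alpha <- blur_alpha_perimeter(pending$alpha, config$blur_sigma)
        pending$supp <- pending$alpha > 0.5
      }
      h <- nrow(pending$alpha); w <- ncol(pending$alpha)
      if (w > W || h > W) { pending <- NULL; next }
      x <- sample.int(W - w + 1L, 1L) - 1L
      y <- sample.int(W - h + 1L, 1L) - 1L
      rows <- (y + 1L):(y + h); cols <- (x + 1L):(x + w)
      occ_win <- label_map[rows, cols] > 0L
      frac <- if (!any(occ_win)) 0 else overlap_fraction(pending$supp, occ_win)
      if (frac <= config$overlap_threshold) {
        canvas[rows, cols, ] <-
          .blend_patch(canvas[rows, cols, , drop = FALSE], pending$pixels,
                       pending$alpha)
        id <- length(instances) + 1L
        win <- label_map[rows, cols]
        win[pending$supp] <- id
        label_map[rows, cols] <- win
        instances[[id]] <- list(instance_id = id, cultivar = pending$cultivar,
                                pasted_area_px = sum(pending$supp),
                                window = c(x, y, x + w, y + h),
                                overlap_at_paste = frac)
        pending <- NULL
      }
    }
    crop_borders(list(canvas = canvas, label_map = label_map,
                      instances = instances), config, seed)
  })
}

#' Center-crop a composed scene to the output size
#'
#' Replicates real scans where seeds adjacent to the image border are cut
#' off: the canvas and label map are center-cropped, instance masks are
#' cropped accordingly, instances left with zero visible pixels are dropped
#' and bounding boxes are recomputed.  Instances merely cut by the new
#' border are retained.
#'
#' @param state scene state at canvas size.
#' @param config a [compose_config()] (uses `canvas_size`, `out_size`).
#' @param rng_seed recorded on the scene for provenance.
#' @return A `seed_scene`.
#' @export
crop_borders <- function(state, config, rng_seed = NA_integer_) {
  if (config$out_size > config$canvas_size)
    stop_seedpheno("out_size exceeds canvas_size", "contract_violation")
  off <- (config$canvas_size - config$out_size) %/% 2L
  idx <- (off + 1L):(off + config$out_size)
  image <- state$canvas[idx, idx, , drop = FALSE]
  label_map <- state$label_map[idx, idx]
  instances <- list()
  for (inst in state$instances) {
    # search only the instance's paste window, shifted into crop coordinates
    wx0 <- max(0L, inst$window[1L] - off); wy0 <- max(0L, inst$window[2L] - off)
    wx1 <- min(config$out_size, inst$window[3L] - off)
    wy1 <- min(config$out_size, inst$window[4L] - off)
    if (wx1 <= wx0 || wy1 <= wy0) next
    sub <- label_map[(wy0 + 1L):wy1, (wx0 + 1L):wx1, drop = FALSE]
    mk <- sub == inst$instance_id
    bb <- mask_bbox(mk)
    if (is.null(bb)) next
    bb <- bb + c(wx0, wy0, wx0, wy0)
    local <- mk[(bb["y0"] - wy0 + 1L):(bb["y1"] - wy0),
                (bb["x0"] - wx0 + 1L):(bb["x1"] - wx0), drop = FALSE]
    instances[[length(instances) + 1L]] <- list(
      instance_id = inst$instance_id, cultivar = inst$cultivar,
      pasted_area_px = inst$pasted_area_px,
      overlap_at_paste = inst$overlap_at_paste %||% NA_real_,
      bbox = unname(bb), area = sum(local), mask = local
    )
  }
  structure(list(image = image, label_map = label_map, instances = instances,
                 config = config, rng_seed = rng_seed),
            class = "seed_scene")
}

#' Full-size visible mask of one scene instance
#'
#' @param scene a `seed_scene`.
#' @param instance_id id as stored in the label map.
#' @return Logical matrix the size of the scene.
#' @export
instance_mask <- function(scene, instance_id) {
  scene$label_map == instance_id
}

#' @export
print.seed_scene <- function(x, ...) {
  cat(sprintf("<seed_scene> %dx%d px, %d instances, seed %s\n",
              nrow(x$label_map), ncol(x$label_map), length(x$instances),
              format(x$rng_seed)))
  invisible(x)
}

#' Scene instances as a tibble
#'
#' One row per visible instance with id, cultivar, bbox coordinates
#' (0-based half-open), visible and pasted pixel areas, and the local
#' binary mask as a list-column.
#'
#' @param scene a `seed_scene`.
#' @return A tibble.
#' @export
scene_instances <- function(scene) {
  if (length(scene$instances) == 0L)
    return(tibble::tibble(instance_id = integer(), cultivar = character(),
                          x0 = integer(), y0 = integer(), x1 = integer(),
                          y1 = integer(), area = integer(),
                          pasted_area_px = integer(),
                          overlap_at_paste = numeric(), mask = list()))
  purrr::map_dfr(scene$instances, function(i)
    tibble::tibble(instance_id = i$instance_id, cultivar = i$cultivar,
                   x0 = i$bbox[1L], y0 = i$bbox[2L], x1 = i$bbox[3L],
                   y1 = i$bbox[4L], area = i$area,
                   pasted_area_px = i$pasted_area_px,
                   overlap_at_paste = i$overlap_at_paste %||% NA_real_,
                   mask = list(i$mask)))
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_images` (image PNG, 16-bit label-map TIFF) pairs plus COCO
#' instance annotations and a manifest.  Each image uses an independent RNG
#' substream derived deterministically from `rng_seed`, so any single image
#' can be regenerated in isolation.
#'
#' @param pool a `sprite_pool`.
#' @param config a [compose_config()].
#' @param n_images number of scenes.
#' @param rng_seed master seed.
#' @param out_dir output directory.
#' @param write_images set `FALSE` to skip the PNG/TIFF rasters (annotations
#'   and manifest are still produced), e.g. for shape audits.
#' @param write_annotations set `FALSE` to also skip the COCO file and keep
#'   only the manifest (fastest audit mode).
#' @return The manifest, invisibly: list with `images` tibble (id, file_name,
#'   width, height, seed), `config`, `rng_seed`, `annotation_file`.
#' @export
generate_dataset <- function(pool, config, n_images, rng_seed, out_dir,
                             write_images = TRUE, write_annotations = TRUE) {
  if (n_images < 1L) stop_seedpheno("n_images must be >= 1", "config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_seedpheno(paste("cannot create", out_dir), "io_error")
  rows <- vector("list", n_images)
  anns <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- derive_stream_seed(rng_seed, i)
    scene <- generate_scene(pool, config, rng_seed = si)
    img_file <- sprintf("img_%05d.png", i)
    lab_file <- sprintf("lab_%05d.tif", i)
    if (write_images) {
      png::writePNG(scene$image, file.path(out_dir, img_file))
      tiff::writeTIFF(scene$label_map / 65535, file.path(out_dir, lab_file),
                      bits.per.sample = 16L, compression = "none")
    }
    rows[[i]] <- tibble::tibble(id = i, file_name = img_file,
                                label_file = lab_file,
                                width = config$out_size,
                                height = config$out_size, seed = si,
                                n_instances = length(scene$instances))
    if (write_annotations) anns[[i]] <- scene_instances(scene)
  }
  images <- dplyr::bind_rows(rows)
  ann_path <- file.path(out_dir, "annotations.json")
  if (write_annotations) write_coco(images, anns, ann_path)
  manifest <- list(images = images, config = unclass(config),
                   rng_seed = rng_seed, annotation_file = "annotations.json")
  jsonlite::write_json(
    list(rng_seed = rng_seed, config = unclass(config),
         annotation_file = "annotations.json",
         images = images),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
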