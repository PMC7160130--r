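#' Construct a seed sprite
#'
#' A sprite is a background-free seed cutout: an RGB raster, a per-pixel
#' opacity raster, and a cultivar tag.  Pixels outside the opacity support
#' are black (0,0,0), mirroring the background-removal convention used when
#' preparing seed image pools from scans.
#'
#' @param pixels numeric H x W x 3 array in [0, 1].
#' @param alpha numeric H x W matrix in [0, 1].
#' @param cultivar cultivar tag (scalar character).
#' @param source_id identifier of the originating scan or generator draw.
#' @return An object of class `seed_sprite` with fields `pixels`, `alpha`,
#'   `cultivar`, `source_id` and `area_px` (count of pixels with alpha > 0.5).
#' @export
seed_sprite <- function(pixels, alpha, cultivar = "unknown", source_id = "") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L,
            is.matrix(alpha), all(dim(alpha) == dim(pixels)[1:2]))
  area <- sum(alpha > 0.5)
  if (area < 1L) stop_seedpheno("sprite has empty alpha support", "empty_sprite")
  structure(
    list(pixels = pixels, alpha = alpha, cultivar = as.character(cultivar),
         source_id = as.character(source_id), area_px = area),
    class = "seed_sprite"
  )
}

#' @export
print.seed_sprite <- function(x, ...) {
  d <- dim(x$alpha)
  cat(sprintf("<seed_sprite> %dx%d px, cultivar '%s', support %d px\n",
              d[1L], d[2L], x$cultivar, x$area_px))
  invisible(x)
}

#' Extract a seed sprite from a scan region
#'
#' Separates one seed from an approximately uniform background by chroma
#' distance: a pixel is foreground when its Euclidean RGB distance from the
#' reference background color exceeds `tolerance`.  The largest connected
#' foreground component is kept, interior holes are filled, the raster is
#' cropped to the tight bounding box of the support, and background pixels
#' are zeroed to (0,0,0).  Opacity is binary at this stage; fractional
#' opacity only arises later from the compositor's perimeter blur.
#'
#' @param scan_region numeric H x W x 3 array in [0, 1] holding one seed.
#' @param bg_color reference background RGB, length-3 numeric in [0, 1].
#'   Default `NULL` estimates it as the median color of the raster border.
#' @param tolerance chroma distance above which a pixel counts as
#'   foreground (default 60/255).
#' @param cultivar,source_id tags carried into the sprite.
#' @return A [seed_sprite()].
#' @export
extract_sprite <- function(scan_region, bg_color = NULL, tolerance = 60 / 255,
                           cultivar = "unknown", source_id = "") {
  stopifnot(length(dim(scan_region)) == 3L, dim(scan_region)[3L] == 3L)
  h <- dim(scan_region)[1L]; w <- dim(scan_region)[2L]
  if (is.null(bg_color)) {
    border <- rbind(scan_region[1L, , ], scan_region[h, , ],
                    scan_region[, 1L, ], scan_region[, w, ])
    bg_color <- apply(border, 2L, stats::median)
  }
  d2 <- (scan_region[, , 1L] - bg_color[1L])^2 +
        (scan_region[, , 2L] - bg_color[2L])^2 +
        (scan_region[, , 3L] - bg_color[3L])^2
  fg <- d2 > tolerance^2
  if (!any(fg)) stop_seedpheno("no foreground pixel: empty sprite", "empty_sprite")

  lab <- .from_ebi(EBImage::bwlabel(.to_ebi(fg * 1)))
  counts <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(counts)
  keep <- .from_ebi(EBImage::fillHull(.to_ebi(keep * 1))) > 0.5

  bb <- mask_bbox(keep)
  rows <- (bb["y0"] + 1L):bb["y1"]; cols <- (bb["x0"] + 1L):bb["x1"]
  alpha <- matrix(0, length(rows), length(cols))
  alpha[keep[rows, cols, drop = FALSE]] <- 1
  px <- scan_region[rows, cols, , drop = FALSE]
  px <- px * as.vector(alpha)  # zero background to (0,0,0)
  seed_sprite(px, alpha, cultivar = cultivar, source_id = source_id)
}

#' Generate a synthetic sprite and background pool
#'
#' Builds a fixture pool that stands in for a scanned seed-image pool:
#' elongated superellipse silhouettes grouped into cultivars, each cultivar
#' with its own size, aspect-ratio, squareness and color distribution, plus
#' multiplicative per-pixel noise for texture, and one or more uniform-color
#' background tiles.  Deterministic for a fixed `rng_seed`.
#'
#' Default geometry emulates cereal grains scanned at typical flatbed
#' resolution: semi-major axes of 30--80 px across cultivars, aspect ratios
#' 1.6--3.0, superellipse exponents 1.5--3.
#'
#' @param rng_seed integer seed controlling every random draw.
#' @param n_cultivars,per_cultivar pool layout; the scanned pools this
#'   emulates held 20 cultivars x 20 seeds = 400 sprites.
#' @param shape_params list overriding any of `size_range` (semi-major axis
#'   px), `aspect_range`, `exponent_range`, `noise_sd` (multiplicative
#'   texture), `size_cv` (within-cultivar size spread).
#' @param canvas_size side of the square background tiles (px).
#' @param n_backgrounds number of background tiles.
#' @param bg_color background RGB; default a scanner-blue chosen for
#'   chroma-key separability.
#' @return A `sprite_pool`: list with `sprites` (list of [seed_sprite()])
#'   and `backgrounds` (list of canvas-sized RGB arrays).
#' @export
make_fixture_pool <- function(rng_seed, n_cultivars = 20L, per_cultivar = 20L,
                              shape_params = list(), canvas_size = 1024L,
                              n_backgrounds = 4L,
                              bg_color = c(0.10, 0.25, 0.75)) {
  if (n_cultivars < 1L || per_cultivar < 1L || n_backgrounds < 1L)
    stop_seedpheno("counts must be >= 1", "config_error")
  p <- utils::modifyList(list(
    size_range = c(30, 80), aspect_range = c(1.6, 3.0),
    exponent_range = c(1.5, 3.0), noise_sd = 0.08, size_cv = 0.10
  ), shape_params)
  if (any(p$size_range <= 0) || any(p$aspect_range <= 0))
    stop_seedpheno("shape_params sizes must be positive", "config_error")

  with_seed(rng_seed, {
    sprites <- vector("list", n_cultivars * per_cultivar)
    k <- 0L
    for (ci in seq_len(n_cultivars)) {
      cname <- sprintf("cv%02d", ci)
      a_mean <- stats::runif(1, p$size_range[1L], p$size_range[2L])
      aspect <- stats::runif(1, p$aspect_range[1L], p$aspect_range[2L])
      expo <- stats::runif(1, p$exponent_range[1L], p$exponent_range[2L])
      base_col <- c(stats::runif(1, 0.55, 0.9), stats::runif(1, 0.45, 0.8),
                    stats::runif(1, 0.15, 0.45))
      for (si in seq_len(per_cultivar)) {
        a <- max(4, stats::rnorm(1, a_mean, p$size_cv * a_mean))
        b <- max(3, a / (aspect * stats::runif(1, 0.92, 1.08)))
        k <- k + 1L
        sprites[[k]] <- .superellipse_sprite(
          a, b, expo, base_col, p$noise_sd,
          cultivar = cname, source_id = sprintf("%s_%02d", cname, si)
        )
      }
    }
    backgrounds <- lapply(seq_len(n_backgrounds), function(i) {
      tile <- array(rep(bg_color, each = canvas_size^2),
                    dim = c(canvas_size, canvas_size, 3L))
      # faint per-tile shading so tiles are distinguishable
      tile + stats::rnorm(1, 0, 0.01)
    })
    structure(list(sprites = sprites, backgrounds = backgrounds),
              class = "sprite_pool")
  })
}

# Rasterize |x/a|^e + |y/b|^e <= 1 (long axis horizontal), colored with
# multiplicative pixel noise.  Consumes RNG; call under with_seed().
.superellipse_sprite <- function(a, b, expo, base_col, noise_sd,
                                 cultivar, source_id) {
  w <- 2L * ceiling(a) + 1L; h <- 2L * ceiling(b) + 1L
  xs <- seq_len(w) - (w + 1) / 2
  ys <- seq_len(h) - (h + 1) / 2
  inside <- outer(ys, xs, function(y, x)
    (abs(x) / a)^expo + (abs(y) / b)^expo <= 1)
  bb <- mask_bbox(inside)
  inside <- inside[(bb["y0"] + 1L):bb["y1"], (bb["x0"] + 1L):bb["x1"],
                   drop = FALSE]
  h <- nrow(inside); w <- ncol(inside)
  alpha <- matrix(0, h, w); alpha[inside] <- 1
  n <- h * w
  px <- array(0, dim = c(h, w, 3L))
  noise <- pmax(0.3, 1 + stats::rnorm(n, 0, noise_sd))
  for (ch in 1:3) px[, , ch] <- pmin(1, base_col[ch] * noise)
  px <- px * as.vector(alpha)
  seed_sprite(px, alpha, cultivar = cultivar, source_id = source_id)
}

#' @export
print.sprite_pool <- function(x, ...) {
  cvs <- unique(vapply(x$sprites, `[[`, "", "cultivar"))
  cat(sprintf("<sprite_pool> %d sprites (%d cultivars), %d backgrounds (%dpx)\n",
              length(x$sprites), length(cvs), length(x$backgrounds),
              nrow(x$backgrounds[[1L]])))
  invisible(x)
}

#' Validate seed-sprite invariants
#'
#' Checks that the opacity support is a single connected component, that
#' pixels outside the support are black, and that the support is non-empty.
#' Used by tests and by pool readers; errors on violation.
#'
#' @param sprite a [seed_sprite()].
#' @return `TRUE`, invisibly.
#' @export
validate_sprite <- function(sprite) {
  stopifnot(inherits(sprite, "seed_sprite"))
  supp <- sprite$alpha > 0.5
  if (!any(supp)) stop_seedpheno("empty alpha support", "invariant_violation")
  lab <- .from_ebi(EBImage::bwlabel(.to_ebi(supp * 1)))
  if (max(lab) != 1L)
    stop_seedpheno("alpha support is not a single connected component",
                   "invariant_violation")
  out <- sprite$alpha == 0
  for (ch in 1:3) {
    if (any(sprite$pixels[, , ch][out] != 0))
      stop_seedpheno("non-black pixel outside alpha support",
                     "invariant_violation")
  }
  invisible(TRUE)
}

#' Write / read a sprite pool on disk
#'
#' Sprites are stored one RGBA PNG each (`<cultivar>_<index>.png`, the
#' opacity in the alpha channel), backgrounds as `background_<i>.png`.
#'
#' @param pool a `sprite_pool`.
#' @param dir output directory, created if needed.
#' @return `write_pool()` the directory, invisibly; `read_pool()` a
#'   `sprite_pool`.
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (s in pool$sprites) {
    counts[[s$cultivar]] <- (counts[[s$cultivar]] %||% 0L) + 1L
    rgba <- array(0, dim = c(dim(s$alpha), 4L))
    rgba[, , 1:3] <- s$pixels; rgba[, , 4L] <- s$alpha
    png::writePNG(rgba, file.path(dir, sprintf("%s_%03d.png", s$cultivar,
                                               counts[[s$cultivar]])))
  }
  for (i in seq_along(pool$backgrounds))
    png::writePNG(pool$backgrounds[[i]],
                  file.path(dir, sprintf("background_%d.png", i)))
  invisible(dir)
}

#' @rdname write_pool
#' @export
read_pool <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  bg_files <- grep("background_", files, value = TRUE)
  sp_files <- setdiff(files, bg_files)
  if (length(sp_files) == 0L || length(bg_files) == 0L)
    stop_seedpheno("pool directory must hold sprites and backgrounds",
                   "config_error")
  sprites <- lapply(sp_files, function(f) {
    a <- png::readPNG(f)
    if (dim(a)[3L] != 4L) stop_seedpheno(paste("not RGBA:", f), "parse_error")
    cultivar <- sub("_[0-9]+$", "", sub("\\.png$", "", basename(f)))
    seed_sprite(a[, , 1:3, drop = FALSE], a[, , 4L], cultivar = cultivar,
                source_id = basename(f))
  })
  backgrounds <- lapply(bg_files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a[, , 1:3, drop = FALSE] else a
  })
  structure(list(sprites = sprites, backgrounds = backgrounds),
            class = "sprite_pool")
}
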