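# Seed morphometry: sub-pixel contour extraction, the eight shape
# descriptors, normalized elliptic Fourier descriptors (EFD), per-group
# mean contours, and PCA with latent-axis contour reconstruction.

#' Extract the outer contour of a binary mask
#'
#' Traces the 0.5 iso-level of the mask by marching squares on a 1 px
#' zero-padded copy, so contours are closed even when the region touches
#' the raster border.  When several closed curves exist (e.g. interior
#' holes), the one enclosing the largest area is returned.  Orientation is
#' normalized so the signed shoelace area is positive.
#'
#' Coordinates are sub-pixel, 0-based, x right / y down; the pixel at
#' matrix position (row r, col c) has center (c - 1, r - 1).
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return A `seed_contour`: list with numeric `x`, `y` (closed polygon,
#'   last vertex distinct from the first).
#' @export
extract_contour <- function(mask) {
  if (!any(mask)) stop_seedpheno("empty mask: no contour", "empty_mask")
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask * 1
  # contourLines wants z[i, j] at (x[i], y[j]); transpose so rows follow x
  cl <- grDevices::contourLines(x = -1:w, y = -1:h, z = t(padded),
                                levels = 0.5)
  if (length(cl) == 0L)
    stop_seedpheno("no iso-contour found", "empty_mask")
  areas <- vapply(cl, function(cc) abs(polygon_area_signed(cc$x, cc$y)), 0)
  best <- cl[[which.max(areas)]]
  x <- best$x; y <- best$y
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n] }
  if (polygon_area_signed(x, y) < 0) { x <- rev(x); y <- rev(y) }
  structure(list(x = x, y = y), class = "seed_contour")
}

#' @export
print.seed_contour <- function(x, ...) {
  cat(sprintf("<seed_contour> %d vertices, area %.1f px^2\n",
              length(x$x), abs(polygon_area_signed(x$x, x$y))))
  invisible(x)
}

# Convex-hull area in pixels: hull polygon over the corner points of the
# region's boundary pixels, rasterized by counting pixel centers inside.
# Centers sit on integers, hull vertices on half-integers, so the
# point-in-polygon test never hits a boundary tie; a filled axis-aligned
# square is its own hull (solidity exactly 1).
.hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  bidx <- which(mask & !core, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  cx <- bidx[, 2L] - 1; cy <- bidx[, 1L] - 1
  px <- c(cx - 0.5, cx + 0.5, cx - 0.5, cx + 0.5)
  py <- c(cy - 0.5, cy - 0.5, cy + 0.5, cy + 0.5)
  ch <- grDevices::chull(px, py)
  vx <- px[ch]; vy <- py[ch]
  # candidate pixel centers: hull bounding box
  crange <- floor(min(vx) + 1):ceiling(max(vx))
  rrange <- floor(min(vy) + 1):ceiling(max(vy))
  qx <- rep(crange, each = length(rrange))
  qy <- rep(rrange, times = length(crange))
  inside <- rep(0L, length(qx))
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > qy) != (vy[j] > qy)) &
      (qx < (vx[j] - vx[i]) * (qy - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- inside + crosses
    j <- i
  }
  sum(inside %% 2L == 1L)
}

#' Eight morphometric descriptors of a segmented seed
#'
#' Computes, for a single-region binary mask: area (pixel count), length
#' and width (major/minor axis lengths of the ellipse with the same
#' normalized second central moments), length-to-width ratio, eccentricity
#' `sqrt(1 - (width/length)^2)`, solidity (area over convex-hull area),
#' perimeter (arc length of the sub-pixel iso-contour polygon), and
#' circularity `4 * pi * area / perimeter^2`.
#'
#' @param mask logical or 0/1 matrix, non-empty, one connected component.
#' @param dpi optional scan resolution; when given, lengths are reported in
#'   mm and areas in mm^2 instead of px.
#' @return One-row tibble with columns `area`, `length`, `width`, `lwr`,
#'   `eccentricity`, `solidity`, `perimeter`, `circularity`.
#' @export
compute_descriptors <- function(mask, dpi = NULL) {
  mask <- mask > 0
  if (!any(mask)) stop_seedpheno("empty mask", "empty_mask")
  lab <- .from_ebi(EBImage::bwlabel(.to_ebi(mask * 1)))
  if (max(lab) > 1L)
    stop_seedpheno(
      "mask has multiple connected components; label or screen it first",
      "multi_component")
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  mu20 <- stats::var(x) * (area - 1) / area
  mu02 <- stats::var(y) * (area - 1) / area
  mu11 <- if (area > 1) stats::cov(x, y) * (area - 1) / area else 0
  if (area == 1L) mu20 <- mu02 <- mu11 <- 0
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2L), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  len <- 4 * sqrt(ev[1L])
  wid <- 4 * sqrt(ev[2L])
  ecc <- if (ev[1L] > 0) sqrt(1 - ev[2L] / ev[1L]) else 0
  cont <- extract_contour(mask)
  perim <- polygon_perimeter(cont$x, cont$y)
  scale <- if (is.null(dpi)) 1 else 25.4 / dpi
  tibble::tibble(
    area = area * scale^2,
    length = len * scale, width = wid * scale,
    lwr = if (wid > 0) len / wid else Inf,
    eccentricity = ecc,
    solidity = area / .hull_area(mask),
    perimeter = perim * scale,
    circularity = 4 * pi * area / perim^2
  )
}

#' Morphometry table for a set of instances
#'
#' Rare fragmented masks (occlusion survivors the screening step did not
#' catch) are measured on their largest connected component.
#'
#' @param instances tibble with `instance_id`, optional `cultivar`, and a
#'   `mask` list-column (local binary masks).
#' @param dpi optional scan resolution for mm units.
#' @return Tibble: one row per instance, id and cultivar plus the eight
#'   descriptors.
#' @export
morphometry_table <- function(instances, dpi = NULL) {
  purrr::map_dfr(seq_len(nrow(instances)), function(i) dplyr::bind_cols(
    tibble::tibble(
      instance_id = instances$instance_id[i],
      cultivar = if ("cultivar" %in% names(instances))
        instances$cultivar[i] else NA_character_),
    compute_descriptors(largest_component(instances$mask[[i]]), dpi = dpi)
  ))
}

#' Largest connected component of a binary mask
#'
#' @param mask logical or 0/1 matrix, non-empty.
#' @return Logical matrix keeping only the largest 4-connected component.
#' @export
largest_component <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop_seedpheno("empty mask", "empty_mask")
  lab <- .from_ebi(EBImage::bwlabel(.to_ebi(mask * 1)))
  if (max(lab) <= 1L) return(mask)
  lab == which.max(tabulate(lab[lab > 0L]))
}

#' Elliptic Fourier coefficients of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier analysis of the closed polygon under
#' chord-length parameterization.  With `normalize = TRUE` the standard
#' size/rotation/starting-point normalization is applied so the first
#' harmonic ellipse has unit semi-major axis aligned with the x-axis; the
#' first three coefficients then equal (1, 0, 0) up to numerical precision.
#'
#' @param contour a `seed_contour` (or list with `x`, `y`).
#' @param harmonics number of harmonics (default 20).
#' @param normalize apply the invariance normalization.
#' @return An `efd_coeffs`: list with `coeffs` (harmonics x 4 matrix,
#'   columns a, b, c, d), `harmonics`, `normalized`, and the raw locus
#'   `A0`, `C0`.
#' @export
efd_coefficients <- function(contour, harmonics = 20L, normalize = TRUE) {
  if (harmonics < 1L) stop_seedpheno("harmonics must be >= 1", "config_error")
  x <- contour$x; y <- contour$y
  dx <- diff(c(x, x[1L])); dy <- diff(c(y, y[1L]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3L || sum(dt) <= 0)
    stop_seedpheno("degenerate contour", "degenerate_contour")
  t <- cumsum(dt); T <- t[length(t)]
  phi <- 2 * pi * t / T
  phi0 <- c(0, phi[-length(phi)])
  co <- matrix(0, harmonics, 4L,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(harmonics)) {
    k <- T / (2 * n^2 * pi^2)
    dcos <- cos(n * phi) - cos(n * phi0)
    dsin <- sin(n * phi) - sin(n * phi0)
    co[n, "a"] <- k * sum(dx / dt * dcos)
    co[n, "b"] <- k * sum(dx / dt * dsin)
    co[n, "c"] <- k * sum(dy / dt * dcos)
    co[n, "d"] <- k * sum(dy / dt * dsin)
  }
  # DC (locus) terms of the raw expansion
  xi <- cumsum(dx) - dx / dt * t
  A0 <- sum(dx / (2 * dt) * diff(c(0, t^2)) + xi * dt) / T + x[1L]
  delta <- cumsum(dy) - dy / dt * t
  C0 <- sum(dy / (2 * dt) * diff(c(0, t^2)) + delta * dt) / T + y[1L]
  out <- structure(list(coeffs = co, harmonics = as.integer(harmonics),
                        normalized = FALSE, A0 = A0, C0 = C0),
                   class = "efd_coeffs")
  if (normalize) normalize_efd(out) else out
}

#' Normalize elliptic Fourier coefficients
#'
#' Removes starting-point, rotation and size effects: rotates the
#' parameterization so the first harmonic starts on its semi-major axis,
#' rotates the coordinate frame onto that axis, and scales by the
#' semi-major magnitude.  After normalization `(a1, b1, c1) = (1, 0, 0)`.
#'
#' @param efd an `efd_coeffs`.
#' @return The normalized `efd_coeffs`.
#' @export
normalize_efd <- function(efd) {
  co <- efd$coeffs
  a1 <- co[1L, "a"]; b1 <- co[1L, "b"]
  c1 <- co[1L, "c"]; d1 <- co[1L, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 - b1^2 + c1^2 - d1^2)
  for (n in seq_len(efd$harmonics)) {
    rot <- matrix(c(cos(n * theta), sin(n * theta),
                    -sin(n * theta), cos(n * theta)), 2L)
    m <- matrix(co[n, ], 2L, byrow = TRUE) %*% rot
    co[n, ] <- c(m[1L, ], m[2L, ])
  }
  psi <- atan2(co[1L, "c"], co[1L, "a"])
  psi_rot <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2L,
                    byrow = TRUE)
  for (n in seq_len(efd$harmonics)) {
    m <- psi_rot %*% matrix(co[n, ], 2L, byrow = TRUE)
    co[n, ] <- c(m[1L, ], m[2L, ])
  }
  size <- abs(co[1L, "a"])
  if (size == 0) stop_seedpheno("degenerate first harmonic",
                                "degenerate_contour")
  co <- co / size
  # The starting-point angle is only determined up to half a period, which
  # leaves a two-fold branch flipping the sign of every even harmonic.
  # Canonicalize: the largest-magnitude even-harmonic entry must be
  # positive (stable under small perturbations of the contour).
  if (efd$harmonics >= 2L) {
    ev <- co[seq(2L, efd$harmonics, by = 2L), , drop = FALSE]
    lead <- ev[which.max(abs(ev))]
    if (length(lead) && abs(lead) > 1e-9 && lead < 0) {
      flip <- seq(2L, efd$harmonics, by = 2L)
      co[flip, ] <- -co[flip, , drop = FALSE]
    }
  }
  efd$coeffs <- co
  efd$normalized <- TRUE
  efd
}

#' Flatten normalized EFD coefficients into the feature vector
#'
#' Coefficients are flattened harmonic-major as `(a1, b1, c1, d1, a2, ...,
#' d_H)` and the first three entries -- constants (1, 0, 0) after
#' normalization -- are dropped, giving `4 * harmonics - 3` features
#' (77 at the default 20 harmonics).
#'
#' @param efd a normalized `efd_coeffs`.
#' @return Named numeric vector of length `4 * harmonics - 3`.
#' @export
efd_features <- function(efd) {
  if (!isTRUE(efd$normalized))
    stop_seedpheno("EFD features require normalized coefficients",
                   "config_error")
  v <- as.vector(t(efd$coeffs))
  nm <- as.vector(t(outer(seq_len(efd$harmonics), c("a", "b", "c", "d"),
                          function(i, s) paste0(s, i))))
  stats::setNames(v, nm)[-(1:3)]
}

#' EFD feature table for a set of instances
#'
#' @param instances tibble with `instance_id`, optional `cultivar`, and a
#'   `mask` list-column.
#' @param harmonics harmonics per contour (default 20).
#' @return Tibble: id, cultivar, and one column per retained coefficient
#'   (`d1`, `a2`, ..., 77 columns at the default).
#' @export
efd_feature_table <- function(instances, harmonics = 20L) {
  purrr::map_dfr(seq_len(nrow(instances)), function(i) {
    f <- efd_features(efd_coefficients(extract_contour(instances$mask[[i]]),
                                       harmonics = harmonics))
    dplyr::bind_cols(
      tibble::tibble(
        instance_id = instances$instance_id[i],
        cultivar = if ("cultivar" %in% names(instances))
          instances$cultivar[i] else NA_character_),
      tibble::as_tibble(as.list(f))
    )
  })
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at uniformly spaced parameter
#' values.  Normalized coefficients reconstruct the shape at unit scale in
#' the normalized frame; raw coefficients include the locus terms.
#'
#' @param efd an `efd_coeffs`.
#' @param n_points number of polygon vertices (at least 3 x harmonics).
#' @return A `seed_contour`.
#' @export
efd_reconstruct <- function(efd, n_points = 300L) {
  if (n_points < 3L * efd$harmonics)
    stop_seedpheno("n_points must be at least 3 x harmonics", "config_error")
  t <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- rep(if (efd$normalized) 0 else efd$A0, n_points)
  y <- rep(if (efd$normalized) 0 else efd$C0, n_points)
  for (n in seq_len(efd$harmonics)) {
    cn <- cos(2 * pi * n * t); sn <- sin(2 * pi * n * t)
    x <- x + efd$coeffs[n, "a"] * cn + efd$coeffs[n, "b"] * sn
    y <- y + efd$coeffs[n, "c"] * cn + efd$coeffs[n, "d"] * sn
  }
  structure(list(x = x, y = y), class = "seed_contour")
}

#' Mean contour of a group of normalized EFD coefficient sets
#'
#' Averages the coefficient arrays element-wise and reconstructs the curve
#' -- the representative shape of a cultivar.
#'
#' @param efds list of normalized `efd_coeffs` with equal harmonic counts.
#' @param n_points vertices of the reconstruction.
#' @return A `seed_contour`; the averaged `efd_coeffs` is attached as
#'   attribute `efd`.
#' @export
mean_contour <- function(efds, n_points = 300L) {
  if (length(efds) == 0L) stop_seedpheno("empty group", "config_error")
  hs <- vapply(efds, `[[`, 0L, "harmonics")
  if (length(unique(hs)) != 1L)
    stop_seedpheno("mixed harmonic counts", "config_error")
  if (!all(vapply(efds, `[[`, TRUE, "normalized")))
    stop_seedpheno("mean contour requires normalized coefficients",
                   "config_error")
  mean_co <- Reduce(`+`, lapply(efds, `[[`, "coeffs")) / length(efds)
  m <- efds[[1L]]
  m$coeffs <- mean_co
  cont <- efd_reconstruct(m, n_points)
  attr(cont, "efd") <- m
  cont
}

#' Principal component analysis of a morphometric feature table
#'
#' Columns are centered, and scaled to unit variance when `standardize`
#' (appropriate for the eight descriptors, whose units differ; EFD
#' features share a scale after normalization and are analyzed
#' unstandardized).  Loading signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param x numeric matrix or data frame (rows = seeds, columns =
#'   features); non-numeric columns such as `instance_id`/`cultivar` are
#'   carried through to the scores table.
#' @param standardize scale columns to unit variance.
#' @return A `seed_pca`: `scores` tibble (carried id columns + PC1..PCk),
#'   `loadings` (p x k matrix), `explained_ratio`, `center`, `scale`,
#'   `sdev`.
#' @export
pca_fit <- function(x, standardize = FALSE) {
  meta <- NULL
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, TRUE)
    meta <- x[!num]
    x <- as.matrix(x[num])
  }
  if (nrow(x) < 2L) stop_seedpheno("need at least 2 rows", "config_error")
  bad <- !apply(is.finite(x), 2L, all)
  if (any(bad))
    stop_seedpheno(paste("non-finite values in column(s):",
                         paste(colnames(x)[bad], collapse = ", ")),
                   "config_error")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop_seedpheno(paste("zero-variance column(s):",
                           paste(colnames(x)[sds == 0], collapse = ", ")),
                     "config_error")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  k <- ncol(pc$rotation)
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- tibble::as_tibble(pc$x)
  if (!is.null(meta) && ncol(meta) > 0L)
    scores <- dplyr::bind_cols(tibble::as_tibble(meta), scores)
  structure(list(
    scores = scores, loadings = pc$rotation,
    explained_ratio = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    scale = if (standardize) pc$scale else rep(1, ncol(x)),
    sdev = pc$sdev, standardize = standardize
  ), class = "seed_pca")
}

#' @export
print.seed_pca <- function(x, ...) {
  cat(sprintf("<seed_pca> %d x %d; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), length(x$center),
              100 * sum(x$explained_ratio[1:min(2, length(x$explained_ratio))])))
  invisible(x)
}

#' Scores of a fitted PCA, one row per seed
#'
#' @param x a `seed_pca`.
#' @param ... unused.
#' @return The scores tibble.
#' @export
tidy.seed_pca <- function(x, ...) x$scores

#' Variance summary of a fitted PCA
#'
#' @param x a `seed_pca`.
#' @param ... unused.
#' @return One-row tibble: components, variance explained by PC1, PC2 and
#'   their sum.
#' @export
glance.seed_pca <- function(x, ...) {
  er <- x$explained_ratio
  tibble::tibble(n_components = length(er),
                 pc1_ratio = er[1L],
                 pc2_ratio = if (length(er) > 1L) er[2L] else NA_real_,
                 pc12_ratio = sum(er[1:min(2L, length(er))]))
}

#' Invert the PCA transform at a point in latent space
#'
#' @param pca a `seed_pca`.
#' @param scores numeric vector of coordinates, recycled against components
#'   (unspecified axes are 0).
#' @return Numeric feature vector on the original scale.
#' @export
pca_invert <- function(pca, scores) {
  k <- ncol(pca$loadings)
  s <- rep(0, k)
  s[seq_along(scores)] <- scores
  as.vector(pca$loadings %*% s) * pca$scale + pca$center
}

#' Reconstruct contours along one PCA axis of the EFD shape space
#'
#' For each position, inverts the PCA transform at that coordinate (all
#' other axes 0) back to the 77-element EFD feature vector, reinserts the
#' normalization constants (1, 0, 0), reshapes to harmonics x 4 and
#' reconstructs the contour -- the latent-space interpolation view of the
#' shape space.
#'
#' @param pca a `seed_pca` fitted on EFD feature columns.
#' @param axis component index.
#' @param positions score values along the axis, e.g. `c(-2, 0, 2) * sd`.
#' @param n_points vertices per reconstruction.
#' @return Tibble with `axis`, `position` and a `contour` list-column.
#' @export
latent_axis_contours <- function(pca, axis = 1L, positions = c(-2, 0, 2),
                                 n_points = 300L) {
  if (axis < 1L || axis > ncol(pca$loadings))
    stop_seedpheno("axis out of range", "config_error")
  p <- nrow(pca$loadings)
  if ((p + 3L) %% 4L != 0L)
    stop_seedpheno("PCA was not fitted on EFD features (p != 4H - 3)",
                   "config_error")
  harmonics <- (p + 3L) %/% 4L
  conts <- lapply(positions, function(pos) {
    s <- rep(0, ncol(pca$loadings)); s[axis] <- pos
    feat <- pca_invert(pca, s)
    co <- matrix(c(1, 0, 0, feat), harmonics, 4L, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
    efd <- structure(list(coeffs = co, harmonics = harmonics,
                          normalized = TRUE, A0 = 0, C0 = 0),
                     class = "efd_coeffs")
    efd_reconstruct(efd, n_points)
  })
  tibble::tibble(axis = axis, position = positions, contour = conts)
}

#' Plot PCA scores in the first two components
#'
#' @param object a `seed_pca`.
#' @param color optional name of a score-table column to color by
#'   (e.g. "cultivar").
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.seed_pca <- function(object, color = NULL, ...) {
  er <- object$explained_ratio
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(color) && color %in% names(object$scores))
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color]]),
                            alpha = 0.7)
  else p + ggplot2::geom_point(alpha = 0.7)
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * er[1L]),
    y = sprintf("PC2 (%.1f%%)", 100 * er[2L])
  ) + ggplot2::theme_minimal()
}

#' Plot one or more contours
#'
#' @param contours a `seed_contour`, a list of them, or a tibble from
#'   [latent_axis_contours()].
#' @param labels optional facet labels.
#' @return A ggplot with aspect ratio 1 and y pointing down (image frame).
#' @export
plot_contours <- function(contours, labels = NULL) {
  if (inherits(contours, "seed_contour")) contours <- list(contours)
  if (is.data.frame(contours)) {
    labels <- labels %||% sprintf("PC%d = %.3g", contours$axis,
                                  contours$position)
    contours <- contours$contour
  }
  labels <- labels %||% as.character(seq_along(contours))
  df <- purrr::map2_dfr(contours, labels, function(cc, lb)
    tibble::tibble(x = c(cc$x, cc$x[1L]), y = c(cc$y, cc$y[1L]), panel = lb))
  df$panel <- factor(df$panel, levels = unique(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
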