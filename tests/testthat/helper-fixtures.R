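# Shared fixtures and independent oracles.  Oracles re-derive expected
# values by a different route than the implementation under test.

# -- raster fixtures ---------------------------------------------------------

disc_mask <- function(r, pad = 11L) {
  side <- 2L * r + 2L * pad - 1L
  ctr <- r + pad
  xs <- matrix(rep(seq_len(side), each = side), side)
  ys <- t(xs)
  (xs - ctr)^2 + (ys - ctr)^2 <= r^2
}

ellipse_mask <- function(a, b, pad = 11L) {
  w <- 2L * a + 2L * pad - 1L; h <- 2L * b + 2L * pad - 1L
  cx <- a + pad; cy <- b + pad
  xs <- matrix(rep(seq_len(w), each = h), h)
  ys <- matrix(rep(seq_len(h), times = w), h)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

square_mask <- function(n, pad = 5L) {
  side <- n + 2L * pad
  m <- matrix(FALSE, side, side)
  m[(pad + 1L):(pad + n), (pad + 1L):(pad + n)] <- TRUE
  m
}

circle_contour <- function(r = 50, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  structure(list(x = r * cos(th), y = r * sin(th)), class = "seed_contour")
}

ellipse_contour <- function(a = 60, b = 30, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  structure(list(x = a * cos(th), y = b * sin(th)), class = "seed_contour")
}

small_pool <- function(seed = 1, canvas = 256L) {
  make_fixture_pool(seed, n_cultivars = 3L, per_cultivar = 3L,
                    shape_params = list(size_range = c(14, 30)),
                    canvas_size = canvas, n_backgrounds = 2L)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(canvas_size = 256L, out_size = 192L, max_trials = 40L), list(...))
  do.call(compose_config, args)
}

# Morphological erosion with zero padding (EBImage treats out-of-raster as
# foreground, which is wrong for sprite interiors).
erode_pad <- function(mask, brush) {
  r <- (nrow(brush) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  er <- t(as.matrix(EBImage::erode(EBImage::Image(t(pad)), brush))) > 0.5
  er[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE]
}

# -- independent oracles -----------------------------------------------------

# Brute-force average precision: walk score-descending prefixes, take TP/FP
# outcomes as given, build the raw PR points, and integrate the envelope by
# scanning, per prefix, every later prefix for the max precision.
ap_bruteforce <- function(outcomes, n_truth) {
  if (n_truth == 0L) return(if (length(outcomes) == 0L) 1 else 0)
  if (length(outcomes) == 0L) return(0)
  tp <- cumsum(outcomes)
  prec <- tp / seq_along(outcomes)
  rec <- tp / n_truth
  ap <- 0
  prev_rec <- 0
  for (i in seq_along(outcomes)) {
    env_p <- max(prec[i:length(prec)])
    ap <- ap + env_p * (rec[i] - prev_rec)
    prev_rec <- rec[i]
  }
  ap
}

# Greedy matching re-derivation giving the per-detection TP/FP outcomes,
# enumerated by explicit loops over a precomputed IoU table.
match_outcomes_bruteforce <- function(ious, scores, threshold) {
  ord <- order(-scores)
  taken <- rep(FALSE, ncol(ious))
  out <- logical(length(scores))
  for (i in ord) {
    best <- 0; bj <- 0L
    for (j in seq_len(ncol(ious))) {
      if (!taken[j] && ious[i, j] >= threshold && ious[i, j] > best) {
        best <- ious[i, j]; bj <- j
      }
    }
    if (bj > 0L) { taken[bj] <- TRUE; out[i] <- TRUE }
  }
  out[ord]
}

# Direct numerical Fourier integration of a closed polygon path: resample
# the path uniformly in arc length at high density and integrate
# x'(t) cos/sin terms by the trapezoid rule -- independent of the
# closed-form Kuhl-Giardina sums in the package.
efd_oracle <- function(contour, harmonics, n_dense = 20000L) {
  x <- c(contour$x, contour$x[1L]); y <- c(contour$y, contour$y[1L])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  t <- c(0, cumsum(seg)); T <- t[length(t)]
  td <- seq(0, T, length.out = n_dense + 1L)
  xd <- stats::approx(t, x, xout = td)$y
  yd <- stats::approx(t, y, xout = td)$y
  dt <- T / n_dense
  tm <- (td[-1L] + td[-length(td)]) / 2
  xm <- (xd[-1L] + xd[-length(xd)]) / 2
  ym <- (yd[-1L] + yd[-length(yd)]) / 2
  co <- matrix(0, harmonics, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(harmonics)) {
    wc <- cos(2 * pi * n * tm / T); ws <- sin(2 * pi * n * tm / T)
    co[n, "a"] <- 2 / T * sum(xm * wc) * dt
    co[n, "b"] <- 2 / T * sum(xm * ws) * dt
    co[n, "c"] <- 2 / T * sum(ym * wc) * dt
    co[n, "d"] <- 2 / T * sum(ym * ws) * dt
  }
  co
}

# Connected-component labeling by flood fill (4-connectivity), implemented
# with an explicit stack -- oracle for sprite support checks.
label_components_bruteforce <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] > 0L) next
      lab[p] <- cur
      r <- (p - 1L) %% h + 1L; cl <- (p - 1L) %/% h + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cl > 1L) p - h, if (cl < w) p + h)) {
        if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
      }
    }
  }
  lab
}
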