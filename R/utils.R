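# Internal raster and RNG helpers shared across modules.
#
# Raster convention throughout the package: matrices/arrays are indexed
# [row = y, col = x] with the origin at the top-left pixel, matching
# png::readPNG().  Bounding boxes are 0-based half-open (x0, y0, x1, y1):
# the 1-based pixel column j spans x in [j - 1, j).

# EBImage stores images [x, y(, channel)]; transpose when crossing over.
.to_ebi <- function(m) {
  if (length(dim(m)) == 2L) EBImage::Image(t(m)) else
    EBImage::Image(aperm(m, c(2L, 1L, 3L)), colormode = "Color")
}

.from_ebi <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

# Tight 0-based half-open bbox of a logical matrix; NULL when empty.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(
    x0 = min(idx[, 2L]) - 1L, y0 = min(idx[, 1L]) - 1L,
    x1 = max(idx[, 2L]),      y1 = max(idx[, 1L])
  )
}

# Signed polygon area (shoelace); positive for counter-clockwise traversal
# in a y-up frame.  Callers only ever need the magnitude or the sign.
polygon_area_signed <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_perimeter <- function(x, y) {
  dx <- diff(c(x, x[1L]))
  dy <- diff(c(y, y[1L]))
  sum(sqrt(dx^2 + dy^2))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-image substream seed: a small integer hash of
# (master seed, stream index), kept inside the 32-bit signed range.
derive_stream_seed <- function(rng_seed, i) {
  s <- (as.double(rng_seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(i) * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_seedpheno <- function(msg, class) {
  stop(structure(
    class = c(class, "seedpheno_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
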