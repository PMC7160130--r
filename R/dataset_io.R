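# COCO-style dataset interchange: instance annotations with uncompressed
# run-length masks, a single "seed" category, and a deterministic
# train/validation/test split.

#' Run-length encode / decode a binary mask
#'
#' COCO uncompressed RLE: counts of alternating background/foreground runs
#' in column-major pixel order, starting with the (possibly zero) leading
#' background run.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param counts integer run lengths.
#' @param h,w raster shape for decoding.
#' @return `rle_encode()` an integer vector; `rle_decode()` a logical matrix.
#' @export
rle_encode <- function(mask) {
  .rle_from_indices(which(mask), length(mask))
}

# Alternating background/foreground run lengths from sorted linear indices
# of the foreground pixels.
.rle_from_indices <- function(idx, n) {
  if (length(idx) == 0L) return(as.integer(n))
  gap <- which(diff(idx) > 1L)
  starts <- idx[c(1L, gap + 1L)]
  ends <- idx[c(gap, length(idx))]
  fg <- ends - starts + 1L
  nb <- length(starts)
  counts <- integer(2L * nb + 1L)
  counts[1L] <- starts[1L] - 1L
  counts[seq(2L, 2L * nb, by = 2L)] <- fg
  if (nb > 1L)
    counts[seq(3L, 2L * nb - 1L, by = 2L)] <- starts[-1L] - ends[-nb] - 1L
  counts[2L * nb + 1L] <- n - ends[nb]
  if (counts[length(counts)] == 0L) counts <- counts[-length(counts)]
  as.integer(counts)
}

# RLE of a local mask placed at (x0, y0) inside an h x w raster, without
# materializing the full raster.
.rle_window <- function(local, x0, y0, h, w) {
  li <- which(local, arr.ind = TRUE)
  gidx <- (x0 + li[, 2L] - 1L) * h + (y0 + li[, 1L])
  .rle_from_indices(sort(gidx), h * w)
}

#' @rdname rle_encode
#' @export
rle_decode <- function(counts, h, w) {
  vals <- rep(c(FALSE, TRUE), length.out = length(counts))
  v <- rep(vals, times = counts)
  if (length(v) != h * w)
    stop_seedpheno("RLE counts do not cover the raster", "parse_error")
  matrix(v, nrow = h, ncol = w)
}

#' Write scenes as COCO instance-segmentation annotations
#'
#' Produces a COCO 1.0 JSON with one "seed" category; masks are stored as
#' uncompressed column-major RLE, bboxes as `[x, y, w, h]`, areas as
#' visible pixel counts.
#'
#' @param images tibble with columns `id`, `file_name`, `width`, `height`
#'   (as produced by [generate_dataset()]), or a list of `seed_scene`s via
#'   [coco_from_scenes()].
#' @param annotations list (one element per image, aligned with `images`)
#'   of [scene_instances()]-style tibbles with `x0,y0,x1,y1,area,mask`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(images, annotations, path) {
  ann_list <- list()
  aid <- 0L
  for (i in seq_len(nrow(images))) {
    tab <- annotations[[i]]
    if (is.null(tab) || nrow(tab) == 0L) next
    for (j in seq_len(nrow(tab))) {
      aid <- aid + 1L
      mk <- tab$mask[[j]]
      h <- images$height[i]; w <- images$width[i]
      counts <- if (all(dim(mk) == c(h, w))) rle_encode(mk) else
        .rle_window(mk, tab$x0[j], tab$y0[j], h, w)
      ann_list[[aid]] <- list(
        id = aid, image_id = images$id[i], category_id = 1L,
        bbox = c(tab$x0[j], tab$y0[j], tab$x1[j] - tab$x0[j],
                 tab$y1[j] - tab$y0[j]),
        area = tab$area[j],
        segmentation = list(size = c(h, w), counts = counts),
        iscrowd = 0L,
        attributes = list(cultivar = tab$cultivar[j] %||% "seed",
                          instance_id = tab$instance_id[j])
      )
      if ("score" %in% names(tab)) ann_list[[aid]]$score <- tab$score[j]
    }
  }
  doc <- list(
    info = list(description = "seedpheno synthetic seed dataset"),
    images = purrr::pmap(
      list(images$id, images$file_name, images$width, images$height),
      function(id, f, w, h) list(id = id, file_name = f, width = w, height = h)
    ),
    annotations = ann_list,
    categories = list(list(id = 1L, name = "seed", supercategory = "plant"))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convenience COCO writer for in-memory scenes
#'
#' @param scenes list of `seed_scene` objects.
#' @param path output JSON path.
#' @param file_names optional image file names.
#' @return `path`, invisibly.
#' @export
coco_from_scenes <- function(scenes, path, file_names = NULL) {
  n <- length(scenes)
  images <- tibble::tibble(
    id = seq_len(n),
    file_name = file_names %||% sprintf("img_%05d.png", seq_len(n)),
    width = vapply(scenes, function(s) ncol(s$label_map), 0L),
    height = vapply(scenes, function(s) nrow(s$label_map), 0L)
  )
  write_coco(images, lapply(scenes, scene_instances), path)
}

#' Read COCO instance annotations
#'
#' Parses a COCO JSON, validates each record (bbox within the image, area
#' consistent with the decoded mask) and returns tidy tables.  Masks are
#' kept as RLE; use [annotation_masks()] to materialize the binary rasters
#' of one image.
#'
#' @param path COCO JSON path.
#' @param validate recompute areas from the RLE and fail on mismatch.
#' @return List with `images` (tibble) and `annotations` (tibble: image_id,
#'   annotation id, bbox columns, area, score if present, cultivar, and the
#'   RLE in a list-column `rle`).
#' @export
read_coco <- function(path, validate = TRUE) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop_seedpheno(
                    paste("malformed COCO JSON:", conditionMessage(e)),
                    "parse_error"))
  images <- purrr::map_dfr(doc$images, function(im)
    tibble::tibble(id = im$id, file_name = im$file_name,
                   width = im$width, height = im$height))
  anns <- purrr::map_dfr(doc$annotations, function(a) {
    im <- images[images$id == a$image_id, ]
    if (nrow(im) != 1L)
      stop_seedpheno(sprintf("annotation %s references unknown image %s",
                             a$id, a$image_id), "parse_error")
    bb <- unlist(a$bbox)
    if (bb[1L] < 0 || bb[2L] < 0 || bb[1L] + bb[3L] > im$width ||
        bb[2L] + bb[4L] > im$height)
      stop_seedpheno(sprintf("annotation %s: bbox outside image bounds", a$id),
                     "validation_error")
    counts <- as.integer(unlist(a$segmentation$counts))
    if (validate) {
      fg <- sum(counts[seq_along(counts) %% 2L == 0L])
      if (fg != a$area || a$area <= 0)
        stop_seedpheno(sprintf(
          "annotation %s: stored area %s disagrees with segmentation", a$id,
          a$area), "validation_error")
    }
    tibble::tibble(
      id = a$id, image_id = a$image_id,
      x0 = bb[1L], y0 = bb[2L], x1 = bb[1L] + bb[3L], y1 = bb[2L] + bb[4L],
      area = a$area,
      score = if (!is.null(a$score)) a$score else NA_real_,
      cultivar = a$attributes$cultivar %||% "seed",
      rle = list(counts)
    )
  })
  if (nrow(anns) == 0L)
    anns <- tibble::tibble(id = integer(), image_id = integer(),
                           x0 = numeric(), y0 = numeric(), x1 = numeric(),
                           y1 = numeric(), area = numeric(),
                           score = numeric(), cultivar = character(),
                           rle = list())
  list(images = images, annotations = anns)
}

#' Decode the masks of one image's annotations
#'
#' @param coco result of [read_coco()].
#' @param image_id image to decode.
#' @return The image's annotation rows with an added `mask` list-column of
#'   full-size logical matrices.
#' @export
annotation_masks <- function(coco, image_id) {
  im <- coco$images[coco$images$id == image_id, ]
  if (nrow(im) != 1L)
    stop_seedpheno(paste("unknown image id", image_id), "alignment_error")
  rows <- coco$annotations[!is.na(coco$annotations$image_id) &
                             coco$annotations$image_id == image_id, ]
  rows$mask <- purrr::map(rows$rle, rle_decode, h = im$height, w = im$width)
  rows
}

#' Deterministic train/validation/test split
#'
#' Uniformly shuffles image ids under `rng_seed` and partitions them into
#' the requested counts.  The study split of a 1200-image synthetic dataset
#' was 989 training / 11 validation / 200 test images.
#'
#' @param image_ids vector of image ids (or a manifest `images` tibble).
#' @param counts named or ordered integer vector `c(train, val, test)`.
#' @param rng_seed shuffle seed.
#' @return Tibble with columns `id` and `split`.
#' @export
split_dataset <- function(image_ids, counts = c(train = 989L, val = 11L,
                                                test = 200L), rng_seed = 1L) {
  if (is.data.frame(image_ids)) image_ids <- image_ids$id
  if (sum(counts) != length(image_ids))
    stop_seedpheno(sprintf("split counts sum to %d but there are %d images",
                           sum(counts), length(image_ids)), "config_error")
  nm <- names(counts) %||% c("train", "val", "test")[seq_along(counts)]
  perm <- with_seed(rng_seed, sample(image_ids))
  split <- rep(nm, times = counts)
  dplyr::arrange(tibble::tibble(id = perm, split = split), .data$id)
}
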