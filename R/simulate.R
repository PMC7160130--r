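#' Simulate detections by perturbing ground-truth instances
#'
#' Produces a controlled stand-in for a detector's output: each
#' ground-truth mask is eroded by `erode_px` and translated by an integer
#' offset drawn uniformly from `[-jitter_px, jitter_px]` on both axes, and
#' assigned a confidence score in [0.5, 1].  With `drop_rate > 0` a
#' fraction of instances is missed entirely.  Larger erosion/jitter lowers
#' the mask IoU against ground truth, so evaluation metrics degrade
#' monotonically with the perturbation magnitude.
#'
#' @param scene a `seed_scene` (or any object accepted by
#'   [scene_instances()]-style tibbles via the `instances` argument).
#' @param erode_px erosion radius in px (0 disables).
#' @param jitter_px maximum absolute translation in px (0 disables).
#' @param drop_rate fraction of instances omitted.
#' @param rng_seed seed for jitter, scores and drops.
#' @return List of detections (`bbox`, `mask`, `score`), suitable for
#'   [evaluate_dataset()].
#' @export
simulate_detections <- function(scene, erode_px = 0L, jitter_px = 0L,
                                drop_rate = 0, rng_seed = 1L) {
  h <- nrow(scene$label_map); w <- ncol(scene$label_map)
  with_seed(rng_seed, {
    dets <- list()
    for (inst in scene$instances) {
      if (drop_rate > 0 && stats::runif(1) < drop_rate) next
      mk <- instance_mask(scene, inst$instance_id)
      if (erode_px > 0L) {
        kern <- EBImage::makeBrush(2L * erode_px + 1L, shape = "disc")
        mk <- .from_ebi(EBImage::erode(.to_ebi(mk * 1), kern)) > 0.5
      }
      if (jitter_px > 0L) {
        dxy <- sample(-jitter_px:jitter_px, 2L, replace = TRUE)
        shifted <- matrix(FALSE, h, w)
        src_r <- pmax(1L, 1L - dxy[2L]):pmin(h, h - dxy[2L])
        dst_r <- src_r + dxy[2L]
        src_c <- pmax(1L, 1L - dxy[1L]):pmin(w, w - dxy[1L])
        dst_c <- src_c + dxy[1L]
        shifted[dst_r, dst_c] <- mk[src_r, src_c]
        mk <- shifted
      }
      bb <- mask_bbox(mk)
      if (is.null(bb)) next
      dets[[length(dets) + 1L]] <- list(
        bbox = unname(bb), mask = mk, score = stats::runif(1, 0.5, 1)
      )
    }
    dets
  })
}

#' Ground-truth instances of a scene in the metrics representation
#'
#' @param scene a `seed_scene`.
#' @return List of instances (`bbox`, `mask`) for [evaluate_dataset()].
#' @export
scene_truths <- function(scene) {
  lapply(scene$instances, function(inst)
    list(bbox = unname(inst$bbox),
         mask = instance_mask(scene, inst$instance_id)))
}
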