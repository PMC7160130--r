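# Detection/segmentation evaluation: IoU, greedy score-ordered matching,
# recall, and average precision under the monotone precision envelope,
# aggregated per image and macro-averaged.

#' Intersection-over-union of two bounding boxes
#'
#' Boxes are 0-based half-open `(x0, y0, x1, y1)`, so a box's pixel area is
#' `(x1 - x0) * (y1 - y0)`.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in [0, 1].
#' @export
bbox_iou <- function(a, b) {
  if (a[3L] <= a[1L] || a[4L] <= a[2L] || b[3L] <= b[1L] || b[4L] <= b[2L])
    stop_seedpheno("degenerate bounding box", "contract_violation")
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
           (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  inter / union
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal shape, at least one non-empty.
#' @return IoU in [0, 1].
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_seedpheno("mask shapes differ", "contract_violation")
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0L)
    stop_seedpheno("both masks empty: IoU undefined", "contract_violation")
  inter / union
}

# Pairwise IoU matrix between detections and ground truths.
.iou_matrix <- function(detections, truths, iou_kind) {
  nd <- length(detections); nt <- length(truths)
  m <- matrix(0, nd, nt)
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    m[i, j] <- if (iou_kind == "bbox")
      bbox_iou(detections[[i]]$bbox, truths[[j]]$bbox)
    else mask_iou(detections[[i]]$mask, truths[[j]]$mask)
  }
  m
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' Detections are visited in descending confidence score (ties by input
#' order); each claims the still-unmatched ground-truth instance with the
#' highest IoU, provided that IoU reaches `iou_threshold`, and is otherwise
#' a false positive.  Ground-truth ties break toward the lower index.
#'
#' @param detections list of detections: each a list with `score`, `bbox`
#'   and (for mask IoU) `mask`.
#' @param truths list of ground-truth instances with `bbox`/`mask`.
#' @param iou_threshold match threshold in (0, 1].
#' @param iou_kind `"bbox"` or `"mask"`.
#' @return A `match_table`: tibble ordered by descending score with columns
#'   `det_index`, `score`, `matched_gt` (NA for false positives), `iou`;
#'   attribute `unmatched_gt` holds the unclaimed ground-truth indices.
#' @export
match_instances <- function(detections, truths, iou_threshold = 0.5,
                            iou_kind = c("mask", "bbox")) {
  iou_kind <- match.arg(iou_kind)
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop_seedpheno("iou_threshold must lie in (0, 1]", "config_error")
  nd <- length(detections); nt <- length(truths)
  scores <- vapply(detections, function(d) d$score %||% 1, 0)
  ord <- order(-scores)  # stable: ties keep input order
  m <- .iou_matrix(detections, truths, iou_kind)
  taken <- rep(FALSE, nt)
  matched <- rep(NA_integer_, nd)
  best_iou <- rep(NA_real_, nd)
  for (i in ord) {
    if (nt == 0L) break
    ious <- m[i, ]
    ious[taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      matched[i] <- j
      best_iou[i] <- m[i, j]
      taken[j] <- TRUE
    }
  }
  tab <- tibble::tibble(det_index = ord, score = scores[ord],
                        matched_gt = matched[ord], iou = best_iou[ord])
  structure(tab, unmatched_gt = which(!taken),
            n_truth = nt, class = c("match_table", class(tab)))
}

#' Recall from a match table
#'
#' Matched ground-truth count over the total; defined as 1 when there is no
#' ground truth (a perfectly empty image scores perfectly).
#'
#' @param table a `match_table`.
#' @param n_truth number of ground-truth instances; defaults to the count
#'   recorded on the table.
#' @return Recall in [0, 1].
#' @export
recall_at <- function(table, n_truth = attr(table, "n_truth")) {
  if (n_truth == 0L) return(1)
  sum(!is.na(table$matched_gt)) / n_truth
}

#' Average precision at one mask-IoU threshold
#'
#' Builds the precision-recall sequence over score-descending detection
#' prefixes, replaces each precision by the maximum precision at equal or
#' higher recall (the monotone envelope), and sums precision times recall
#' increment -- the rectangle approximation of the area under the curve.
#'
#' @param detections,truths as in [match_instances()].
#' @param iou_threshold mask-IoU threshold in (0, 1].
#' @param iou_kind IoU flavor, mask by default.
#' @return AP in [0, 1].  With no ground truth, 1 if there are also no
#'   detections and 0 otherwise.
#' @export
average_precision <- function(detections, truths, iou_threshold = 0.5,
                              iou_kind = "mask") {
  nt <- length(truths)
  if (nt == 0L) return(if (length(detections) == 0L) 1 else 0)
  if (length(detections) == 0L) return(0)
  tab <- match_instances(detections, truths, iou_threshold, iou_kind)
  tp <- cumsum(!is.na(tab$matched_gt))
  k <- seq_along(tp)
  precision <- tp / k
  recall <- tp / nt
  # monotone envelope: max precision over equal-or-higher recall
  envelope <- rev(cummax(rev(precision)))
  dr <- diff(c(0, recall))
  sum(envelope * dr)
}

#' AP at 0.50, 0.75 and averaged over the 0.50--0.95 sweep
#'
#' Computes mask AP at thresholds 0.50, 0.55, ..., 0.95 (ten values);
#' `ap_range` is their unweighted mean, `ap_50` and `ap_75` the values at
#' those two thresholds.
#'
#' @param detections,truths as in [match_instances()].
#' @return Named list `ap_50`, `ap_75`, `ap_range`, plus `ap_by_threshold`.
#' @export
ap_sweep <- function(detections, truths) {
  thresholds <- seq(0.50, 0.95, by = 0.05)
  aps <- vapply(thresholds, function(t)
    average_precision(detections, truths, t, "mask"), 0)
  names(aps) <- sprintf("%.2f", thresholds)
  list(ap_50 = aps[["0.50"]], ap_75 = aps[["0.75"]],
       ap_range = mean(aps), ap_by_threshold = aps)
}

# Evaluate one image: Recall_50 on bounding boxes, APs on masks.
.evaluate_image <- function(detections, truths) {
  nt <- length(truths)
  recall_50 <- if (nt == 0L) 1 else
    recall_at(match_instances(detections, truths, 0.5, "bbox"))
  sw <- ap_sweep(detections, truths)
  tibble::tibble(n_truth = nt, n_det = length(detections),
                 recall_50 = recall_50, ap_50 = sw$ap_50, ap_75 = sw$ap_75,
                 ap_range = sw$ap_range)
}

#' Evaluate detections against ground truth over a dataset
#'
#' Metrics are computed per image (one cultivar per image in the scanned
#' datasets this mirrors) and the dataset-level values are unweighted means
#' over images (macro average).
#'
#' @param detections named list: image id -> list of detections (each with
#'   `score`, `bbox`, `mask`).
#' @param truths named list: image id -> list of ground-truth instances.
#' @return A `seed_eval`: list with `per_image` (tibble, one row per image:
#'   `image_id`, `recall_50`, `ap_50`, `ap_75`, `ap_range`) and `summary`
#'   (one-row tibble of macro means).
#' @export
evaluate_dataset <- function(detections, truths) {
  ids <- names(truths)
  if (is.null(ids) || is.null(names(detections)))
    stop_seedpheno("detections and truths must be named by image id",
                   "alignment_error")
  if (!setequal(ids, names(detections)))
    stop_seedpheno("image ids differ between detections and truths",
                   "alignment_error")
  per_image <- purrr::map_dfr(ids, function(id)
    dplyr::bind_cols(tibble::tibble(image_id = id),
                     .evaluate_image(detections[[id]], truths[[id]])))
  summary <- dplyr::summarise(
    per_image,
    n_images = dplyr::n(),
    recall_50 = mean(.data$recall_50), ap_50 = mean(.data$ap_50),
    ap_75 = mean(.data$ap_75), ap_range = mean(.data$ap_range)
  )
  structure(list(per_image = per_image, summary = summary),
            class = "seed_eval")
}

#' @export
print.seed_eval <- function(x, ...) {
  cat("<seed_eval> macro average over", x$summary$n_images, "images\n")
  print(x$summary)
  invisible(x)
}

#' Evaluate two COCO files (ground truth vs scored detections)
#'
#' @param gt_path COCO JSON with ground-truth instances.
#' @param pred_path COCO JSON whose annotations carry a `score`.
#' @return A `seed_eval` (see [evaluate_dataset()]).
#' @export
evaluate_coco <- function(gt_path, pred_path) {
  gt <- read_coco(gt_path)
  pr <- read_coco(pred_path, validate = FALSE)
  ids <- gt$images$id
  to_list <- function(coco, id, need_score) {
    rows <- annotation_masks(coco, id)
    lapply(seq_len(nrow(rows)), function(j) list(
      bbox = c(rows$x0[j], rows$y0[j], rows$x1[j], rows$y1[j]),
      mask = rows$mask[[j]],
      score = if (need_score) rows$score[j] else 1
    ))
  }
  truths <- stats::setNames(lapply(ids, to_list, coco = gt,
                                   need_score = FALSE), ids)
  dets <- stats::setNames(lapply(ids, to_list, coco = pr,
                                 need_score = TRUE), ids)
  evaluate_dataset(dets, truths)
}

#' Tidy evaluation results to one row per image
#'
#' @param x a `seed_eval`.
#' @param ... unused.
#' @return The `per_image` tibble.
#' @export
tidy.seed_eval <- function(x, ...) x$per_image

#' One-row macro summary of an evaluation
#'
#' @param x a `seed_eval`.
#' @param ... unused.
#' @return The `summary` tibble.
#' @export
glance.seed_eval <- function(x, ...) x$summary

#' Plot per-image evaluation metrics
#'
#' @param object a `seed_eval`.
#' @param ... unused.
#' @return A ggplot: per-image bars for each metric.
#' @export
autoplot.seed_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image,
                              c("recall_50", "ap_50", "ap_75", "ap_range"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$image_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "image", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
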