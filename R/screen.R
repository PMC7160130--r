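# Post-processing filter cascade: keep only isolated, well-segmented seeds
# before morphometry.  Stages run in order -- image-margin check, solidity
# lower-quantile cut, length-to-width-ratio quantile band -- with each
# stage's thresholds recomputed on the survivors of the previous stage.

#' Filter-cascade configuration
#'
#' Defaults follow the study settings: a 5 px image margin, removal below
#' the 25% lower quantile of solidity, and removal outside the 5%/95%
#' quantile band of the length-to-width ratio.
#'
#' @param margin margin width in px.
#' @param solidity_lower_q lower quantile for the solidity cut.
#' @param lwr_lower_q,lwr_upper_q quantile band for the length-to-width
#'   ratio.
#' @return A `filter_config` list.
#' @export
filter_config <- function(margin = 5L, solidity_lower_q = 0.25,
                          lwr_lower_q = 0.05, lwr_upper_q = 0.95) {
  qs <- c(solidity_lower_q, lwr_lower_q, lwr_upper_q)
  if (any(qs < 0) || any(qs > 1))
    stop_seedpheno("quantiles must lie in [0, 1]", "config_error")
  if (lwr_lower_q >= lwr_upper_q)
    stop_seedpheno("LWR lower quantile must be below the upper", "config_error")
  if (margin < 0) stop_seedpheno("margin must be >= 0", "config_error")
  structure(list(margin = as.integer(margin),
                 solidity_lower_q = solidity_lower_q,
                 lwr_lower_q = lwr_lower_q, lwr_upper_q = lwr_upper_q),
            class = "filter_config")
}

#' Remove instances whose bounding box protrudes into the image margin
#'
#' An instance is removed iff its bbox intersects the margin band:
#' `x0 < margin`, `y0 < margin`, `x1 > width - margin` or
#' `y1 > height - margin` (0-based half-open boxes).
#'
#' @param instances tibble with bbox columns `x0, y0, x1, y1`.
#' @param image_size `c(width, height)` in px.
#' @param margin margin width in px.
#' @return The input with a logical column `keep_margin`.
#' @export
margin_filter <- function(instances, image_size, margin = 5L) {
  if (margin >= min(image_size) / 2)
    stop_seedpheno("margin must be below half the image side", "config_error")
  dplyr::mutate(instances, keep_margin =
    .data$x0 >= margin & .data$y0 >= margin &
    .data$x1 <= image_size[1L] - margin & .data$y1 <= image_size[2L] - margin)
}

#' Quantile outlier partition of a scalar trait
#'
#' Thresholds are the type-7 (linear interpolation) quantiles of the input
#' values; a value is removed iff strictly below the lower threshold or
#' strictly above the upper one.  With all values equal nothing is strictly
#' outside, so nothing is removed.
#'
#' @param values numeric vector (>= 1 value).
#' @param lower_q,upper_q quantile levels, or `NULL` to skip that side.
#' @return List with `keep` (logical), `lower`, `upper` (thresholds, NA when
#'   the side is skipped).
#' @export
quantile_filter <- function(values, lower_q = NULL, upper_q = NULL) {
  if (length(values) == 0L)
    stop_seedpheno("no values to filter", "config_error")
  lower <- if (!is.null(lower_q))
    unname(stats::quantile(values, lower_q, type = 7)) else NA_real_
  upper <- if (!is.null(upper_q))
    unname(stats::quantile(values, upper_q, type = 7)) else NA_real_
  keep <- rep(TRUE, length(values))
  if (!is.na(lower)) keep <- keep & values >= lower
  if (!is.na(upper)) keep <- keep & values <= upper
  list(keep = keep, lower = lower, upper = upper)
}

#' Solidity and length-to-width ratio of a (possibly fragmented) region
#'
#' The screening traits, computed without requiring a single connected
#' component: occlusion can split a visible mask into fragments, and such
#' regions should flow into the solidity stage (their hull covers the
#' fragments, so solidity collapses) rather than error.  Full morphometry
#' of accepted seeds remains the job of [compute_descriptors()], which
#' does insist on one component.
#'
#' @param mask logical or 0/1 matrix, non-empty.
#' @return List with `solidity` and `lwr`.
#' @export
region_traits <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop_seedpheno("empty mask", "empty_mask")
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  if (area == 1L) return(list(solidity = 1, lwr = 1))
  mu20 <- stats::var(x) * (area - 1) / area
  mu02 <- stats::var(y) * (area - 1) / area
  mu11 <- stats::cov(x, y) * (area - 1) / area
  ev <- pmax(eigen(matrix(c(mu20, mu11, mu11, mu02), 2L),
                   symmetric = TRUE)$values, 0)
  list(solidity = area / .hull_area(mask),
       lwr = if (ev[2L] > 0) sqrt(ev[1L] / ev[2L]) else Inf)
}

#' Apply the margin / solidity / LWR filter cascade
#'
#' Stage order matches the study: (1) margin check on bounding boxes;
#' (2) solidity lower-quantile cut, thresholded on the margin survivors;
#' (3) length-to-width-ratio quantile band, thresholded on the solidity
#' survivors.  A removed instance records the first stage that rejected it
#' and is not re-examined later.
#'
#' @param instances tibble with `instance_id`, bbox columns `x0, y0, x1,
#'   y1`, and a `mask` list-column of local binary masks (one connected
#'   region each), e.g. from [scene_instances()] or [annotation_masks()].
#' @param image_size `c(width, height)` in px.
#' @param config a [filter_config()].
#' @return A `filter_report`: tibble with `instance_id`, `kept`, `reason`
#'   (`NA`, `"margin"`, `"solidity"` or `"lwr"`), `solidity`, `lwr`;
#'   attribute `thresholds` records the cutoffs used.
#' @export
apply_filters <- function(instances, image_size, config = filter_config()) {
  n <- nrow(instances)
  reason <- rep(NA_character_, n)

  mf <- margin_filter(instances, image_size, config$margin)
  reason[!mf$keep_margin] <- "margin"

  # traits computed once per instance on the local mask
  solidity <- rep(NA_real_, n)
  lwr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- region_traits(instances$mask[[i]])
    solidity[i] <- d$solidity
    lwr[i] <- d$lwr
  }

  sol_thr <- NA_real_
  alive <- is.na(reason)
  if (any(alive)) {
    qf <- quantile_filter(solidity[alive], lower_q = config$solidity_lower_q)
    sol_thr <- qf$lower
    reason[alive][!qf$keep] <- "solidity"
  }

  lwr_lo <- NA_real_; lwr_hi <- NA_real_
  alive <- is.na(reason)
  if (any(alive)) {
    qf <- quantile_filter(lwr[alive], lower_q = config$lwr_lower_q,
                          upper_q = config$lwr_upper_q)
    lwr_lo <- qf$lower; lwr_hi <- qf$upper
    reason[alive][!qf$keep] <- "lwr"
  }

  rep_tab <- tibble::tibble(instance_id = instances$instance_id,
                            kept = is.na(reason), reason = reason,
                            solidity = solidity, lwr = lwr)
  structure(rep_tab,
            thresholds = list(solidity = sol_thr, lwr_lower = lwr_lo,
                              lwr_upper = lwr_hi),
            config = config,
            class = c("filter_report", class(rep_tab)))
}

#' Filter a COCO annotation file and write the survivors
#'
#' Runs [apply_filters()] independently per image and writes a filtered
#' COCO JSON plus the per-instance report.
#'
#' @param in_path COCO JSON of segmented instances.
#' @param out_path filtered COCO JSON destination.
#' @param config a [filter_config()].
#' @param report_path optional CSV destination for the report.
#' @return The combined `filter_report` tibble (column `image_id` added),
#'   invisibly.
#' @export
filter_coco <- function(in_path, out_path, config = filter_config(),
                        report_path = NULL) {
  coco <- read_coco(in_path)
  reports <- vector("list", nrow(coco$images))
  kept_ann <- vector("list", nrow(coco$images))
  for (k in seq_len(nrow(coco$images))) {
    id <- coco$images$id[k]
    rows <- annotation_masks(coco, id)
    if (nrow(rows) == 0L) next
    rows$instance_id <- rows$id
    loc <- lapply(seq_len(nrow(rows)), function(j) {
      bb <- c(rows$x0[j], rows$y0[j], rows$x1[j], rows$y1[j])
      rows$mask[[j]][(bb[2L] + 1L):bb[4L], (bb[1L] + 1L):bb[3L], drop = FALSE]
    })
    rows$mask <- loc
    rep_i <- apply_filters(rows, c(coco$images$width[k], coco$images$height[k]),
                           config)
    reports[[k]] <- dplyr::mutate(tibble::as_tibble(rep_i), image_id = id)
    keep_rows <- rows[rep_i$kept, ]
    kept_ann[[k]] <- tibble::tibble(
      instance_id = keep_rows$instance_id, cultivar = keep_rows$cultivar,
      x0 = keep_rows$x0, y0 = keep_rows$y0, x1 = keep_rows$x1,
      y1 = keep_rows$y1, area = keep_rows$area, mask = keep_rows$mask
    )
  }
  write_coco(coco$images, kept_ann, out_path)
  report <- dplyr::bind_rows(reports)
  if (!is.null(report_path)) utils::write.csv(report, report_path,
                                              row.names = FALSE)
  invisible(report)
}
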