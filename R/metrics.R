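#' Intersection over union
#'
#' For binary masks, |a & b| / |a | b| over pixels; for axis-aligned boxes
#' \code{c(x0, y0, x1, y1)} (x1 > x0, y1 > y0), the continuous area ratio.
#' Two empty inputs have IoU 1 by convention.
#'
#' @param a,b two binary matrices of identical dimensions, or two length-4
#'   numeric boxes.
#' @return IoU in [0, 1].
#' @export
iou <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    stop_if_not(all(dim(a) == dim(b)), "mask dimensions differ")
    inter <- sum(a != 0 & b != 0)
    uni <- sum(a != 0 | b != 0)
    if (uni == 0) return(1)
    return(inter / uni)
  }
  stop_if_not(length(a) == 4 && length(b) == 4, "boxes must be c(x0, y0, x1, y1)")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  area <- function(z) max(0, z[3] - z[1]) * max(0, z[4] - z[2])
  uni <- area(a) + area(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

# Greedy matching by descending confidence (ties: higher IoU); each ground
# truth consumable once; a match requires IoU strictly > threshold.
# conf: length-D vector; iou_mat: D x G matrix. Returns logical TP flags in
# the original detection order.
match_detections <- function(conf, iou_mat, threshold) {
  D <- length(conf); G <- ncol(iou_mat)
  tp <- logical(D)
  if (D == 0 || G == 0) return(tp)
  best_iou <- apply(iou_mat, 1, max)
  ord <- order(-conf, -best_iou)
  used <- logical(G)
  for (d in ord) {
    cand <- which(!used & iou_mat[d, ] > threshold)
    if (length(cand) > 0) {
      g <- cand[which.max(iou_mat[d, cand])]
      used[g] <- TRUE
      tp[d] <- TRUE
    }
  }
  tp
}

#' Average precision from a precision-recall curve
#'
#' Computes AP = sum_n (r_n - r_{n-1}) p_n over the confidence thresholds of
#' the detection set (every distinct confidence value is a threshold), with
#' no interpolation smoothing. Detections are matched to ground truths
#' greedily by descending confidence; each ground truth matches at most one
#' detection at IoU strictly greater than \code{iou_threshold}.
#'
#' @param conf numeric vector of detection confidences (length D).
#' @param iou_mat D x G matrix of detection-to-ground-truth IoU values.
#' @param iou_threshold matching threshold (default 0.5).
#' @return AP in [0, 1].
#' @export
average_precision <- function(conf, iou_mat, iou_threshold = 0.5) {
  iou_mat <- as.matrix(iou_mat)
  if (length(conf) > 0) {
    stop_if_not(nrow(iou_mat) == length(conf), "iou_mat must have one row per detection")
    stop_if_not(all(conf >= 0 & conf <= 1), "confidences must lie in [0, 1]")
  }
  G <- ncol(iou_mat)
  stop_if_not(G > 0, "AP is undefined with no ground truths")
  if (length(conf) == 0) return(0)
  tp <- match_detections(conf, iou_mat, iou_threshold)
  ord <- order(conf, decreasing = TRUE)
  conf_s <- conf[ord]; tp_s <- tp[ord]
  cum_tp <- cumsum(tp_s)
  # threshold set = distinct confidences; each threshold admits all
  # detections with conf >= that value
  last_of_group <- which(!duplicated(conf_s, fromLast = TRUE))
  r <- cum_tp[last_of_group] / G
  p <- cum_tp[last_of_group] / last_of_group
  sum((r - c(0, r[-length(r)])) * p)
}

#' PR-curve points underlying [average_precision()]
#'
#' @inheritParams average_precision
#' @return data.frame with \code{threshold}, \code{recall}, \code{precision}
#'   ordered by descending confidence threshold.
#' @export
pr_curve <- function(conf, iou_mat, iou_threshold = 0.5) {
  iou_mat <- as.matrix(iou_mat)
  tp <- match_detections(conf, iou_mat, iou_threshold)
  ord <- order(conf, decreasing = TRUE)
  conf_s <- conf[ord]; cum_tp <- cumsum(tp[ord])
  idx <- which(!duplicated(conf_s, fromLast = TRUE))
  data.frame(threshold = conf_s[idx],
             recall = cum_tp[idx] / ncol(iou_mat),
             precision = cum_tp[idx] / idx)
}

# build a D x G IoU matrix for one geometry ("mask" or "box"); detections
# and gts are lists with $mask / $bbox and $image_id
iou_matrix <- function(dets, gts, geometry) {
  D <- length(dets); G <- length(gts)
  m <- matrix(0, max(D, 1), max(G, 1))[seq_len(D), seq_len(G), drop = FALSE]
  if (D == 0 || G == 0) return(matrix(0, D, G))
  for (d in seq_len(D)) for (g in seq_len(G)) {
    if (!identical(dets[[d]]$image_id %||% 1L, gts[[g]]$image_id %||% 1L)) next
    m[d, g] <- if (geometry == "mask") iou(dets[[d]]$mask, gts[[g]]$mask)
               else iou(dets[[d]]$bbox, gts[[g]]$bbox)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive c(x0, y0, x1, y1) half-open pixel box from a mask if absent
ensure_bbox <- function(obj) {
  if (is.null(obj$bbox) && !is.null(obj$mask)) {
    bb <- mask_bbox(obj$mask)
    obj$bbox <- c(bb$x0, bb$y0, bb$x1 + 1, bb$y1 + 1)
  }
  obj
}

#' mAP suite: mAP50 and mAP50:95 for boxes and masks
#'
#' mAP50 is the mean over classes of AP at IoU 0.5; mAP50:95 averages mAP
#' over the ten IoU thresholds 0.50, 0.55, ..., 0.95. Both are computed
#' separately for bounding boxes (B) and segmentation masks (M).
#'
#' @param detections list of detections: each a list with \code{class_id},
#'   \code{confidence}, \code{mask} (binary frame matrix) and/or \code{bbox}
#'   (c(x0, y0, x1, y1)), and optional \code{image_id}.
#' @param ground_truths list of ground truths with the same fields (no
#'   confidence).
#' @return list: \code{mAP50_B}, \code{mAP50_M}, \code{mAP5095_B},
#'   \code{mAP5095_M}, \code{ap_per_class} (at IoU 0.5, by geometry).
#' @export
map_suite <- function(detections, ground_truths) {
  stop_if_not(length(ground_truths) > 0, "no ground truths")
  detections <- lapply(detections, ensure_bbox)
  ground_truths <- lapply(ground_truths, ensure_bbox)
  classes <- sort(unique(vapply(ground_truths, function(g) as.integer(g$class_id), integer(1))))
  stop_if_not(length(classes) > 0, "empty class set")
  thresholds <- seq(0.5, 0.95, by = 0.05)
  has_mask <- all(vapply(ground_truths, function(g) !is.null(g$mask), logical(1))) &&
    (length(detections) == 0 ||
       all(vapply(detections, function(d) !is.null(d$mask), logical(1))))

  ap_at <- function(geometry, thr) {
    vapply(classes, function(cl) {
      dets <- Filter(function(d) d$class_id == cl, detections)
      gts <- Filter(function(g) g$class_id == cl, ground_truths)
      conf <- vapply(dets, function(d) d$confidence, numeric(1))
      average_precision(conf, iou_matrix(dets, gts, geometry), thr)
    }, numeric(1))
  }
  map_b <- vapply(thresholds, function(t) mean(ap_at("box", t)), numeric(1))
  map_m <- if (has_mask) vapply(thresholds, function(t) mean(ap_at("mask", t)), numeric(1)) else rep(NA_real_, 10)
  list(mAP50_B = map_b[1], mAP50_M = map_m[1],
       mAP5095_B = mean(map_b), mAP5095_M = mean(map_m),
       ap_per_class = list(box = ap_at("box", 0.5),
                           mask = if (has_mask) ap_at("mask", 0.5) else NULL),
       classes = classes)
}

#' Classification-mode AP over ROIs
#'
#' Scores each region of interest by the maximum detection confidence inside
#' it and evaluates MMD vs non-MMD classification with the same
#' precision-recall AP formula (every positive ROI is one ground truth; a
#' scored ROI is a true positive iff it is a positive ROI).
#'
#' @param scores per-ROI maximum confidence scores.
#' @param is_positive logical, per-ROI ground-truth class.
#' @return AP in [0, 1].
#' @export
classification_ap <- function(scores, is_positive) {
  stop_if_not(length(scores) == length(is_positive), "length mismatch")
  stop_if_not(any(is_positive), "no positive ROIs")
  im <- diag(as.numeric(is_positive))[, is_positive, drop = FALSE]
  average_precision(scores, im, iou_threshold = 0.5)
}

#' Region specification for contrast / noise measurement
#'
#' @param M_obj,M_back,M_noise binary masks over the measured image;
#'   \code{M_obj} and \code{M_back} must be disjoint.
#' @return a \code{region_spec}.
#' @export
region_spec <- function(M_obj = NULL, M_back = NULL, M_noise = NULL) {
  if (!is.null(M_obj)) M_obj <- as_mask(M_obj)
  if (!is.null(M_back)) M_back <- as_mask(M_back)
  if (!is.null(M_noise)) M_noise <- as_mask(M_noise)
  if (!is.null(M_obj) && !is.null(M_back)) {
    stop_if_not(sum(M_obj * M_back) == 0, "M_obj and M_back must be disjoint")
  }
  structure(list(M_obj = M_obj, M_back = M_back, M_noise = M_noise),
            class = "region_spec")
}

#' Michelson contrast between object and background regions
#'
#' (mean_obj - mean_back) / (mean_obj + mean_back), means taken over the
#' named regions of the image.
#'
#' @param image an \code{xr_image}.
#' @param regions a [region_spec()] with non-empty \code{M_obj}, \code{M_back}.
#' @return contrast in [-1, 1].
#' @export
michelson_contrast <- function(image, regions) {
  stop_if_not(inherits(regions, "region_spec"), "regions must be a region_spec")
  stop_if_not(!is.null(regions$M_obj) && mask_area(regions$M_obj) > 0, "M_obj empty")
  stop_if_not(!is.null(regions$M_back) && mask_area(regions$M_back) > 0, "M_back empty")
  v <- unclass(image)
  mo <- mean(v[regions$M_obj == 1]); mb <- mean(v[regions$M_back == 1])
  if (mo + mb == 0) stop("contrast undefined: both region means are zero", call. = FALSE)
  (mo - mb) / (mo + mb)
}

#' Robust noise estimate from a homogeneous region
#'
#' The median absolute deviation of pixel intensities in the noise region —
#' the median of absolute deviations from the median intensity — scaled by
#' 1.4826 to approximate the standard deviation of Gaussian noise.
#'
#' @param image an \code{xr_image}.
#' @param region binary noise-region mask (or a [region_spec()] with
#'   \code{M_noise}).
#' @return sigma estimate in intensity units.
#' @export
estimate_noise <- function(image, region) {
  if (inherits(region, "region_spec")) region <- region$M_noise
  region <- as_mask(region)
  stop_if_not(mask_area(region) > 0, "noise region is empty")
  v <- unclass(image)[region == 1]
  1.4826 * stats::median(abs(v - stats::median(v)))
}

#' Assemble an evaluation report
#'
#' @param map a [map_suite()] result (optional).
#' @param lsr localization success ratio in [0, 1] (optional).
#' @param contrast Michelson contrast (optional).
#' @param noise_sigma noise estimate (optional).
#' @return an \code{eval_report} list.
#' @export
eval_report <- function(map = NULL, lsr = NULL, contrast = NULL, noise_sigma = NULL) {
  structure(list(mAP50_B = map$mAP50_B, mAP50_M = map$mAP50_M,
                 mAP5095_B = map$mAP5095_B, mAP5095_M = map$mAP5095_M,
                 ap_per_class = map$ap_per_class,
                 lsr = lsr, contrast = contrast, noise_sigma = noise_sigma),
            class = "eval_report")
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report an [eval_report()].
#' @param stem output path stem (writes \code{<stem>.json}, \code{<stem>.csv}).
#' @export
write_eval_report <- function(report, stem) {
  flat <- report[c("mAP50_B", "mAP50_M", "mAP5095_B", "mAP5095_M",
                   "lsr", "contrast", "noise_sigma")]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  jsonlite::write_json(flat, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(metric = names(flat),
                              value = unlist(flat), row.names = NULL),
                   paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}
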