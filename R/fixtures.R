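#' Scripted device trajectory
#'
#' @param waypoints k x 2 matrix of (x, y) waypoints in pixels.
#' @param speed pixels per frame along the polyline path (> 0).
#' @param n_frames frame count.
#' @param occlusion_windows list of integer vectors \code{c(first, last)}
#'   (0-based frame indices) during which the instance is rendered beneath
#'   the device mask.
#' @param seed integer seed.
#' @return a \code{trajectory_spec}.
#' @export
trajectory_spec <- function(waypoints, speed, n_frames,
                            occlusion_windows = list(), seed = NULL) {
  waypoints <- as.matrix(waypoints)
  stop_if_not(nrow(waypoints) >= 2 && ncol(waypoints) == 2,
              "need at least two (x, y) waypoints")
  stop_if_not(is_num1(speed) && speed > 0, "speed must be > 0")
  stop_if_not(is_num1(n_frames) && n_frames >= 1, "n_frames must be >= 1")
  for (w in occlusion_windows) {
    stop_if_not(length(w) == 2 && w[1] >= 0 && w[2] < n_frames && w[1] <= w[2],
                "occlusion windows must lie within [0, n_frames)")
  }
  structure(list(waypoints = waypoints, speed = speed,
                 n_frames = as.integer(n_frames),
                 occlusion_windows = occlusion_windows, seed = seed),
            class = "trajectory_spec")
}

# position at arclength s along the waypoint polyline (clamped to the end)
path_position <- function(waypoints, s) {
  seg <- diff(waypoints)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- min(max(s, 0), cum[length(cum)])
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  k <- min(k, nrow(seg))
  t <- if (lens[k] > 0) (s - cum[k]) / lens[k] else 0
  waypoints[k, ] + t * seg[k, ]
}

in_any_window <- function(frame0, windows) {
  any(vapply(windows, function(w) frame0 >= w[1] && frame0 <= w[2], logical(1)))
}

#' Render a scripted frame sequence with per-frame ground truth
#'
#' Moves one sprite instance along the waypoint path at \code{speed} pixels
#' per frame (frame k sits at arclength k * speed), alpha-blending it into
#' the background each frame with a fixed per-sequence contrast draw. During
#' occlusion windows the instance is rendered beneath \code{M_device}
#' (device pixels restored over the blend). Frames whose visible fraction
#' falls below \code{cfg$min_visible_fraction} carry no label.
#'
#' @param background an \code{xr_image}.
#' @param mask3 the scene [mask_triple()].
#' @param sprite the \code{sprite} to animate.
#' @param traj a [trajectory_spec()].
#' @param cfg a [randomization_config()]; contrast, target height and
#'   visibility threshold are taken from it. Rotation is frozen per sequence.
#' @param noise optional [noise_spec()] applied per frame (seed offset by
#'   frame index so frames differ).
#' @return list: \code{frames} (list of \code{xr_image}), \code{labels}
#'   (per-frame list of [instance_label()], possibly empty), \code{truth}
#'   (data.frame: frame, x, y, bbox sides, visible), \code{sprite} (the
#'   transformed instance).
#' @export
make_sequence <- function(background, mask3, sprite, traj, cfg, noise = NULL) {
  stop_if_not(inherits(traj, "trajectory_spec"), "traj must be a trajectory_spec")
  W <- img_width(background); H <- img_height(background)
  with_seed(traj$seed, {
    sp <- transform_sprite(sprite, cfg)
    h <- nrow(sp$mask); w <- ncol(sp$mask)
    rho <- stats::runif(1, cfg$rho_low, cfg$rho_high)
    frames <- vector("list", traj$n_frames)
    labels <- vector("list", traj$n_frames)
    truth <- data.frame(frame = integer(traj$n_frames), x = NA_real_, y = NA_real_,
                        w = w, h = h, visible = FALSE)
    for (k in seq_len(traj$n_frames) - 1L) {
      ctr <- path_position(traj$waypoints, k * traj$speed)
      px <- round(ctr[1] - (w - 1) / 2); py <- round(ctr[2] - (h - 1) / 2)
      if (px < 0 || py < 0 || px + w > W || py + h > H) {
        stop(sprintf("path leaves the frame at frame %d (centre %.1f, %.1f)",
                     k, ctr[1], ctr[2]), call. = FALSE)
      }
      rows <- (py + 1L):(py + h); cols <- (px + 1L):(px + w)
      v_b <- unclass(background)[rows, cols, drop = FALSE]
      v_t <- pmin(pmax(rho * v_b, cfg$v_min), cfg$v_max)
      bl <- blend(background, sp, c(px, py), v_t, mode = "corrected")
      img <- unclass(bl$image)
      occluded <- in_any_window(k, traj$occlusion_windows)
      occ_px <- matrix(0L, h, w)
      if (occluded) {
        sub_dev <- mask3$M_device[rows, cols, drop = FALSE]
        occ_px <- sp$mask * sub_dev
        if (any(occ_px == 1)) {
          patch <- img[rows, cols, drop = FALSE]
          bgp <- unclass(background)[rows, cols, drop = FALSE]
          patch[occ_px == 1] <- bgp[occ_px == 1]
          img[rows, cols] <- patch
        }
      }
      visible <- matrix(0L, H, W)
      visible[rows, cols] <- sp$mask * (1L - occ_px)
      frac <- sum(visible) / sum(sp$mask)
      fr <- xr_image(img)
      if (!is.null(noise)) {
        ns <- noise
        ns$seed <- if (is.null(noise$seed)) NULL else noise$seed + k
        fr <- inject_noise(fr, ns)
      }
      frames[[k + 1L]] <- fr
      truth[k + 1L, ] <- list(k, ctr[1], ctr[2], w, h, frac >= cfg$min_visible_fraction)
      labels[[k + 1L]] <- if (frac >= cfg$min_visible_fraction && sum(visible) >= 3) {
        list(label_from_mask(visible, sp$class_id, W, H)$label)
      } else {
        list()
      }
    }
    list(frames = frames, labels = labels, truth = truth, sprite = sp)
  })
}

#' Mock detector specification
#'
#' @param fn_rate per-frame probability of dropping the true detection.
#' @param fp_rate expected clutter detections per frame (Poisson mean);
#'   clutter is placed uniformly over the frame so that only the temporal
#'   gate — not luck — can reject it.
#' @param position_jitter_sigma Gaussian jitter of surviving detections, px.
#' @param confidence_range clutter confidence bounds within [0, 1].
#' @param seed integer seed.
#' @return a \code{mock_detector_spec}.
#' @export
mock_detector_spec <- function(fn_rate = 0, fp_rate = 0, position_jitter_sigma = 0,
                               confidence_range = c(0.3, 0.9), seed = NULL) {
  stop_if_not(is_num1(fn_rate) && fn_rate >= 0 && fn_rate <= 1, "fn_rate in [0, 1]")
  stop_if_not(is_num1(fp_rate) && fp_rate >= 0, "fp_rate >= 0")
  stop_if_not(is_num1(position_jitter_sigma) && position_jitter_sigma >= 0,
              "jitter sigma >= 0")
  stop_if_not(all(confidence_range >= 0 & confidence_range <= 1) &&
                confidence_range[1] <= confidence_range[2],
              "confidence_range must be within [0, 1]")
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate,
                 position_jitter_sigma = position_jitter_sigma,
                 confidence_range = confidence_range, seed = seed),
            class = "mock_detector_spec")
}

#' Ground-truth-driven mock detector
#'
#' Builds a detector satisfying the tracking detector interface from
#' per-frame ground truth: the true detection is dropped with probability
#' \code{fn_rate}, surviving positions are jittered by Gaussian noise, and
#' Poisson(\code{fp_rate}) clutter detections with sizes near the true
#' object's are added at uniform frame positions. The full detection stream
#' is drawn once at construction under \code{spec$seed}, so repeated calls
#' on the same frame (e.g. from overlapping patches) are consistent and two
#' detectors built from the same spec produce identical streams.
#'
#' @param spec a [mock_detector_spec()].
#' @param truth the \code{truth} data.frame of [make_sequence()] (columns
#'   frame, x, y, w, h, visible).
#' @param frame_dims c(width, height) of the frames.
#' @param class_id class id to report.
#' @return function \code{(crop, offset, frame_index)} -> list of
#'   [detection()]s in frame coordinates whose centres fall inside the crop.
#' @export
mock_detector <- function(spec, truth, frame_dims, class_id = 0L) {
  stop_if_not(inherits(spec, "mock_detector_spec"), "spec must be a mock_detector_spec")
  W <- frame_dims[1]; H <- frame_dims[2]
  per_frame <- with_seed(spec$seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      out <- list()
      tr <- truth[i, ]
      if (isTRUE(tr$visible) && stats::runif(1) >= spec$fn_rate) {
        ctr <- c(tr$x, tr$y)
        if (spec$position_jitter_sigma > 0) {
          ctr <- ctr + stats::rnorm(2, 0, spec$position_jitter_sigma)
        }
        out[[1]] <- detection(
          bbox = c(ctr[1] - tr$w / 2, ctr[2] - tr$h / 2,
                   ctr[1] + tr$w / 2, ctr[2] + tr$h / 2),
          confidence = stats::runif(1, 0.6, 0.95), class_id = class_id)
      }
      n_fp <- stats::rpois(1, spec$fp_rate)
      for (j in seq_len(n_fp)) {
        cx <- stats::runif(1, 0, W - 1); cy <- stats::runif(1, 0, H - 1)
        sw <- tr$w * stats::runif(1, 0.8, 1.2); sh <- tr$h * stats::runif(1, 0.8, 1.2)
        out[[length(out) + 1L]] <- detection(
          bbox = c(cx - sw / 2, cy - sh / 2, cx + sw / 2, cy + sh / 2),
          confidence = stats::runif(1, spec$confidence_range[1],
                                    spec$confidence_range[2]),
          class_id = class_id)
      }
      out
    })
  })
  function(crop, offset, frame_index) {
    stop_if_not(frame_index >= 1 && frame_index <= length(per_frame),
                "frame index out of range")
    x0 <- offset[1]; y0 <- offset[2]
    x1 <- x0 + ncol(crop); y1 <- y0 + nrow(crop)
    Filter(function(d) d$position[1] >= x0 && d$position[1] < x1 &&
             d$position[2] >= y0 && d$position[2] < y1,
           per_frame[[frame_index]])
  }
}

#' File-backed oracle detector
#'
#' Reads the per-frame label files of a dataset and serves the stored
#' polygons back as detections at a fixed confidence — a perfect detector
#' for end-to-end tracking runs with no trained model.
#'
#' @param label_paths character vector of label files, one per frame.
#' @param frame_dims c(width, height) used to denormalize polygons.
#' @param confidence reported confidence.
#' @return a detector function \code{(crop, offset, frame_index)}.
#' @export
oracle_detector <- function(label_paths, frame_dims, confidence = 0.9) {
  W <- frame_dims[1]; H <- frame_dims[2]
  per_frame <- lapply(label_paths, function(p) {
    lapply(read_labels(p), function(lb) {
      poly <- label_polygon_px(lb, W, H)
      detection(bbox = c(min(poly[, 1]), min(poly[, 2]),
                         max(poly[, 1]) + 1, max(poly[, 2]) + 1),
                confidence = confidence, class_id = lb$class_id, polygon = poly)
    })
  })
  function(crop, offset, frame_index) {
    x0 <- offset[1]; y0 <- offset[2]
    x1 <- x0 + ncol(crop); y1 <- y0 + nrow(crop)
    Filter(function(d) d$position[1] >= x0 && d$position[1] < x1 &&
             d$position[2] >= y0 && d$position[2] < y1,
           per_frame[[frame_index]])
  }
}
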