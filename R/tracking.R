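#' Frame preprocessing: brightness/contrast rescale and histogram equalization
#'
#' Applies the linear map \code{v * contrast + brightness} (clipped to
#' [0, 255]) and then, when requested, global histogram equalization. A
#' constant frame has a degenerate histogram and is returned unchanged by
#' the equalization step; any non-constant frame spans the full [0, 255]
#' range afterwards.
#'
#' @param frame an \code{xr_image}.
#' @param brightness additive offset in intensity units.
#' @param contrast multiplicative gain.
#' @param equalize logical; apply histogram equalization.
#' @return preprocessed \code{xr_image}.
#' @export
preprocess_frame <- function(frame, brightness = 0, contrast = 1, equalize = FALSE) {
  v <- unclass(frame)
  if (brightness != 0 || contrast != 1) v <- clip8(v * contrast + brightness)
  if (equalize) {
    vals <- sort(unique(as.vector(v)))
    if (length(vals) > 1) {
      cdf <- cumsum(tabulate(match(as.vector(v), vals), length(vals)))
      cdf_min <- cdf[1]
      lut <- round(255 * (cdf - cdf_min) / (length(v) - cdf_min))
      v <- matrix(lut[match(as.vector(v), vals)], nrow(v), ncol(v))
    }
  }
  xr_image(v)
}

#' Detection object
#'
#' @param bbox axis-aligned box \code{c(x0, y0, x1, y1)} in frame
#'   coordinates (half-open pixel box).
#' @param confidence detector confidence in [0, 1].
#' @param class_id integer class id.
#' @param polygon optional frame-coordinate polygon vertices.
#' @param source_patch optional patch index the detection came from.
#' @return a \code{detection} list with a derived \code{position} (bbox
#'   centre).
#' @export
detection <- function(bbox, confidence, class_id = 0L, polygon = NULL,
                      source_patch = NULL) {
  stop_if_not(length(bbox) == 4 && bbox[3] >= bbox[1] && bbox[4] >= bbox[2],
              "bbox must be c(x0, y0, x1, y1)")
  stop_if_not(is_num1(confidence) && confidence >= 0 && confidence <= 1,
              "confidence must be in [0, 1]")
  structure(list(bbox = as.numeric(bbox), confidence = confidence,
                 class_id = as.integer(class_id), polygon = polygon,
                 source_patch = source_patch,
                 position = c((bbox[1] + bbox[3]) / 2, (bbox[2] + bbox[4]) / 2)),
            class = "detection")
}

#' Detection gate configuration
#'
#' The five acceptance criteria applied to raw detections: (1) a minimum
#' model confidence; (2) geometric consistency of the detected device (the
#' bbox's short side within \code{width_range} and long side within
#' \code{length_range}); (3) temporal continuity — distance between the
#' detection and the Kalman-predicted position at most \code{max_step},
#' widened by a factor (1 + 0.5 * frames_since_detection) while coasting;
#' (4) anatomical plausibility — distance to the lumen centreline at most
#' \code{max_centreline_distance} when a centreline is supplied; (5) the
#' historical localization success rate over the past ten frames — when it
#' drops below \code{min_history_rate} the confidence threshold is escalated
#' towards 1 (halving the remaining headroom), demanding stronger evidence
#' after a run of failures.
#'
#' @param min_confidence confidence gate in [0, 1].
#' @param width_range,length_range acceptable bbox short/long side in pixels.
#' @param max_step maximum displacement per frame in pixels; the default of
#'   12 reflects the slow device motion regime (a few px/frame at clinical
#'   frame rates) with headroom for detector jitter.
#' @param max_centreline_distance pixels; \code{Inf} disables gate (4).
#' @param min_history_rate success-rate floor for gate (5), in [0, 1].
#' @param max_coast_frames consecutive misses before the tracker falls back
#'   to global search.
#' @return a \code{gate_config}.
#' @export
gate_config <- function(min_confidence = 0.25,
                        width_range = c(2, 120), length_range = c(2, 240),
                        max_step = 12, max_centreline_distance = Inf,
                        min_history_rate = 0.5, max_coast_frames = 15L) {
  stop_if_not(width_range[1] < width_range[2] && length_range[1] < length_range[2],
              "size ranges must be non-degenerate")
  stop_if_not(is_num1(max_step) && max_step > 0, "max_step must be > 0")
  structure(list(min_confidence = min_confidence, width_range = width_range,
                 length_range = length_range, max_step = max_step,
                 max_centreline_distance = max_centreline_distance,
                 min_history_rate = min_history_rate,
                 max_coast_frames = as.integer(max_coast_frames)),
            class = "gate_config")
}

#' Tracker state
#'
#' Constant-velocity Kalman state (x, y, vx, vy) with covariance, the
#' current mode (GLOBAL full-frame search or LOCAL region-of-interest), the
#' success history of the last ten frames and the coasting counter.
#'
#' @param position initial (x, y) in pixels.
#' @param velocity initial (vx, vy) in pixels/frame.
#' @param covariance 4 x 4 positive-semidefinite matrix.
#' @param mode \code{"GLOBAL"} or \code{"LOCAL"}.
#' @return a \code{track_state}.
#' @export
track_state <- function(position, velocity = c(0, 0),
                        covariance = diag(c(25, 25, 25, 25)), mode = "GLOBAL") {
  stop_if_not(all(dim(covariance) == c(4, 4)), "covariance must be 4 x 4")
  stop_if_not(isTRUE(all.equal(covariance, t(covariance))) &&
                all(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values > -1e-8),
              "covariance must be symmetric positive-semidefinite")
  structure(list(position = as.numeric(position), velocity = as.numeric(velocity),
                 covariance = covariance, mode = mode, roi = NULL,
                 history = logical(0), frames_since_detection = 0L,
                 object_size = NULL),
            class = "track_state")
}

history_rate <- function(state) {
  if (length(state$history) == 0) return(1)
  mean(state$history)
}

# effective confidence gate after escalation by criterion (5)
effective_min_confidence <- function(gates, state) {
  if (history_rate(state) < gates$min_history_rate) {
    gates$min_confidence + 0.5 * (1 - gates$min_confidence)
  } else {
    gates$min_confidence
  }
}

# minimum distance from point p to a polyline (k x 2 matrix)
point_polyline_distance <- function(p, line) {
  if (nrow(line) == 1) return(sqrt(sum((p - line[1, ])^2)))
  a <- line[-nrow(line), , drop = FALSE]; b <- line[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, `+`)
  t <- pmin(pmax(rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-12), 0), 1)
  proj <- a + ab * t
  sqrt(min(rowSums(sweep(proj, 2, p)^2)))
}

#' Filter detections through the five acceptance gates
#'
#' Applies the gates of [gate_config()] against the Kalman-predicted
#' position in \code{state}; among survivors the detection nearest the
#' predicted position is selected.
#'
#' @param detections list of [detection()] objects.
#' @param state the current [track_state()] (position = predicted position).
#' @param gates a [gate_config()].
#' @param centreline optional k x 2 polyline of lumen centreline points.
#' @return list: \code{accepted} (best surviving detection or \code{NULL}),
#'   \code{survivors} (all passing detections).
#' @export
filter_detections <- function(detections, state, gates, centreline = NULL) {
  min_conf <- effective_min_confidence(gates, state)
  widen <- 1 + 0.5 * state$frames_since_detection
  pass <- vapply(detections, function(d) {
    if (d$confidence < min_conf) return(FALSE)
    sides <- sort(c(d$bbox[3] - d$bbox[1], d$bbox[4] - d$bbox[2]))
    if (sides[1] < gates$width_range[1] || sides[1] > gates$width_range[2]) return(FALSE)
    if (sides[2] < gates$length_range[1] || sides[2] > gates$length_range[2]) return(FALSE)
    if (!is.null(state$position)) {
      if (sqrt(sum((d$position - state$position)^2)) > gates$max_step * widen) return(FALSE)
    }
    if (!is.null(centreline) && is.finite(gates$max_centreline_distance)) {
      if (point_polyline_distance(d$position, centreline) >
            gates$max_centreline_distance) return(FALSE)
    }
    TRUE
  }, logical(1))
  survivors <- detections[pass]
  if (length(survivors) == 0) return(list(accepted = NULL, survivors = survivors))
  if (is.null(state$position)) {
    best <- which.max(vapply(survivors, function(d) d$confidence, numeric(1)))
  } else {
    best <- which.min(vapply(survivors, function(d)
      sum((d$position - state$position)^2), numeric(1)))
  }
  list(accepted = survivors[[best]], survivors = survivors)
}

# constant-velocity transition and white-acceleration process noise
kalman_matrices <- function(dt = 1, q = 0.05) {
  F_ <- diag(4); F_[1, 3] <- dt; F_[2, 4] <- dt
  Q <- q * rbind(cbind(diag(2) * dt^4 / 4, diag(2) * dt^3 / 2),
                 cbind(diag(2) * dt^3 / 2, diag(2) * dt^2))
  list(F_ = F_, Q = Q)
}

#' One adaptive Kalman predict/update step
#'
#' Constant-velocity prediction; when a measurement is present, a standard
#' update whose measurement-noise covariance is scaled by 1/confidence (the
#' adaptivity: low-confidence detections pull the state less). Without a
#' measurement the state coasts on the prediction and the coasting counter
#' increments. The ten-frame success history is shifted accordingly.
#'
#' @param state a [track_state()].
#' @param measurement optional (x, y) position; non-finite values are
#'   treated as missing.
#' @param confidence measurement confidence in (0, 1].
#' @param dt frame interval (frames).
#' @param q white-acceleration process-noise intensity (px^2/frame^4);
#'   defaults are low because device speed is bounded (under 3 mm/s at up to
#'   30 frames/s).
#' @param r0 baseline measurement noise variance (px^2).
#' @return the updated \code{track_state}.
#' @export
kalman_step <- function(state, measurement = NULL, confidence = 1,
                        dt = 1, q = 0.05, r0 = 1) {
  km <- kalman_matrices(dt, q)
  x <- c(state$position, state$velocity)
  x <- km$F_ %*% x
  P <- km$F_ %*% state$covariance %*% t(km$F_) + km$Q

  if (!is.null(measurement) && all(is.finite(measurement))) {
    H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
    R <- diag(2) * r0 / max(confidence, 1e-6)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (measurement - H %*% x)
    IKH <- diag(4) - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)  # Joseph form keeps P PSD
    state$frames_since_detection <- 0L
    success <- TRUE
  } else {
    state$frames_since_detection <- state$frames_since_detection + 1L
    success <- FALSE
  }
  state$position <- as.numeric(x[1:2])
  state$velocity <- as.numeric(x[3:4])
  state$covariance <- (P + t(P)) / 2
  state$history <- utils::tail(c(state$history, success), 10)
  state
}

# merge duplicate detections across overlapping patches: clusters at
# box-IoU >= 0.5, keeping the highest-confidence member of each cluster
merge_duplicates <- function(detections, iou_threshold = 0.5) {
  if (length(detections) <= 1) return(detections)
  ord <- order(vapply(detections, function(d) d$confidence, numeric(1)),
               decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(k) iou(k$bbox, detections[[i]]$bbox) >= iou_threshold,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- detections[[i]]
  }
  kept
}

#' Track a device through a frame sequence (dual-mode loop)
#'
#' Starts in GLOBAL mode: the frame is tiled into overlapping patches
#' ([tile_image()]), the detector runs per patch, detections are lifted to
#' frame coordinates and duplicates across overlaps merged (box IoU >= 0.5,
#' max confidence kept). Once a detection is accepted the tracker switches
#' to LOCAL mode, running the detector only on a region of interest around
#' the last known position (side = max(4 x object size,
#' \code{roi_min_side})). After \code{max_coast_frames} consecutive misses
#' it reverts to GLOBAL. The logged position is the accepted measurement
#' when one exists and the Kalman prediction while coasting (occlusion
#' interpolation). The \code{localized} flag of the log marks frames with an
#' accepted detection; the localization success ratio (LSR) counts a frame
#' as successfully localized when the tracker produced a position from a
#' live track — an accepted detection, or Kalman interpolation within
#' \code{max_coast_frames} of the last acceptance — divided by total frames.
#' \code{detection_rate} is the stricter accepted-detections-only ratio.
#'
#' @param frames list of \code{xr_image} frames (or character paths).
#' @param detector function \code{(crop, offset, frame_index)} returning a
#'   list of [detection()]s in frame coordinates (\code{offset} is the
#'   crop's 0-based top-left corner).
#' @param gates a [gate_config()].
#' @param grid_spec list with \code{n_cols}, \code{n_rows},
#'   \code{min_overlap_fraction} for global-mode tiling.
#' @param centreline optional lumen centreline polyline for gate (4).
#' @param roi_min_side minimum LOCAL-mode crop side in pixels.
#' @param q,r0 Kalman noise parameters, see [kalman_step()].
#' @return list: \code{log} (data.frame: frame, x, y, confidence, mode,
#'   localized), \code{lsr}, \code{detection_rate}, \code{states}
#'   (per-frame \code{track_state}).
#' @export
track_sequence <- function(frames, detector, gates = gate_config(),
                           grid_spec = list(n_cols = 5L, n_rows = 5L,
                                            min_overlap_fraction = 0.1),
                           centreline = NULL, roi_min_side = 64L,
                           q = 0.05, r0 = 1) {
  n <- length(frames)
  stop_if_not(n > 0, "no frames supplied")
  get_frame <- function(i) {
    f <- frames[[i]]
    if (is.character(f)) read_image(f) else f
  }
  state <- NULL
  log <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                    confidence = numeric(0), mode = character(0),
                    localized = logical(0))
  states <- vector("list", n)

  for (i in seq_len(n)) {
    frame <- get_frame(i)
    W <- img_width(frame); H <- img_height(frame)
    mode <- if (is.null(state)) "GLOBAL" else state$mode

    dets <- tryCatch({
      if (mode == "GLOBAL") {
        grid <- tile_image(frame, grid_spec$n_cols, grid_spec$n_rows,
                           grid_spec$min_overlap_fraction)
        all <- list()
        for (p in seq_along(grid$patches)) {
          d <- detector(xr_image(grid$patches[[p]]), grid$offsets[p, ], i)
          all <- c(all, d)
        }
        merge_duplicates(all)
      } else {
        side <- max(4 * max(state$object_size %||% 0), roi_min_side)
        x0 <- max(0, min(round(state$position[1] - side / 2), W - 1))
        y0 <- max(0, min(round(state$position[2] - side / 2), H - 1))
        x1 <- min(W, x0 + side); y1 <- min(H, y0 + side)
        crop <- unclass(frame)[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
        detector(xr_image(crop), c(x0, y0), i)
      }
    }, error = function(e) {
      warning(sprintf("detector failed on frame %d: %s", i, conditionMessage(e)))
      list()
    })

    if (is.null(state)) {
      # no track yet: gate on confidence/geometry only, seed from the best
      seedst <- track_state(position = c(NA, NA))
      seedst$position <- NULL
      fl <- filter_detections(dets, seedst, gates, centreline)
      if (!is.null(fl$accepted)) {
        d <- fl$accepted
        state <- track_state(position = d$position, mode = "LOCAL")
        state$object_size <- max(d$bbox[3] - d$bbox[1], d$bbox[4] - d$bbox[2])
        state$history <- TRUE
        log[nrow(log) + 1L, ] <- list(i, d$position[1], d$position[2],
                                      d$confidence, "GLOBAL", TRUE)
      } else {
        log[nrow(log) + 1L, ] <- list(i, NA_real_, NA_real_, NA_real_, "GLOBAL", FALSE)
      }
      states[[i]] <- state
      next
    }

    # predict, gate against the prediction, then update or coast
    pred <- kalman_step(state, measurement = NULL, dt = 1, q = q, r0 = r0)
    gate_state <- state
    gate_state$position <- pred$position
    fl <- filter_detections(dets, gate_state, gates, centreline)
    if (!is.null(fl$accepted)) {
      d <- fl$accepted
      state <- kalman_step(state, measurement = d$position,
                           confidence = d$confidence, dt = 1, q = q, r0 = r0)
      state$mode <- "LOCAL"
      state$object_size <- max(d$bbox[3] - d$bbox[1], d$bbox[4] - d$bbox[2])
      log[nrow(log) + 1L, ] <- list(i, d$position[1], d$position[2],
                                    d$confidence, mode, TRUE)
    } else {
      state <- pred
      if (state$frames_since_detection >= gates$max_coast_frames) state$mode <- "GLOBAL"
      log[nrow(log) + 1L, ] <- list(i, state$position[1], state$position[2],
                                    NA_real_, mode, FALSE)
    }
    states[[i]] <- state
  }
  coasting_ok <- vapply(states, function(s) {
    !is.null(s) && s$frames_since_detection <= gates$max_coast_frames
  }, logical(1))
  list(log = log,
       lsr = mean(log$localized | (!is.na(log$x) & coasting_ok)),
       detection_rate = mean(log$localized),
       states = states)
}

#' Write a track log as CSV
#'
#' @param result a [track_sequence()] result.
#' @param path CSV path.
#' @export
write_track_log <- function(result, path) {
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}
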