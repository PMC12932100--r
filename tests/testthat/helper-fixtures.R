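# shared in-code fixtures: no binary assets, everything built at test time

# a closed circular contour object (continuous, not mask-traced)
circle_contour <- function(cx, cy, r, n = 200) {
  th <- seq(0, 2 * pi, length.out = n)[-n]
  pts <- cbind(cx + r * cos(th), cy + r * sin(th))
  structure(list(points = rbind(pts, pts[1, , drop = FALSE]), closed = TRUE),
            class = "contour")
}

test_sprite <- function(seed = 5, l_min = 12, l_max = 20, intensity = 55) {
  ct <- generate_spline_contour(spline_shape_params(
    n = 9, centre = c(0, 0), l_min = l_min, l_max = l_max,
    n_interp = 160, seed = seed))
  contour_to_sprite(ct, intensity = intensity, class_id = 0L)
}

test_scene <- function(seed = 2, width = 256, height = 256,
                       n_lumen = 2, n_devices = 1) {
  m3 <- make_mask_triple(width, height, n_lumen, n_devices, seed = seed)
  list(mask3 = m3, background = render_background(m3, seed = seed))
}

# Independent brute-force AP oracle: its own greedy matcher, and an explicit
# loop over every distinct confidence threshold computing precision/recall
# from scratch at each.
oracle_greedy_match <- function(conf, iou_mat, threshold) {
  D <- length(conf)
  tp <- logical(D)
  if (D == 0 || ncol(iou_mat) == 0) return(tp)
  best <- apply(iou_mat, 1, max)
  used <- logical(ncol(iou_mat))
  for (d in order(-conf, -best)) {
    ok <- which(!used & iou_mat[d, ] > threshold)
    if (length(ok)) {
      g <- ok[which.max(iou_mat[d, ok])]
      used[g] <- TRUE
      tp[d] <- TRUE
    }
  }
  tp
}

oracle_ap <- function(conf, iou_mat, threshold = 0.5) {
  G <- ncol(iou_mat)
  if (length(conf) == 0) return(0)
  thresholds <- sort(unique(conf), decreasing = TRUE)
  r_prev <- 0
  ap <- 0
  for (t in thresholds) {
    keep <- conf >= t
    tp <- oracle_greedy_match(conf[keep], iou_mat[keep, , drop = FALSE], threshold)
    TP <- sum(tp)
    r <- TP / G
    p <- TP / sum(keep)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# random small detection/GT box instance for AP property tests
random_ap_instance <- function(seed) {
  set.seed(seed)
  G <- sample(1:5, 1)
  D <- sample(0:10, 1)
  gt_boxes <- lapply(seq_len(G), function(i) {
    x <- runif(1, 0, 80); y <- runif(1, 0, 80)
    c(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20))
  })
  det_boxes <- lapply(seq_len(D), function(i) {
    if (runif(1) < 0.6 && G > 0) {
      b <- gt_boxes[[sample(G, 1)]] + runif(4, -4, 4)  # near a GT
      c(pmin(b[1], b[3] - 1), pmin(b[2], b[4] - 1), pmax(b[3], b[1] + 1), pmax(b[4], b[2] + 1))
    } else {
      x <- runif(1, 0, 80); y <- runif(1, 0, 80)
      c(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20))
    }
  })
  conf <- runif(D)
  im <- matrix(0, max(D, 0), G)
  for (d in seq_len(D)) for (g in seq_len(G)) {
    im[d, g] <- iou(det_boxes[[d]], gt_boxes[[g]])
  }
  list(conf = conf, iou_mat = im)
}

# a rendered constant-velocity sequence plus its mock detector
tracking_fixture <- function(n_frames = 300, fn_rate = 0.2, fp_rate = 0.1,
                             jitter = 1, seed = 7) {
  sc <- test_scene(seed = 2, n_lumen = 0, n_devices = 1)
  spr <- test_sprite(seed = 5)
  cfg <- randomization_config(seed = 3, target_height = 20, height_jitter = 0,
                              rotation_range = 0, occlusion_probability = 0)
  wp <- rbind(c(40, 40), c(216, 40), c(216, 216), c(40, 216), c(40, 40))
  traj <- trajectory_spec(wp, speed = 2, n_frames = n_frames, seed = 4)
  seqq <- make_sequence(sc$background, sc$mask3, spr, traj, cfg)
  det <- mock_detector(
    mock_detector_spec(fn_rate = fn_rate, fp_rate = fp_rate,
                       position_jitter_sigma = jitter, seed = seed),
    seqq$truth, c(256, 256))
  list(seq = seqq, detector = det, scene = sc, sprite = spr, cfg = cfg)
}
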