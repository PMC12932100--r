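test_that("preprocessing is identity by default and equalization spans the range", {
  sc <- test_scene(seed = 1)
  expect_identical(unclass(preprocess_frame(sc$background)), unclass(sc$background))
  const <- xr_image(matrix(90, 40, 40))
  eq <- preprocess_frame(const, equalize = TRUE)
  expect_equal(length(unique(as.vector(unclass(eq)))), 1)  # degenerate histogram
  eq2 <- preprocess_frame(sc$background, equalize = TRUE)
  expect_equal(min(eq2), 0)
  expect_equal(max(eq2), 255)
  bright <- preprocess_frame(const, brightness = 20, contrast = 1.5)
  expect_true(all(unclass(bright) == 90 * 1.5 + 20))
})

test_that("the five gates reject by confidence, geometry, step, centreline and history", {
  g <- gate_config(min_confidence = 0.5, width_range = c(5, 30),
                   length_range = c(5, 60), max_step = 30,
                   max_centreline_distance = 15)
  st <- track_state(position = c(100, 100))
  near <- function(dx, dy, conf = 0.9, w = 10, h = 20) {
    detection(c(100 + dx - w / 2, 100 + dy - h / 2, 100 + dx + w / 2, 100 + dy + h / 2), conf)
  }
  # gate 1: confidence
  expect_null(filter_detections(list(near(0, 0, conf = 0.2)), st, g)$accepted)
  # gate 2: geometry
  expect_null(filter_detections(list(near(0, 0, w = 2, h = 3)), st, g)$accepted)
  expect_null(filter_detections(list(near(0, 0, w = 40, h = 80)), st, g)$accepted)
  # gate 3: temporal continuity
  expect_null(filter_detections(list(near(100, 0)), st, g)$accepted)
  # gate 4: centreline plausibility
  cl <- cbind(seq(0, 200, 10), 100)
  expect_null(filter_detections(list(near(0, 40)), st, g, centreline = cl)$accepted)
  expect_false(is.null(filter_detections(list(near(0, 10)), st, g, centreline = cl)$accepted))
  # gate 5: history escalation raises the confidence bar
  st_bad <- st; st_bad$history <- rep(c(TRUE, FALSE), c(2, 8))
  expect_null(filter_detections(list(near(0, 0, conf = 0.6)), st_bad, g)$accepted)
  expect_false(is.null(filter_detections(list(near(0, 0, conf = 0.9)), st_bad, g)$accepted))
  # nearest survivor is selected
  res <- filter_detections(list(near(12, 0), near(5, 0)), st, g)
  expect_equal(res$accepted$position[1], 105)
})

test_that("the coasting gate widens with frames since detection", {
  g <- gate_config(min_confidence = 0.1, max_step = 30)
  st <- track_state(position = c(0, 0))
  st$frames_since_detection <- 4L  # widen factor 3
  d <- detection(c(70 - 5, -5, 70 + 5, 5), 0.9)
  expect_false(is.null(filter_detections(list(d), st, g)$accepted))
  st$frames_since_detection <- 0L
  expect_null(filter_detections(list(d), st, g)$accepted)
})

test_that("the Kalman filter converges on constant-velocity motion", {
  st <- track_state(position = c(0, 0))
  errs <- numeric(0)
  for (k in 1:15) {
    st <- kalman_step(st, measurement = c(2 * k, k), confidence = 1)
    errs <- c(errs, sqrt(sum((st$position - c(2 * k, k))^2)))
  }
  expect_lt(errs[10], 0.5)
  expect_equal(st$velocity, c(2, 1), tolerance = 0.1)
})

test_that("coasting continues the linear path through a measurement gap", {
  st <- track_state(position = c(0, 0))
  for (k in 1:12) {
    meas <- if (k >= 6 && k <= 9) NULL else c(2 * k, 0)
    st <- kalman_step(st, meas, confidence = 1)
    if (k >= 6 && k <= 9) {
      expect_lt(abs(st$position[1] - 2 * k), 2)
      expect_lt(abs(st$position[2]), 2)
    }
  }
  expect_equal(st$frames_since_detection, 0L)
})

test_that("a stationary target's estimate converges to the repeated measurement", {
  st <- track_state(position = c(10, 10))
  for (k in 1:30) st <- kalman_step(st, c(50, 60), confidence = 1)
  expect_equal(st$position, c(50, 60), tolerance = 0.2)
})

test_that("covariance stays symmetric positive-semidefinite under random stepping", {
  set.seed(8)
  st <- track_state(position = c(0, 0))
  for (k in 1:2000) {
    meas <- if (runif(1) < 0.7) runif(2, 0, 200) else NULL
    st <- kalman_step(st, meas, confidence = runif(1, 0.05, 1))
    P <- st$covariance
    expect_identical(P, t(P))
    expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_lte(length(st$history), 10)
})

test_that("non-finite measurements are treated as missing", {
  st <- track_state(position = c(5, 5))
  st2 <- kalman_step(st, c(NaN, 3))
  expect_equal(st2$frames_since_detection, 1L)
})

test_that("duplicate detections across patch overlaps merge to max confidence", {
  d1 <- detection(c(10, 10, 30, 30), 0.9)
  d2 <- detection(c(11, 11, 31, 31), 0.7)   # IoU > 0.5 with d1
  d3 <- detection(c(100, 100, 120, 120), 0.8)
  m <- fluorosyn:::merge_duplicates(list(d2, d1, d3))
  expect_length(m, 2)
  confs <- sort(vapply(m, function(d) d$confidence, numeric(1)))
  expect_equal(confs, c(0.8, 0.9))
})

test_that("a perfect detector with open gates reproduces ground truth exactly", {
  fx <- tracking_fixture(n_frames = 60, fn_rate = 0, fp_rate = 0, jitter = 0)
  gates <- gate_config(min_confidence = 0, width_range = c(0.1, 500),
                       length_range = c(0.1, 500), max_step = 1e6)
  res <- track_sequence(fx$seq$frames, fx$detector, gates)
  expect_equal(res$lsr, 1)
  expect_equal(res$detection_rate, 1)
  expect_equal(res$log$x, fx$seq$truth$x, tolerance = 1e-9)
  expect_equal(res$log$y, fx$seq$truth$y, tolerance = 1e-9)
})

test_that("mode protocol: LOCAL after acceptance, GLOBAL after max_coast_frames", {
  fx <- tracking_fixture(n_frames = 40, fn_rate = 0, fp_rate = 0, jitter = 0)
  # withhold all detections for frames 10..30 by wrapping the detector
  base <- fx$detector
  det <- function(crop, offset, i) if (i >= 10 && i <= 30) list() else base(crop, offset, i)
  gates <- gate_config(max_coast_frames = 5)
  res <- track_sequence(fx$seq$frames, det, gates)
  expect_equal(res$log$mode[1], "GLOBAL")      # before initialization
  expect_equal(res$log$mode[3], "LOCAL")       # after first acceptance
  # during the outage the tracker coasts then falls back to global search
  expect_equal(res$log$mode[10 + 3], "LOCAL")  # still coasting (3 < 5 misses)
  expect_equal(res$log$mode[10 + 7], "GLOBAL") # after 5 consecutive misses
  expect_false(any(res$log$localized[10:30]))
  expect_true(all(res$log$localized[32:40]))   # re-acquired
})

test_that("clutter far from the prediction never perturbs the track", {
  fx <- tracking_fixture(n_frames = 80, fn_rate = 0, fp_rate = 1.5, jitter = 0)
  res <- track_sequence(fx$seq$frames, fx$detector, gate_config())
  keep <- !is.na(res$log$x)
  err <- sqrt((res$log$x - fx$seq$truth$x)^2 + (res$log$y - fx$seq$truth$y)^2)[keep]
  expect_lt(max(err), 1e-6)  # jitter-free truth: accepted measurements are exact
})

test_that("LSR equals the fraction of localized frames", {
  # drop the very first frame's detection: the track initializes late and the
  # strict and interpolation-aware definitions coincide (9/10 -> 0.9)
  fx <- tracking_fixture(n_frames = 10, fn_rate = 0, fp_rate = 0, jitter = 0)
  base <- fx$detector
  det <- function(crop, offset, i) if (i == 1) list() else base(crop, offset, i)
  res <- track_sequence(fx$seq$frames, det, gate_config())
  expect_equal(res$detection_rate, 0.9)
  expect_equal(res$lsr, 0.9)
})
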