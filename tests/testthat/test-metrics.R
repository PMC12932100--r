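test_that("IoU handles masks, boxes and edge conventions", {
  a <- matrix(0L, 10, 10); a[1:2, 1:2] <- 1L
  expect_equal(iou(a, a), 1)
  b <- matrix(0L, 10, 10); b[5:6, 5:6] <- 1L
  expect_equal(iou(a, b), 0)
  # 2x2 squares overlapping in 2 px -> 2/6
  c2 <- matrix(0L, 10, 10); c2[1:2, 2:3] <- 1L
  expect_equal(iou(a, c2), 2 / 6)
  expect_equal(iou(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)  # both empty
  expect_error(iou(a, matrix(0L, 5, 5)), "dimensions")
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 6)
})

test_that("average precision reproduces the hand-evaluated PR curve", {
  # 2 GT; ranked detections TP(0.9), FP(0.8), TP(0.7)
  im <- rbind(c(1, 0), c(0, 0), c(0, 1))
  ap <- average_precision(c(0.9, 0.8, 0.7), im, 0.5)
  expect_equal(ap, 0.5 * 1 + 0 * 0.5 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect and all-false cases
  expect_equal(average_precision(c(0.9, 0.8), diag(2), 0.5), 1)
  expect_equal(average_precision(c(0.9, 0.8), matrix(0, 2, 2), 0.5), 0)
  expect_error(average_precision(numeric(0), matrix(0, 0, 0)), "no ground truths")
})

test_that("AP matches the brute-force threshold-enumeration oracle", {
  for (s in 1:200) {
    inst <- random_ap_instance(s)
    for (thr in c(0.5, 0.75)) {
      expect_equal(average_precision(inst$conf, inst$iou_mat, thr),
                   oracle_ap(inst$conf, inst$iou_mat, thr),
                   tolerance = 1e-12)
    }
  }
})

test_that("AP is invariant under monotone confidence rescaling", {
  for (s in 1:25) {
    inst <- random_ap_instance(s)
    if (length(inst$conf) == 0) next
    resc <- inst$conf^3 * 0.9 + 0.05  # strictly monotone into [0, 1]
    expect_equal(average_precision(inst$conf, inst$iou_mat, 0.5),
                 average_precision(resc, inst$iou_mat, 0.5), tolerance = 1e-12)
  }
})

test_that("matching is strict (> threshold) and greedy by confidence", {
  im <- matrix(0.5, 1, 1)
  expect_equal(average_precision(1, im, 0.5), 0)    # IoU exactly 0.5 fails
  expect_equal(average_precision(1, im, 0.49), 1)
  # one GT, two detections: the higher-confidence one consumes the GT
  im2 <- rbind(0.9, 0.8)
  pr <- pr_curve(c(0.6, 0.9), im2, 0.5)
  expect_equal(pr$precision, c(1, 0.5))
})

test_that("mAP suite averages classes and the ten IoU thresholds", {
  mk <- function(x0, y0, s = 10) {
    m <- matrix(0L, 60, 60); m[(y0 + 1):(y0 + s), (x0 + 1):(x0 + s)] <- 1L
    m
  }
  gt <- list(list(class_id = 0L, mask = mk(5, 5)),
             list(class_id = 1L, mask = mk(30, 30)))
  perfect <- list(list(class_id = 0L, confidence = 0.9, mask = mk(5, 5)),
                  list(class_id = 1L, confidence = 0.9, mask = mk(30, 30)))
  r <- map_suite(perfect, gt)
  expect_equal(r$mAP50_B, 1); expect_equal(r$mAP50_M, 1)
  expect_equal(r$mAP5095_B, 1); expect_equal(r$mAP5095_M, 1)

  # a single detection at a fixed partial overlap: AP is 1 at thresholds
  # strictly below the realized IoU and 0 above, so mAP50:95 counts the
  # passing thresholds
  gt1 <- list(list(class_id = 0L, mask = mk(0, 0, 10)))
  det1 <- list(list(class_id = 0L, confidence = 0.9, mask = mk(2, 0, 10)))
  realized <- iou(det1[[1]]$mask, gt1[[1]]$mask)  # 80/120 = 2/3
  r1 <- map_suite(det1, gt1)
  expect_equal(r1$mAP5095_M, mean(seq(0.5, 0.95, 0.05) < realized))
  expect_lte(r1$mAP5095_B, r1$mAP50_B)  # monotone in threshold
})

test_that("classification-mode AP scores ROIs by max confidence", {
  expect_equal(classification_ap(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(classification_ap(c(0.9, 0.2), c(FALSE, TRUE)), 0.5)
})

test_that("Michelson contrast follows the two-region formula", {
  img <- xr_image(matrix(0, 20, 20))
  mo <- matrix(0L, 20, 20); mo[1:5, 1:5] <- 1L
  mb <- matrix(0L, 20, 20); mb[10:14, 10:14] <- 1L
  v <- matrix(40, 20, 20); v[1:5, 1:5] <- 60
  expect_equal(michelson_contrast(xr_image(v), region_spec(mo, mb)), 0.2)
  v2 <- matrix(50, 20, 20)
  expect_equal(michelson_contrast(xr_image(v2), region_spec(mo, mb)), 0)
  v3 <- matrix(0, 20, 20); v3[1:5, 1:5] <- 80
  expect_equal(michelson_contrast(xr_image(v3), region_spec(mo, mb)), 1)
  expect_error(region_spec(mo, mo), "disjoint")
})

test_that("MAD noise estimate matches the hand-computed value and recovers sigma", {
  v <- matrix(0, 1, 5); v[1, ] <- 1:5
  m <- matrix(1L, 1, 5)
  expect_equal(estimate_noise(xr_image(v), m), 1.4826)
  expect_equal(estimate_noise(xr_image(matrix(7, 4, 4)), matrix(1L, 4, 4)), 0)

  set.seed(2)
  big <- matrix(pmin(pmax(128 + stats::rnorm(200 * 200, 0, 10), 0), 255), 200, 200)
  est <- estimate_noise(xr_image(big), matrix(1L, 200, 200))
  expect_lt(abs(est - 10) / 10, 0.03)
})

test_that("the MAD estimator resists salt-and-pepper outliers where sd does not", {
  set.seed(5)
  n <- 200 * 200
  clean <- 128 + stats::rnorm(n, 0, 10)
  contaminate <- function(v, frac) {
    idx <- sample(n, frac * n)
    v[idx] <- ifelse(stats::runif(length(idx)) < 0.5, 0, 255)
    matrix(pmin(pmax(v, 0), 255), 200, 200)
  }
  region <- matrix(1L, 200, 200)
  # light contamination barely moves the estimate
  est5 <- estimate_noise(xr_image(contaminate(clean, 0.05)), region)
  expect_lt(abs(est5 - 10) / 10, 0.10)
  # at heavy contamination the MAD stays bounded (its known inflation is the
  # 0.5/(1 - eps) Gaussian quantile, ~1.43 sigma at eps = 0.25) while the
  # plain standard deviation explodes
  v25 <- contaminate(clean, 0.25)
  est25 <- estimate_noise(xr_image(v25), region)
  expect_lt(abs(est25 - 10) / 10, 0.5)
  expect_gt(stats::sd(v25), 4 * 10)
})

test_that("eval reports serialize to JSON and CSV", {
  rep <- eval_report(map = list(mAP50_B = 1, mAP50_M = 1, mAP5095_B = 0.9,
                                mAP5095_M = 0.8, ap_per_class = NULL),
                     lsr = 0.97, contrast = 0.12, noise_sigma = 4.2)
  stem <- file.path(withr::local_tempdir(), "report")
  write_eval_report(rep, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(j$lsr, 0.97)
  csv <- utils::read.csv(paste0(stem, ".csv"))
  expect_true(all(c("mAP50_B", "lsr") %in% csv$metric))
})
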