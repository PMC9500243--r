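infer_model <- function(seed = 3) {
  # anchors chosen so group 2 (stride 8 in the improved variant) holds (16,18)
  a <- anchor_set(matrix(c(3, 4, 5, 6, 7, 5, 16, 18, 20, 22, 17, 21,
                           40, 44, 52, 50, 60, 62), ncol = 2, byrow = TRUE))
  cfg <- detector_config("improved", 64L, 1L, a, width_mult = 0.125)
  build_detector(cfg, seed = seed)
}

test_that("decode follows the YOLO convention (worked example)", {
  m <- infer_model()
  raw <- forward_detector(m, list(array(0, c(64, 64, 3))))
  # zero out everything, then place one confident prediction with t_* = 0 at
  # cell (0,0) of the stride-8 scale, anchor (16,18)
  for (s in 1:3) raw[[s]]$x[] <- -30
  s8 <- which(m$strides == 8L)
  awh <- m$config$anchors$wh[m$config$anchors$scale_groups[[s8]], ]
  a_idx <- which(awh[, 1] == 16 & awh[, 2] == 18)
  off <- (a_idx - 1L) * 6L
  raw[[s8]]$x[1, off + 1:4] <- 0    # t_x = t_y = t_w = t_h = 0
  raw[[s8]]$x[1, off + 5:6] <- 30   # objectness, class
  dets <- decode_predictions(raw, m, conf_threshold = 0.5)
  expect_length(dets, 1)
  b <- dets[[1]]$box
  # centre = (0 + sigmoid(0)) * 8 = 4; size = anchor * exp(0)
  expect_equal(c((b$x_min + b$x_max) / 2, (b$y_min + b$y_max) / 2), c(4, 4))
  expect_equal(c(b$x_max - b$x_min, b$y_max - b$y_min), c(16, 18))
  expect_gt(dets[[1]]$confidence, 0.99)
})

test_that("very negative objectness decodes to ~zero confidence", {
  m <- infer_model()
  raw <- forward_detector(m, list(array(0, c(64, 64, 3))))
  for (s in 1:3) raw[[s]]$x[] <- -30
  dets <- decode_predictions(raw, m, conf_threshold = 0)
  expect_true(all(vapply(dets, function(d) d$confidence, numeric(1)) < 1e-10))
})

test_that("vectorised decode agrees with a per-cell scalar loop", {
  m <- infer_model(seed = 7)
  set.seed(55)
  raw <- forward_detector(m, list(array(runif(64 * 64 * 3), c(64, 64, 3))))
  dets <- decode_predictions(raw, m, conf_threshold = 0)
  sig <- function(x) 1 / (1 + exp(-x))
  clamp <- function(x) pmin(pmax(x, -10), 10)  # the decode convention
  expected <- 0L
  for (s in 1:3) {
    r <- raw[[s]]
    awh <- m$config$anchors$wh[m$config$anchors$scale_groups[[s]], ]
    stride <- m$strides[s]
    for (a in 1:3) {
      off <- (a - 1L) * 6L
      expected <- expected +
        sum(sig(r$x[, off + 5]) * sig(r$x[, off + 6]) > 0)
    }
    # check a handful of random cells exactly
    for (probe in 1:10) {
      i <- sample(nrow(r$x), 1); a <- sample(3, 1)
      off <- (a - 1L) * 6L
      cx <- (i - 1L) %% (r$h * r$w) %% r$w
      cy <- (i - 1L) %% (r$h * r$w) %/% r$w
      px <- (cx + sig(r$x[i, off + 1])) * stride
      py <- (cy + sig(r$x[i, off + 2])) * stride
      pw <- awh[a, 1] * exp(clamp(r$x[i, off + 3]))
      ph <- awh[a, 2] * exp(clamp(r$x[i, off + 4]))
      conf <- sig(r$x[i, off + 5]) * sig(r$x[i, off + 6])
      if (conf == 0) next  # filtered by decode
      hit <- Filter(function(d) {
        abs(d$confidence - conf) < 1e-12 &&
          abs((d$box$x_min + d$box$x_max) / 2 - px) < 1e-9 &&
          abs((d$box$y_min + d$box$y_max) / 2 - py) < 1e-9 &&
          abs((d$box$x_max - d$box$x_min) - pw) < 1e-9 &&
          abs((d$box$y_max - d$box$y_min) - ph) < 1e-9
      }, dets)
      expect_gte(length(hit), 1)  # saturated cells can decode identically
    }
  }
  expect_length(dets, expected)
  # decoded centres always lie inside their source cell
  for (s in 1:3) {
    r <- raw[[s]]
    awh <- m$config$anchors$wh[m$config$anchors$scale_groups[[s]], ]
    d <- plateletdetect:::decode_scale_grid(r, awh, m$strides[s], 1L)
    for (a in 1:3) {
      cx <- ((seq_len(nrow(r$x)) - 1L) %% (r$h * r$w)) %% r$w
      expect_true(all(d[[a]][, "px"] >= cx * m$strides[s]))
      expect_true(all(d[[a]][, "px"] <= (cx + 1) * m$strides[s]))
    }
  }
})

test_that("nms keeps the highest-confidence box per duplicate group", {
  b <- box(0, 0, 10, 10)
  d <- list(detection(b, 0.9), detection(b, 0.8))
  kept <- nms(d)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$confidence, 0.9)
  disjoint <- list(detection(box(0, 0, 5, 5), 0.5),
                   detection(box(20, 20, 30, 30), 0.4),
                   detection(box(50, 0, 60, 10), 0.9))
  expect_length(nms(disjoint), 3)
  expect_identical(nms(list()), list())
  # different classes are never suppressed against each other
  d2 <- list(detection(b, 0.9, "platelet"), detection(b, 0.8, "rbc"))
  expect_length(nms(d2), 2)
})

test_that("nms equals the brute-force reference on random scenes", {
  set.seed(61)
  for (rep in 1:30) {
    sc <- random_scene(n_gt = 6, n_det = 50)
    for (thr in c(0.3, 0.45, 0.7)) {
      a <- nms(sc$dets, thr)
      b <- oracle_nms(sc$dets, thr)
      expect_identical(length(a), length(b))
      for (i in seq_along(a)) {
        expect_identical(a[[i]]$confidence, b[[i]]$confidence)
        expect_identical(unlist(a[[i]]$box[1:4]), unlist(b[[i]]$box[1:4]))
      }
      # survivors never exceed the overlap threshold pairwise
      if (length(a) > 1) {
        mm <- pairwise_matrix(lapply(a, function(d) d$box),
                              lapply(a, function(d) d$box), "iou")
        diag(mm) <- 0
        expect_lte(max(mm), thr)
      }
    }
  }
})

test_that("detect is deterministic and threshold-monotone", {
  m <- infer_model(seed = 9)
  img <- generate_image(smear_config_high_contrast(96L), seed = 3)$image
  d1 <- detect(m, img, conf_threshold = 0)
  d2 <- detect(m, img, conf_threshold = 0)
  expect_identical(length(d1), length(d2))
  if (length(d1) > 0) {
    expect_identical(d1[[1]]$confidence, d2[[1]]$confidence)
  }
  expect_length(detect(m, img, conf_threshold = 1), 0)
  # a lower threshold keeps a superset of a higher threshold's detections
  hi <- detect(m, img, conf_threshold = 0.3)
  lo <- detect(m, img, conf_threshold = 0.05)
  expect_gte(length(lo), length(hi))
  key <- function(d) sprintf("%.9f_%.3f", d$confidence, d$box$x_min)
  expect_true(all(vapply(hi, key, character(1)) %in%
                  vapply(lo, key, character(1))))
  # detections come back clipped to the original image frame
  for (d in lo) {
    expect_gte(d$box$x_min, 0); expect_lte(d$box$x_max, 96)
    expect_gte(d$box$y_min, 0); expect_lte(d$box$y_max, 96)
  }
})
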