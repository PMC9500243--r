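# Shared fixture builders. Everything is generated in code; no binary files.

# n random valid boxes inside a size x size frame
random_boxes <- function(n, size = 64, min_side = 1, max_side = 20,
                         integer_coords = FALSE) {
  lapply(seq_len(n), function(i) {
    w <- runif(1, min_side, max_side)
    h <- runif(1, min_side, max_side)
    x <- runif(1, 0, size - w)
    y <- runif(1, 0, size - h)
    if (integer_coords) {
      x <- floor(x); y <- floor(y)
      w <- max(1, round(w)); h <- max(1, round(h))
    }
    box(x, y, x + w, y + h)
  })
}

# Straight-line scalar transcription of the CIOU formula, independent of the
# package implementation (kept deliberately verbose).
oracle_ciou <- function(p, g) {
  iw <- min(p$x_max, g$x_max) - max(p$x_min, g$x_min)
  ih <- min(p$y_max, g$y_max) - max(p$y_min, g$y_min)
  inter <- if (iw > 0 && ih > 0) iw * ih else 0
  ap <- (p$x_max - p$x_min) * (p$y_max - p$y_min)
  ag <- (g$x_max - g$x_min) * (g$y_max - g$y_min)
  iou_v <- inter / (ap + ag - inter)
  rho2 <- ((p$x_min + p$x_max) / 2 - (g$x_min + g$x_max) / 2)^2 +
          ((p$y_min + p$y_max) / 2 - (g$y_min + g$y_max) / 2)^2
  cw <- max(p$x_max, g$x_max) - min(p$x_min, g$x_min)
  ch <- max(p$y_max, g$y_max) - min(p$y_min, g$y_min)
  c2 <- cw^2 + ch^2
  nu <- (4 / pi^2) *
    (atan((g$x_max - g$x_min) / (g$y_max - g$y_min)) -
     atan((p$x_max - p$x_min) / (p$y_max - p$y_min)))^2
  alpha <- if ((1 - iou_v) + nu > 0) nu / ((1 - iou_v) + nu) else 0
  iou_v - rho2 / c2 - alpha * nu
}

# Pixel-rasterization IOU for integer-coordinate boxes on a grid: fill the
# two rectangles and count cells.
oracle_raster_iou <- function(a, b, size = 64) {
  grid_a <- matrix(FALSE, size, size)
  grid_b <- matrix(FALSE, size, size)
  if (a$x_max > a$x_min && a$y_max > a$y_min) {
    grid_a[(a$y_min + 1):a$y_max, (a$x_min + 1):a$x_max] <- TRUE
  }
  if (b$x_max > b$x_min && b$y_max > b$y_min) {
    grid_b[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- TRUE
  }
  inter <- sum(grid_a & grid_b)
  uni <- sum(grid_a | grid_b)
  if (uni == 0) 0 else inter / uni
}

# Reference greedy NMS, written as a plain double loop.
oracle_nms <- function(dets, thr) {
  ord <- order(-vapply(dets, function(d) d$confidence, numeric(1)))
  kept <- list()
  for (i in ord) {
    suppressed <- FALSE
    for (k in kept) {
      if (k$class_name == dets[[i]]$class_name &&
          iou(k$box, dets[[i]]$box) > thr) {
        suppressed <- TRUE
        break
      }
    }
    if (!suppressed) kept[[length(kept) + 1L]] <- dets[[i]]
  }
  kept
}

# Reference greedy detection-GT matcher (independent double loop).
oracle_match <- function(dets, gts, thr) {
  ord <- order(-vapply(dets, function(d) d$confidence, numeric(1)))
  used <- logical(length(gts))
  tp <- 0L
  for (i in ord) {
    best <- -1; bj <- 0L
    for (j in seq_along(gts)) {
      if (used[j] || gts[[j]]$label != dets[[i]]$class_name) next
      v <- iou(dets[[i]]$box, gts[[j]])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0L && best >= thr) { tp <- tp + 1L; used[bj] <- TRUE }
  }
  list(TP = tp, FP = length(dets) - tp, FN = length(gts) - tp)
}

# AP by explicit prefix enumeration: precision at every prefix times the
# recall gained at that prefix.
oracle_ap <- function(flags, n_gt) {
  total <- 0
  prev_rec <- 0
  for (k in seq_along(flags)) {
    tp_k <- sum(flags[seq_len(k)])
    prec_k <- tp_k / k
    rec_k <- tp_k / n_gt
    total <- total + prec_k * (rec_k - prev_rec)
    prev_rec <- rec_k
  }
  total
}

# Random synthetic detections around (and away from) ground truths.
random_scene <- function(n_gt = 5, n_det = 12, size = 100) {
  gts <- random_boxes(n_gt, size = size, min_side = 5, max_side = 20)
  dets <- lapply(seq_len(n_det), function(i) {
    base <- if (i <= n_gt) gts[[i]] else random_boxes(1, size = size)[[1]]
    jit <- runif(4, -4, 4)
    b <- box(base$x_min + jit[1], base$y_min + jit[2],
             max(base$x_min + jit[1] + 1, base$x_max + jit[3]),
             max(base$y_min + jit[2] + 1, base$y_max + jit[4]))
    detection(b, runif(1))
  })
  list(gts = gts, dets = dets)
}

# A small in-memory dataset of synthetic smears (written to a temp dir).
tiny_dataset <- function(n_images = 8, image_size = 96, seed = 5,
                         counts = c(6L, 1L, 1L)) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- smear_config_high_contrast(image_size = image_size)
  generate_dataset(cfg, n_images = n_images, out_dir = dir, seed = seed,
                   counts = counts)
  list(dir = dir, split = load_dataset(dir), config = cfg)
}
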