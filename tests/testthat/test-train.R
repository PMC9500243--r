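tiny_model <- function(input = 32L, nc = 1L, seed = 3,
                       class_names = "platelet") {
  a <- anchor_set(matrix(c(3, 4, 5, 6, 7, 5, 9, 10, 12, 11, 10, 14,
                           16, 18, 20, 22, 28, 30), ncol = 2, byrow = TRUE))
  cfg <- detector_config("improved", input, nc, a, width_mult = 0.125,
                         class_names = class_names)
  build_detector(cfg, seed = seed)
}

test_that("lr schedule follows the published recipe", {
  cfg <- train_config()
  expect_identical(lr_at(1, cfg), 0.001)
  expect_equal(lr_at(2, cfg), 0.001 * 0.92)
  expect_equal(lr_at(50, cfg), 0.001 * 0.92^49)
  expect_equal(lr_at(51, cfg), 0.0001 * 0.92^50)
  expect_equal(lr_at(100, cfg), 0.0001 * 0.92^99)
  expect_error(lr_at(0, cfg), "epoch")
  expect_error(lr_at(101, cfg), "epoch")
  expect_true(all(diff(lr_at(1:100, cfg)) < 0))
  expect_error(train_config(lr_drop_epoch = 100, epochs = 100))
})

test_that("assign_targets picks the match-parameter argmax anchor", {
  m <- tiny_model()
  anchors <- m$config$anchors
  # a GT with exactly anchor 5's shape (12, 11) -> that anchor, score 2
  gt <- list(list(box(10 - 6, 10 - 5.5, 10 + 6, 10 + 5.5)))
  tg <- assign_targets(gt, anchors, m$strides, 32L)
  hits <- do.call(rbind, lapply(seq_along(tg), function(s) {
    if (nrow(tg[[s]])) cbind(scale = s, tg[[s]]) else NULL
  }))
  expect_identical(nrow(hits), 1L)
  s <- hits$scale[1]
  picked <- anchors$scale_groups[[s]][hits$anchor[1]]
  expect_equal(unname(anchors$wh[picked, ]), c(12, 11))
  # two GTs in different cells -> two disjoint positives
  gt2 <- list(list(box(1, 1, 7, 7), box(20, 20, 28, 29)))
  tg2 <- assign_targets(gt2, anchors, m$strides, 32L)
  expect_identical(sum(vapply(tg2, nrow, integer(1))), 2L)
})

test_that("assignment equals a brute-force argmax oracle on random scenes", {
  m <- tiny_model()
  anchors <- m$config$anchors
  a_scale <- integer(9); a_local <- integer(9)
  for (s in 1:3) {
    a_scale[anchors$scale_groups[[s]]] <- s
    a_local[anchors$scale_groups[[s]]] <- seq_len(3)
  }
  set.seed(19)
  for (rep in 1:20) {
    gtb <- random_boxes(3, size = 32, min_side = 2, max_side = 20)
    tg <- assign_targets(list(gtb), anchors, m$strides, 32L)
    expect_identical(sum(vapply(tg, nrow, integer(1))), 3L)
    for (g in gtb) {
      w <- g$x_max - g$x_min; h <- g$y_max - g$y_min
      scores <- vapply(1:9, function(j) {
        match_parameter(box(-anchors$wh[j, 1] / 2, -anchors$wh[j, 2] / 2,
                            anchors$wh[j, 1] / 2, anchors$wh[j, 2] / 2),
                        box(-w / 2, -h / 2, w / 2, h / 2))
      }, numeric(1))
      jbest <- which.max(scores)
      s <- a_scale[jbest]
      row <- tg[[s]]
      cx <- floor((g$x_min + g$x_max) / 2 / m$strides[s])
      cy <- floor((g$y_min + g$y_max) / 2 / m$strides[s])
      hit <- row$anchor == a_local[jbest] & row$cell_x == cx & row$cell_y == cy
      expect_true(any(hit))
    }
  }
})

test_that("every ground truth yields exactly one positive", {
  m <- tiny_model(input = 64L)
  set.seed(21)
  for (rep in 1:10) {
    gtb <- lapply(1:3, function(i) {
      random_boxes(sample(0:4, 1), size = 64, min_side = 3, max_side = 25)
    })
    tg <- assign_targets(gtb, m$config$anchors, m$strides, 64L)
    expect_identical(sum(vapply(tg, nrow, integer(1))),
                     sum(vapply(gtb, length, integer(1))))
  }
})

test_that("loss is ~0 when predictions sit exactly on targets", {
  m <- tiny_model()
  anchors <- m$config$anchors
  gt <- list(list(box(9, 7, 21, 18)))  # 12 x 11 box
  tg <- assign_targets(gt, anchors, m$strides, 32L)
  raw <- forward_detector(m, list(array(0.2, c(32, 32, 3))), training = TRUE)
  # overwrite logits so every anchor decodes exactly onto its target
  for (s in 1:3) {
    raw[[s]]$x[] <- -20  # objectness/class floor, sigmod ~ 0
    tt <- tg[[s]]
    if (nrow(tt) == 0) next
    per <- 6L
    awh <- anchors$wh[anchors$scale_groups[[s]], , drop = FALSE]
    for (r in seq_len(nrow(tt))) {
      rowi <- (tt$img[r] - 1L) * raw[[s]]$h * raw[[s]]$w +
        tt$cell_y[r] * raw[[s]]$w + tt$cell_x[r] + 1L
      off <- (tt$anchor[r] - 1L) * per
      fx <- tt$gx[r] / m$strides[s] - tt$cell_x[r]
      fy <- tt$gy[r] / m$strides[s] - tt$cell_y[r]
      raw[[s]]$x[rowi, off + 1L] <- log(fx / (1 - fx))
      raw[[s]]$x[rowi, off + 2L] <- log(fy / (1 - fy))
      raw[[s]]$x[rowi, off + 3L] <- log(tt$gw[r] / awh[tt$anchor[r], 1])
      raw[[s]]$x[rowi, off + 4L] <- log(tt$gh[r] / awh[tt$anchor[r], 2])
      raw[[s]]$x[rowi, off + 5L] <- 20   # objectness
      raw[[s]]$x[rowi, off + 6L] <- 20   # class
    }
  }
  loss <- compute_loss(raw, tg, m, gt)
  expect_lt(loss$total, 1e-3)
  expect_lt(loss$box, 1e-9)
})

test_that("empty ground truth zeroes the box and class terms", {
  m <- tiny_model()
  gt <- list(list())
  tg <- assign_targets(gt, m$config$anchors, m$strides, 32L)
  raw <- forward_detector(m, list(array(0.5, c(32, 32, 3))), training = TRUE)
  loss <- compute_loss(raw, tg, m, gt)
  expect_identical(loss$box, 0)
  expect_identical(loss$cls, 0)
  expect_gt(loss$obj, 0)
  expect_identical(loss$npos, 0L)
})

test_that("loss gradients match finite differences to 1e-4", {
  m <- tiny_model(nc = 2L, class_names = c("platelet", "rbc"))
  set.seed(42)
  imgs <- list(array(runif(32 * 32 * 3), c(32, 32, 3)),
               array(runif(32 * 32 * 3), c(32, 32, 3)))
  gt <- list(list(box(4, 5, 12, 14), box(20, 18, 29, 30, label = "rbc")),
             list(box(10, 2, 18, 9)))
  tg <- assign_targets(gt, m$config$anchors, m$strides, 32L,
                       m$config$class_names)
  raw <- forward_detector(m, imgs, training = TRUE)
  loss_of <- function(r) compute_loss(r, tg, m, gt)$total
  L <- compute_loss(raw, tg, m, gt)
  eps <- 1e-6
  for (s in 1:3) {
    k <- min(12L, nrow(raw[[s]]$x))
    idx <- cbind(sample(nrow(raw[[s]]$x), k), sample(ncol(raw[[s]]$x), k))
    if (nrow(tg[[s]]) > 0) {  # always include a positive cell's channels
      npix <- raw[[s]]$h * raw[[s]]$w
      prow <- (tg[[s]]$img[1] - 1L) * npix +
        tg[[s]]$cell_y[1] * raw[[s]]$w + tg[[s]]$cell_x[1] + 1L
      off <- (tg[[s]]$anchor[1] - 1L) * 7L
      idx <- rbind(idx, cbind(prow, off + 1:7))
    }
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      rp <- raw; rp[[s]]$x[i, j] <- rp[[s]]$x[i, j] + eps
      rm_ <- raw; rm_[[s]]$x[i, j] <- rm_[[s]]$x[i, j] - eps
      fd <- (loss_of(rp) - loss_of(rm_)) / (2 * eps)
      expect_equal(L$grads[[s]][i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("short training runs are deterministic and write a checkpoint", {
  ds <- tiny_dataset(n_images = 8, image_size = 96, seed = 5)
  run_once <- function() {
    m <- tiny_model(input = 64L, seed = 4)
    tcfg <- train_config(epochs = 2L, lr_drop_epoch = 1L, batch_size = 4L,
                         seed = 9, validate_every = 2L)
    ckpt <- tempfile(fileext = ".ckpt")
    res <- train_detector(m, ds$split, tcfg, checkpoint_path = ckpt,
                          verbose = FALSE)
    list(log = res$log, ckpt = ckpt)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_true(file.exists(r1$ckpt))
  expect_identical(nrow(r1$log), 2L)
  expect_equal(r1$log$loss, r2$log$loss, tolerance = 1e-12)
  expect_false(is.na(r1$log$val_ap[2]))
  m_back <- load_checkpoint(r1$ckpt)
  expect_s3_class(m_back, "detector")
  expect_error(train_detector(tiny_model(64L), list(train = list()),
                              train_config(epochs = 1L)), "empty")
  unlink(c(r1$ckpt, r2$ckpt))
})

test_that("single-image overfit drives the loss down by >= 90%", {
  cfgS <- smear_config_high_contrast(96L)
  g <- generate_image(cfgS, seed = 11)
  m <- tiny_model(input = 96L, seed = 2)
  img <- plateletdetect:::image_rows(g$image)
  gt <- list(g$record$boxes)
  st <- plateletdetect:::adam_state()
  first <- NA_real_; last <- NA_real_
  for (it in 1:200) {
    raw <- forward_detector(m, list(img), training = TRUE)
    tg <- assign_targets(gt, m$config$anchors, m$strides, 96L)
    L <- compute_loss(raw, tg, m, gt)
    gm <- list()
    for (s in 1:3) gm[[m$head_names[s]]] <- L$grads[[s]]
    pg <- plateletdetect:::graph_backward(m$nodes, m$params,
                                          attr(raw, "fwd"), gm)
    plateletdetect:::adam_step(m$params, pg, st, 0.001)
    if (it == 1) first <- L$total
    last <- L$total
  }
  expect_lt(last, 0.1 * first)
})
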