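#' Training configuration
#'
#' Defaults follow the published recipe: 100 epochs, initial learning rate
#' 0.001 dropped to 0.0001 after epoch 50, a per-epoch multiplicative decay
#' of 0.92 on top (see [lr_at()]), batch size 4, ignore threshold 0.5.
#'
#' @param epochs total epochs (default 100).
#' @param base_lr learning rate for epochs 1..`lr_drop_epoch` (default 0.001).
#' @param dropped_lr rate after the drop (default 0.0001).
#' @param lr_drop_epoch epoch after which `dropped_lr` applies (default 50).
#' @param lr_decay per-epoch multiplicative factor (default 0.92).
#' @param batch_size images per optimisation step (default 4).
#' @param ignore_threshold plain-IOU threshold above which an unassigned
#'   prediction overlapping a ground truth is excluded from the objectness
#'   loss (default 0.5).
#' @param box_weight weight of the `1 - CIOU` localisation term (default 5;
#'   small targets need tight boxes, see the methods vignette).
#' @param neg_weight weight of the per-negative objectness term (default 25;
#'   balances duplicate suppression against recall, see the methods
#'   vignette).
#' @param validate_every compute validation AP every this many epochs
#'   (default 1; validation also always runs on the final epoch).
#' @param seed master seed for shuffling.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, base_lr = 0.001, dropped_lr = 0.0001,
                         lr_drop_epoch = 50L, lr_decay = 0.92,
                         batch_size = 4L, ignore_threshold = 0.5,
                         box_weight = 5, neg_weight = 25,
                         validate_every = 1L, seed = 1L) {
  stopifnot(lr_decay > 0, lr_decay <= 1, lr_drop_epoch < epochs,
            batch_size >= 1L, epochs >= 1L)
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 dropped_lr = dropped_lr,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 ignore_threshold = ignore_threshold,
                 box_weight = box_weight, neg_weight = neg_weight,
                 validate_every = as.integer(validate_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' `lr(e) = base(e) * decay^(e-1)` with `base(e) = base_lr` for
#' `e <= lr_drop_epoch` and `dropped_lr` afterwards. The published schedule
#' states both a fixed drop at epoch 50 and a per-epoch 0.92 multiplicative
#' adjustment; this composes the two (see the methods vignette for why).
#'
#' @param epoch 1-based epoch, `1 <= epoch <= config$epochs`.
#' @param config a [train_config()].
#' @return the learning rate, non-increasing in `epoch`.
#' @export
lr_at <- function(epoch, config) {
  if (any(epoch < 1L) || any(epoch > config$epochs)) {
    stop(sprintf("epoch must lie in [1, %d]", config$epochs))
  }
  base <- ifelse(epoch <= config$lr_drop_epoch, config$base_lr,
                 config$dropped_lr)
  base * config$lr_decay^(epoch - 1)
}

# ---- target assignment ------------------------------------------------------

#' Assign ground-truth boxes to (scale, cell, anchor) positives
#'
#' Each ground truth is matched to the anchor maximising the CIOU+IOU match
#' parameter between the two shapes centre-aligned at the origin (so the
#' distance term vanishes and only overlap + aspect terms act). The matched
#' anchor determines the scale; the cell containing the box centre at that
#' scale's stride holds the positive. If that (cell, anchor) slot is already
#' taken the next-best anchor is tried; a ground truth with no free slot is
#' dropped with a warning (rare, implies heavily overlapping targets).
#'
#' @param gt_boxes_batch list (one element per batch image) of lists of
#'   [box()]es in network (letterboxed) coordinates.
#' @param anchors an [anchor_set()] with scale groups ordered finest-first.
#' @param strides integer stride per scale (finest first), e.g. `c(4, 8, 16)`.
#' @param input_size network input size.
#' @param class_names class vocabulary mapping labels to target indices.
#' @return list with one element per scale: `data.frame(img, cell_x, cell_y,
#'   anchor, gx, gy, gw, gh, cls)` where `(gx, gy, gw, gh)` is the target box
#'   in centre form (network pixels) and `anchor` indexes within the scale
#'   group.
#' @export
assign_targets <- function(gt_boxes_batch, anchors, strides, input_size,
                           class_names = "platelet") {
  n_scales <- length(anchors$scale_groups)
  stopifnot(length(strides) == n_scales)
  wh <- anchors$wh
  # anchor global index -> (scale, local index)
  a_scale <- integer(nrow(wh)); a_local <- integer(nrow(wh))
  for (s in seq_len(n_scales)) {
    g <- anchors$scale_groups[[s]]
    a_scale[g] <- s
    a_local[g] <- seq_along(g)
  }
  anchor_boxes <- matrix_to_boxes(cbind(-wh[, 1] / 2, -wh[, 2] / 2,
                                        wh[, 1] / 2, wh[, 2] / 2))
  rows <- lapply(seq_len(n_scales), function(s) list())
  taken <- new.env(parent = emptyenv())
  dropped <- 0L
  for (i in seq_along(gt_boxes_batch)) {
    for (gtb in gt_boxes_batch[[i]]) {
      gw <- gtb$x_max - gtb$x_min; gh <- gtb$y_max - gtb$y_min
      gx <- (gtb$x_min + gtb$x_max) / 2; gy <- (gtb$y_min + gtb$y_max) / 2
      if (gx < 0 || gx > input_size || gy < 0 || gy > input_size) {
        warning("ground-truth centre outside the image; clipping")
        gx <- min(max(gx, 0), input_size)
        gy <- min(max(gy, 0), input_size)
      }
      shape <- box(-gw / 2, -gh / 2, gw / 2, gh / 2)
      mp <- vapply(anchor_boxes, function(a) match_parameter(a, shape),
                   numeric(1))
      placed <- FALSE
      for (j in order(mp, decreasing = TRUE)) {
        s <- a_scale[j]
        grid <- input_size %/% strides[s]
        cx <- min(max(floor(gx / strides[s]), 0), grid - 1)
        cy <- min(max(floor(gy / strides[s]), 0), grid - 1)
        key <- sprintf("%d_%d_%d_%d_%d", i, s, cx, cy, a_local[j])
        if (!exists(key, envir = taken, inherits = FALSE)) {
          assign(key, TRUE, envir = taken)
          cls <- match(gtb$label, class_names)
          if (is.na(cls)) cls <- 1L
          rows[[s]][[length(rows[[s]]) + 1L]] <-
            c(i, cx, cy, a_local[j], gx, gy, gw, gh, cls)
          placed <- TRUE
          break
        }
      }
      if (!placed) dropped <- dropped + 1L
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d ground truth(s) had no free (cell, anchor) slot", dropped))
  }
  lapply(rows, function(rr) {
    m <- if (length(rr)) do.call(rbind, rr) else matrix(numeric(0), 0, 9)
    data.frame(img = as.integer(m[, 1]), cell_x = as.integer(m[, 2]),
               cell_y = as.integer(m[, 3]), anchor = as.integer(m[, 4]),
               gx = m[, 5], gy = m[, 6], gw = m[, 7], gh = m[, 8],
               cls = as.integer(m[, 9]))
  })
}

# ---- CIOU with analytic gradient -------------------------------------------

# CIOU of a predicted box in centre form (px, py, pw, ph) against a fixed
# ground truth (gx, gy, gw, gh), plus the exact gradient with respect to the
# four prediction parameters (including the alpha(IOU, nu) dependence, so the
# gradient matches finite differences, not just the usual detached-alpha
# training approximation).
ciou_center_grad <- function(px, py, pw, ph, gx, gy, gw, gh) {
  px1 <- px - pw / 2; px2 <- px + pw / 2
  py1 <- py - ph / 2; py2 <- py + ph / 2
  gx1 <- gx - gw / 2; gx2 <- gx + gw / 2
  gy1 <- gy - gh / 2; gy2 <- gy + gh / 2
  # d corner / d (px, pw): px1 -> (1, -1/2), px2 -> (1, 1/2)
  iw <- min(px2, gx2) - max(px1, gx1)
  ih <- min(py2, gy2) - max(py1, gy1)
  have_int <- iw > 0 && ih > 0 && pw > 0 && ph > 0
  area_p <- max(pw, 0) * max(ph, 0)
  I <- if (have_int) iw * ih else 0
  U <- area_p + gw * gh - I
  iou_v <- if (U > 0) I / U else 0
  # gradients of I wrt (px, py, pw, ph)
  dI <- c(0, 0, 0, 0)
  if (have_int) {
    diw_dpx <- (if (px2 < gx2) 1 else 0) - (if (px1 > gx1) 1 else 0)
    diw_dpw <- (if (px2 < gx2) 0.5 else 0) + (if (px1 > gx1) 0.5 else 0)
    dih_dpy <- (if (py2 < gy2) 1 else 0) - (if (py1 > gy1) 1 else 0)
    dih_dph <- (if (py2 < gy2) 0.5 else 0) + (if (py1 > gy1) 0.5 else 0)
    dI <- c(ih * diw_dpx, iw * dih_dpy, ih * diw_dpw, iw * dih_dph)
  }
  dAp <- c(0, 0, ph, pw)
  dU <- dAp - dI
  dIOU <- if (U > 0) (dI * U - I * dU) / U^2 else c(0, 0, 0, 0)
  # distance penalty rho^2 / c^2
  rho2 <- (px - gx)^2 + (py - gy)^2
  cw <- max(px2, gx2) - min(px1, gx1)
  chh <- max(py2, gy2) - min(py1, gy1)
  c2 <- cw^2 + chh^2
  if (c2 > 0) {
    drho2 <- c(2 * (px - gx), 2 * (py - gy), 0, 0)
    dcw_dpx <- (if (px2 > gx2) 1 else 0) - (if (px1 < gx1) 1 else 0)
    dcw_dpw <- (if (px2 > gx2) 0.5 else 0) + (if (px1 < gx1) 0.5 else 0)
    dch_dpy <- (if (py2 > gy2) 1 else 0) - (if (py1 < gy1) 1 else 0)
    dch_dph <- (if (py2 > gy2) 0.5 else 0) + (if (py1 < gy1) 0.5 else 0)
    dc2 <- c(2 * cw * dcw_dpx, 2 * chh * dch_dpy,
             2 * cw * dcw_dpw, 2 * chh * dch_dph)
    dist_pen <- rho2 / c2
    ddist <- drho2 / c2 - rho2 * dc2 / c2^2
  } else {
    dist_pen <- 0; ddist <- c(0, 0, 0, 0)
  }
  # aspect term
  if (pw > 0 && ph > 0 && gw > 0 && gh > 0) {
    kk <- 4 / pi^2
    delta <- atan(gw / gh) - atan(pw / ph)
    nu <- kk * delta^2
    denom_wh <- pw^2 + ph^2
    dnu <- c(0, 0,
             -2 * kk * delta * ph / denom_wh,
              2 * kk * delta * pw / denom_wh)
  } else {
    nu <- 0; dnu <- c(0, 0, 0, 0)
  }
  D <- (1 - iou_v) + nu
  if (D > 0) {
    alpha_nu <- nu^2 / D
    dalpha_nu <- ((2 * nu * D - nu^2) * dnu + nu^2 * dIOU) / D^2
  } else {
    alpha_nu <- 0; dalpha_nu <- c(0, 0, 0, 0)
  }
  list(value = iou_v - dist_pen - alpha_nu,
       grad = dIOU - ddist - dalpha_nu,
       iou = iou_v)
}

# ---- loss -------------------------------------------------------------------

# Decode a whole raw scale grid to centre-form boxes (vectorised); returns a
# list of matrices (one per anchor) with columns px, py, pw, ph plus the
# sigmoid derivatives needed for the chain rule.
decode_scale_grid <- function(raw, anchor_wh, stride, num_classes) {
  per <- 5L + num_classes
  S_h <- raw$h; S_w <- raw$w
  npix <- S_h * S_w
  idx <- seq_len(nrow(raw$x)) - 1L
  rem <- idx %% npix
  cx_cell <- rem %% S_w
  cy_cell <- rem %/% S_w
  lapply(seq_len(nrow(anchor_wh)), function(a) {
    off <- (a - 1L) * per
    tx <- raw$x[, off + 1L]; ty <- raw$x[, off + 2L]
    tw <- raw$x[, off + 3L]; th <- raw$x[, off + 4L]
    sx <- sigmoid(tx); sy <- sigmoid(ty)
    ew <- exp(pmin(pmax(tw, -10), 10)); eh <- exp(pmin(pmax(th, -10), 10))
    cbind(px = (cx_cell + sx) * stride, py = (cy_cell + sy) * stride,
          pw = anchor_wh[a, 1] * ew, ph = anchor_wh[a, 2] * eh,
          dsx = sx * (1 - sx) * stride, dsy = sy * (1 - sy) * stride)
  })
}

#' Composite detection loss with gradients
#'
#' `total = box_weight * mean_over_positives(1 - CIOU(decoded, target))
#'        + mean_over_positives BCE(objectness at 1)
#'        + neg_weight * mean_over_negatives BCE(objectness at 0)
#'        + mean_over_positives BCE(class logits)`.
#' Objectness BCE is balanced by normalising the positive and negative sums
#' by their own counts (so a 10^4-cell grid with ten positives does not drown
#' the signal), then re-weighting the negative mean by `neg_weight` to keep
#' enough suppression pressure on near-duplicates. Predictions that are not positives but whose decoded
#' box overlaps some ground truth with IOU above `ignore_threshold` are
#' excluded from the negative objectness term (the standard ignore rule,
#' plain IOU). An image with no ground truth contributes exactly zero box and
#' class loss.
#'
#' @param raw_outputs list of raw per-scale feature maps from
#'   [forward_detector()] (finest first).
#' @param targets output of [assign_targets()].
#' @param model the detector (for anchors/strides/classes).
#' @param gt_boxes_batch the ground truth per image (for the ignore rule).
#' @param ignore_threshold see [train_config()].
#' @param box_weight weight of the localisation term.
#' @param neg_weight weight of the mean negative objectness term.
#' @return list `(total, box, obj, cls, npos, grads)` where `grads[[s]]` is
#'   the gradient matrix for scale `s`'s raw feature map.
#' @export
compute_loss <- function(raw_outputs, targets, model, gt_boxes_batch,
                         ignore_threshold = 0.5, box_weight = 5,
                         neg_weight = 25) {
  cfg <- model$config
  nc <- cfg$num_classes
  per <- 5L + nc
  anchors <- cfg$anchors
  strides <- model$strides
  npos_total <- sum(vapply(targets, nrow, integer(1)))
  denom_pos <- max(1L, npos_total)
  box_loss <- 0; obj_pos_loss <- 0; obj_neg_loss <- 0; cls_loss <- 0
  n_neg_total <- 0
  grads <- vector("list", length(raw_outputs))
  neg_sig <- vector("list", length(raw_outputs))  # sigmoid(obj) of negatives
  for (s in seq_along(raw_outputs)) {
    raw <- raw_outputs[[s]]
    A <- length(anchors$scale_groups[[s]])
    awh <- anchors$wh[anchors$scale_groups[[s]], , drop = FALSE]
    g <- matrix(0, nrow(raw$x), ncol(raw$x))
    npix <- raw$h * raw$w
    tt <- targets[[s]]
    # ---- objectness masks
    obj_cols <- (seq_len(A) - 1L) * per + 5L
    pos_mask <- matrix(FALSE, nrow(raw$x), A)
    if (nrow(tt) > 0) {
      rows <- (tt$img - 1L) * npix + tt$cell_y * raw$w + tt$cell_x + 1L
      pos_mask[cbind(rows, tt$anchor)] <- TRUE
    }
    ignore_mask <- matrix(FALSE, nrow(raw$x), A)
    decoded <- decode_scale_grid(raw, awh, strides[s], nc)
    any_gt <- any(vapply(gt_boxes_batch, length, integer(1)) > 0)
    if (ignore_threshold < 1 && any_gt) {
      for (i in seq_along(gt_boxes_batch)) {
        gtl <- gt_boxes_batch[[i]]
        if (length(gtl) == 0) next
        gtm <- boxes_to_matrix(gtl)
        img_rows <- (i - 1L) * npix + seq_len(npix)
        for (a in seq_len(A)) {
          d <- decoded[[a]][img_rows, , drop = FALSE]
          pb <- cbind(d[, "px"] - d[, "pw"] / 2, d[, "py"] - d[, "ph"] / 2,
                      d[, "px"] + d[, "pw"] / 2, d[, "py"] + d[, "ph"] / 2)
          im <- pairwise_matrix_xyxy(pb, gtm, "iou")
          best <- im[cbind(seq_len(nrow(im)), max.col(im, "first"))]
          ignore_mask[img_rows, a] <- best > ignore_threshold
        }
      }
    }
    neg_mask <- !pos_mask & !ignore_mask
    # ---- objectness loss + gradient
    for (a in seq_len(A)) {
      oc <- obj_cols[a]
      logits <- raw$x[, oc]
      sig <- sigmoid(logits)
      pos <- pos_mask[, a]; neg <- neg_mask[, a]
      if (any(pos)) {
        obj_pos_loss <- obj_pos_loss + sum(bce_logits(logits[pos], 1))
        g[pos, oc] <- g[pos, oc] + (sig[pos] - 1) / denom_pos
      }
      if (any(neg)) {
        obj_neg_loss <- obj_neg_loss + sum(bce_logits(logits[neg], 0))
        n_neg_total <- n_neg_total + sum(neg)
      }
    }
    neg_sig[[s]] <- list(neg_mask = neg_mask, obj_cols = obj_cols)
    # ---- box + class loss on positives
    if (nrow(tt) > 0) {
      rows <- (tt$img - 1L) * npix + tt$cell_y * raw$w + tt$cell_x + 1L
      for (r in seq_len(nrow(tt))) {
        a <- tt$anchor[r]; row <- rows[r]
        off <- (a - 1L) * per
        d <- decoded[[a]][row, ]
        cg <- ciou_center_grad(d[["px"]], d[["py"]], d[["pw"]], d[["ph"]],
                               tt$gx[r], tt$gy[r], tt$gw[r], tt$gh[r])
        box_loss <- box_loss + (1 - cg$value)
        # chain: d(pw)/d(tw) = pw, d(px)/d(tx) = sigmoid'(tx) * stride
        dt <- -cg$grad * c(d[["dsx"]], d[["dsy"]], d[["pw"]], d[["ph"]])
        g[row, off + 1:4] <- g[row, off + 1:4] +
          dt * box_weight / denom_pos
        # class loss (one-hot over nc channels)
        ccols <- off + 5L + seq_len(nc)
        clogits <- raw$x[row, ccols]
        ctarget <- as.numeric(seq_len(nc) == tt$cls[r])
        cls_loss <- cls_loss + sum(bce_logits(clogits, ctarget))
        g[row, ccols] <- g[row, ccols] +
          (sigmoid(clogits) - ctarget) / denom_pos
      }
    }
    grads[[s]] <- g
  }
  denom_neg <- max(1L, n_neg_total)
  # negative objectness gradients need the global negative count, so they are
  # applied in a second pass
  for (s in seq_along(raw_outputs)) {
    raw <- raw_outputs[[s]]
    info <- neg_sig[[s]]
    for (a in seq_along(info$obj_cols)) {
      oc <- info$obj_cols[a]
      neg <- info$neg_mask[, a]
      if (any(neg)) {
        grads[[s]][neg, oc] <- grads[[s]][neg, oc] +
          neg_weight * sigmoid(raw$x[neg, oc]) / denom_neg
      }
    }
  }
  box_loss <- box_loss / denom_pos
  cls_loss <- cls_loss / denom_pos
  obj_loss <- obj_pos_loss / denom_pos +
    neg_weight * obj_neg_loss / denom_neg
  list(total = box_weight * box_loss + obj_loss + cls_loss,
       box = box_loss, obj = obj_loss, cls = cls_loss,
       npos = npos_total, grads = grads)
}

# ---- optimiser --------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (state$t %||% 0L) + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in ls(grads)) {
    g <- get(nm, envir = grads)
    p <- get(nm, envir = params)
    st <- state[[nm]] %||% list()
    for (field in names(g)) {
      gf <- g[[field]]
      m <- st[[paste0("m_", field)]] %||% (gf * 0)
      v <- st[[paste0("v_", field)]] %||% (gf * 0)
      m <- beta1 * m + (1 - beta1) * gf
      v <- beta2 * v + (1 - beta2) * gf^2
      p[[field]] <- p[[field]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      st[[paste0("m_", field)]] <- m
      st[[paste0("v_", field)]] <- v
    }
    state[[nm]] <- st
    assign(nm, p, envir = params)
  }
  invisible(state)
}

# ---- training loop ----------------------------------------------------------

# Load + letterbox every record once; returns list(images, boxes) aligned.
prepare_records <- function(records, input_size, divisor) {
  images <- vector("list", length(records))
  boxes <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    img <- read_image(r$image_path)
    lb <- letterbox(img, r, target_size = input_size, divisor = divisor)
    images[[i]] <- image_rows(lb$image)  # pre-converted to the fm layout
    boxes[[i]] <- lb$record$boxes
  }
  list(images = images, boxes = boxes)
}

#' Train a detector
#'
#' Deterministic given the seeds (single-threaded, fixed data order per
#' seeded shuffle). Logs loss components every epoch and validation AP every
#' `config$validate_every` epochs; keeps the best-on-validation parameters
#' (falling back to the final epoch when there is no validation split).
#'
#' @param model a [build_detector()] result (modified in place and returned).
#' @param split a `dataset_split`; `train` must be non-empty, `val` may be
#'   empty.
#' @param config a [train_config()].
#' @param checkpoint_path if non-`NULL`, the best checkpoint is written here.
#' @param verbose print a line per epoch.
#' @return list `(model, log)`: `log` is a data.frame with one row per epoch
#'   (epoch, lr, loss, box, obj, cls, val_ap).
#' @export
train_detector <- function(model, split, config = train_config(),
                           checkpoint_path = NULL, verbose = TRUE) {
  if (length(split$train) == 0L) stop("empty training split")
  cfg <- model$config
  divisor <- max(model$strides)
  tr <- prepare_records(split$train, cfg$input_size, divisor)
  va <- if (length(split$val) > 0) {
    prepare_records(split$val, cfg$input_size, divisor)
  } else NULL
  n <- length(tr$images)
  state <- adam_state()
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    box = numeric(0), obj = numeric(0), cls = numeric(0),
                    val_ap = numeric(0))
  best_ap <- -Inf
  best_params <- NULL
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(epoch, config)
    order_idx <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    sums <- c(loss = 0, box = 0, obj = 0, cls = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order_idx[start:min(start + config$batch_size - 1L, n)]
      raw <- forward_detector(model, tr$images[idx], training = TRUE)
      gt_batch <- tr$boxes[idx]
      targets <- assign_targets(gt_batch, cfg$anchors, model$strides,
                                cfg$input_size, cfg$class_names)
      loss <- compute_loss(raw, targets, model, gt_batch,
                           ignore_threshold = config$ignore_threshold,
                           box_weight = config$box_weight,
                           neg_weight = config$neg_weight)
      grad_map <- list()
      for (s in seq_along(model$head_names)) {
        grad_map[[model$head_names[s]]] <- loss$grads[[s]]
      }
      pgrads <- graph_backward(model$nodes, model$params, attr(raw, "fwd"),
                               grad_map)
      adam_step(model$params, pgrads, state, lr)
      sums <- sums + c(loss$total, loss$box, loss$obj, loss$cls)
      nb <- nb + 1L
    }
    val_ap <- NA_real_
    if (!is.null(va) &&
        (epoch %% config$validate_every == 0L || epoch == config$epochs)) {
      val_ap <- evaluate_prepared(model, va)$ap
      if (val_ap >= best_ap) {
        best_ap <- val_ap
        best_params <- mget(ls(model$params), envir = model$params)
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = sums[1] / nb, box = sums[2] / nb,
                                 obj = sums[3] / nb, cls = sums[4] / nb,
                                 val_ap = val_ap))
    pd_log("epoch %3d lr %.2e loss %.4f (box %.4f obj %.4f cls %.4f) val AP %s",
           epoch, lr, sums[1] / nb, sums[2] / nb, sums[3] / nb, sums[4] / nb,
           ifelse(is.na(val_ap), "-", sprintf("%.3f", val_ap)),
           verbose = verbose)
  }
  if (!is.null(best_params)) {
    for (nm in names(best_params)) {
      assign(nm, best_params[[nm]], envir = model$params)
    }
  }
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  rownames(log) <- NULL
  list(model = model, log = log)
}

# AP on already letterboxed images/boxes (validation fast path: images are in
# network coordinates, so no inverse letterbox round trip is needed).
evaluate_prepared <- function(model, prep, conf_threshold = 0.25,
                              nms_iou = 0.45, eval_iou = 0.5) {
  all_dets <- list()
  all_gts <- list()
  for (i in seq_along(prep$images)) {
    raw <- forward_detector(model, prep$images[i], training = FALSE)
    dets <- decode_predictions(raw, model, conf_threshold = conf_threshold)
    dets <- nms(dets, iou_threshold = nms_iou)
    all_dets[[i]] <- dets
    all_gts[[i]] <- prep$boxes[[i]]
  }
  evaluate_detections(all_dets, all_gts, eval_iou = eval_iou)
}
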