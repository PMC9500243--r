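#' A single detection
#'
#' @param box a [box()] (clipped to image bounds by [detect()]).
#' @param confidence objectness times class probability, in `[0, 1]`.
#' @param class_name predicted class.
#' @return object of class `"detection"`.
#' @export
detection <- function(box, confidence, class_name = box$label) {
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(box = box, confidence = confidence,
                 class_name = class_name),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection %s %.3f %s>\n", x$class_name, x$confidence,
              format(x$box)))
  invisible(x)
}

#' Decode raw grids into detections
#'
#' YOLO-v3 decode convention per cell and anchor:
#' `centre = (cell + sigmoid(t_xy)) * stride`, `size = anchor * exp(t_wh)`
#' (with `t_wh` clamped to `[-10, 10]` for numerical safety),
#' `confidence = sigmoid(objectness) * sigmoid(class logit)`, converted to
#' corner form. Detections below `conf_threshold` are discarded.
#'
#' @param raw_outputs list of raw per-scale feature maps (finest first),
#'   from [forward_detector()]; a single-image batch.
#' @param model the detector (anchors, strides, class names).
#' @param conf_threshold minimum confidence (default 0, i.e. keep all).
#'   Confidence is a product of two sigmoids, hence strictly below 1: a
#'   threshold of 1 (or more) always yields an empty result, even when
#'   saturated logits round the product up to 1 in floating point.
#' @return list of [detection()]s in network (letterboxed) coordinates.
#' @export
decode_predictions <- function(raw_outputs, model, conf_threshold = 0) {
  if (conf_threshold >= 1) return(list())
  cfg <- model$config
  nc <- cfg$num_classes
  per <- 5L + nc
  dets <- list()
  for (s in seq_along(raw_outputs)) {
    raw <- raw_outputs[[s]]
    if (raw$n != 1L) stop("decode_predictions expects a single-image batch")
    group <- cfg$anchors$scale_groups[[s]]
    awh <- cfg$anchors$wh[group, , drop = FALSE]
    if (ncol(raw$x) != nrow(awh) * per) {
      stop(sprintf("scale %d: %d channels but %d anchors x (5+%d) expected",
                   s, ncol(raw$x), nrow(awh), nc))
    }
    decoded <- decode_scale_grid(raw, awh, model$strides[s], nc)
    for (a in seq_len(nrow(awh))) {
      off <- (a - 1L) * per
      obj <- sigmoid(raw$x[, off + 5L])
      cls_p <- sigmoid(raw$x[, off + 5L + seq_len(nc), drop = FALSE])
      best_cls <- max.col(cls_p, ties.method = "first")
      conf <- obj * cls_p[cbind(seq_along(obj), best_cls)]
      keep <- which(conf >= conf_threshold & conf > 0)
      d <- decoded[[a]]
      for (r in keep) {
        b <- box(d[r, "px"] - d[r, "pw"] / 2, d[r, "py"] - d[r, "ph"] / 2,
                 d[r, "px"] + d[r, "pw"] / 2, d[r, "py"] + d[r, "ph"] / 2,
                 label = cfg$class_names[best_cls[r]])
        dets[[length(dets) + 1L]] <- detection(b, conf[r])
      }
    }
  }
  dets
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in order of descending confidence (ties broken by
#' input order, for determinism); a detection is removed when its IOU with an
#' already-kept detection of the same class exceeds `iou_threshold`. The
#' output is sorted by confidence.
#'
#' @param dets list of [detection()]s from one image.
#' @param iou_threshold suppression threshold (default 0.45).
#' @return the surviving detections, confidence-sorted.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (length(dets) == 0L) return(list())
  conf <- vapply(dets, function(d) d$confidence, numeric(1))
  cls <- vapply(dets, function(d) d$class_name, character(1))
  m <- boxes_to_matrix(lapply(dets, function(d) d$box))
  ord <- order(-conf)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    if (length(keep) > 0) {
      ious <- pairwise_matrix_xyxy(m[i, , drop = FALSE],
                                   m[keep, , drop = FALSE], "iou")[1, ]
      ok <- all(ious <= iou_threshold | cls[keep] != cls[i])
    }
    if (ok) keep <- c(keep, i)
  }
  dets[keep]
}

#' Detect objects in an image
#'
#' Full single-image inference: letterbox to the network input, forward pass
#' (inference batch statistics), decode, confidence filter, NMS, then map
#' back to original image coordinates and clip to image bounds. Deterministic
#' for a fixed checkpoint.
#'
#' @param model a trained (or freshly built) detector.
#' @param image `H x W x 3` array, or a path readable by [read_image()].
#' @param conf_threshold confidence cutoff (default 0.25).
#' @param iou_threshold NMS threshold (default 0.45).
#' @return list of [detection()]s in original image coordinates.
#' @export
detect <- function(model, image, conf_threshold = 0.25, iou_threshold = 0.45) {
  if (is.character(image)) image <- read_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  rec <- image_record("in-memory", w, h, list())
  lb <- letterbox(image, rec, target_size = model$config$input_size,
                  divisor = max(model$strides))
  raw <- forward_detector(model, list(lb$image), training = FALSE)
  dets <- decode_predictions(raw, model, conf_threshold = conf_threshold)
  dets <- nms(dets, iou_threshold = iou_threshold)
  inv <- attr(lb$record, "inv_map")
  out <- lapply(dets, function(d) {
    detection(unletterbox_box(d$box, inv), d$confidence, d$class_name)
  })
  out[!vapply(out, function(d) is_degenerate(d$box), logical(1))]
}

#' Write detections as one-line-per-detection text
#'
#' Format: `image class confidence x_min y_min x_max y_max`, whitespace
#' separated, one row per detection.
#'
#' @param dets list of [detection()]s.
#' @param image_name identifier for the first column.
#' @param path output file, or `""` for stdout.
#' @return `path` invisibly.
#' @export
write_detections <- function(dets, image_name, path = "") {
  lines <- vapply(dets, function(d) {
    sprintf("%s %s %.6f %.2f %.2f %.2f %.2f", image_name, d$class_name,
            d$confidence, d$box$x_min, d$box$y_min, d$box$x_max, d$box$y_max)
  }, character(1))
  if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}
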