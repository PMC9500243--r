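#' Anchor prior set
#'
#' An ordered set of `(w, h)` prior shapes plus a partition of the anchors
#' into one group per detection scale (3 groups of 3 by default). Groups are
#' ordered smallest to largest mean area; the smallest-area group is bound to
#' the finest grid, where small targets such as platelets live.
#'
#' @param wh numeric matrix with columns `w`, `h` (pixels), one row per anchor.
#' @param scale_groups list of integer index vectors, one per scale, or `NULL`
#'   to assign with [assign_scales()] when the count divides evenly.
#' @return object of class `"anchor_set"`.
#' @export
anchor_set <- function(wh, scale_groups = NULL) {
  wh <- as.matrix(wh)
  stopifnot(ncol(wh) == 2, all(wh > 0))
  colnames(wh) <- c("w", "h")
  obj <- structure(list(wh = wh, scale_groups = scale_groups),
                   class = "anchor_set")
  if (is.null(scale_groups) && nrow(wh) %% 3L == 0L) {
    obj <- assign_scales(obj, n_scales = 3L)
  }
  obj
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set: %d anchors, %d scale groups>\n",
              nrow(x$wh), length(x$scale_groups)))
  for (i in seq_along(x$scale_groups)) {
    g <- x$scale_groups[[i]]
    cat(sprintf("  scale %d (finest first): %s\n", i,
                paste(sprintf("(%g,%g)", x$wh[g, 1], x$wh[g, 2]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Reference 9-anchor platelet prior set
#'
#' The published platelet anchor shapes obtained by k-means on the original
#' 412-image stained-smear dataset: (3,6), (16,18), (13,19), (29,29), (13,25),
#' (24,30), (24,39), (39,42), (45,60). Shipped verbatim in published order as
#' a named constant; they cannot be re-derived without that private dataset.
#' Scale groups are assigned by area as for computed anchors.
#'
#' @return an [anchor_set()].
#' @export
default_platelet_anchors <- function() {
  wh <- matrix(c(3, 6, 16, 18, 13, 19, 29, 29, 13, 25,
                 24, 30, 24, 39, 39, 42, 45, 60),
               ncol = 2, byrow = TRUE)
  anchor_set(wh)
}

# 1 - IOU between center-aligned shapes; boxes: n x 2 (w,h), centroids: k x 2.
shape_iou_dist <- function(wh, centroids) {
  n <- nrow(wh); k <- nrow(centroids)
  bw <- matrix(wh[, 1], n, k); bh <- matrix(wh[, 2], n, k)
  cw <- matrix(centroids[, 1], n, k, byrow = TRUE)
  ch <- matrix(centroids[, 2], n, k, byrow = TRUE)
  inter <- pmin(bw, cw) * pmin(bh, ch)
  1 - inter / (bw * bh + cw * ch - inter)
}

#' Cluster ground-truth box shapes into anchor priors
#'
#' k-means over the `(w, h)` shapes of ground-truth boxes. The default
#' distance is `1 - IOU` of the centre-aligned shapes (the YOLO-family
#' convention that makes the resulting priors meaningful to the detection
#' head); plain Euclidean distance on `(w, h)` is available behind
#' `distance = "euclidean"`. Centroids are updated as the arithmetic mean of
#' member shapes, initialised by sampling `k` distinct boxes with `seed`,
#' iterated to unchanged assignment or `max_iter`, ties broken toward the
#' lowest cluster index, and returned sorted ascending by area.
#'
#' @param boxes list of ground-truth [box()]es (positions ignored, shapes
#'   used); degenerate boxes are excluded with a warning.
#' @param k number of anchors (default 9).
#' @param seed integer seed controlling initialisation.
#' @param max_iter iteration cap (default 300).
#' @param distance `"iou"` (default) or `"euclidean"`.
#' @return an [anchor_set()] with `scale_groups` set when `k %% 3 == 0`.
#' @export
kmeans_anchors <- function(boxes, k = 9L, seed = 1L, max_iter = 300L,
                           distance = c("iou", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(k >= 1L)
  deg <- vapply(boxes, is_degenerate, logical(1))
  if (any(deg)) {
    warning(sprintf("excluding %d degenerate box(es) from clustering", sum(deg)))
    boxes <- boxes[!deg]
  }
  m <- boxes_to_matrix(boxes)
  wh <- cbind(m[, 3] - m[, 1], m[, 4] - m[, 2])
  if (nrow(wh) < k) {
    stop(sprintf("need at least k = %d boxes, got %d", k, nrow(wh)))
  }
  dist_fun <- if (distance == "iou") {
    shape_iou_dist
  } else {
    function(wh, ce) {
      n <- nrow(wh); kk <- nrow(ce)
      dw <- matrix(wh[, 1], n, kk) - matrix(ce[, 1], n, kk, byrow = TRUE)
      dh <- matrix(wh[, 2], n, kk) - matrix(ce[, 2], n, kk, byrow = TRUE)
      sqrt(dw^2 + dh^2)
    }
  }
  centroids <- with_seed(seed, {
    # canonical (sorted) order of the distinct shapes, so initialisation --
    # and hence the whole run -- is invariant to input box ordering
    uniq <- unique(wh)
    uniq <- uniq[order(uniq[, 1], uniq[, 2]), , drop = FALSE]
    if (nrow(uniq) >= k) uniq[sample.int(nrow(uniq), k), , drop = FALSE]
    else wh[sample.int(nrow(wh), k), , drop = FALSE]
  })
  assign_prev <- rep(0L, nrow(wh))
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- dist_fun(wh, centroids)
    assign_cur <- max.col(-d, ties.method = "first")
    objective <- c(objective, mean(d[cbind(seq_len(nrow(wh)), assign_cur)]))
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(k)) {
      members <- wh[assign_cur == j, , drop = FALSE]
      if (nrow(members) > 0) centroids[j, ] <- colMeans(members)
      # empty cluster keeps its previous centroid
    }
  }
  centroids <- centroids[order(centroids[, 1] * centroids[, 2]), , drop = FALSE]
  out <- if (k %% 3L == 0L) anchor_set(centroids) else
    anchor_set(centroids, scale_groups = list(seq_len(k)))
  # per-iteration mean (1 - best IOU), for convergence diagnostics
  attr(out, "objective_trace") <- objective
  out
}

#' Mean best IOU of a box set against an anchor set
#'
#' For each box, the best centre-aligned IOU against any anchor; averaged
#' over boxes. The standard diagnostic of how well a prior set fits a
#' dataset's shape distribution; in `[0, 1]`, 1 when every shape has an
#' exactly matching anchor.
#'
#' @param boxes non-empty list of boxes.
#' @param anchors an [anchor_set()].
#' @return scalar in `[0, 1]`.
#' @export
mean_best_iou <- function(boxes, anchors) {
  if (length(boxes) == 0L) stop("empty box list")
  m <- boxes_to_matrix(boxes)
  wh <- cbind(m[, 3] - m[, 1], m[, 4] - m[, 2])
  d <- shape_iou_dist(wh, anchors$wh)
  mean(1 - apply(d, 1, min))
}

#' Partition anchors into per-scale groups
#'
#' Sorts anchors ascending by area and splits them contiguously into
#' `n_scales` equal groups. Group 1 (smallest shapes) is bound to the finest
#' detection grid (104 x 104 in the improved variant at input 416), the last
#' group to the coarsest.
#'
#' @param anchors an [anchor_set()].
#' @param n_scales number of detection scales (default 3).
#' @return the anchor set with `scale_groups` set. The anchor list itself is
#'   left in its original order (so the published constant stays verbatim);
#'   groups are index vectors into it, area-sorted within and across groups.
#' @export
assign_scales <- function(anchors, n_scales = 3L) {
  k <- nrow(anchors$wh)
  if (k %% n_scales != 0L) {
    stop(sprintf("anchor count %d not divisible by n_scales %d", k, n_scales))
  }
  per <- k %/% n_scales
  ord <- order(anchors$wh[, 1] * anchors$wh[, 2])
  groups <- split(ord, rep(seq_len(n_scales), each = per))
  names(groups) <- NULL
  structure(list(wh = anchors$wh, scale_groups = groups),
            class = "anchor_set")
}

#' Write / read anchors in the "w,h" per line dialect
#'
#' @param anchors an [anchor_set()].
#' @param path output file.
#' @return `path` invisibly / an [anchor_set()].
#' @export
write_anchors <- function(anchors, path) {
  writeLines(sprintf("%g,%g", anchors$wh[, 1], anchors$wh[, 2]), path)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  parts <- strsplit(trimws(readLines(path)), ",")
  parts <- parts[vapply(parts, length, 1L) == 2L]
  wh <- do.call(rbind, lapply(parts, as.numeric))
  anchor_set(wh)
}
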