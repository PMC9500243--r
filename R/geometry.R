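#' Axis-aligned bounding box
#'
#' Constructs a box in the package's internal coordinate convention:
#' continuous, 0-based, half-open `[x_min, x_max) x [y_min, y_max)`, so
#' `area = (x_max - x_min) * (y_max - y_min)`. Pascal VOC's 1-based inclusive
#' pixel indices are converted to this convention at I/O time (see
#' [read_voc()]); all geometry below is convention-free.
#'
#' Boxes with non-positive extent are permitted but flagged degenerate; the
#' similarity functions treat them as "no overlap possible" rather than
#' raising, so one corrupt annotation cannot abort a batch evaluation.
#'
#' @param x_min,y_min,x_max,y_max box corners (continuous pixels).
#' @param label class name, default `"platelet"`.
#' @return an object of class `"box"` (named list).
#' @export
#' @examples
#' b <- box(0, 0, 10, 10)
#' iou(b, b) # 1
box <- function(x_min, y_min, x_max, y_max, label = "platelet") {
  stopifnot(is.numeric(x_min), is.numeric(y_min),
            is.numeric(x_max), is.numeric(y_max))
  structure(list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                 label = as.character(label)),
            class = "box")
}

#' @export
format.box <- function(x, ...) {
  sprintf("<box %s (%.6g,%.6g)-(%.6g,%.6g)>",
          x$label, x$x_min, x$y_min, x$x_max, x$y_max)
}

#' @export
print.box <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname box
#' @param b a box.
#' @export
box_area <- function(b) {
  max(0, b$x_max - b$x_min) * max(0, b$y_max - b$y_min)
}

#' @rdname box
#' @export
is_degenerate <- function(b) {
  b$x_max <= b$x_min || b$y_max <= b$y_min
}

# Boxes as a 4-column matrix (x_min, y_min, x_max, y_max) for vectorised paths.
boxes_to_matrix <- function(boxes) {
  if (length(boxes) == 0L) {
    return(matrix(numeric(0), 0L, 4L,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max"))))
  }
  m <- t(vapply(boxes, function(b) c(b$x_min, b$y_min, b$x_max, b$y_max),
                numeric(4)))
  colnames(m) <- c("x_min", "y_min", "x_max", "y_max")
  m
}

matrix_to_boxes <- function(m, label = "platelet") {
  lapply(seq_len(nrow(m)), function(i) {
    box(m[i, 1], m[i, 2], m[i, 3], m[i, 4], label = label)
  })
}

#' Intersection over union of two boxes
#'
#' `IOU(C, G) = area(C ∩ G) / area(C ∪ G)`: 1 for identical boxes,
#' 0 for boxes whose interiors are disjoint. Degenerate (zero-area) boxes
#' return 0 -- no overlap is possible.
#'
#' @param a,b boxes from [box()].
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (is_degenerate(a) || is_degenerate(b)) return(0)
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Complete IOU (CIOU) of a predicted and a ground-truth box
#'
#' `CIOU = IOU - rho^2(b, b_gt) / c^2 - alpha * nu`, where `rho^2` is the
#' squared distance between box centres, `c` the diagonal of the smallest
#' enclosing box, `nu = (4/pi^2) * (atan(w_gt/h_gt) - atan(w/h))^2` the
#' aspect-ratio consistency term, and `alpha = nu / ((1 - IOU) + nu)` the
#' balance weight (0 when the denominator is 0). Unlike plain IOU the value
#' keeps discriminating between non-overlapping boxes: it decreases as the
#' centres move apart, which is exactly why it enters the anchor-matching
#' score ([match_parameter()]).
#'
#' Degenerate boxes contribute IOU = 0 but the distance penalty is still
#' computed; when both boxes collapse to the same point the enclosing
#' diagonal is 0 and the penalty is defined as 0.
#'
#' @param pred,gt predicted and ground-truth boxes.
#' @return scalar `<= 1` (can be negative for distant boxes).
#' @export
ciou <- function(pred, gt) {
  v <- ciou_terms(
    pred$x_min, pred$y_min, pred$x_max, pred$y_max,
    gt$x_min, gt$y_min, gt$x_max, gt$y_max)
  v[["ciou"]]
}

# Shared scalar kernel: returns iou, ciou and the penalty pieces.
ciou_terms <- function(px1, py1, px2, py2, gx1, gy1, gx2, gy2) {
  pw <- px2 - px1; ph <- py2 - py1
  gw <- gx2 - gx1; gh <- gy2 - gy1
  deg_p <- pw <= 0 || ph <= 0
  deg_g <- gw <= 0 || gh <= 0
  if (deg_p || deg_g) {
    iou_v <- 0
  } else {
    iw <- min(px2, gx2) - max(px1, gx1)
    ih <- min(py2, gy2) - max(py1, gy1)
    inter <- if (iw > 0 && ih > 0) iw * ih else 0
    iou_v <- inter / (pw * ph + gw * gh - inter)
  }
  rho2 <- ((px1 + px2) / 2 - (gx1 + gx2) / 2)^2 +
          ((py1 + py2) / 2 - (gy1 + gy2) / 2)^2
  cw <- max(px2, gx2) - min(px1, gx1)
  ch <- max(py2, gy2) - min(py1, gy1)
  c2 <- cw^2 + ch^2
  dist_pen <- if (c2 > 0) rho2 / c2 else 0
  # aspect term needs positive sides on both boxes
  if (deg_p || deg_g) {
    nu <- 0
  } else {
    nu <- (4 / pi^2) * (atan(gw / gh) - atan(pw / ph))^2
  }
  denom <- (1 - iou_v) + nu
  alpha <- if (denom > 0) nu / denom else 0
  c(iou = iou_v, ciou = iou_v - dist_pen - alpha * nu,
    nu = nu, alpha = alpha, dist_pen = dist_pen)
}

#' Anchor-matching score: CIOU + IOU
#'
#' The assignment score used to pick the best prior for each ground-truth
#' box: the sum of [ciou()] and [iou()]. It equals 2 only for identical
#' boxes, and -- unlike IOU alone -- is never flat for disjoint boxes: the
#' CIOU centre-distance term keeps a usable gradient as a far prediction
#' slides toward the target.
#'
#' @inheritParams ciou
#' @return scalar `<= 2`.
#' @export
match_parameter <- function(pred, gt) {
  ciou(pred, gt) + iou(pred, gt)
}

#' Pairwise similarity matrix
#'
#' Applies one of the scalar similarity measures to every pair from two box
#' lists. The vectorised implementation agrees with the scalar functions to
#' machine precision.
#'
#' @param boxes_a,boxes_b lists of boxes.
#' @param kind one of `"iou"`, `"ciou"`, `"match"`.
#' @return `length(boxes_a) x length(boxes_b)` numeric matrix.
#' @export
pairwise_matrix <- function(boxes_a, boxes_b, kind = c("iou", "ciou", "match")) {
  kind <- match.arg(kind)
  a <- boxes_to_matrix(boxes_a)
  b <- boxes_to_matrix(boxes_b)
  pairwise_matrix_xyxy(a, b, kind)
}

# Vectorised kernel on 4-column corner matrices.
pairwise_matrix_xyxy <- function(a, b, kind = "iou") {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), na, nb))
  ax1 <- matrix(a[, 1], na, nb); ay1 <- matrix(a[, 2], na, nb)
  ax2 <- matrix(a[, 3], na, nb); ay2 <- matrix(a[, 4], na, nb)
  bx1 <- matrix(b[, 1], na, nb, byrow = TRUE); by1 <- matrix(b[, 2], na, nb, byrow = TRUE)
  bx2 <- matrix(b[, 3], na, nb, byrow = TRUE); by2 <- matrix(b[, 4], na, nb, byrow = TRUE)
  aw <- ax2 - ax1; ah <- ay2 - ay1
  bw <- bx2 - bx1; bh <- by2 - by1
  deg <- aw <= 0 | ah <= 0 | bw <= 0 | bh <= 0
  iw <- pmin(ax2, bx2) - pmax(ax1, bx1)
  ih <- pmin(ay2, by2) - pmax(ay1, by1)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  uni <- pmax(aw, 0) * pmax(ah, 0) + pmax(bw, 0) * pmax(bh, 0) - inter
  iou_m <- ifelse(deg | uni <= 0, 0, inter / uni)
  if (kind == "iou") return(iou_m)
  rho2 <- ((ax1 + ax2) / 2 - (bx1 + bx2) / 2)^2 +
          ((ay1 + ay2) / 2 - (by1 + by2) / 2)^2
  c2 <- (pmax(ax2, bx2) - pmin(ax1, bx1))^2 +
        (pmax(ay2, by2) - pmin(ay1, by1))^2
  dist_pen <- ifelse(c2 > 0, rho2 / c2, 0)
  nu <- ifelse(deg, 0, (4 / pi^2) * (atan(bw / bh) - atan(aw / ah))^2)
  denom <- (1 - iou_m) + nu
  alpha <- ifelse(denom > 0, nu / denom, 0)
  ciou_m <- iou_m - dist_pen - alpha * nu
  if (kind == "ciou") ciou_m else ciou_m + iou_m
}
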