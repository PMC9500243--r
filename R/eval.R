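#' Match detections to ground truth
#'
#' Greedy protocol by descending confidence: each detection is a true
#' positive if its IOU with some not-yet-matched ground-truth box of the same
#' class is at least `eval_iou` (the best-IOU ground truth is consumed),
#' otherwise a false positive; ground truths left unmatched are false
#' negatives. TN is undefined for detection and reported as `NA`.
#'
#' @param dets list of [detection()]s (sorted internally by confidence).
#' @param gts list of ground-truth [box()]es.
#' @param eval_iou matching threshold (default 0.5, the VOC convention; the
#'   published 0.45 setting is the NMS threshold, not this one).
#' @return list: `flags` (logical TP flag per detection, in confidence
#'   order), `confidences` (matching order), and `counts`
#'   (`TP`, `FP`, `FN`, `TN = NA`).
#' @export
match_detections <- function(dets, gts, eval_iou = 0.5) {
  conf <- vapply(dets, function(d) d$confidence, numeric(1))
  ord <- order(-conf)
  dets <- dets[ord]
  flags <- logical(length(dets))
  matched <- logical(length(gts))
  if (length(gts) > 0) gtm <- boxes_to_matrix(gts)
  gcls <- vapply(gts, function(g) g$label, character(1))
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    if (length(gts) == 0) next
    dm <- boxes_to_matrix(list(d$box))
    ious <- as.vector(pairwise_matrix_xyxy(dm, gtm, "iou"))
    ious[matched | gcls != d$class_name] <- -1
    j <- which.max(ious)
    if (length(j) == 1 && ious[j] >= eval_iou) {
      flags[i] <- TRUE
      matched[j] <- TRUE
    }
  }
  tp <- sum(flags)
  list(flags = flags, confidences = conf[ord],
       counts = list(TP = tp, FP = length(dets) - tp,
                     FN = length(gts) - tp, TN = NA))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2TP/(2TP+FP+FN)` (identically
#' the harmonic mean `2/(1/P + 1/R)`). A zero denominator yields 0 by
#' convention (documented, so "no detections" reads as zero precision rather
#' than an error).
#'
#' @param counts list with `TP`, `FP`, `FN` (e.g. from [match_detections()]).
#' @return scalar in `[0, 1]`.
#' @export
precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) 0 else counts$TP / d
}

#' @rdname precision
#' @export
recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) 0 else counts$TP / d
}

#' @rdname precision
#' @param p,r alternatively, compute F1 from precision and recall directly
#'   (harmonic mean), e.g. from a published table row.
#' @export
f1 <- function(counts = NULL, p = NULL, r = NULL) {
  if (!is.null(counts)) {
    d <- 2 * counts$TP + counts$FP + counts$FN
    return(if (d == 0) 0 else 2 * counts$TP / d)
  }
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Ranked precision-recall curve
#'
#' Builds `P(k)` and `r(k)` for `k = 1..M` confidence-ranked detections,
#' plus the recall increments `dr(k)`: the quantities entering the raw
#' Riemann-sum AP.
#'
#' @param flags logical TP flags in confidence order (from
#'   [match_detections()]).
#' @param n_gt number of ground-truth boxes.
#' @return list of class `"pr_curve"`: `precision`, `recall`, `delta_recall`.
#' @export
pr_curve <- function(flags, n_gt) {
  k <- seq_along(flags)
  tp_cum <- cumsum(flags)
  prec <- if (length(k)) tp_cum / k else numeric(0)
  rec <- if (n_gt > 0) tp_cum / n_gt else rep(0, length(k))
  structure(list(precision = prec, recall = rec,
                 delta_recall = diff(c(0, rec)), n_gt = n_gt),
            class = "pr_curve")
}

#' Average precision
#'
#' `AP = sum_k P(k) * dr(k)` over the ranked detections -- the raw
#' (uninterpolated) Riemann sum, equal to the area under the stepwise P-R
#' path. No 11-point or all-point interpolation is applied.
#'
#' @param curve a [pr_curve()].
#' @return scalar in `[0, 1]`; defined as 0 (with a warning) when there are
#'   no ground-truth boxes.
#' @export
average_precision <- function(curve) {
  if (curve$n_gt == 0) {
    warning("AP undefined with zero ground-truth boxes; returning 0")
    return(0)
  }
  sum(curve$precision * curve$delta_recall)
}

#' Evaluate detections over a set of images
#'
#' Pools per-image matches into one confidence-ranked list (the VOC
#' protocol) and reports counts, precision/recall/F1 at the given operating
#' point, and AP.
#'
#' @param dets_per_image list of per-image detection lists.
#' @param gts_per_image list of per-image ground-truth box lists.
#' @param eval_iou matching threshold (default 0.5).
#' @return list: `counts`, `precision`, `recall`, `f1`, `ap`, `curve`.
#' @export
evaluate_detections <- function(dets_per_image, gts_per_image, eval_iou = 0.5) {
  stopifnot(length(dets_per_image) == length(gts_per_image))
  flags <- logical(0)
  confs <- numeric(0)
  n_gt <- 0L
  for (i in seq_along(dets_per_image)) {
    m <- match_detections(dets_per_image[[i]], gts_per_image[[i]],
                          eval_iou = eval_iou)
    flags <- c(flags, m$flags)
    confs <- c(confs, m$confidences)
    n_gt <- n_gt + length(gts_per_image[[i]])
  }
  ord <- order(-confs)
  flags <- flags[ord]
  counts <- list(TP = sum(flags), FP = sum(!flags),
                 FN = n_gt - sum(flags), TN = NA)
  curve <- pr_curve(flags, n_gt)
  list(counts = counts, precision = precision(counts),
       recall = recall(counts), f1 = f1(counts),
       ap = if (n_gt > 0) average_precision(curve) else 0,
       curve = curve, confidences = confs[ord])
}

#' Precision/recall/F1 across confidence thresholds
#'
#' Recomputes the confusion counts at every confidence cutoff and reports the
#' per-threshold precision, recall and F1 arrays plus the argmax-F1
#' threshold: the data behind precision-threshold, recall-threshold,
#' F1-threshold and P-R plots. Recall is non-increasing in the threshold;
#' precision tends to rise but is not guaranteed monotone.
#'
#' @param dets_per_image,gts_per_image as in [evaluate_detections()].
#' @param thresholds confidence cutoffs (default `seq(0, 1, 0.01)`).
#' @param eval_iou matching threshold.
#' @return data.frame (threshold, TP, FP, FN, precision, recall, f1) with the
#'   argmax-F1 threshold in attribute `"best_threshold"`.
#' @export
threshold_sweep <- function(dets_per_image, gts_per_image,
                            thresholds = seq(0, 1, by = 0.01),
                            eval_iou = 0.5) {
  rows <- lapply(thresholds, function(th) {
    kept <- lapply(dets_per_image, function(dets) {
      Filter(function(d) d$confidence >= th, dets)
    })
    ev <- evaluate_detections(kept, gts_per_image, eval_iou = eval_iou)
    data.frame(threshold = th, TP = ev$counts$TP, FP = ev$counts$FP,
               FN = ev$counts$FN, precision = ev$precision,
               recall = ev$recall, f1 = ev$f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_threshold") <- out$threshold[which.max(out$f1)]
  out
}

#' Comparison report table
#'
#' Emits the method-comparison layout (method, AP, F1, precision, recall,
#' wall time) as a data.frame plus tab-delimited text, with percentages
#' printed to two decimals. TN is undefined for detection and never appears.
#'
#' @param runs named list; each element a list with `ap`, `f1`, `precision`,
#'   `recall` (fractions in `[0,1]`) and optionally `time_s`.
#' @param path optional output file for the delimited text.
#' @return the data.frame (percent-scaled), invisibly if `path` given.
#' @export
comparison_report <- function(runs, path = NULL) {
  stopifnot(length(runs) >= 1)
  df <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    data.frame(method = nm, AP = 100 * r$ap, F1 = 100 * r$f1,
               precision = 100 * r$precision, recall = 100 * r$recall,
               time_s = r$time_s %||% NA_real_)
  }))
  if (!is.null(path)) {
    utils::write.table(format(df, digits = 4), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
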