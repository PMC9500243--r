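#' One annotated image
#'
#' @param image_path path to the image file (may be relative to the
#'   annotation directory).
#' @param width,height image dimensions in pixels.
#' @param boxes list of [box()]es in the internal 0-based half-open
#'   convention; boxes are clipped to `[0, width] x [0, height]` and
#'   degenerate results dropped with a warning.
#' @return object of class `"image_record"`.
#' @export
image_record <- function(image_path, width, height, boxes = list()) {
  stopifnot(width > 0, height > 0)
  clipped <- 0L
  keep <- list()
  for (b in boxes) {
    cb <- box(max(0, b$x_min), max(0, b$y_min),
              min(width, b$x_max), min(height, b$y_max), label = b$label)
    if (cb$x_min != b$x_min || cb$y_min != b$y_min ||
        cb$x_max != b$x_max || cb$y_max != b$y_max) clipped <- clipped + 1L
    if (!is_degenerate(cb)) keep[[length(keep) + 1L]] <- cb
  }
  if (clipped > 0L) {
    warning(sprintf("%s: clipped %d out-of-bounds box(es)", image_path, clipped))
  }
  structure(list(image_path = image_path, width = as.integer(width),
                 height = as.integer(height), boxes = keep),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s %dx%d, %d box(es)>\n",
              x$image_path, x$width, x$height, length(x$boxes)))
  invisible(x)
}

#' Read a Pascal VOC annotation file
#'
#' Parses the classic VOC dialect (`size` block plus one `object` block per
#' box). VOC stores 1-based inclusive pixel bounds; these are converted to
#' the internal 0-based half-open convention as `x_min <- xmin - 1`,
#' `x_max <- xmax` (likewise for y), so a VOC box `(1,1,10,10)` becomes
#' internal `(0,0,10,10)`. Class names are preserved; `difficult` and
#' `truncated` flags are parsed but ignored. Objects with `xmax <= xmin` or
#' `ymax <= ymin` are dropped with a warning.
#'
#' @param xml_path path to the `.xml` annotation.
#' @return an [image_record()].
#' @export
read_voc <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) {
    stop(sprintf("%s: missing <size> block", xml_path))
  }
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- list()
  dropped <- 0L
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    num <- function(tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
    }
    xmin <- num("xmin"); ymin <- num("ymin")
    xmax <- num("xmax"); ymax <- num("ymax")
    if (!is.finite(xmin) || xmax <= xmin || ymax <= ymin) {
      dropped <- dropped + 1L
      next
    }
    boxes[[length(boxes) + 1L]] <- box(xmin - 1, ymin - 1, xmax, ymax, label = nm)
  }
  if (dropped > 0L) {
    warning(sprintf("%s: dropped %d empty-extent object(s)", xml_path, dropped))
  }
  img <- if (is.na(fname) || fname == "") {
    sub("\\.xml$", ".ppm", basename(xml_path))
  } else fname
  image_record(file.path(dirname(xml_path), img), w, h, boxes)
}

#' Write a Pascal VOC annotation file
#'
#' Inverse of [read_voc()]: emits `folder`, `filename`, `size` and one
#' `object` block per box, converting internal 0-based half-open coordinates
#' back to VOC's 1-based inclusive integers (`xmin <- x_min + 1`,
#' `xmax <- x_max`).
#'
#' @param record an [image_record()].
#' @param xml_path output path.
#' @return `xml_path`, invisibly.
#' @export
write_voc <- function(record, xml_path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", basename(dirname(record$image_path)))
  xml2::xml_add_child(doc, "filename", basename(record$image_path))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$width))
  xml2::xml_add_child(size, "height", as.character(record$height))
  xml2::xml_add_child(size, "depth", "3")
  for (b in record$boxes) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", b$label)
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    # %.17g guarantees doubles survive the decimal round trip bit-exactly
    xml2::xml_add_child(bb, "xmin", sprintf("%.17g", b$x_min + 1))
    xml2::xml_add_child(bb, "ymin", sprintf("%.17g", b$y_min + 1))
    xml2::xml_add_child(bb, "xmax", sprintf("%.17g", b$x_max))
    xml2::xml_add_child(bb, "ymax", sprintf("%.17g", b$y_max))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Split records into train / validation / test
#'
#' Deterministic seeded random partition. When `counts` is `NULL` the split
#' mirrors the reference dataset's 296/33/83 proportions of 412
#' (~0.72/0.08/0.20): `n_train = round(n * 296/412)`,
#' `n_val = round(n * 33/412)`, remainder test.
#'
#' @param records list of [image_record()]s.
#' @param counts integer vector `(n_train, n_val, n_test)` summing to
#'   `length(records)`, or `NULL` for the default proportions.
#' @param seed integer seed.
#' @return list with class `"dataset_split"` and fields `train`, `val`, `test`.
#' @export
split_dataset <- function(records, counts = NULL, seed = 1L) {
  n <- length(records)
  if (is.null(counts)) {
    n_train <- round(n * 296 / 412)
    n_val <- round(n * 33 / 412)
    counts <- c(n_train, n_val, n - n_train - n_val)
  }
  counts <- as.integer(counts)
  if (length(counts) != 3L || sum(counts) != n || any(counts < 0L)) {
    stop(sprintf("counts (%s) must be 3 non-negative integers summing to %d",
                 paste(counts, collapse = ","), n))
  }
  perm <- with_seed(seed, sample.int(n))
  idx_train <- perm[seq_len(counts[1])]
  idx_val <- perm[counts[1] + seq_len(counts[2])]
  idx_test <- perm[counts[1] + counts[2] + seq_len(counts[3])]
  structure(list(train = records[idx_train],
                 val = records[idx_val],
                 test = records[idx_test]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split train=%d val=%d test=%d>\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Letterbox an image and its boxes to the network input size
#'
#' Aspect-preserving resize to fit inside `target_size x target_size`,
#' padded symmetrically with neutral gray (0.5). Boxes are mapped by the same
#' affine transform; the returned record carries the inverse map (attribute
#' `"inv_map"`: `scale`, `pad_x`, `pad_y`) so detections can be reported in
#' original image coordinates. Uniform scaling means IOU between any two
#' boxes is exactly preserved.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`, or `NULL` to transform
#'   only the record (annotation-only pipelines).
#' @param record the matching [image_record()].
#' @param target_size network input size; must be divisible by `divisor`.
#' @param divisor stride divisibility requirement: 32 for the baseline
#'   variant, 16 for the improved variant.
#' @return list `(image, record)`; `record` has the `"inv_map"` attribute.
#' @export
letterbox <- function(image, record, target_size = 416L, divisor = 32L) {
  if (target_size %% divisor != 0L) {
    stop(sprintf("target_size %d must be divisible by %d", target_size, divisor))
  }
  w <- record$width; h <- record$height
  scale <- min(target_size / w, target_size / h)
  new_w <- round(w * scale); new_h <- round(h * scale)
  pad_x <- (target_size - new_w) / 2
  pad_y <- (target_size - new_h) / 2
  out_img <- NULL
  if (!is.null(image)) {
    resized <- resize_bilinear(image, new_h, new_w)
    out_img <- array(0.5, dim = c(target_size, target_size, 3))
    y0 <- floor(pad_y); x0 <- floor(pad_x)
    out_img[y0 + seq_len(new_h), x0 + seq_len(new_w), ] <- resized
  }
  boxes <- lapply(record$boxes, function(b) {
    box(b$x_min * scale + floor(pad_x), b$y_min * scale + floor(pad_y),
        b$x_max * scale + floor(pad_x), b$y_max * scale + floor(pad_y),
        label = b$label)
  })
  rec <- structure(list(image_path = record$image_path,
                        width = as.integer(target_size),
                        height = as.integer(target_size), boxes = boxes),
                   class = "image_record")
  attr(rec, "inv_map") <- list(scale = scale, pad_x = floor(pad_x),
                               pad_y = floor(pad_y),
                               orig_w = w, orig_h = h)
  list(image = out_img, record = rec)
}

#' Map a letterboxed-space box back to original image coordinates
#'
#' @param b a [box()] in network coordinates.
#' @param inv_map the `"inv_map"` attribute produced by [letterbox()].
#' @return a [box()] in original coordinates, clipped to the image.
#' @export
unletterbox_box <- function(b, inv_map) {
  out <- box((b$x_min - inv_map$pad_x) / inv_map$scale,
             (b$y_min - inv_map$pad_y) / inv_map$scale,
             (b$x_max - inv_map$pad_x) / inv_map$scale,
             (b$y_max - inv_map$pad_y) / inv_map$scale,
             label = b$label)
  box(max(0, out$x_min), max(0, out$y_min),
      min(inv_map$orig_w, out$x_max), min(inv_map$orig_h, out$y_max),
      label = b$label)
}

#' Write split manifests (ImageSets/Main style)
#'
#' One plain-text file per subset listing annotation basenames (no
#' extension), the classic VOC layout.
#'
#' @param split a [split_dataset()] result.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_split_manifests <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in c("train", "val", "test")) {
    ids <- vapply(split[[part]], function(r) {
      sub("\\.[a-zA-Z]+$", "", basename(r$image_path))
    }, character(1))
    writeLines(ids, file.path(dir, paste0(part, ".txt")))
  }
  invisible(dir)
}
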