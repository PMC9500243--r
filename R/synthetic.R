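#' Synthetic stained-smear generator configuration
#'
#' Parameters of the deterministic blood-smear emulator used for offline
#' testing and the scaled-down training benchmark. The rendered scene is a
#' pale stained background, large round erythrocyte-like disks with pale
#' centres (rendered but deliberately NOT labelled -- they are hard-negative
#' distractors whose pixel values sit close to the background, as in real
#' stained smears), and small irregular darker-stained elliptical blobs
#' standing in for platelets, which are the labelled class. Platelets are
#' roughly 1/10 the erythrocyte diameter, mirroring the 2-4 um platelet vs
#' ~25 um-scale erythrocyte ratio of real smears.
#'
#' @param image_size square image side in pixels (default 416).
#' @param n_platelets integer range, platelets per image (default `c(3, 12)`).
#' @param platelet_diameter pixel range of platelet major diameters
#'   (default `c(6, 16)`).
#' @param n_erythrocytes integer range of unlabeled distractor disks
#'   (default `c(8, 20)`).
#' @param erythrocyte_diameter pixel range of distractor diameters
#'   (default `c(60, 110)`).
#' @param background_color,erythrocyte_color,platelet_color RGB triples in
#'   `[0,1]`; the platelet stain is darker purple than the background.
#' @param color_jitter per-shape uniform color perturbation amplitude.
#' @param noise_sigma gaussian pixel noise s.d. (default 0.02).
#' @param max_box_iou labelled boxes are re-sampled until their IOU with
#'   every existing labelled box is `<=` this (default 0.6), keeping the
#'   detection task well-posed.
#' @param seed default seed used when callers do not supply one.
#' @return object of class `"smear_config"`.
#' @export
smear_config <- function(image_size = 416L,
                         n_platelets = c(3L, 12L),
                         platelet_diameter = c(6, 16),
                         n_erythrocytes = c(8L, 20L),
                         erythrocyte_diameter = c(60, 110),
                         background_color = c(0.93, 0.87, 0.90),
                         erythrocyte_color = c(0.91, 0.72, 0.74),
                         platelet_color = c(0.48, 0.30, 0.58),
                         color_jitter = 0.05,
                         noise_sigma = 0.02,
                         max_box_iou = 0.6,
                         seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              n_platelets = as.integer(n_platelets),
              platelet_diameter = as.numeric(platelet_diameter),
              n_erythrocytes = as.integer(n_erythrocytes),
              erythrocyte_diameter = as.numeric(erythrocyte_diameter),
              background_color = background_color,
              erythrocyte_color = erythrocyte_color,
              platelet_color = platelet_color,
              color_jitter = color_jitter,
              noise_sigma = noise_sigma,
              max_box_iou = max_box_iou,
              seed = as.integer(seed))
  validate_smear_config(cfg)
  structure(cfg, class = "smear_config")
}

validate_smear_config <- function(cfg) {
  if (cfg$image_size < 32L) stop("image_size too small")
  rngs <- list(n_platelets = cfg$n_platelets,
               platelet_diameter = cfg$platelet_diameter,
               n_erythrocytes = cfg$n_erythrocytes,
               erythrocyte_diameter = cfg$erythrocyte_diameter)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(r < 0) || r[2] < r[1]) {
      stop(sprintf("%s must be a non-negative (lo, hi) range", nm))
    }
  }
  if (cfg$platelet_diameter[2] >= cfg$erythrocyte_diameter[1]) {
    stop("platelet diameters must stay below erythrocyte diameters")
  }
  invisible(cfg)
}

#' High-contrast preset for the scaled-down training benchmark
#'
#' Same scene statistics as [smear_config()] but at reduced resolution with
#' a stronger platelet-background contrast, fewer and fainter distractors and
#' less noise: the easiest variant of the task, used by the end-to-end
#' desk-scale training check so that ~20 CPU epochs suffice to learn it.
#'
#' @param image_size square image side (default 160, the reduced network input).
#' @return a [smear_config()].
#' @export
smear_config_high_contrast <- function(image_size = 160L) {
  smear_config(image_size = image_size,
               n_platelets = c(3L, 7L),
               platelet_diameter = c(8, 16),
               n_erythrocytes = c(2L, 5L),
               erythrocyte_diameter = c(40, 64),
               erythrocyte_color = c(0.93, 0.80, 0.82),
               platelet_color = c(0.30, 0.12, 0.40),
               color_jitter = 0.03,
               noise_sigma = 0.01)
}

runif_range <- function(n, r) stats::runif(n, r[1], r[2])

# Render one filled (possibly rotated) ellipse onto img by alpha blending;
# returns the updated image. cx, cy are 0-based centre coordinates.
render_ellipse <- function(img, cx, cy, rx, ry, theta, color, alpha = 1,
                           edge_soft = 1) {
  size_y <- dim(img)[1]; size_x <- dim(img)[2]
  pad <- max(rx, ry) + edge_soft + 1
  xs <- max(1, floor(cx - pad + 1)):min(size_x, ceiling(cx + pad + 1))
  ys <- max(1, floor(cy - pad + 1)):min(size_y, ceiling(cy + pad + 1))
  if (length(xs) == 0 || length(ys) == 0) return(img)
  gx <- matrix(xs - 1 - cx, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys - 1 - cy, length(ys), length(xs))
  ct <- cos(theta); st <- sin(theta)
  u <- (gx * ct + gy * st) / rx
  v <- (-gx * st + gy * ct) / ry
  r <- sqrt(u^2 + v^2)
  # soft edge over ~edge_soft pixels of the minor radius
  soft <- pmin(pmax((1 - r) * min(rx, ry) / edge_soft, 0), 1) * alpha
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    img[ys, xs, ch] <- patch * (1 - soft) + color[ch] * soft
  }
  img
}

#' Generate one synthetic smear image with annotations
#'
#' Fully deterministic given `(config, seed)`: renders the background,
#' unlabeled erythrocyte disks with pale centres, then platelet blobs as
#' small stained ellipses with random eccentricity (major/minor up to 1.8),
#' rotation and a darker granular core. One tight VOC-style box is emitted
#' per platelet; placements whose box IOU with an existing platelet box
#' exceeds `config$max_box_iou` are re-sampled (up to 50 tries, then the
#' platelet is skipped).
#'
#' @param config a [smear_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param image_path path recorded in the returned record (no file written).
#' @return list `(image, record)`: the `H x W x 3` array and [image_record()].
#' @export
generate_image <- function(config, seed = config$seed,
                           image_path = "synthetic.ppm") {
  validate_smear_config(config)
  s <- config$image_size
  with_seed(seed, {
    img <- array(rep(config$background_color, each = s * s), dim = c(s, s, 3))
    # gentle illumination gradient
    grad <- outer(seq(-1, 1, length.out = s), seq(-1, 1, length.out = s),
                  function(a, b) 0.02 * (a + b) / 2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + grad
    n_ery <- if (config$n_erythrocytes[2] > 0) {
      sample(config$n_erythrocytes[1]:config$n_erythrocytes[2], 1)
    } else 0L
    for (i in seq_len(n_ery)) {
      d <- runif_range(1, config$erythrocyte_diameter)
      cx <- stats::runif(1, 0, s - 1); cy <- stats::runif(1, 0, s - 1)
      col <- pmin(pmax(config$erythrocyte_color +
                         stats::runif(3, -config$color_jitter,
                                      config$color_jitter), 0), 1)
      img <- render_ellipse(img, cx, cy, d / 2, d / 2 * stats::runif(1, 0.9, 1),
                            stats::runif(1, 0, pi), col, alpha = 0.85,
                            edge_soft = 2)
      # pale biconcave-style centre
      pale <- pmin(col + 0.10, 1)
      img <- render_ellipse(img, cx, cy, d / 5, d / 5, 0, pale, alpha = 0.8,
                            edge_soft = 2)
    }
    n_plt <- sample(config$n_platelets[1]:config$n_platelets[2], 1)
    boxes <- list()
    placed <- matrix(numeric(0), 0, 4)
    for (i in seq_len(n_plt)) {
      for (try in 1:50) {
        dmaj <- runif_range(1, config$platelet_diameter)
        ecc <- stats::runif(1, 1.0, 1.8)
        dmin <- max(dmaj / ecc, config$platelet_diameter[1] / 1.8)
        theta <- stats::runif(1, 0, pi)
        rx <- dmaj / 2; ry <- dmin / 2
        # tight axis-aligned half-extents of the rotated ellipse
        hx <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
        hy <- sqrt((rx * sin(theta))^2 + (ry * cos(theta))^2)
        cx <- stats::runif(1, hx + 1, s - hx - 2)
        cy <- stats::runif(1, hy + 1, s - hy - 2)
        cand <- c(cx - hx, cy - hy, cx + hx, cy + hy)
        ok <- TRUE
        if (nrow(placed) > 0) {
          ious <- pairwise_matrix_xyxy(matrix(cand, 1), placed, "iou")
          same_center <- any(abs(placed[, 1] + placed[, 3] - 2 * cx) < 1e-9 &
                               abs(placed[, 2] + placed[, 4] - 2 * cy) < 1e-9)
          ok <- all(ious <= config$max_box_iou) && !same_center
        }
        if (ok) {
          col <- pmin(pmax(config$platelet_color +
                             stats::runif(3, -config$color_jitter,
                                          config$color_jitter), 0), 1)
          img <- render_ellipse(img, cx, cy, rx, ry, theta, col,
                                alpha = 0.95, edge_soft = 1)
          # darker granular core speckle
          img <- render_ellipse(img, cx + stats::runif(1, -rx / 4, rx / 4),
                                cy + stats::runif(1, -ry / 4, ry / 4),
                                rx / 2.5, ry / 2.5, theta,
                                pmax(col - 0.12, 0), alpha = 0.9,
                                edge_soft = 1)
          placed <- rbind(placed, cand)
          boxes[[length(boxes) + 1L]] <-
            box(cand[1], cand[2], cand[3], cand[4], label = "platelet")
          break
        }
      }
    }
    if (config$noise_sigma > 0) {
      img <- img + array(stats::rnorm(s * s * 3, 0, config$noise_sigma),
                         dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         record = image_record(image_path, s, s, boxes))
  })
}

#' Generate a dataset of synthetic smears on disk
#'
#' Writes `n_images` images (PPM by default) with matching VOC annotation
#' files plus `ImageSets/Main`-style split manifests. Each image uses an
#' independent substream seed derived from `(seed, index)` so generation is
#' reproducible regardless of order. With the defaults (`n_images = 412`,
#' `counts = NULL`) the split manifests come out 296/296-33-83 style:
#' 296 train, 33 val, 83 test.
#'
#' @param config a [smear_config()].
#' @param n_images number of images (>= 5).
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @param counts split counts passed to [split_dataset()] (`NULL` = default
#'   proportions).
#' @param format `"ppm"` (default, no dependencies) or `"png"`.
#' @return a `dataset_split` of the on-disk records (invisible file layout:
#'   `images/`, `annotations/`, `splits/`).
#' @export
generate_dataset <- function(config, n_images = 412L, out_dir, seed = 1L,
                             counts = NULL, format = c("ppm", "png")) {
  format <- match.arg(format)
  if (n_images < 5L) stop("n_images must be >= 5")
  img_dir <- file.path(out_dir, "images")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    stem <- sprintf("smear_%04d", i)
    ipath <- file.path(img_dir, paste0(stem, ".", format))
    g <- generate_image(config, seed = derive_seed(seed, i),
                        image_path = ipath)
    write_image(g$image, ipath)
    write_voc(g$record, file.path(ann_dir, paste0(stem, ".xml")))
    records[[i]] <- g$record
  }
  split <- split_dataset(records, counts = counts, seed = seed)
  write_split_manifests(split, file.path(out_dir, "splits"))
  split
}

#' Load a dataset previously written by [generate_dataset()]
#'
#' @param dir the dataset root.
#' @return a `dataset_split` with records read back through [read_voc()].
#' @export
load_dataset <- function(dir) {
  ann_dir <- file.path(dir, "annotations")
  img_dir <- file.path(dir, "images")
  out <- list()
  for (part in c("train", "val", "test")) {
    ids <- readLines(file.path(dir, "splits", paste0(part, ".txt")))
    out[[part]] <- lapply(ids, function(id) {
      r <- read_voc(file.path(ann_dir, paste0(id, ".xml")))
      # annotation stores only the basename; rebind to the images dir
      fname <- basename(r$image_path)
      hit <- list.files(img_dir, pattern = paste0("^", id, "\\."),
                        full.names = TRUE)
      r$image_path <- if (length(hit) > 0) hit[1] else file.path(img_dir, fname)
      r
    })
  }
  structure(out, class = "dataset_split")
}
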