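#' Detector configuration
#'
#' @param variant `"baseline"`: classic three-scale top-down fusion with
#'   heads at strides 32/16/8 (13/26/52 grids at input 416). `"improved"`:
#'   the small-target variant -- the full backbone is kept but the top-down
#'   fusion starts at the stride-16 feature and fuses down through stride 8
#'   to stride 4, so the heads sit at strides 16/8/4 (26/52/104 grids at
#'   input 416) and no head reads the 13 x 13 stride-32 map, whose receptive
#'   field has already washed out platelet-scale detail.
#' @param input_size square network input; must be divisible by 32 (the
#'   backbone always downsamples five times).
#' @param num_classes number of object classes (default 1, "platelet").
#' @param anchors an [anchor_set()] with 3 scale groups; group 1 (smallest
#'   shapes) feeds the finest head.
#' @param width_mult channel width multiplier in (0, 1]; channels are rounded
#'   to multiples of 8 with a floor of 8, so desk-scale test models stay valid.
#' @param class_names character vector of class names (length `num_classes`).
#' @return object of class `"detector_config"`.
#' @export
detector_config <- function(variant = c("improved", "baseline"),
                            input_size = 416L,
                            num_classes = 1L,
                            anchors = default_platelet_anchors(),
                            width_mult = 1,
                            class_names = "platelet") {
  variant <- match.arg(variant)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) {
    stop(sprintf("input_size %d must be divisible by 32", input_size))
  }
  stopifnot(width_mult > 0, width_mult <= 1,
            length(anchors$scale_groups) == 3L,
            length(class_names) == num_classes)
  structure(list(variant = variant, input_size = input_size,
                 num_classes = as.integer(num_classes), anchors = anchors,
                 width_mult = width_mult, class_names = class_names),
            class = "detector_config")
}

# channel width under the multiplier: multiples of 8, floor 8
ch_width <- function(c, width_mult) {
  max(8L, as.integer(round(c * width_mult / 8) * 8))
}

# Darknet-53-style backbone: 5 stride-2 subsampling convolutions interleaved
# with residual stages Res1/Res2/Res8/Res8/Res4. Returns the names of the
# stride-4/8/16/32 feature nodes.
build_backbone <- function(b, width_mult) {
  ch <- function(c) ch_width(c, width_mult)
  res_block <- function(tag, input, cout) {
    half <- ch(cout / 2)
    a <- b$cbl(paste0(tag, "_a"), input, half, k = 1L)
    c2 <- b$cbl(paste0(tag, "_b"), a, ch(cout), k = 3L)
    b$add_node(paste0(tag, "_add"), c2, input)
  }
  x <- b$input("image", 3L)
  x <- b$cbl("conv1", x, ch(32))
  x <- b$cbl("down1", x, ch(64), stride = 2L)
  x <- res_block("r1_1", x, 64)
  x <- b$cbl("down2", x, ch(128), stride = 2L)
  for (i in 1:2) x <- res_block(sprintf("r2_%d", i), x, 128)
  c2 <- x  # stride 4
  x <- b$cbl("down3", x, ch(256), stride = 2L)
  for (i in 1:8) x <- res_block(sprintf("r3_%d", i), x, 256)
  c3 <- x  # stride 8
  x <- b$cbl("down4", x, ch(512), stride = 2L)
  for (i in 1:8) x <- res_block(sprintf("r4_%d", i), x, 512)
  c4 <- x  # stride 16
  x <- b$cbl("down5", x, ch(1024), stride = 2L)
  for (i in 1:4) x <- res_block(sprintf("r5_%d", i), x, 1024)
  c5 <- x  # stride 32
  list(c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}

# The Fig.-1 fusion pattern: five alternating 1x1/3x3 CBL blocks.
five_cbl <- function(b, tag, input, c_lo, c_hi) {
  x <- b$cbl(paste0(tag, "_1"), input, c_lo, k = 1L)
  x <- b$cbl(paste0(tag, "_2"), x, c_hi, k = 3L)
  x <- b$cbl(paste0(tag, "_3"), x, c_lo, k = 1L)
  x <- b$cbl(paste0(tag, "_4"), x, c_hi, k = 3L)
  b$cbl(paste0(tag, "_5"), x, c_lo, k = 1L)
}

head_branch <- function(b, tag, input, c_hi, head_channels, obj_channels) {
  x <- b$cbl(paste0(tag, "_conv"), input, c_hi, k = 3L)
  b$conv(paste0(tag, "_out"), x, head_channels, k = 1L,
         obj_channels = obj_channels)
}

#' Build a detector
#'
#' Constructs the network graph and initialises parameters. Head channel
#' count per scale is `anchors_per_scale * (5 + num_classes)`; per anchor the
#' channels are `(t_x, t_y, t_w, t_h, objectness, class logits...)`.
#' The improved variant computes the full backbone (so baseline and improved
#' share every backbone parameter name) but its fusion path never feeds the
#' stride-32 map to a head.
#'
#' @param config a [detector_config()].
#' @param seed seed for weight initialisation.
#' @return object of class `"detector"`; heads are ordered finest grid first,
#'   matching anchor scale-group order (group 1 = smallest anchors = finest).
#' @export
build_detector <- function(config, seed = 1L) {
  stopifnot(inherits(config, "detector_config"))
  wm <- config$width_mult
  ch <- function(c) ch_width(c, wm)
  a_per <- length(config$anchors$scale_groups[[1]])
  head_ch <- a_per * (5L + config$num_classes)
  per_anchor <- 5L + config$num_classes
  obj_channels <- (seq_len(a_per) - 1L) * per_anchor + 5L
  b <- graph_builder()
  bk <- build_backbone(b, wm)
  if (config$variant == "baseline") {
    p5 <- five_cbl(b, "p5", bk$c5, ch(512), ch(1024))
    h5 <- head_branch(b, "head32", p5, ch(1024), head_ch, obj_channels)
    u5 <- b$cbl("lat5", p5, ch(256), k = 1L)
    u5 <- b$upsample("up5", u5)
    m4 <- b$concat("cat4", u5, bk$c4)
    p4 <- five_cbl(b, "p4", m4, ch(256), ch(512))
    h4 <- head_branch(b, "head16", p4, ch(512), head_ch, obj_channels)
    u4 <- b$cbl("lat4", p4, ch(128), k = 1L)
    u4 <- b$upsample("up4", u4)
    m3 <- b$concat("cat3", u4, bk$c3)
    p3 <- five_cbl(b, "p3", m3, ch(128), ch(256))
    h3 <- head_branch(b, "head8", p3, ch(256), head_ch, obj_channels)
    head_names <- c(h3, h4, h5)      # finest first
    strides <- c(8L, 16L, 32L)
  } else {
    p4 <- five_cbl(b, "p4", bk$c4, ch(256), ch(512))
    h4 <- head_branch(b, "head16", p4, ch(512), head_ch, obj_channels)
    u4 <- b$cbl("lat4", p4, ch(128), k = 1L)
    u4 <- b$upsample("up4", u4)
    m3 <- b$concat("cat3", u4, bk$c3)
    p3 <- five_cbl(b, "p3", m3, ch(128), ch(256))
    h3 <- head_branch(b, "head8", p3, ch(256), head_ch, obj_channels)
    # new shallow path: stride 8 -> stride 4, widths half of the 52x52 path
    u3 <- b$cbl("lat3", p3, ch(64), k = 1L)
    u3 <- b$upsample("up3", u3)
    m2 <- b$concat("cat2", u3, bk$c2)
    p2 <- five_cbl(b, "p2", m2, ch(64), ch(128))
    h2 <- head_branch(b, "head4", p2, ch(128), head_ch, obj_channels)
    head_names <- c(h2, h3, h4)      # finest first
    strides <- c(4L, 8L, 16L)
  }
  params <- with_seed(seed, init_graph_params(b$nodes))
  structure(list(nodes = b$nodes, params = params, config = config,
                 head_names = head_names, strides = strides),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf("<detector %s, input %d, width_mult %g, %d parameters>\n",
              x$config$variant, x$config$input_size, x$config$width_mult,
              n_parameters(x)))
  cat(sprintf("  heads (finest first): %s at strides %s\n",
              paste(x$head_names, collapse = ", "),
              paste(x$strides, collapse = "/")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [build_detector()] result.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  total <- 0
  for (nm in ls(model$params)) {
    p <- get(nm, envir = model$params)
    for (field in c("W", "b", "gamma", "beta")) {
      if (!is.null(p[[field]])) total <- total + length(p[[field]])
    }
  }
  total
}

# Named vector: parameter element counts per graph node (for structural tests).
parameter_shapes <- function(model) {
  out <- list()
  for (nm in ls(model$params)) {
    p <- get(nm, envir = model$params)
    out[[nm]] <- vapply(p[c("W", "gamma", "beta", "b")],
                        function(v) if (is.null(v)) 0L else length(v),
                        integer(1))
  }
  out
}

# One image as a (h*w) x 3 row-per-pixel matrix (the fm layout block).
image_rows <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- matrix(0, h * w, 3)
  for (ch in 1:3) m[, ch] <- as.vector(t(img[, , ch]))
  attr(m, "hw") <- c(h, w)
  m
}

# Convert a batch (list of H x W x 3 arrays, or of image_rows() matrices)
# to the network's fm layout.
images_to_fm <- function(images) {
  if (is.matrix(images[[1]])) {
    hw <- attr(images[[1]], "hw")
    return(fm(do.call(rbind, images), length(images), hw[1], hw[2]))
  }
  n <- length(images)
  h <- dim(images[[1]])[1]; w <- dim(images[[1]])[2]
  x <- matrix(0, n * h * w, 3)
  for (i in seq_len(n)) {
    img <- images[[i]]
    stopifnot(all(dim(img)[1:2] == c(h, w)))
    x[(i - 1) * h * w + seq_len(h * w), ] <- image_rows(img)
  }
  fm(x, n, h, w)
}

#' Forward pass
#'
#' @param model a detector.
#' @param images list of letterboxed `input_size x input_size x 3` arrays.
#' @param training use batch statistics and record the autodiff cache.
#' @return list of raw per-scale prediction feature maps (finest grid first),
#'   each `list(x, n, h, w)` with `anchors_per_scale * (5 + num_classes)`
#'   channels; with `training = TRUE` the full forward record is attached as
#'   attribute `"fwd"` for the loss/backward step.
#' @export
forward_detector <- function(model, images, training = FALSE) {
  sz <- model$config$input_size
  for (img in images) {
    d <- if (is.matrix(img)) attr(img, "hw") else dim(img)[1:2]
    if (!all(d == c(sz, sz))) {
      stop(sprintf("expected %dx%d letterboxed input, got %dx%d",
                   sz, sz, d[1], d[2]))
    }
  }
  input <- images_to_fm(images)
  fwd <- graph_forward(model$nodes, model$params, input,
                       training = training, keep_cache = training)
  outs <- lapply(model$head_names, function(nm) fwd$values[[nm]])
  names(outs) <- model$head_names
  if (training) attr(outs, "fwd") <- fwd
  outs
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single serialized file holding the parameters and the
#' [detector_config()] that built them.
#'
#' @param model a detector.
#' @param path checkpoint file.
#' @return `path` / the restored detector.
#' @export
save_checkpoint <- function(model, path) {
  params_list <- mget(ls(model$params), envir = model$params)
  saveRDS(list(config = model$config, params = params_list,
               format_version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$config, seed = 1L)
  for (nm in names(ck$params)) assign(nm, ck$params[[nm]], envir = model$params)
  model
}
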