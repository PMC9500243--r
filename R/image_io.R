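#' Read and write RGB images
#'
#' Images are `H x W x 3` numeric arrays in `[0, 1]`. Binary PPM (P6, 8-bit)
#' is supported natively so the package has no hard image-library dependency;
#' `.png` is read/written through the `png` package and `.jpg`/`.jpeg` read
#' through `jpeg` when those packages are installed.
#'
#' @param path image file; format chosen by extension.
#' @return `read_image`: the array. `write_image`: `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pnm")) return(read_ppm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package; use PPM instead")
    }
    img <- png::readPNG(path)
    return(ensure_rgb(img))
  }
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("reading JPEG requires the 'jpeg' package; use PPM instead")
    }
    return(ensure_rgb(jpeg::readJPEG(path)))
  }
  stop(sprintf("unsupported image extension '%s' (use ppm/png/jpg)", ext))
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pnm")) return(write_ppm(image, path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package; use PPM instead")
    }
    png::writePNG(image, path)
    return(invisible(path))
  }
  stop(sprintf("unsupported image extension '%s' (use ppm/png)", ext))
}

ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    # skip whitespace and '#' comments, return next ASCII token
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PPM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[ \t\r\n]", ch)) break
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- token()
  if (magic != "P6") stop(sprintf("unsupported PPM magic '%s' (want P6)", magic))
  w <- as.integer(token()); h <- as.integer(token())
  maxval <- as.integer(token())
  if (maxval > 255L) stop("16-bit PPM not supported")
  raw_px <- readBin(con, "raw", n = w * h * 3L)
  v <- as.integer(raw_px) / maxval
  # file order: rows top to bottom, channels interleaved per pixel
  arr <- aperm(array(v, dim = c(3, w, h)), c(3, 2, 1))
  arr
}

write_ppm <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  v <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  interleaved <- as.vector(aperm(array(v, dim = dim(image)), c(3, 2, 1)))
  writeBin(as.raw(interleaved), con)
  invisible(path)
}

# Bilinear resize of an H x W x 3 array to out_h x out_w.
resize_bilinear <- function(image, out_h, out_w) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h == out_h && w == out_w) return(image)
  # sample positions at pixel centres (align centres of source/target grids)
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, 3))
  for (ch in 1:3) {
    m <- image[, , ch]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
    cc <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
    wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
    wym <- matrix(wy, out_h, out_w)
    out[, , ch] <- (a * (1 - wxm) + b * wxm) * (1 - wym) +
                   (cc * (1 - wxm) + d * wxm) * wym
  }
  out
}
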