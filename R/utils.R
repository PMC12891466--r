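#' Read a raster image into an H x W x 3 array
#'
#' PNG and TIFF are read natively; JPEG is supported when the EBImage package
#' is installed. Grayscale images are expanded to three identical channels,
#' alpha channels are dropped.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return Numeric array of dimension height x width x 3, values in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package")
    }
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an H x W x 3 array as a PNG file
#' @param img Numeric array (values clipped to \[0, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

# --- homography helpers -----------------------------------------------------
# Points are (x, y) with x = 0-based column, y = 0-based row; homogeneous
# 3x3 matrices act on column vectors (x, y, 1)'.

#' Apply a 3x3 homography to 2D points
#' @param h 3x3 matrix.
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(h, pts) {
  pts <- matrix(pts, ncol = 2)
  p <- h %*% rbind(t(pts), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

# Direct linear transform from exactly 4 point correspondences.
fit_homography4 <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(a, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Warp an image (or stack of planes) by homography `h` mapping input -> output
# coordinates. Output size defaults to input size.
warp_image <- function(img, h, out_h = NULL, out_w = NULL,
                       mode = c("bilinear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  single <- length(dim(img)) == 2L
  if (single) img <- array(img, c(dim(img), 1L))
  if (is.null(out_h)) out_h <- dim(img)[1]
  if (is.null(out_w)) out_w <- dim(img)[2]
  hin <- solve(h) # kernel expects output -> input
  out <- warp_perspective(img, hin, out_h, out_w,
                          if (mode == "bilinear") 1L else 0L, fill)
  if (single) out <- out[, , 1]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# vectorized per-pixel argmax / max over the planes of an H x W x C array;
# returns list(which = 1-based plane index matrix, max = value matrix)
argmax_planes <- function(arr) {
  wmax <- matrix(1L, dim(arr)[1], dim(arr)[2])
  vmax <- arr[, , 1]
  for (c in seq_len(dim(arr)[3])[-1]) {
    plane <- arr[, , c]
    sel <- plane > vmax
    vmax[sel] <- plane[sel]
    wmax[sel] <- c
  }
  list(which = wmax, max = vmax)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
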