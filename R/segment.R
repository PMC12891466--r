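#' Run a segmentation network over an image of any size
#'
#' Images no larger than the tile budget are processed in one forward pass.
#' Larger images are processed as overlapping tiles whose softmax
#' probabilities are blended with a separable cosine-ramp weight window, so
#' tile seams do not introduce discontinuities.
#'
#' @param model A `unet_model`.
#' @param image H x W x C array (or H x W matrix for single-channel models),
#'   or a path readable by [read_image()].
#' @param tile_px Tile size for large images (default 1024).
#' @param overlap_px Overlap between neighbouring tiles (default 128).
#' @return H x W x out_channels array of per-pixel class probabilities
#'   (summing to 1 at every pixel), with a `classes` attribute.
#' @export
segment <- function(model, image, tile_px = 1024, overlap_px = 128) {
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  h <- dim(image)[1]; w <- dim(image)[2]
  C <- model$config$out_channels
  if (h <= tile_px && w <= tile_px) {
    probs <- softmax_hwc(unet_forward(model, image)$logits)
  } else {
    step <- tile_px - overlap_px
    starts <- function(total) {
      if (total <= tile_px) return(0L)
      s <- seq(0L, total - tile_px, by = step)
      if (tail(s, 1) != total - tile_px) s <- c(s, total - tile_px)
      s
    }
    ramp <- function(n, ov) {
      wgt <- rep(1, n)
      k <- min(ov, n %/% 2)
      if (k > 0) {
        r <- (1 - cos(pi * (seq_len(k) - 0.5) / k)) / 2
        wgt[seq_len(k)] <- r
        wgt[n + 1 - seq_len(k)] <- r
      }
      wgt
    }
    acc <- array(0, c(h, w, C))
    wacc <- matrix(0, h, w)
    for (ry in starts(h)) {
      for (rx in starts(w)) {
        th <- min(tile_px, h - ry); tw <- min(tile_px, w - rx)
        tile <- image[ry + seq_len(th), rx + seq_len(tw), , drop = FALSE]
        pt <- softmax_hwc(unet_forward(model, tile)$logits)
        wg <- outer(ramp(th, overlap_px), ramp(tw, overlap_px))
        for (c in seq_len(C)) {
          acc[ry + seq_len(th), rx + seq_len(tw), c] <-
            acc[ry + seq_len(th), rx + seq_len(tw), c] + pt[, , c] * wg
        }
        wacc[ry + seq_len(th), rx + seq_len(tw)] <-
          wacc[ry + seq_len(th), rx + seq_len(tw)] + wg
      }
    }
    probs <- acc / array(wacc, c(h, w, C))
  }
  attr(probs, "classes") <- if (C == 4) SEG_CLASSES else c("background", LEAD_NAMES)[seq_len(C)]
  probs
}
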