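#' Soft Dice + focal segmentation loss
#'
#' The loss is the sum of a soft Dice term, `1 - mean over classes of
#' (2 sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)` computed on softmax
#' probabilities, and a focal term, the mean over pixels of
#' `-(1 - p_true)^gamma * log(p_true)`. With `gamma = 0` the focal term is
#' plain cross-entropy.
#'
#' @param logits Array (H x W x C) of unnormalized class scores.
#' @param target Integer matrix (H x W) of class labels in `1..C`.
#' @param focal_gamma Focusing exponent (default 2).
#' @param class_weights Optional length-C nonnegative weights applied to both
#'   terms' class contributions.
#' @param eps Dice smoothing constant.
#' @param want_grad Also return the gradient with respect to the logits.
#' @return List with `loss`, `dice_term`, `focal_term` and optionally `grad`.
#' @export
dice_focal_loss <- function(logits, target, focal_gamma = 2,
                            class_weights = NULL, eps = 1e-5,
                            want_grad = FALSE) {
  d <- dim(logits)
  if (length(target) == 0) stop("empty target")
  if (!all(dim(target) == d[1:2])) stop("target/logits shape mismatch")
  C <- d[3]
  n <- d[1] * d[2]
  if (is.null(class_weights)) class_weights <- rep(1, C)
  cw <- class_weights / sum(class_weights) * C
  p <- matrix(softmax_hwc(logits), n, C)
  tvec <- as.integer(target)
  if (any(tvec < 1 | tvec > C)) stop("target labels out of range")
  th <- matrix(0, n, C)
  th[cbind(seq_len(n), tvec)] <- 1

  # soft Dice
  inter <- colSums(p * th)
  denom <- colSums(p) + colSums(th)
  dice_c <- (2 * inter + eps) / (denom + eps)
  dice_term <- 1 - sum(cw * dice_c) / C

  # focal
  pt <- p[cbind(seq_len(n), tvec)]
  pt <- pmax(pt, 1e-12)
  wpix <- cw[tvec]
  focal_pix <- (1 - pt)^focal_gamma * (-log(pt))
  focal_term <- mean(wpix * focal_pix)

  out <- list(loss = dice_term + focal_term, dice_term = dice_term,
              focal_term = focal_term)
  if (want_grad) {
    dp <- matrix(0, n, C)
    # dice: d dice_c / d p_c(i) = (2 th - dice_c) / (denom + eps)
    for (c in seq_len(C)) {
      dp[, c] <- dp[, c] - cw[c] / C * (2 * th[, c] - dice_c[c]) / (denom[c] + eps)
    }
    # focal depends on p_true only
    g <- focal_gamma
    dfoc <- wpix * (g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) * (if (g > 0) 1 else 0) -
                      (1 - pt)^g / pt) / n
    dp[cbind(seq_len(n), tvec)] <- dp[cbind(seq_len(n), tvec)] + dfoc
    # chain through softmax
    dot <- rowSums(dp * p)
    dlog <- p * (dp - dot)
    out$grad <- array(dlog, d)
  }
  out
}
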