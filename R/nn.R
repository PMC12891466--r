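# Low-level neural-network primitives. Feature maps are numeric arrays of
# dimension (H, W, C); convolution weights are arrays of dimension
# (k, k, Cin, Cout) reshaped to (k*k*Cin, Cout) matrices for the GEMM kernel.

conv_fwd <- function(x, w, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  wm <- matrix(w, prod(dim(w)[1:3]), dim(w)[4])
  conv2d_fwd(x, wm, k, stride, pad)
}

conv_bwd <- function(x, w, dy, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  wm <- matrix(w, prod(dim(w)[1:3]), dim(w)[4])
  r <- conv2d_bwd(x, wm, dy, k, stride, pad)
  r$dw <- array(r$dw, dim(w))
  r
}

inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  inv_std <- 1 / sqrt(v + eps)
  xn <- (xm - rep(mu, each = n)) * rep(inv_std, each = n)
  y <- xn * rep(g, each = n) + rep(b, each = n)
  list(y = array(y, d), cache = list(xn = xn, inv_std = inv_std, g = g, d = d))
}

inorm_bwd <- function(dy, cache) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  xn <- cache$xn
  dg <- colSums(dym * xn)
  db <- colSums(dym)
  dxn <- dym * rep(cache$g, each = n)
  sum_dxn <- colSums(dxn)
  sum_dxn_xn <- colSums(dxn * xn)
  dx <- (dxn - rep(sum_dxn / n, each = n) -
           xn * rep(sum_dxn_xn / n, each = n)) * rep(cache$inv_std, each = n)
  list(dx = array(dx, d), dg = dg, db = db)
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}

lrelu_bwd <- function(dy, neg, slope) {
  dy[neg] <- dy[neg] * slope
  dy
}

softmax_hwc <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  xm <- xm - apply(xm, 1, max)
  e <- exp(xm)
  array(e / rowSums(e), d)
}
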