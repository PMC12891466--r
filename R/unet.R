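#' U-Net configuration
#'
#' @param encoder_widths Ordered channel counts, one per resolution level.
#'   The defaults of the two bundled networks are
#'   `c(32, 64, 128, 256, 320, 320, 320, 320)` (main, 4-class) and
#'   `c(32, 64, 128, 256, 256)` (lead-text, 13-class).
#' @param in_channels Input channels.
#' @param out_channels Output classes (>= 2).
#' @param negative_slope LeakyReLU negative slope.
#' @return A `unet_config` list.
#' @export
unet_config <- function(encoder_widths = c(32, 64, 128, 256, 320, 320, 320, 320),
                        in_channels = 3, out_channels = 4,
                        negative_slope = 0.01) {
  if (length(encoder_widths) < 1 || any(encoder_widths <= 0)) {
    stop("encoder_widths must be non-empty and positive")
  }
  if (out_channels < 2) stop("out_channels must be >= 2")
  structure(list(encoder_widths = as.integer(encoder_widths),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 negative_slope = negative_slope),
            class = "unet_config")
}

# He-initialized convolution weight of dim (k, k, cin, cout)
init_conv <- function(k, cin, cout, rng_sd_scale = 1) {
  sd <- sqrt(2 / (k * k * cin)) * rng_sd_scale
  array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout))
}

#' Build the main 4-class residual segmentation U-Net
#'
#' The architecture has one encoder block per width: two bias-free
#' conv3x3-InstanceNorm-LeakyReLU stages wrapped in a residual shortcut (a
#' bias-free 3x3 projection convolution when the channel count changes,
#' identity otherwise), followed by a width-preserving 2x2 stride-2
#' convolution with InstanceNorm-LeakyReLU for downsampling. A single
#' residual bottleneck block sits below the deepest level. Each decoder block
#' upsamples bilinearly by 2, concatenates the skip connection, and applies
#' one conv3x3-InstanceNorm-LeakyReLU stage; a final 3x3 convolution (the
#' only layer with a bias) projects to the output classes. At the default
#' configuration this network has 22,611,780 trainable parameters (22.6 M).
#'
#' @param config A [unet_config()]; defaults to the full-size main network.
#' @param seed Integer seed for weight initialization.
#' @return A `unet_model` (list of `config` and named parameter arrays).
#' @export
build_main_unet <- function(config = unet_config(), seed = 1) {
  build_unet(config, seed)
}

#' Build the lightweight 13-class lead-text U-Net
#'
#' Same architectural principles as [build_main_unet()] but five levels with
#' widths (32, 64, 128, 256, 256), a single input channel (the text-class
#' probability map) and 13 output classes (12 leads + background).
#'
#' @param config A [unet_config()]; defaults to the text-network recipe.
#' @param seed Integer seed for weight initialization.
#' @return A `unet_model`.
#' @export
build_text_unet <- function(config = unet_config(c(32, 64, 128, 256, 256),
                                                 in_channels = 1,
                                                 out_channels = 13),
                            seed = 1) {
  build_unet(config, seed)
}

build_unet <- function(config, seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  w <- config$encoder_widths
  depth <- length(w)
  p <- list()
  cin <- config$in_channels
  for (i in seq_len(depth)) {
    nm <- function(s) paste0("enc", i, "_", s)
    p[[nm("conv1")]] <- init_conv(3, cin, w[i])
    p[[nm("in1_g")]] <- rep(1, w[i]); p[[nm("in1_b")]] <- rep(0, w[i])
    p[[nm("conv2")]] <- init_conv(3, w[i], w[i])
    p[[nm("in2_g")]] <- rep(1, w[i]); p[[nm("in2_b")]] <- rep(0, w[i])
    if (cin != w[i]) p[[nm("proj")]] <- init_conv(3, cin, w[i])
    p[[nm("down")]] <- init_conv(2, w[i], w[i])
    p[[nm("ind_g")]] <- rep(1, w[i]); p[[nm("ind_b")]] <- rep(0, w[i])
    cin <- w[i]
  }
  p[["bot_conv1"]] <- init_conv(3, w[depth], w[depth])
  p[["bot_in1_g"]] <- rep(1, w[depth]); p[["bot_in1_b"]] <- rep(0, w[depth])
  p[["bot_conv2"]] <- init_conv(3, w[depth], w[depth])
  p[["bot_in2_g"]] <- rep(1, w[depth]); p[["bot_in2_b"]] <- rep(0, w[depth])
  cup <- w[depth]
  for (i in rev(seq_len(depth))) {
    nm <- function(s) paste0("dec", i, "_", s)
    p[[nm("conv")]] <- init_conv(3, cup + w[i], w[i])
    p[[nm("in_g")]] <- rep(1, w[i]); p[[nm("in_b")]] <- rep(0, w[i])
    cup <- w[i]
  }
  p[["head_w"]] <- init_conv(3, w[1], config$out_channels)
  p[["head_b"]] <- rep(0, config$out_channels)
  structure(list(config = config, params = p), class = "unet_model")
}

#' Count trainable parameters of a model
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> widths (%s), %d -> %d channels, %s parameters\n",
              paste(x$config$encoder_widths, collapse = ", "),
              x$config$in_channels, x$config$out_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# residual block: two conv-IN-lrelu stages plus shortcut
resblock_fwd <- function(x, p, pre, slope) {
  g <- function(s) p[[paste0(pre, s)]]
  h1 <- conv_fwd(x, g("conv1"))
  n1 <- inorm_fwd(h1, g("in1_g"), g("in1_b"))
  a1 <- lrelu_fwd(n1$y, slope)
  h2 <- conv_fwd(a1$y, g("conv2"))
  n2 <- inorm_fwd(h2, g("in2_g"), g("in2_b"))
  s <- if (!is.null(g("proj"))) conv_fwd(x, g("proj")) else x
  a2 <- lrelu_fwd(n2$y + s, slope)
  list(y = a2$y,
       cache = list(x = x, a1y = a1$y, n1 = n1$cache, n2 = n2$cache,
                    neg1 = a1$neg, neg2 = a2$neg, has_proj = !is.null(g("proj"))))
}

resblock_bwd <- function(dy, p, pre, cache, grads, slope) {
  g <- function(s) p[[paste0(pre, s)]]
  dsum <- lrelu_bwd(dy, cache$neg2, slope)
  # shortcut branch
  if (cache$has_proj) {
    r <- conv_bwd(cache$x, g("proj"), dsum)
    grads[[paste0(pre, "proj")]] <- grads[[paste0(pre, "proj")]] + r$dw
    dx_short <- r$dx
  } else {
    dx_short <- dsum
  }
  nb2 <- inorm_bwd(dsum, cache$n2)
  grads[[paste0(pre, "in2_g")]] <- grads[[paste0(pre, "in2_g")]] + nb2$dg
  grads[[paste0(pre, "in2_b")]] <- grads[[paste0(pre, "in2_b")]] + nb2$db
  r2 <- conv_bwd(cache$a1y, g("conv2"), nb2$dx)
  grads[[paste0(pre, "conv2")]] <- grads[[paste0(pre, "conv2")]] + r2$dw
  da1 <- lrelu_bwd(r2$dx, cache$neg1, slope)
  nb1 <- inorm_bwd(da1, cache$n1)
  grads[[paste0(pre, "in1_g")]] <- grads[[paste0(pre, "in1_g")]] + nb1$dg
  grads[[paste0(pre, "in1_b")]] <- grads[[paste0(pre, "in1_b")]] + nb1$db
  r1 <- conv_bwd(cache$x, g("conv1"), nb1$dx)
  grads[[paste0(pre, "conv1")]] <- grads[[paste0(pre, "conv1")]] + r1$dw
  list(dx = r1$dx + dx_short, grads = grads)
}

#' Forward pass of a U-Net
#'
#' Inputs of any spatial size are zero-padded on the bottom/right to a
#' multiple of `2^depth` and the logits are cropped back.
#'
#' @param model A `unet_model`.
#' @param x Input array (H x W x in_channels) or matrix (single channel).
#' @param want_cache Keep intermediate activations for [unet_backward()].
#' @return List with `logits` (H x W x out_channels) and (optionally) `cache`.
#' @export
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  slope <- cfg$negative_slope
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != cfg$in_channels) stop("input channel mismatch")
  h0 <- dim(x)[1]; w0 <- dim(x)[2]
  depth <- length(cfg$encoder_widths)
  mult <- 2^depth
  hp <- ceiling(h0 / mult) * mult
  wp <- ceiling(w0 / mult) * mult
  if (hp != h0 || wp != w0) {
    xp <- array(0, c(hp, wp, dim(x)[3]))
    xp[seq_len(h0), seq_len(w0), ] <- x
    x <- xp
  }
  caches <- list(h0 = h0, w0 = w0, hp = hp, wp = wp, enc = vector("list", depth),
                 down = vector("list", depth), dec = vector("list", depth))
  cur <- x
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    rb <- resblock_fwd(cur, p, paste0("enc", i, "_"), slope)
    skips[[i]] <- rb$y
    caches$enc[[i]] <- rb$cache
    d <- conv_fwd(rb$y, p[[paste0("enc", i, "_down")]], stride = 2L, pad = 0L)
    nd <- inorm_fwd(d, p[[paste0("enc", i, "_ind_g")]], p[[paste0("enc", i, "_ind_b")]])
    ad <- lrelu_fwd(nd$y, slope)
    caches$down[[i]] <- list(x = rb$y, n = nd$cache, neg = ad$neg)
    cur <- ad$y
  }
  bot <- resblock_fwd(cur, p, "bot_", slope)
  caches$bot <- bot$cache
  cur <- bot$y
  for (i in rev(seq_len(depth))) {
    u <- upsample2_fwd(cur)
    cat3 <- array(c(u, skips[[i]]), c(dim(u)[1], dim(u)[2],
                                      dim(u)[3] + dim(skips[[i]])[3]))
    h <- conv_fwd(cat3, p[[paste0("dec", i, "_conv")]])
    n <- inorm_fwd(h, p[[paste0("dec", i, "_in_g")]], p[[paste0("dec", i, "_in_b")]])
    a <- lrelu_fwd(n$y, slope)
    caches$dec[[i]] <- list(cat = cat3, n = n$cache, neg = a$neg,
                            c_up = dim(u)[3], in_h = dim(cur)[1], in_w = dim(cur)[2])
    cur <- a$y
  }
  logits <- conv_fwd(cur, p$head_w)
  logits <- logits + rep(p$head_b, each = dim(logits)[1] * dim(logits)[2])
  caches$head_x <- if (want_cache) cur else NULL
  logits <- logits[seq_len(h0), seq_len(w0), , drop = FALSE]
  if (want_cache) list(logits = logits, cache = caches) else list(logits = logits)
}

#' Backward pass of a U-Net
#'
#' @param model A `unet_model`.
#' @param cache Cache from `unet_forward(..., want_cache = TRUE)`.
#' @param dlogits Gradient of the loss with respect to the logits.
#' @return Named list of parameter gradients.
#' @export
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  slope <- cfg$negative_slope
  depth <- length(cfg$encoder_widths)
  grads <- lapply(p, function(z) array(0, dim(z) %||% length(z)))
  if (cache$hp != cache$h0 || cache$wp != cache$w0) {
    dl <- array(0, c(cache$hp, cache$wp, dim(dlogits)[3]))
    dl[seq_len(cache$h0), seq_len(cache$w0), ] <- dlogits
    dlogits <- dl
  }
  n_px <- dim(dlogits)[1] * dim(dlogits)[2]
  grads$head_b <- grads$head_b + colSums(matrix(dlogits, n_px, dim(dlogits)[3]))
  r <- conv_bwd(cache$head_x, p$head_w, dlogits)
  grads$head_w <- grads$head_w + r$dw
  dcur <- r$dx
  dskips <- vector("list", depth)
  for (i in seq_len(depth)) {
    dc <- cache$dec[[i]]
    da <- lrelu_bwd(dcur, dc$neg, slope)
    nb <- inorm_bwd(da, dc$n)
    grads[[paste0("dec", i, "_in_g")]] <- grads[[paste0("dec", i, "_in_g")]] + nb$dg
    grads[[paste0("dec", i, "_in_b")]] <- grads[[paste0("dec", i, "_in_b")]] + nb$db
    rc <- conv_bwd(dc$cat, p[[paste0("dec", i, "_conv")]], nb$dx)
    grads[[paste0("dec", i, "_conv")]] <- grads[[paste0("dec", i, "_conv")]] + rc$dw
    cu <- dc$c_up
    du <- rc$dx[, , seq_len(cu), drop = FALSE]
    dskips[[i]] <- rc$dx[, , cu + seq_len(dim(rc$dx)[3] - cu), drop = FALSE]
    dcur <- upsample2_bwd(du, dc$in_h, dc$in_w)
  }
  rb <- resblock_bwd(dcur, p, "bot_", cache$bot, grads, slope)
  grads <- rb$grads
  dcur <- rb$dx
  for (i in rev(seq_len(depth))) {
    dn <- cache$down[[i]]
    da <- lrelu_bwd(dcur, dn$neg, slope)
    nb <- inorm_bwd(da, dn$n)
    grads[[paste0("enc", i, "_ind_g")]] <- grads[[paste0("enc", i, "_ind_g")]] + nb$dg
    grads[[paste0("enc", i, "_ind_b")]] <- grads[[paste0("enc", i, "_ind_b")]] + nb$db
    rd <- conv_bwd(dn$x, p[[paste0("enc", i, "_down")]], nb$dx, stride = 2L, pad = 0L)
    grads[[paste0("enc", i, "_down")]] <- grads[[paste0("enc", i, "_down")]] + rd$dw
    dy <- rd$dx + dskips[[i]]
    rb <- resblock_bwd(dy, p, paste0("enc", i, "_"), cache$enc[[i]], grads, slope)
    grads <- rb$grads
    dcur <- rb$dx
  }
  grads
}
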