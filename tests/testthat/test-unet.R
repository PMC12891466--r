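test_that("the default main network hits its reference parameter budget", {
  m <- build_main_unet()
  expect_equal(n_parameters(m), 22611780)
  expect_equal(round(n_parameters(m) / 1e6, 1), 22.6)
})

test_that("the text network is smaller and has 13 output planes", {
  tx <- build_text_unet()
  m <- build_main_unet()
  expect_lt(n_parameters(tx), n_parameters(m))
  expect_equal(tx$config$out_channels, 13)
  expect_equal(tx$config$in_channels, 1)
  out <- unet_forward(tx, matrix(runif(32 * 32), 32, 32))$logits
  expect_equal(dim(out), c(32, 32, 13))
})

test_that("forward passes preserve spatial size, padding odd sizes", {
  model <- build_main_unet(tiny_unet_config(), seed = 2)
  for (sz in list(c(16, 16), c(24, 40), c(19, 33))) {
    x <- array(runif(prod(sz) * 3), c(sz, 3))
    out <- unet_forward(model, x)$logits
    expect_equal(dim(out), c(sz, 4))
  }
  expect_error(unet_forward(model, array(0, c(16, 16, 2))), "channel")
  expect_error(unet_config(numeric(0)), "encoder_widths")
  expect_error(unet_config(c(8, 16), out_channels = 1), "out_channels")
})

test_that("backward gradients match finite differences", {
  model <- build_main_unet(unet_config(c(4, 6), in_channels = 2,
                                       out_channels = 3), seed = 3)
  set.seed(4)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  target <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
  loss_of <- function(m) {
    dice_focal_loss(unet_forward(m, x)$logits, target)$loss
  }
  fwd <- unet_forward(model, x, want_cache = TRUE)
  l <- dice_focal_loss(fwd$logits, target, want_grad = TRUE)
  grads <- unet_backward(model, fwd$cache, l$grad)
  eps <- 1e-5
  for (nm in c("enc1_conv1", "enc2_in1_g", "dec1_conv", "head_w", "head_b",
               "bot_conv2", "enc1_proj")) {
    g <- grads[[nm]]
    set.seed(nchar(nm))
    idx <- sample(length(g), min(3, length(g)))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip through disk", {
  model <- build_main_unet(tiny_unet_config(), seed = 6)
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$config$encoder_widths, model$config$encoder_widths)
  expect_equal(back$params, model$params)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(unet_forward(back, x)$logits, unet_forward(model, x)$logits)
})
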