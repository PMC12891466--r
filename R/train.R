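#' Training configuration
#'
#' Defaults follow the full-scale training protocol: batch 12,
#' 1024 px patches, Muon (momentum 0.95) for convolutions with AdamW (betas
#' 0.9/0.999, weight decay 0.001) for the normalization affines, cosine decay
#' from 0.0037 to 0.00037 over 20,000 batches then constant. Desk-scale
#' training uses far smaller values for all of these.
#'
#' @param batch_size Samples per optimization step.
#' @param patch_px Square crop size the stream is expected to yield.
#' @param lr_init,lr_final Initial and final learning rates
#'   (`lr_final <= lr_init`).
#' @param schedule_batches Batches until the schedule reaches `lr_final`.
#' @param weight_decay Decoupled weight decay.
#' @param muon_momentum Muon momentum coefficient.
#' @param adamw_betas AdamW beta pair.
#' @param epochs Nominal epoch count (informational; training length is
#'   set by `n_steps` in [train_unet()]).
#' @param focal_gamma Focal-loss exponent.
#' @param optimizer `"muon_adamw"` (default) or the pure-`"adamw"` fallback.
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 12, patch_px = 1024, lr_init = 0.0037,
                         lr_final = 0.00037, schedule_batches = 20000,
                         weight_decay = 0.001, muon_momentum = 0.95,
                         adamw_betas = c(0.9, 0.999), epochs = 45,
                         focal_gamma = 2, optimizer = "muon_adamw", seed = 1) {
  if (lr_final > lr_init) stop("lr_final must be <= lr_init")
  if (any(c(batch_size, patch_px, lr_init, lr_final, schedule_batches,
            muon_momentum) <= 0)) {
    stop("training hyperparameters must be positive")
  }
  structure(list(batch_size = batch_size, patch_px = patch_px,
                 lr_init = lr_init, lr_final = lr_final,
                 schedule_batches = schedule_batches,
                 weight_decay = weight_decay, muon_momentum = muon_momentum,
                 adamw_betas = adamw_betas, epochs = epochs,
                 focal_gamma = focal_gamma, optimizer = optimizer,
                 seed = seed),
            class = "train_config")
}

#' Train a U-Net on a stream of image/mask crops
#'
#' @param model A `unet_model`.
#' @param sample_stream Function of the 1-based step index returning a list
#'   of `batch_size` samples, each a list with `image` (H x W x C array) and
#'   `class_mask` (H x W integer matrix with labels `0..C-1` as produced by
#'   the renderer, or `1..C`).
#' @param config A [train_config()].
#' @param n_steps Number of optimization steps.
#' @param verbose Print the smoothed loss every 25 steps.
#' @return The trained model, with a `loss_log` element (one entry per step).
#' @export
train_unet <- function(model, sample_stream, config = train_config(),
                       n_steps = 100, verbose = FALSE) {
  state <- make_optimizer_state(model$params)
  loss_log <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    batch <- sample_stream(step)
    grads <- NULL
    loss_acc <- 0
    for (s in batch) {
      target <- s$class_mask
      if (min(target) == 0L) target <- target + 1L
      fwd <- unet_forward(model, s$image, want_cache = TRUE)
      l <- dice_focal_loss(fwd$logits, target, focal_gamma = config$focal_gamma,
                           want_grad = TRUE)
      if (!is.finite(l$loss)) {
        stop(sprintf("training diverged at step %d (loss = %g)", step, l$loss))
      }
      g <- unet_backward(model, fwd$cache, l$grad / length(batch))
      grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
      loss_acc <- loss_acc + l$loss / length(batch)
    }
    lr <- lr_schedule(step - 1L, config$lr_init, config$lr_final,
                      config$schedule_batches)
    res <- optimizer_step(model$params, grads, state, lr, config)
    model$params <- res$params
    state <- res$state
    loss_log[step] <- loss_acc
    if (verbose && step %% 25 == 0) {
      message(sprintf("step %4d  lr %.5f  loss %.4f", step, lr,
                      mean(tail(loss_log[seq_len(step)], 25))))
    }
  }
  model$loss_log <- c(model$loss_log, loss_log)
  model
}

#' Save / load model checkpoints
#'
#' Checkpoints are written as a pair of plain files: a JSON header with the
#' configuration and parameter shapes, and a little-endian float64 binary
#' blob with the parameter values in header order.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (the JSON header; the blob gets `.bin`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  shapes <- lapply(model$params, function(p) dim(p) %||% length(p))
  hdr <- list(config = unclass(model$config), shapes = shapes)
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (p in model$params) writeBin(as.numeric(p), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(unet_config, hdr$config[c("encoder_widths", "in_channels",
                                           "out_channels", "negative_slope")])
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  params <- list()
  for (nm in names(hdr$shapes)) {
    shp <- unlist(hdr$shapes[[nm]])
    vals <- readBin(con, "numeric", n = prod(shp), size = 8, endian = "little")
    params[[nm]] <- if (length(shp) > 1) array(vals, shp) else vals
  }
  structure(list(config = cfg, params = params), class = "unet_model")
}
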