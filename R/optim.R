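# Optimizers: Muon (orthogonalized momentum via Newton-Schulz iteration) for
# convolution kernels, AdamW for the instance-norm affine parameters and the
# head bias.

# Quintic Newton-Schulz iteration approximately orthogonalizing a matrix
# (coefficients from the standard Muon recipe).
newton_schulz5 <- function(m, steps = 5, eps = 1e-7) {
  a <- 3.4445; b <- -4.775; c <- 2.0315
  transposed <- nrow(m) > ncol(m)
  x <- if (transposed) t(m) else m
  x <- x / (sqrt(sum(x^2)) + eps)
  for (i in seq_len(steps)) {
    aa <- x %*% t(x)
    bb <- b * aa + c * (aa %*% aa)
    x <- a * x + bb %*% x
  }
  if (transposed) t(x) else x
}

# LR schedule: cosine decay from lr_init to lr_final over schedule_batches,
# constant afterwards. step is 0-based.
lr_schedule <- function(step, lr_init = 0.0037, lr_final = 0.00037,
                        schedule_batches = 20000) {
  if (step >= schedule_batches) return(lr_final)
  lr_final + (lr_init - lr_final) * (1 + cos(pi * step / schedule_batches)) / 2
}

make_optimizer_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

# conv kernels (4-D arrays) get Muon; everything else AdamW
is_muon_param <- function(p) length(dim(p)) == 4L

optimizer_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adamw_betas[1]; b2 <- cfg$adamw_betas[2]
  wd <- cfg$weight_decay
  use_muon <- !identical(cfg$optimizer, "adamw")
  for (nm in names(params)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    if (use_muon && is_muon_param(p)) {
      dm <- dim(p)
      gm <- matrix(g, prod(dm[1:3]), dm[4])
      mm <- matrix(state$m[[nm]], prod(dm[1:3]), dm[4])
      mm <- cfg$muon_momentum * mm + gm
      state$m[[nm]] <- array(mm, dm)
      upd <- newton_schulz5(mm)
      scale <- sqrt(max(1, dm[4] / prod(dm[1:3]))) # rows = fan-out
      params[[nm]] <- p * (1 - lr * wd) - lr * scale * array(upd, dm)
    } else {
      m <- b1 * state$m[[nm]] + (1 - b1) * g
      v <- b2 * state$v[[nm]] + (1 - b2) * g^2
      state$m[[nm]] <- m
      state$v[[nm]] <- v
      mhat <- m / (1 - b1^state$t)
      vhat <- v / (1 - b2^state$t)
      params[[nm]] <- p * (1 - lr * wd) - lr * mhat / (sqrt(vhat) + 1e-8)
    }
  }
  list(params = params, state = state)
}
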