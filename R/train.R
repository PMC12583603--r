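#' Training hyperparameters
#'
#' Upstream-style defaults: SGD with Nesterov momentum 0.99, initial
#' learning rate 0.01 with polynomial decay `lr0 * (1 - epoch/total)^0.9`
#' computed from the global epoch count, equally weighted Dice +
#' cross-entropy loss, 10 iterations per epoch and a 1/3 forced-foreground
#' patch-sampling rate. All overridable.
#'
#' @param lr0 initial learning rate.
#' @param momentum SGD momentum.
#' @param nesterov use Nesterov momentum.
#' @param total_epochs horizon of the polynomial decay.
#' @param iterations_per_epoch optimizer steps per epoch.
#' @param batch_size patches per step; `NULL` uses the plan's batch size.
#' @param oversample_fg probability a patch is centered on a foreground voxel.
#' @return list of hyperparameters.
#' @export
train_hyperparams <- function(lr0 = 0.01, momentum = 0.99, nesterov = TRUE,
                              total_epochs = 100L, iterations_per_epoch = 10L,
                              batch_size = NULL, oversample_fg = 1 / 3) {
  list(lr0 = lr0, momentum = momentum, nesterov = nesterov,
       total_epochs = as.integer(total_epochs),
       iterations_per_epoch = as.integer(iterations_per_epoch),
       batch_size = batch_size, oversample_fg = oversample_fg)
}

poly_lr <- function(hp, epoch) {
  hp$lr0 * (1 - min(epoch, hp$total_epochs - 1L) / hp$total_epochs)^0.9
}

resample_plane <- function(x, new_shape, nearest = FALSE) {
  .resample2d(x, as.integer(new_shape[1]), as.integer(new_shape[2]), nearest)
}

#' Preprocess a case to a plan's target spacing
#'
#' Resamples the image (bilinear) and mask (nearest) to the plan's target
#' spacing and z-scores the image intensities (per-image mean/sd). The
#' returned case records its native geometry so predictions can be mapped
#' back.
#'
#' @param case a case list (`image`, `mask`, `spacing`).
#' @param plan a 2D `fedseg_plan`.
#' @return a preprocessed case with `image`, `mask`, `spacing`
#'   (= target spacing), `native_shape`, `native_spacing`.
#' @export
preprocess_case <- function(case, plan) {
  if (length(dim(case$image)) != 2L) stopf("only 2D cases can be preprocessed")
  new_shape <- pmax(as.integer(round(dim(case$image) * case$spacing / plan$target_spacing)), 4L)
  img <- resample_plane(case$image, new_shape, nearest = FALSE)
  msk <- NULL
  if (!is.null(case$mask)) {
    msk <- array(as.integer(resample_plane(case$mask * 1.0, new_shape, nearest = TRUE)),
                 new_shape)
  }
  s <- stats::sd(img)
  img <- (img - mean(img)) / (if (s > 0) s else 1)
  list(image = img, mask = msk, spacing = plan$target_spacing,
       native_shape = dim(case$image), native_spacing = case$spacing,
       name = case$name %||% NA_character_)
}

# pad a 2D plane (constant value) so it is at least `shape`
pad_to <- function(x, shape, value = 0) {
  d <- dim(x)
  if (all(d >= shape)) return(x)
  out <- array(value, pmax(d, shape))
  out[seq_len(d[1]), seq_len(d[2])] <- x
  out
}

# sample one (patch, labels) pair from a preprocessed case
sample_patch <- function(case, patch, force_fg = FALSE) {
  img <- pad_to(case$image, patch)
  msk <- pad_to(case$mask, patch, 0L)
  d <- dim(img)
  if (force_fg && any(msk > 0)) {
    idx <- which(msk > 0)
    ctr <- arrayInd(idx[sample.int(length(idx), 1)], d)
    tl <- pmin(pmax(as.integer(ctr - patch %/% 2L), 1L), d - patch + 1L)
  } else {
    tl <- c(sample.int(d[1] - patch[1] + 1L, 1), sample.int(d[2] - patch[2] + 1L, 1))
  }
  ri <- tl[1]:(tl[1] + patch[1] - 1L)
  rj <- tl[2]:(tl[2] + patch[2] - 1L)
  list(x = img[ri, rj], y = msk[ri, rj])
}

#' Fresh optimizer state (momentum buffers)
#'
#' An environment holding per-layer momentum buffers; kept local to each
#' client and never exchanged.
#' @return an empty environment.
#' @export
new_opt_state <- function() new.env(parent = emptyenv())

sgd_step <- function(state, grads, opt, lr, momentum, nesterov) {
  for (nm in names(state$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    buf <- opt[[nm]]
    if (is.null(buf)) buf <- 0
    buf <- momentum * buf + g
    d <- if (nesterov) g + momentum * buf else buf
    state$params[[nm]] <- state$params[[nm]] - lr * d
    opt[[nm]] <- buf
  }
  state
}

#' Train a model state for one epoch
#'
#' One epoch is `hp$iterations_per_epoch` SGD steps over randomly sampled
#' patches (seeded, so training is deterministic). The learning rate is
#' computed from the state's global epoch counter via polynomial decay.
#' Optimizer momentum buffers live in `opt_state` (an environment) and are
#' kept local to the caller — they are never part of the exchanged state.
#'
#' @param state a `fedseg_state`.
#' @param cases list of preprocessed cases (see [preprocess_case()]).
#' @param plan the `fedseg_plan` the state was built from.
#' @param hp hyperparameters from [train_hyperparams()].
#' @param opt_state optimizer state from [new_opt_state()]; created if `NULL`.
#' @param seed RNG seed for this epoch's patch sampling.
#' @return list with `state` (epoch counter advanced), `opt_state`, and
#'   `losses` (per-iteration total loss trace).
#' @export
train_one_epoch <- function(state, cases, plan, hp = train_hyperparams(),
                            opt_state = NULL, seed = 0L) {
  if (!length(cases)) stopf("empty client")
  arch <- build_architecture(plan, state$metadata$in_channels, state$metadata$n_classes)
  if (is.null(opt_state)) opt_state <- new_opt_state()
  patch <- plan$patch_size
  bs <- hp$batch_size %||% plan$batch_size
  epoch <- state$metadata$epoch
  lr <- poly_lr(hp, epoch)
  losses <- numeric(hp$iterations_per_epoch)
  with_seed(derive_seed(seed, "epoch", epoch), {
    for (it in seq_len(hp$iterations_per_epoch)) {
      xb <- array(0, c(patch, 1L, bs))
      yb <- array(0L, c(patch, bs))
      for (b in seq_len(bs)) {
        cs <- cases[[sample.int(length(cases), 1)]]
        pt <- sample_patch(cs, patch, force_fg = stats::runif(1) < hp$oversample_fg)
        xb[, , 1L, b] <- pt$x
        yb[, , b] <- pt$y
      }
      fw <- net_fw(state, arch, xb, keep_cache = lr != 0)
      ls <- seg_loss(fw$logits, yb, state$metadata$n_classes, grad = lr != 0)
      if (!is.finite(ls$loss)) stopf("diverged")
      losses[it] <- ls$loss
      if (lr != 0) {
        grads <- net_bw(state, arch, fw, ls$dlogits)
        state <- sgd_step(state, grads, opt_state, lr, hp$momentum, hp$nesterov)
      }
    }
  })
  state$metadata$epoch <- epoch + 1L
  list(state = state, opt_state = opt_state, losses = losses)
}

#' Segment a case with a trained state
#'
#' The image is preprocessed to the plan's target spacing, tiled with
#' half-patch overlap, per-tile softmax maps are averaged, and the argmax
#' labels are resampled (nearest) back to the native grid.
#'
#' @param state a `fedseg_state`.
#' @param case a raw case (`image`, `spacing`; `mask` optional/ignored).
#' @param plan the matching `fedseg_plan`.
#' @return integer label array of the case's native shape.
#' @export
predict_case <- function(state, case, plan) {
  arch <- build_architecture(plan, state$metadata$in_channels, state$metadata$n_classes)
  pp <- preprocess_case(list(image = case$image, mask = NULL, spacing = case$spacing),
                        plan)
  patch <- plan$patch_size
  img <- pad_to(pp$image, patch)
  d <- dim(img)
  K <- state$metadata$n_classes
  acc <- array(0, c(d, K))
  cnt <- array(0, d)
  step <- pmax(patch %/% 2L, 1L)
  starts1 <- unique(c(seq(1L, d[1] - patch[1] + 1L, by = step[1]), d[1] - patch[1] + 1L))
  starts2 <- unique(c(seq(1L, d[2] - patch[2] + 1L, by = step[2]), d[2] - patch[2] + 1L))
  for (i in starts1) for (j in starts2) {
    ri <- i:(i + patch[1] - 1L); rj <- j:(j + patch[2] - 1L)
    xb <- array(img[ri, rj], c(patch, 1L, 1L))
    P <- softmax4(net_fw(state, arch, xb)$logits)
    acc[ri, rj, ] <- acc[ri, rj, ] + P[, , , 1L]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  lab <- apply(sweep(acc, c(1, 2), cnt, `/`), c(1, 2), which.max) - 1L
  lab <- lab[seq_len(dim(pp$image)[1]), seq_len(dim(pp$image)[2]), drop = FALSE]
  array(as.integer(resample_plane(lab * 1.0, pp$native_shape, nearest = TRUE)),
        pp$native_shape)
}
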