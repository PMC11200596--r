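# Masked-autoencoder domain adaptation. The encoder (shared geometry with
# the classifier) sees only the visible patches; a lightweight transformer
# decoder fills masked positions with a learned mask token and regresses
# the missing pixels. Only the encoder survives pre-training: it is
# transplanted into the classifier with load_pretrained_encoder().

#' Random patch mask
#'
#' Chooses exactly `round(ratio * n_patches)` patches uniformly without
#' replacement. Deterministic given the seed.
#'
#' @param n_patches Number of patches in the token grid.
#' @param ratio Masking fraction in `[0, 1]` (default 0.75).
#' @param seed Integer seed.
#' @return List of class `mask_spec` with `mask` (logical vector, `TRUE` =
#'   masked) and `ratio`.
#' @export
random_mask <- function(n_patches, ratio = 0.75, seed = 0L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio > 1)
    stop("mask ratio must be a single value in [0, 1]", call. = FALSE)
  n_patches <- as.integer(n_patches)
  k <- as.integer(round(ratio * n_patches))
  mask <- rep(FALSE, n_patches)
  if (k > 0L) {
    set.seed(seed)
    mask[sample.int(n_patches, k)] <- TRUE
  }
  structure(list(mask = mask, ratio = ratio), class = "mask_spec")
}

#' Masked-patch reconstruction loss
#'
#' Mean squared error over the pixels of masked patches only; predictions
#' on visible patches do not contribute (their gradient is identically
#' zero).
#'
#' @param pred,target N x p^2 matrices of per-patch pixel values.
#' @param mask A `mask_spec` or logical vector of length N.
#' @return Nonnegative scalar; 0 when no patch is masked.
#' @export
mae_loss <- function(pred, target, mask) {
  if (inherits(mask, "mask_spec")) mask <- mask$mask
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ", call. = FALSE)
  if (length(mask) != nrow(pred))
    stop("mask length does not match the patch count", call. = FALSE)
  if (!any(mask)) return(0)
  mean((pred[mask, , drop = FALSE] - target[mask, , drop = FALSE])^2)
}

init_mae <- function(cfg, decoder_dim = 16L, decoder_depth = 1L,
                     seed = 0L) {
  set.seed(seed)
  D <- cfg$embed_dim; Dd <- as.integer(decoder_dim)
  N <- n_patches(cfg); P2 <- cfg$patch_size^2L
  w <- list(
    encoder = init_encoder(cfg),
    decoder = list(
      Wd = matrix(stats::rnorm(D * Dd, sd = 0.02), D, Dd),
      bd = rep(0, Dd),
      mask_tok = matrix(stats::rnorm(Dd, sd = 0.02), 1, Dd),
      dpos = matrix(stats::rnorm((N + 1L) * Dd, sd = 0.02), N + 1L, Dd),
      blocks = lapply(seq_len(decoder_depth), function(i) init_block(Dd, 2)),
      lnf = list(g = rep(1, Dd), b = rep(0, Dd)),
      Wout = matrix(stats::rnorm(Dd * P2, sd = 0.02), Dd, P2),
      bout = rep(0, P2)
    )
  )
  class(w) <- "mae_weights"
  w
}

# Forward pass for one image under a fixed mask. Returns loss, per-patch
# predictions, and (optionally) caches for the backward pass.
mae_forward <- function(x, w, cfg, mask, cache = FALSE, norm_pix = FALSE) {
  enc <- w$encoder; dec <- w$decoder
  # same per-image standardization as the classifier forward pass, so the
  # pre-trained encoder sees identical input statistics after transplant
  mu <- mean(x); sg <- stats::sd(as.vector(x))
  x <- (x - mu) / max(sg, 1e-6)
  target <- image_to_patches(x, cfg$patch_size)
  if (norm_pix) {
    mu <- rowMeans(target); sd <- sqrt(apply(target, 1, stats::var) + 1e-6)
    target <- (target - mu) / sd
  }
  N <- nrow(target)
  vis <- which(!mask)
  tok_all <- linear_forward(target_raw <- image_to_patches(x, cfg$patch_size),
                            enc$We, enc$be)
  tok_vis <- tok_all[vis, , drop = FALSE] + enc$pos[vis + 1L, , drop = FALSE]
  tok <- rbind(enc$cls + enc$pos[1L, , drop = FALSE], tok_vis)
  run <- encoder_run(tok, enc, cfg, cache = cache)
  z <- linear_forward(run$tokens, dec$Wd, dec$bd)
  Dd <- ncol(z)
  seqd <- matrix(rep(dec$mask_tok, N + 1L), N + 1L, Dd, byrow = TRUE)
  seqd[1L, ] <- z[1L, ]
  if (length(vis)) seqd[vis + 1L, ] <- z[-1L, , drop = FALSE]
  seq_in <- seqd + dec$dpos
  dcaches <- if (cache) vector("list", length(dec$blocks)) else NULL
  h <- seq_in
  for (l in seq_along(dec$blocks)) {
    bf <- block_forward(h, dec$blocks[[l]], n_heads = 1L)
    if (cache) dcaches[[l]] <- bf
    h <- bf$y
  }
  lnf <- layernorm_forward(h, dec$lnf$g, dec$lnf$b)
  pred <- linear_forward(lnf$y[-1L, , drop = FALSE], dec$Wout, dec$bout)
  loss <- mae_loss(pred, target, mask)
  out <- list(loss = loss, pred = pred, target = target)
  if (cache)
    out$cache <- list(run = run, z = z, vis = vis, N = N, lnf = lnf,
                      dblocks = dcaches, dec_in = seq_in, mask = mask,
                      patches = target_raw)
  out
}

mae_backward <- function(fwd, w, cfg) {
  cache <- fwd$cache
  enc <- w$encoder; dec <- w$decoder
  mask <- cache$mask; N <- cache$N; vis <- cache$vis
  nm <- sum(mask); P2 <- ncol(fwd$pred)
  dpred <- matrix(0, N, P2)
  if (nm > 0) {
    diff <- fwd$pred - fwd$target
    dpred[mask, ] <- 2 * diff[mask, , drop = FALSE] / (nm * P2)
  }
  gout <- linear_backward(dpred, cache$lnf$y[-1L, , drop = FALSE], dec$Wout)
  dlnf_y <- rbind(0, gout$dx)
  lb <- layernorm_backward(dlnf_y, cache$lnf, dec$lnf$g)
  d <- lb$dx
  dblocks <- vector("list", length(dec$blocks))
  for (l in rev(seq_along(dec$blocks))) {
    bb <- block_backward(d, cache$dblocks[[l]], dec$blocks[[l]], n_heads = 1L)
    dblocks[[l]] <- bb$grads
    d <- bb$dx
  }
  ddpos <- d
  dseqd <- d
  dmask_tok <- matrix(colSums(dseqd[-1L, , drop = FALSE][mask, , drop = FALSE]),
                      1)
  dz <- matrix(0, length(vis) + 1L, ncol(dseqd))
  dz[1L, ] <- dseqd[1L, ]
  if (length(vis)) dz[-1L, ] <- dseqd[vis + 1L, , drop = FALSE]
  gd <- linear_backward(dz, cache$run$tokens, dec$Wd)
  eb <- encoder_backward_run(gd$dx, cache$run, enc, cfg)
  dtok <- eb$dtokens
  dcls <- dtok[1L, , drop = FALSE]
  dpos <- matrix(0, N + 1L, cfg$embed_dim)
  dpos[1L, ] <- dtok[1L, ]
  if (length(vis)) dpos[vis + 1L, ] <- dtok[-1L, , drop = FALSE]
  dtok_vis <- dtok[-1L, , drop = FALSE]
  gWe <- t(cache$patches[vis, , drop = FALSE]) %*% dtok_vis
  gbe <- colSums(dtok_vis)
  list(
    encoder = list(We = gWe, be = gbe, cls = dcls, pos = dpos,
                   blocks = eb$grads$blocks, lnf = eb$grads$lnf),
    decoder = list(Wd = gd$dW, bd = gd$db, mask_tok = dmask_tok,
                   dpos = ddpos, blocks = dblocks,
                   lnf = list(g = lb$dg, b = lb$db),
                   Wout = gout$dW, bout = gout$db)
  )
}

#' Pre-train a domain-adaptation encoder by masked reconstruction
#'
#' Trains encoder + decoder with AdamW to reconstruct randomly masked
#' patches of healthy-sample images. The returned checkpoint carries the
#' encoder (for [load_pretrained_encoder()]), the full autoencoder weights,
#' the generating config and a per-epoch loss log.
#'
#' @param images List of image matrices (all `cfg$image_size` square) or a
#'   `wavevit_dataset`.
#' @param cfg A [wavevit_config()].
#' @param epochs Number of passes over the data (0 returns the
#'   initialization unchanged).
#' @param seed Master seed: initialization, masks and batch order all
#'   derive from it.
#' @param mask_ratio Fraction of patches masked per image (default 0.75).
#' @param batch_size Images per optimizer step.
#' @param lr AdamW learning rate.
#' @param decoder_dim,decoder_depth Decoder width and depth (discarded
#'   after pre-training).
#' @param norm_pix Regress per-patch-normalized pixels instead of raw ones.
#' @return Checkpoint list with `encoder`, `mae`, `config`, `log`.
#' @export
mae_pretrain <- function(images, cfg, epochs = 5L, seed = 0L,
                         mask_ratio = 0.75, batch_size = 16L, lr = 1e-3,
                         decoder_dim = 16L, decoder_depth = 1L,
                         norm_pix = FALSE) {
  if (inherits(images, "wavevit_dataset")) images <- lapply(images$items, `[[`, "image")
  if (length(images) == 0L) stop("pre-training dataset is empty", call. = FALSE)
  w <- init_mae(cfg, decoder_dim, decoder_depth, seed = seed)
  opt <- adamw_init(unclass(w))
  N <- n_patches(cfg)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    set.seed(seed + 1000L * ep)
    order_idx <- sample.int(length(images))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, length(images), by = batch_size)) {
      idx <- order_idx[start:min(start + batch_size - 1L, length(images))]
      total <- par_zeros_like(unclass(w))
      bl <- 0
      for (i in idx) {
        step <- step + 1L
        m <- random_mask(N, mask_ratio, seed = seed + 7L * step)
        fwd <- mae_forward(images[[i]], w, cfg, m$mask, cache = TRUE,
                           norm_pix = norm_pix)
        g <- mae_backward(fwd, w, cfg)
        total <- par_add_scaled(total, g)
        bl <- bl + fwd$loss
      }
      total <- par_map(total, function(x) x / length(idx))
      r <- adamw_step(unclass(w), total, opt, lr = lr)
      w <- structure(r$params, class = "mae_weights")
      opt <- r$state
      ep_loss <- ep_loss + bl / length(idx)
      n_batches <- n_batches + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n_batches))
  }
  list(encoder = w$encoder, mae = w, config = cfg, log = log)
}

#' Visualize masked reconstruction
#'
#' Produces the masked input, the model reconstruction (predicted patches
#' at masked positions, original pixels elsewhere) and the original, for a
#' side-by-side figure of the pre-training behaviour.
#'
#' @param x Image matrix.
#' @param checkpoint A [mae_pretrain()] checkpoint.
#' @param mask_ratio Masking fraction.
#' @param seed Mask seed.
#' @return List of three image matrices: `masked`, `reconstruction`,
#'   `original`.
#' @export
mae_reconstruct <- function(x, checkpoint, mask_ratio = 0.75, seed = 0L) {
  cfg <- checkpoint$config
  m <- random_mask(n_patches(cfg), mask_ratio, seed = seed)
  fwd <- mae_forward(x, checkpoint$mae, cfg, m$mask, cache = FALSE)
  mu <- mean(x); sg <- max(stats::sd(as.vector(x)), 1e-6)
  patches <- image_to_patches(x, cfg$patch_size)
  masked <- patches; masked[m$mask, ] <- 0
  recon <- patches  # predictions are in standardized units; map back
  recon[m$mask, ] <- pmin(pmax(mu + sg * fwd$pred[m$mask, , drop = FALSE], 0), 1)
  list(masked = patches_to_image(masked, cfg$patch_size, cfg$image_size),
       reconstruction = patches_to_image(recon, cfg$patch_size, cfg$image_size),
       original = x)
}
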