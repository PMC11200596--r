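# Wavelet-fusion Vision Transformer classifier.
#
# The model is a standard patch-token transformer: the input image passes
# through the wavelet extraction-and-fusion module, whose full-resolution
# output is added residually to the image; the result is cut into
# non-overlapping patches, linearly embedded, prefixed with a class token,
# summed with learned positional embeddings and run through a stack of
# pre-norm transformer blocks. The class token (default) or mean-pooled
# tokens feed a linear head over the four diagnostic classes.

#' Model configuration
#'
#' @param image_size Input side length in pixels (images are square after
#'   resizing); must be divisible by `patch_size`.
#' @param patch_size Patch side length in pixels.
#' @param embed_dim Token channel width.
#' @param depth Number of transformer blocks.
#' @param heads Number of attention heads (must divide `embed_dim`).
#' @param n_classes Number of output classes (>= 2).
#' @param wefm_depth Convolution layers per fusion stack.
#' @param wefm_placement How the fusion module joins the backbone:
#'   `"residual"` (image + fused image, default) or `"replace"` (fused
#'   image only) or `"none"` (plain transformer, for ablations).
#' @param pool `"cls"` (class-token pooling, default) or `"mean"`.
#' @param mlp_ratio Width multiplier of the block MLPs.
#' @return A list of class `wavevit_config`.
#' @export
wavevit_config <- function(image_size = 224L, patch_size = 16L,
                           embed_dim = 768L, depth = 12L, heads = 12L,
                           n_classes = 4L, wefm_depth = 4L,
                           wefm_placement = c("residual", "replace", "none"),
                           pool = c("cls", "mean"), mlp_ratio = 4) {
  wefm_placement <- match.arg(wefm_placement)
  pool <- match.arg(pool)
  image_size <- as.integer(image_size); patch_size <- as.integer(patch_size)
  if (image_size %% patch_size != 0L)
    stop(sprintf("image_size (%d) is not divisible by patch_size (%d)",
                 image_size, patch_size), call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (embed_dim %% heads != 0L)
    stop("embed_dim must be divisible by heads", call. = FALSE)
  structure(list(image_size = image_size, patch_size = patch_size,
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), n_classes = as.integer(n_classes),
                 wefm_depth = as.integer(wefm_depth),
                 wefm_placement = wefm_placement, pool = pool,
                 mlp_ratio = mlp_ratio),
            class = "wavevit_config")
}

#' Desk-scale configuration for tests and examples
#'
#' 32-pixel images, 8-pixel patches (16 tokens), 2 blocks, 32 channels:
#' small enough to train on one CPU in seconds while exercising every code
#' path of the full-size model.
#' @param ... Overrides passed to [wavevit_config()].
#' @export
wavevit_tiny_config <- function(...) {
  args <- list(image_size = 32L, patch_size = 8L, embed_dim = 32L,
               depth = 2L, heads = 4L, n_classes = 4L, wefm_depth = 2L,
               mlp_ratio = 2)
  override <- list(...)
  args[names(override)] <- override
  do.call(wavevit_config, args)
}

n_patches <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2L

# Cut an H x W image matrix into N x p^2 patch rows. Patches are ordered
# row-major over the patch grid; pixels within a patch are column-major
# (R's native vectorization order).
image_to_patches <- function(x, patch) {
  H <- nrow(x); W <- ncol(x)
  if (H %% patch != 0L || W %% patch != 0L)
    stop(sprintf("image %dx%d is not divisible into %d-pixel patches",
                 H, W, patch), call. = FALSE)
  gh <- H %/% patch; gw <- W %/% patch
  out <- matrix(0, gh * gw, patch * patch)
  k <- 0L
  for (r in seq_len(gh)) {
    rows <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(gw)) {
      k <- k + 1L
      out[k, ] <- as.vector(x[rows, ((cc - 1L) * patch + 1L):(cc * patch)])
    }
  }
  out
}

patches_to_image <- function(p, patch, image_size) {
  g <- image_size %/% patch
  x <- matrix(0, image_size, image_size)
  k <- 0L
  for (r in seq_len(g)) {
    rows <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(g)) {
      k <- k + 1L
      x[rows, ((cc - 1L) * patch + 1L):(cc * patch)] <- matrix(p[k, ], patch, patch)
    }
  }
  x
}

#' Embed an image as a sequence of patch tokens
#'
#' Cuts the image into `(image_size/patch_size)^2` non-overlapping patches,
#' projects each linearly to `embed_dim` channels and adds the patch's
#' positional embedding (class token excluded).
#'
#' @param x Numeric matrix, `image_size` x `image_size`.
#' @param cfg A [wavevit_config()].
#' @param weights Optional model weights; when omitted, a fresh seed-0
#'   initialization is used (shape inspection / testing).
#' @return N x embed_dim token matrix.
#' @export
patch_embed <- function(x, cfg, weights = NULL) {
  if (nrow(x) != cfg$image_size || ncol(x) != cfg$image_size)
    stop(sprintf("expected a %dx%d image, got %dx%d", cfg$image_size,
                 cfg$image_size, nrow(x), ncol(x)), call. = FALSE)
  if (is.null(weights)) weights <- wavevit_init(cfg, seed = 0L)
  enc <- weights$encoder
  p <- image_to_patches(x, cfg$patch_size)
  tok <- linear_forward(p, enc$We, enc$be)
  tok + enc$pos[-1L, , drop = FALSE]
}

init_encoder <- function(cfg) {
  D <- cfg$embed_dim
  P2 <- cfg$patch_size^2L
  N <- n_patches(cfg)
  list(
    We = matrix(stats::rnorm(P2 * D, sd = 0.02), P2, D),
    be = rep(0, D),
    cls = matrix(stats::rnorm(D, sd = 0.02), 1, D),
    pos = matrix(stats::rnorm((N + 1L) * D, sd = 0.02), N + 1L, D),
    blocks = lapply(seq_len(cfg$depth), function(i) init_block(D, cfg$mlp_ratio)),
    lnf = list(g = rep(1, D), b = rep(0, D))
  )
}

#' Initialize model weights
#'
#' @param cfg A [wavevit_config()].
#' @param seed Integer seed; identical seeds give bit-identical weights.
#' @return A `wavevit_weights` tree with `encoder`, `head` and `wefm`
#'   sub-trees.
#' @export
wavevit_init <- function(cfg, seed = 0L) {
  set.seed(seed)
  w <- list(
    encoder = init_encoder(cfg),
    head = list(W = matrix(stats::rnorm(cfg$embed_dim * cfg$n_classes, sd = 0.02),
                           cfg$embed_dim, cfg$n_classes),
                b = rep(0, cfg$n_classes)),
    wefm = if (cfg$wefm_placement == "none") NULL else
      wefm_weights(channels = 1L, depth = cfg$wefm_depth,
                   seed = seed + 1L)
  )
  class(w) <- "wavevit_weights"
  w
}

# Run the encoder over a token matrix (class token already prepended and
# positional embeddings added). Returns final tokens plus per-block caches.
encoder_run <- function(tok, enc, cfg, cache = FALSE) {
  caches <- if (cache) vector("list", cfg$depth) else NULL
  h <- tok
  for (l in seq_len(cfg$depth)) {
    bf <- block_forward(h, enc$blocks[[l]], cfg$heads)
    if (cache) caches[[l]] <- bf
    h <- bf$y
  }
  lnf <- layernorm_forward(h, enc$lnf$g, enc$lnf$b)
  list(tokens = lnf$y, pre_lnf = h, lnf = lnf, blocks = caches)
}

encoder_backward_run <- function(dtok, run, enc, cfg) {
  lb <- layernorm_backward(dtok, run$lnf, enc$lnf$g)
  d <- lb$dx
  bgrads <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    bb <- block_backward(d, run$blocks[[l]], enc$blocks[[l]], cfg$heads)
    bgrads[[l]] <- bb$grads
    d <- bb$dx
  }
  list(dtokens = d, grads = list(blocks = bgrads,
                                 lnf = list(g = lb$dg, b = lb$db)))
}

# Full forward pass for one image. Returns logits, probabilities and, when
# cache = TRUE, every intermediate needed for the backward pass.
model_forward <- function(x, weights, cfg, cache = FALSE) {
  if (!is.matrix(x)) x <- grid_channel(as_feature_grid(x), 1L)
  if (nrow(x) != cfg$image_size || ncol(x) != cfg$image_size)
    stop(sprintf("expected a %dx%d image, got %dx%d", cfg$image_size,
                 cfg$image_size, nrow(x), ncol(x)), call. = FALSE)
  enc <- weights$encoder
  # standardize per image (zero mean, unit variance) so token activations
  # start at a healthy scale regardless of the acquisition intensity range
  mu <- mean(x); sg <- stats::sd(as.vector(x))
  x <- (x - mu) / max(sg, 1e-6)
  wef_out <- NULL
  if (cfg$wefm_placement == "none") {
    xin <- x
  } else {
    wef_out <- wefm_forward(x, weights$wefm, cache = cache)
    fused <- grid_channel(wef_out, 1L)
    xin <- if (cfg$wefm_placement == "residual") x + fused else fused
  }
  if (any(!is.finite(xin)))
    stop("non-finite values after wavelet fusion module", call. = FALSE)
  patches <- image_to_patches(xin, cfg$patch_size)
  tok <- linear_forward(patches, enc$We, enc$be)
  tok <- rbind(enc$cls, tok) + enc$pos
  run <- encoder_run(tok, enc, cfg, cache = cache)
  if (any(!is.finite(run$tokens)))
    stop("non-finite values in transformer encoder output", call. = FALSE)
  pooled <- if (cfg$pool == "cls") run$tokens[1L, , drop = FALSE]
            else matrix(colMeans(run$tokens[-1L, , drop = FALSE]), 1)
  logits <- as.vector(linear_forward(pooled, weights$head$W, weights$head$b))
  if (any(!is.finite(logits)))
    stop("non-finite values in classification head", call. = FALSE)
  probs <- as.vector(softmax_rows(matrix(logits, 1)))
  out <- list(logits = logits, probs = probs)
  if (cache)
    out$cache <- list(x = x, wef_out = wef_out, patches = patches,
                      run = run, pooled = pooled)
  out
}

# The trainable view of a weight tree: numeric sub-trees only, in a fixed
# order, so gradients/optimizer state can mirror it structurally.
trainable_params <- function(weights) {
  tp <- list(encoder = weights$encoder, head = weights$head)
  if (!is.null(weights$wefm)) tp$wefm <- weights$wefm$stacks
  tp
}

set_trainable <- function(weights, tp) {
  weights$encoder <- tp$encoder
  weights$head <- tp$head
  if (!is.null(weights$wefm)) weights$wefm$stacks <- tp$wefm
  weights
}

# Backward from dlogits (length n_classes) to parameter gradients, in the
# trainable_params structure.
model_backward <- function(dlogits, fwd, weights, cfg) {
  cache <- fwd$cache
  enc <- weights$encoder
  gh <- linear_backward(matrix(dlogits, 1), cache$pooled, weights$head$W)
  N1 <- n_patches(cfg) + 1L
  dtok_out <- matrix(0, N1, cfg$embed_dim)
  if (cfg$pool == "cls") {
    dtok_out[1L, ] <- gh$dx
  } else {
    dtok_out[-1L, ] <- matrix(rep(gh$dx / (N1 - 1L), N1 - 1L),
                              N1 - 1L, cfg$embed_dim, byrow = TRUE)
  }
  eb <- encoder_backward_run(dtok_out, cache$run, enc, cfg)
  dtok <- eb$dtokens                     # gradient w.r.t. tok + pos
  dpos <- dtok
  dcls <- dtok[1L, , drop = FALSE]
  gp <- linear_backward(dtok[-1L, , drop = FALSE], cache$patches, enc$We)
  dxin <- patches_to_image(gp$dx, cfg$patch_size, cfg$image_size)
  wefm_grads <- NULL
  if (cfg$wefm_placement != "none") {
    wb <- wefm_backward(array(dxin, c(1L, dim(dxin))), cache$wef_out,
                        weights$wefm)
    wefm_grads <- wb$grads
  }
  grads <- list(
    encoder = list(We = gp$dW, be = gp$db, cls = dcls, pos = dpos,
                   blocks = eb$grads$blocks, lnf = eb$grads$lnf),
    head = list(W = gh$dW, b = gh$db)
  )
  if (!is.null(wefm_grads)) grads$wefm <- wefm_grads
  grads
}

# Mean-CE loss and summed gradients over a labeled batch of image matrices.
batch_loss_grads <- function(images, labels, weights, cfg,
                             sample_weights = NULL) {
  n <- length(images)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  total <- par_zeros_like(trainable_params(weights))
  loss <- 0
  probs <- matrix(0, n, cfg$n_classes)
  for (i in seq_len(n)) {
    fwd <- model_forward(images[[i]], weights, cfg, cache = TRUE)
    probs[i, ] <- fwd$probs
    p <- matrix(fwd$probs, 1)
    li <- as.integer(labels[i])
    loss <- loss + sample_weights[i] * (-log(max(p[1, li + 1L], 1e-12)))
    dlog <- as.vector(softmax_ce_grad(p, li)) * sample_weights[i]
    g <- model_backward(dlog, fwd, weights, cfg)
    total <- par_add_scaled(total, g)
  }
  wsum <- sum(sample_weights)
  if (wsum > 0) {
    total <- par_map(total, function(x) x / wsum)
    loss <- loss / wsum
  }
  list(loss = loss, grads = total, probs = probs)
}

#' Classify a single image
#'
#' Runs the full forward path (wavelet fusion, patch embedding, transformer
#' encoder, pooling, linear head) and returns logits with softmax
#' probabilities.
#'
#' @param x Image matrix of size `image_size` x `image_size`, values in
#'   any finite range.
#' @param weights A `wavevit_weights` tree.
#' @param cfg The matching [wavevit_config()].
#' @return List with `logits` (length `n_classes`), `probs` (simplex
#'   vector) and `class` (0-based argmax, ties to the lowest index).
#' @export
classify <- function(x, weights, cfg) {
  fwd <- model_forward(x, weights, cfg, cache = FALSE)
  list(logits = fwd$logits, probs = fwd$probs,
       class = which.max(fwd$probs) - 1L)
}

#' Transplant a pre-trained encoder into a classifier
#'
#' Replaces the classifier's encoder sub-tree (patch embedding, class token,
#' positional embeddings, transformer blocks, final norm) with the encoder
#' from a domain-adaptation checkpoint. Head and wavelet-fusion parameters
#' are untouched. The operation is idempotent.
#'
#' @param weights Classifier `wavevit_weights`.
#' @param checkpoint A checkpoint list with `encoder` and `config` entries,
#'   as produced by [mae_pretrain()].
#' @return Updated weights.
#' @export
load_pretrained_encoder <- function(weights, checkpoint) {
  if (is.null(checkpoint$encoder)) stop("checkpoint has no encoder", call. = FALSE)
  mism <- character(0)
  geom <- function(name, a, b) {
    if (!identical(dim(a), dim(b)))
      mism <<- c(mism, sprintf("%s: %s vs %s", name,
                               paste(dim(a), collapse = "x"),
                               paste(dim(b), collapse = "x")))
  }
  geom("patch embedding", weights$encoder$We, checkpoint$encoder$We)
  geom("positional embedding", weights$encoder$pos, checkpoint$encoder$pos)
  if (length(weights$encoder$blocks) != length(checkpoint$encoder$blocks))
    mism <- c(mism, sprintf("depth: %d vs %d", length(weights$encoder$blocks),
                            length(checkpoint$encoder$blocks)))
  if (length(mism) > 0)
    stop("incompatible encoder geometry: ", paste(mism, collapse = "; "),
         call. = FALSE)
  weights$encoder <- checkpoint$encoder
  weights
}

#' Save / load a weight checkpoint
#'
#' Checkpoints are single-file archives with named sub-trees (`encoder`,
#' `head`, `wefm`) plus the generating config; round-tripping is bit-exact.
#' @param object Checkpoint list or weights.
#' @param path File path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint file not found: ", path, call. = FALSE)
  readRDS(path)
}
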