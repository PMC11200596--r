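# ---- feature grids ---------------------------------------------------------
# A feature grid is a C x H x W numeric array; plain H x W matrices are
# accepted everywhere and treated as single-channel.

as_feature_grid <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature grid must be a matrix or a C x H x W array", call. = FALSE)
  if (!all(is.finite(x))) stop("feature grid contains non-finite values", call. = FALSE)
  x
}

grid_channel <- function(x, c) x[c, , , drop = TRUE]

#' Single-level orthonormal Haar decomposition
#'
#' Splits a feature grid into the four half-resolution frequency sub-bands
#' (approximation `ll` plus the three detail orientations). The transform is
#' the separable orthonormal Haar filter pair `low = (u + v)/sqrt(2)`,
#' `high = (u - v)/sqrt(2)` applied along rows and columns with dyadic
#' downsampling, so total coefficient energy equals input energy and
#' [idwt_reconstruct()] inverts it exactly.
#'
#' Sub-band naming: `lh` is the vertical-detail band (low-pass over columns,
#' high-pass over rows); `hl` is the horizontal-detail band.
#'
#' @param x A numeric matrix (H x W) or C x H x W array with even H and W.
#' @return An object of class `subband_set`: list with components `ll`,
#'   `lh`, `hl`, `hh`, each a C x H/2 x W/2 array.
#' @examples
#' s <- dwt_decompose(matrix(1, 4, 4))
#' s$ll[1, 1, 1]  # 2: a 2x2 block of ones averages to 2c under orthonormal Haar
#' @export
dwt_decompose <- function(x) {
  x <- as_feature_grid(x)
  d <- dim(x)
  if (d[2] %% 2L != 0L)
    stop(sprintf("height (%d) must be even for dyadic decomposition", d[2]), call. = FALSE)
  if (d[3] %% 2L != 0L)
    stop(sprintf("width (%d) must be even for dyadic decomposition", d[3]), call. = FALSE)
  ri <- seq.int(1L, d[2], by = 2L)
  ci <- seq.int(1L, d[3], by = 2L)
  a <- x[, ri, ci, drop = FALSE]       # top-left of each 2x2 block
  b <- x[, ri, ci + 1L, drop = FALSE]  # top-right
  cc <- x[, ri + 1L, ci, drop = FALSE] # bottom-left
  dd <- x[, ri + 1L, ci + 1L, drop = FALSE]
  out <- list(
    ll = (a + b + cc + dd) / 2,
    lh = (a + b - cc - dd) / 2,
    hl = (a - b + cc - dd) / 2,
    hh = (a - b - cc + dd) / 2
  )
  class(out) <- "subband_set"
  out
}

#' Inverse of the single-level Haar decomposition
#'
#' Reassembles a feature grid from four equally shaped sub-band planes.
#' For an untouched [dwt_decompose()] output this is exact (perfect
#' reconstruction) up to floating-point rounding.
#'
#' @param s A `subband_set` or plain list with `ll`, `lh`, `hl`, `hh`.
#' @return A C x 2H' x 2W' array.
#' @export
idwt_reconstruct <- function(s) {
  planes <- lapply(s[c("ll", "lh", "hl", "hh")], as_feature_grid)
  dims <- lapply(planes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("sub-band planes have mismatched shapes", call. = FALSE)
  d <- dims[[1]]
  out <- array(0, dim = c(d[1], 2L * d[2], 2L * d[3]))
  ri <- seq.int(1L, 2L * d[2], by = 2L)
  ci <- seq.int(1L, 2L * d[3], by = 2L)
  ll <- planes$ll; lh <- planes$lh; hl <- planes$hl; hh <- planes$hh
  out[, ri, ci] <- (ll + lh + hl + hh) / 2
  out[, ri, ci + 1L] <- (ll + lh - hl - hh) / 2
  out[, ri + 1L, ci] <- (ll - lh + hl - hh) / 2
  out[, ri + 1L, ci + 1L] <- (ll - lh - hl + hh) / 2
  out
}

# ---- 2-D convolution (same padding) ----------------------------------------
# w has dim (kh, kw, c_in, c_out); x is c_in x H x W. Zero padding keeps the
# spatial size. Vectorized over the kernel taps, which is plenty at the
# grid sizes this package trains at.

conv2d_forward <- function(x, w, b) {
  dx <- dim(x); dw <- dim(w)
  if (dx[1] != dw[3])
    stop(sprintf("channel mismatch: input has %d channels, weights expect %d",
                 dx[1], dw[3]), call. = FALSE)
  kh <- dw[1]; kw <- dw[2]; c_out <- dw[4]
  H <- dx[2]; W <- dx[3]
  oh <- (kh - 1L) %/% 2L; ow <- (kw - 1L) %/% 2L
  out <- array(rep(b, each = H * W), dim = c(H, W, c_out))
  for (di in seq_len(kh)) {
    si <- di - 1L - oh  # row shift applied to input
    r_out <- max(1L, 1L - si):min(H, H - si)
    if (length(r_out) == 0L) next
    r_in <- r_out + si
    for (dj in seq_len(kw)) {
      sj <- dj - 1L - ow
      c_out_idx <- max(1L, 1L - sj):min(W, W - sj)
      if (length(c_out_idx) == 0L) next
      c_in_idx <- c_out_idx + sj
      for (ci in seq_len(dx[1])) {
        xs <- x[ci, r_in, c_in_idx]
        for (co in seq_len(c_out)) {
          wv <- w[di, dj, ci, co]
          if (wv != 0)
            out[r_out, c_out_idx, co] <- out[r_out, c_out_idx, co] + wv * xs
        }
      }
    }
  }
  aperm(out, c(3L, 1L, 2L))
}

conv2d_backward <- function(dy, x, w) {
  dx <- dim(x); dw <- dim(w)
  kh <- dw[1]; kw <- dw[2]
  H <- dx[2]; W <- dx[3]
  oh <- (kh - 1L) %/% 2L; ow <- (kw - 1L) %/% 2L
  gx <- array(0, dim = dx)
  gw <- array(0, dim = dw)
  gb <- apply(dy, 1, sum)
  for (di in seq_len(kh)) {
    si <- di - 1L - oh
    r_out <- max(1L, 1L - si):min(H, H - si)
    if (length(r_out) == 0L) next
    r_in <- r_out + si
    for (dj in seq_len(kw)) {
      sj <- dj - 1L - ow
      c_out_idx <- max(1L, 1L - sj):min(W, W - sj)
      if (length(c_out_idx) == 0L) next
      c_in_idx <- c_out_idx + sj
      for (ci in seq_len(dx[1])) {
        xs <- x[ci, r_in, c_in_idx]
        for (co in seq_len(dw[4])) {
          dys <- dy[co, r_out, c_out_idx]
          gw[di, dj, ci, co] <- sum(xs * dys)
          wv <- w[di, dj, ci, co]
          if (wv != 0)
            gx[ci, r_in, c_in_idx] <- gx[ci, r_in, c_in_idx] + wv * dys
        }
      }
    }
  }
  list(dx = gx, dw = gw, db = gb)
}

act_forward <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         linear = x,
         stop("unknown activation: ", activation, call. = FALSE))
}

act_backward <- function(dy, x, activation) {
  switch(activation,
         relu = dy * (x > 0),
         linear = dy)
}

# ---- fusion weights --------------------------------------------------------

#' Create per-sub-band convolutional fusion stacks
#'
#' Builds one independent convolutional stack per frequency sub-band
#' (`ll`, `lh`, `hl`, `hh`). Each stack has `depth` layers of `kernel` x
#' `kernel` same-padding convolutions; hidden layers use the stack's
#' activation and the final layer is linear, so an identity-initialized
#' stack can reproduce its input exactly.
#'
#' @param channels Input/output channel count of each stack (the feature
#'   grid's channel count, 1 for raw images).
#' @param depth Number of convolution layers per stack (default 4).
#' @param hidden Hidden width; defaults to `channels`.
#' @param kernel Odd kernel size (default 3).
#' @param activation Hidden-layer nonlinearity: `"relu"` (default) or
#'   `"linear"`.
#' @param init `"random"` (scaled Gaussian) or `"identity"` (centre-tap-1
#'   kernels, zero bias; forces linear activation so the stack is the
#'   identity map).
#' @param seed Seed for random initialization.
#' @return An object of class `fusion_weights`.
#' @export
wefm_weights <- function(channels = 1L, depth = 4L, hidden = channels,
                         kernel = 3L, activation = "relu",
                         init = c("random", "identity"), seed = 0L) {
  init <- match.arg(init)
  stopifnot(depth >= 1L, kernel %% 2L == 1L, channels >= 1L, hidden >= 1L)
  if (init == "identity") activation <- "linear"
  widths <- c(channels, rep(hidden, depth - 1L), channels)
  centre <- (kernel + 1L) %/% 2L
  set.seed(seed)
  make_stack <- function() {
    lapply(seq_len(depth), function(l) {
      c_in <- widths[l]; c_out <- widths[l + 1L]
      w <- array(0, dim = c(kernel, kernel, c_in, c_out))
      if (init == "random") {
        w[] <- stats::rnorm(length(w), sd = sqrt(2 / (kernel * kernel * c_in)))
      } else {
        for (co in seq_len(c_out)) {
          ci <- ((co - 1L) %% c_in) + 1L
          w[centre, centre, ci, co] <- 1
        }
      }
      list(w = w, b = numeric(c_out))
    })
  }
  out <- list(
    stacks = list(ll = make_stack(), lh = make_stack(),
                  hl = make_stack(), hh = make_stack()),
    depth = depth, channels = channels, hidden = hidden,
    kernel = kernel, activation = activation
  )
  class(out) <- "fusion_weights"
  out
}

#' Identity fusion weights
#'
#' Convenience constructor for stacks that leave every sub-band unchanged,
#' making [wefm_forward()] the identity map.
#' @inheritParams wefm_weights
#' @export
wefm_identity_weights <- function(channels = 1L, depth = 4L, kernel = 3L) {
  wefm_weights(channels = channels, depth = depth, kernel = kernel,
               init = "identity")
}

run_stack <- function(x, stack, activation, cache = FALSE) {
  n <- length(stack)
  pre <- vector("list", n)   # pre-activation outputs
  inp <- vector("list", n)   # layer inputs
  h <- x
  for (l in seq_len(n)) {
    inp[[l]] <- h
    z <- conv2d_forward(h, stack[[l]]$w, stack[[l]]$b)
    pre[[l]] <- z
    h <- if (l < n) act_forward(z, activation) else z
  }
  if (cache) list(out = h, pre = pre, inp = inp) else list(out = h)
}

run_stack_backward <- function(dy, cache, stack, activation) {
  n <- length(stack)
  grads <- vector("list", n)
  d <- dy
  for (l in rev(seq_len(n))) {
    if (l < n) d <- act_backward(d, cache$pre[[l]], activation)
    g <- conv2d_backward(d, cache$inp[[l]], stack[[l]]$w)
    grads[[l]] <- list(w = g$dw, b = g$db)
    d <- g$dx
  }
  list(dx = d, grads = grads)
}

#' Fuse wavelet sub-bands with per-band convolutional stacks
#'
#' Each sub-band plane is processed by its own convolutional stack; spatial
#' shape is preserved.
#'
#' @param s A `subband_set`.
#' @param weights A `fusion_weights` object from [wefm_weights()].
#' @param cache Keep intermediates for backpropagation.
#' @return A `fused_subband_set` (same shape contract as the input); when
#'   `cache = TRUE`, the caches are attached as attribute `"cache"`.
#' @export
fuse_subbands <- function(s, weights, cache = FALSE) {
  stopifnot(inherits(weights, "fusion_weights"))
  bands <- c("ll", "lh", "hl", "hh")
  caches <- list()
  out <- list()
  for (b in bands) {
    x <- as_feature_grid(s[[b]])
    if (dim(x)[1] != weights$channels)
      stop(sprintf("channel mismatch on band %s: plane has %d channels, stacks expect %d",
                   b, dim(x)[1], weights$channels), call. = FALSE)
    r <- run_stack(x, weights$stacks[[b]], weights$activation, cache = cache)
    out[[b]] <- r$out
    if (cache) caches[[b]] <- r
  }
  class(out) <- c("fused_subband_set", "subband_set")
  if (cache) attr(out, "cache") <- caches
  out
}

fuse_subbands_backward <- function(dout, fused, weights) {
  caches <- attr(fused, "cache")
  if (is.null(caches)) stop("fuse_subbands must be called with cache = TRUE")
  bands <- c("ll", "lh", "hl", "hh")
  ds <- list(); grads <- list()
  for (b in bands) {
    r <- run_stack_backward(dout[[b]], caches[[b]], weights$stacks[[b]],
                            weights$activation)
    ds[[b]] <- r$dx
    grads[[b]] <- r$grads
  }
  list(ds = ds, grads = grads)
}

#' Wavelet extraction-and-fusion forward pass
#'
#' Decomposes a feature grid into its four Haar sub-bands, passes each
#' through its own convolutional stack, and reconstructs the full-resolution
#' grid by the inverse transform. Output shape always equals input shape.
#'
#' @param x Feature grid (matrix or C x H x W array, even spatial dims).
#' @param weights A `fusion_weights` object.
#' @param cache Keep intermediates for backpropagation.
#' @return A C x H x W array; with `cache = TRUE` an attribute `"cache"` is
#'   attached for [wefm_backward()].
#' @export
wefm_forward <- function(x, weights, cache = FALSE) {
  x <- as_feature_grid(x)
  s <- dwt_decompose(x)
  f <- fuse_subbands(s, weights, cache = cache)
  out <- idwt_reconstruct(f)
  if (cache) attr(out, "cache") <- list(fused = f)
  out
}

# Backward through IDWT o fuse o DWT. The Haar pair is orthonormal, so the
# adjoint of IDWT is DWT and vice versa.
wefm_backward <- function(dout, fwd_out, weights) {
  cache <- attr(fwd_out, "cache")
  if (is.null(cache)) stop("wefm_forward must be called with cache = TRUE")
  dfused <- dwt_decompose(dout)          # adjoint of idwt_reconstruct
  r <- fuse_subbands_backward(dfused, cache$fused, weights)
  dx <- idwt_reconstruct(r$ds)           # adjoint of dwt_decompose
  list(dx = dx, grads = r$grads)
}

subband_energy <- function(s) {
  sum(vapply(s[c("ll", "lh", "hl", "hh")], function(p) sum(p^2), numeric(1)))
}
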