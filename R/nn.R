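# Minimal neural-network core: parameter trees (nested lists of numeric
# arrays), analytic forward/backward passes for the transformer layers, and
# an AdamW optimizer. Everything operates on per-image token matrices
# (N tokens x D channels); batches are lists of such matrices. All shapes in
# this package are small enough that plain BLAS matmuls dominate the cost.

# ---- parameter-tree utilities ----------------------------------------------

par_map <- function(p, f) {
  if (is.list(p)) lapply(p, par_map, f = f) else f(p)
}

par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- par_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

par_zeros_like <- function(p) par_map(p, function(x) x * 0)

par_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, par_flatten), use.names = FALSE) else as.numeric(p)
}

par_unflatten <- function(p, v) {
  i <- 0L
  rec <- function(node) {
    if (is.list(node)) return(lapply(node, rec))
    n <- length(node)
    out <- node
    out[] <- v[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  rec(p)
}

par_add_scaled <- function(a, b, s = 1) par_map2(a, b, function(x, y) x + s * y)

par_identical <- function(a, b, tol = 0) {
  max(abs(par_flatten(a) - par_flatten(b))) <= tol
}

# ---- elementary layers -----------------------------------------------------

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

layernorm_forward <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv, xc = xc)
}

layernorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  D <- ncol(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  # dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

linear_forward <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

linear_backward <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = t(x) %*% dy, db = colSums(dy))
}

# ---- multi-head self-attention ---------------------------------------------

attention_forward <- function(x, p, n_heads) {
  D <- ncol(x)
  dh <- D %/% n_heads
  Q <- linear_forward(x, p$Wq, p$bq)
  K <- linear_forward(x, p$Wk, p$bk)
  V <- linear_forward(x, p$Wv, p$bv)
  O <- matrix(0, nrow(x), D)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    Ah <- softmax_rows(S)
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
    A[[h]] <- Ah
  }
  y <- linear_forward(O, p$Wo, p$bo)
  list(y = y, Q = Q, K = K, V = V, O = O, A = A, x = x)
}

attention_backward <- function(dy, cache, p, n_heads) {
  D <- ncol(cache$x)
  dh <- D %/% n_heads
  go <- linear_backward(dy, cache$O, p$Wo)
  dO <- go$dx
  dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dAh <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(Ah) %*% dOh
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  gq <- linear_backward(dQ, cache$x, p$Wq)
  gk <- linear_backward(dK, cache$x, p$Wk)
  gv <- linear_backward(dV, cache$x, p$Wv)
  list(dx = gq$dx + gk$dx + gv$dx,
       grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                    Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db))
}

# ---- transformer block (pre-norm) ------------------------------------------

block_forward <- function(x, p, n_heads) {
  ln1 <- layernorm_forward(x, p$ln1$g, p$ln1$b)
  at <- attention_forward(ln1$y, p$attn, n_heads)
  x1 <- x + at$y
  ln2 <- layernorm_forward(x1, p$ln2$g, p$ln2$b)
  h1 <- linear_forward(ln2$y, p$mlp$W1, p$mlp$b1)
  a1 <- gelu(h1)
  mo <- linear_forward(a1, p$mlp$W2, p$mlp$b2)
  y <- x1 + mo
  list(y = y, x_in = x, ln1 = ln1, at = at, x1 = x1, ln2 = ln2, h1 = h1,
       a1 = a1)
}

block_backward <- function(dy, cache, p, n_heads) {
  g2 <- linear_backward(dy, cache$a1, p$mlp$W2)
  dh1 <- g2$dx * gelu_grad(cache$h1)
  g1 <- linear_backward(dh1, cache$ln2$y, p$mlp$W1)
  l2 <- layernorm_backward(g1$dx, cache$ln2, p$ln2$g)
  dx1 <- dy + l2$dx
  ab <- attention_backward(dx1, cache$at, p$attn, n_heads)
  l1 <- layernorm_backward(ab$dx, cache$ln1, p$ln1$g)
  dx <- dx1 + l1$dx
  list(dx = dx,
       grads = list(ln1 = list(g = l1$dg, b = l1$db),
                    attn = ab$grads,
                    ln2 = list(g = l2$dg, b = l2$db),
                    mlp = list(W1 = g1$dW, b1 = g1$db,
                               W2 = g2$dW, b2 = g2$db)))
}

init_block <- function(D, mlp_ratio = 4) {
  Dm <- as.integer(round(D * mlp_ratio))
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  s <- 0.02
  list(
    ln1 = list(g = rep(1, D), b = rep(0, D)),
    attn = list(Wq = rmat(D, D, s), bq = rep(0, D),
                Wk = rmat(D, D, s), bk = rep(0, D),
                Wv = rmat(D, D, s), bv = rep(0, D),
                Wo = rmat(D, D, s), bo = rep(0, D)),
    ln2 = list(g = rep(1, D), b = rep(0, D)),
    mlp = list(W1 = rmat(D, Dm, s), b1 = rep(0, Dm),
               W2 = rmat(Dm, D, s), b2 = rep(0, D))
  )
}

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = par_zeros_like(params), v = par_zeros_like(params), t = 0L)
}

# Weight decay is applied to 2-D+ arrays only (weights, embeddings), never
# to biases or layer-norm gains, matching common practice.
adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    decay <- if (!is.null(dim(p)) && length(dim(p)) >= 2L) weight_decay else 0
    p_new <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    list(p = p_new, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      pn <- p; mn <- m; vn <- v
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        pn[[i]] <- r$p; mn[[i]] <- r$m; vn[[i]] <- r$v
      }
      list(p = pn, m = mn, v = vn)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- losses -----------------------------------------------------------------

#' Mean cross-entropy of predicted class probabilities
#'
#' @param probs N x C matrix of predicted probabilities (rows on the
#'   simplex), or a single probability vector.
#' @param labels Integer class labels in `0..C-1`.
#' @return Mean negative log-likelihood (nonnegative).
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs))
    stop("labels and predictions are misaligned", call. = FALSE)
  if (any(labels < 0L | labels >= ncol(probs)))
    stop("label out of range [0, n_classes)", call. = FALSE)
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), labels + 1L)], eps)))
}

softmax_ce_grad <- function(probs, labels) {
  # gradient of mean CE w.r.t. logits, given softmax probabilities
  n <- nrow(probs)
  g <- probs
  g[cbind(seq_len(n), as.integer(labels) + 1L)] <-
    g[cbind(seq_len(n), as.integer(labels) + 1L)] - 1
  g / n
}
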