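# Shared fixtures. Everything is generated in code at test time; the tiny
# geometry below exercises every code path of the full-size model in
# seconds on one CPU.

tiny_cfg <- function(...) wavevit_tiny_config(...)

micro_cfg <- function(...) {
  wavevit_tiny_config(image_size = 16L, patch_size = 8L, embed_dim = 8L,
                      depth = 2L, heads = 2L, wefm_depth = 2L, ...)
}

tiny_spec <- function(...) synthetic_spec(image_size = 32L, ...)

rand_image <- function(n = 32L, seed = 1L) {
  set.seed(seed)
  matrix(stats::runif(n * n), n, n)
}

# Brute-force separable Haar oracle: filter rows then columns with
# low = (u + v)/sqrt(2), high = (u - v)/sqrt(2), explicit loops. Kept
# deliberately independent of the package's vectorized implementation.
oracle_haar <- function(x) {
  H <- nrow(x); W <- ncol(x)
  lo_r <- matrix(0, H / 2, W); hi_r <- matrix(0, H / 2, W)
  for (i in seq_len(H / 2)) {
    u <- x[2 * i - 1, ]; v <- x[2 * i, ]
    lo_r[i, ] <- (u + v) / sqrt(2)
    hi_r[i, ] <- (u - v) / sqrt(2)
  }
  band <- function(m, pass) {
    out <- matrix(0, nrow(m), W / 2)
    for (j in seq_len(W / 2)) {
      u <- m[, 2 * j - 1]; v <- m[, 2 * j]
      out[, j] <- if (pass == "low") (u + v) / sqrt(2) else (u - v) / sqrt(2)
    }
    out
  }
  list(ll = band(lo_r, "low"), lh = band(hi_r, "low"),
       hl = band(lo_r, "high"), hh = band(hi_r, "high"))
}

# Direct sliding-window convolution oracle (same padding), scalar loops.
oracle_conv3 <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + k[di + 2, dj + 2] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Brute-force AUC oracle: probability a random positive outranks a random
# negative, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
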