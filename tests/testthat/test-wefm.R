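test_that("single-level Haar decomposition matches the brute-force oracle", {
  set.seed(11)
  for (dims in list(c(4, 4), c(8, 6), c(16, 16))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    s <- dwt_decompose(x)
    o <- oracle_haar(x)
    for (b in c("ll", "lh", "hl", "hh")) {
      expect_equal(dim(s[[b]]), c(1L, dims[1] / 2, dims[2] / 2))
      expect_equal(s[[b]][1, , ], o[[b]], tolerance = 1e-12)
    }
  }
})

test_that("decomposition reproduces the worked 2x2 and constant examples", {
  s <- dwt_decompose(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]]
  expect_equal(as.numeric(s$ll), 5)
  expect_equal(as.numeric(s$hl), -1)
  expect_equal(as.numeric(s$lh), -2)
  expect_equal(as.numeric(s$hh), 0)

  s2 <- dwt_decompose(matrix(1, 4, 4))
  expect_true(all(s2$ll == 2))
  expect_true(all(s2$lh == 0) && all(s2$hl == 0) && all(s2$hh == 0))
})

test_that("odd spatial dimensions are rejected with the offending axis named", {
  expect_error(dwt_decompose(matrix(0, 5, 4)), "height")
  expect_error(dwt_decompose(matrix(0, 4, 7)), "width")
})

test_that("transform pair is orthonormal: reconstruction, energy, linearity", {
  set.seed(21)
  for (rep in 1:20) {
    x <- matrix(rnorm(12 * 10), 12, 10)
    y <- matrix(rnorm(12 * 10), 12, 10)
    sx <- dwt_decompose(x)
    # perfect reconstruction
    expect_lt(max(abs(idwt_reconstruct(sx)[1, , ] - x)), 1e-6)
    # energy conservation
    expect_lt(abs(wavevit:::subband_energy(sx) - sum(x^2)), 1e-6)
    # linearity per sub-band
    a <- 2.5; b <- -1.25
    sxy <- dwt_decompose(a * x + b * y)
    sy <- dwt_decompose(y)
    for (bd in c("ll", "lh", "hl", "hh"))
      expect_equal(sxy[[bd]], a * sx[[bd]] + b * sy[[bd]], tolerance = 1e-10)
  }
  # all-zero sub-bands reconstruct the zero image; constant ll inverts
  z <- lapply(list(ll = 1, lh = 1, hl = 1, hh = 1), function(i) matrix(0, 2, 2))
  expect_true(all(idwt_reconstruct(z) == 0))
  z$ll <- matrix(2, 2, 2)
  expect_true(all(abs(idwt_reconstruct(z) - 1) < 1e-12))
})

test_that("idwt_reconstruct rejects mismatched plane shapes", {
  s <- dwt_decompose(matrix(1, 4, 4))
  s$hh <- matrix(0, 3, 3)
  expect_error(idwt_reconstruct(s), "mismatch")
})

test_that("fusion stacks preserve shape and the conv layer matches a sliding-window oracle", {
  set.seed(5)
  x <- matrix(rnorm(64), 8, 8)
  s <- dwt_decompose(x)
  w <- wefm_weights(depth = 3, seed = 2)
  f <- fuse_subbands(s, w)
  for (b in c("ll", "lh", "hl", "hh"))
    expect_equal(dim(f[[b]]), dim(s[[b]]))

  # single 3x3 averaging kernel against the direct oracle on a ramp
  ramp <- matrix(seq_len(16) / 16, 4, 4)
  k <- matrix(1 / 9, 3, 3)
  got <- wavevit:::conv2d_forward(array(ramp, c(1, 4, 4)),
                                  array(k, c(3, 3, 1, 1)), 0)
  expect_equal(got[1, , ], oracle_conv3(ramp, k), tolerance = 1e-12)
})

test_that("channel mismatch between weights and sub-band raises a configuration error", {
  s <- dwt_decompose(array(rnorm(2 * 4 * 4), c(2, 4, 4)))
  w <- wefm_weights(channels = 1L, depth = 2)
  expect_error(fuse_subbands(s, w), "channel mismatch")
})

test_that("identity-initialized stacks make wefm_forward the identity map", {
  set.seed(9)
  x <- matrix(rnorm(144), 12, 12)
  for (depth in c(3L, 4L)) {
    w <- wefm_identity_weights(depth = depth)
    expect_lt(max(abs(wefm_forward(x, w)[1, , ] - x)), 1e-6)
  }
})

test_that("wefm_forward preserves shape and is deterministic", {
  w <- wefm_weights(depth = 4, seed = 7)
  x <- rand_image(32, seed = 3)
  y1 <- wefm_forward(x, w)
  y2 <- wefm_forward(x, w)
  expect_equal(dim(y1), c(1L, 32L, 32L))
  expect_identical(y1, y2)
})

test_that("wefm backward agrees with numerical gradients", {
  ns <- asNamespace("wavevit")
  set.seed(13)
  x <- matrix(rnorm(64), 8, 8)
  w <- wefm_weights(depth = 2, seed = 4)
  fwd <- wefm_forward(x, w, cache = TRUE)
  dout <- array(rnorm(64), c(1, 8, 8))
  bk <- ns$wefm_backward(dout, fwd, w)
  loss_of <- function(stacks) {
    w2 <- w; w2$stacks <- stacks
    sum(wefm_forward(x, w2) * dout)
  }
  flat <- ns$par_flatten(w$stacks)
  gflat <- ns$par_flatten(bk$grads)
  set.seed(3)
  for (i in sample(length(flat), 12)) {
    eps <- 1e-6
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    num <- (loss_of(ns$par_unflatten(w$stacks, vp)) -
            loss_of(ns$par_unflatten(w$stacks, vm))) / (2 * eps)
    expect_lt(abs(num - gflat[i]) / max(1e-8, abs(num) + abs(gflat[i])), 1e-4)
  }
})
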