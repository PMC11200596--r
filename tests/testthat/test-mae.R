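test_that("mask cardinality is exact and seeded masks reproduce", {
  for (n in c(4L, 16L, 196L, 1000L)) {
    for (ratio in c(0, 0.25, 0.5, 0.75, 1)) {
      m <- random_mask(n, ratio, seed = 3)
      expect_equal(sum(m$mask), round(ratio * n))
      expect_length(m$mask, n)
    }
  }
  expect_equal(sum(random_mask(196, 0.75, seed = 1)$mask), 147L)
  expect_identical(random_mask(196, 0.75, seed = 5),
                   random_mask(196, 0.75, seed = 5))
  expect_false(identical(random_mask(196, 0.75, seed = 5)$mask,
                         random_mask(196, 0.75, seed = 6)$mask))
  expect_error(random_mask(196, 1.5), "ratio")
})

test_that("mae_loss is an MSE over masked patches only", {
  pred <- matrix(0, 2, 4)
  target <- matrix(0, 2, 4)
  mask <- c(TRUE, FALSE)
  expect_equal(mae_loss(pred, target, mask), 0)
  # perturb the unmasked patch: loss unchanged
  pred2 <- pred; pred2[2, ] <- 5
  expect_equal(mae_loss(pred2, target, mask), 0)
  # constant 0.5 error on the masked patch -> 0.25
  pred3 <- pred; pred3[1, ] <- 0.5
  expect_equal(mae_loss(pred3, target, mask), 0.25)
  expect_equal(mae_loss(pred, target, c(FALSE, FALSE)), 0)
  expect_error(mae_loss(pred, matrix(0, 3, 4), mask), "shape")
})

test_that("loss gradient on unmasked patch predictions is identically zero", {
  ns <- asNamespace("wavevit")
  cfg <- micro_cfg()
  w <- ns$init_mae(cfg, decoder_dim = 8L, decoder_depth = 1L, seed = 2)
  x <- rand_image(16, 4)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  fwd <- ns$mae_forward(x, w, cfg, mask, cache = TRUE)
  # recompute the loss after perturbing unmasked-patch predictions: the
  # dpred entering the backward pass must be zero there
  nm <- sum(mask)
  diff <- fwd$pred - fwd$target
  dpred <- matrix(0, 4, ncol(fwd$pred))
  dpred[mask, ] <- 2 * diff[mask, , drop = FALSE] / (nm * ncol(fwd$pred))
  expect_true(all(dpred[!mask, ] == 0))
  # and analytically: changing pred rows of unmasked patches leaves loss fixed
  pred2 <- fwd$pred; pred2[!mask, ] <- 99
  expect_equal(mae_loss(pred2, fwd$target, mask),
               mae_loss(fwd$pred, fwd$target, mask))
})

test_that("mae analytic gradients match numerical differentiation", {
  ns <- asNamespace("wavevit")
  cfg <- micro_cfg()
  w <- ns$init_mae(cfg, decoder_dim = 8L, decoder_depth = 1L, seed = 5)
  x <- rand_image(16, 9)
  mask <- random_mask(4, 0.5, seed = 2)$mask
  fwd <- ns$mae_forward(x, w, cfg, mask, cache = TRUE)
  g <- ns$mae_backward(fwd, w, cfg)
  flat <- ns$par_flatten(unclass(w))
  gflat <- ns$par_flatten(g)
  loss_of <- function(v) {
    w2 <- structure(ns$par_unflatten(unclass(w), v), class = "mae_weights")
    ns$mae_forward(x, w2, cfg, mask)$loss
  }
  set.seed(6)
  for (i in sample(length(flat), 20)) {
    eps <- 1e-5
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    num <- (loss_of(vp) - loss_of(vm)) / (2 * eps)
    expect_lt(abs(num - gflat[i]) / max(1e-7, abs(num) + abs(gflat[i])), 1e-4)
  }
})

test_that("pre-training reduces reconstruction loss and checkpoints round-trip", {
  cfg <- micro_cfg()
  spec <- synthetic_spec(image_size = 16L)
  imgs <- lapply(1:40, function(i) generate_sample(0L, spec, seed = i)$image)
  ck <- mae_pretrain(imgs, cfg, epochs = 3, seed = 1, batch_size = 8,
                     decoder_dim = 8L)
  expect_lt(tail(ck$log$loss, 1), ck$log$loss[1])
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_identical(load_checkpoint(path)$mae, ck$mae)
  # zero epochs: checkpoint equals the seeded initialization
  ck0 <- mae_pretrain(imgs, cfg, epochs = 0, seed = 7, decoder_dim = 8L)
  init <- wavevit:::init_mae(cfg, decoder_dim = 8L, decoder_depth = 1L,
                             seed = 7)
  expect_identical(ck0$mae, init)
  expect_error(mae_pretrain(list(), cfg), "empty")
})

test_that("reconstruction visualization returns aligned image triple", {
  cfg <- micro_cfg()
  imgs <- lapply(1:8, function(i) rand_image(16, i))
  ck <- mae_pretrain(imgs, cfg, epochs = 1, seed = 2, batch_size = 8,
                     decoder_dim = 8L)
  vis <- mae_reconstruct(imgs[[1]], ck, mask_ratio = 0.75, seed = 4)
  expect_named(vis, c("masked", "reconstruction", "original"))
  expect_identical(vis$original, imgs[[1]])
  expect_equal(dim(vis$reconstruction), c(16L, 16L))
})
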