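test_that("labeled subset selection is exact, seeded, and strips labels", {
  ds <- generate_dataset(30, tiny_spec(), seed = 3)
  sub <- select_labeled_subset(ds, 25L, seed = 1)
  expect_length(sub$labeled$items, 100L)
  labs <- vapply(sub$labeled$items, `[[`, integer(1), "label")
  expect_equal(as.integer(table(labs)), rep(25L, 4))
  expect_length(sub$unlabeled, 20L)
  expect_true(is.matrix(sub$unlabeled[[1]]))
  sub2 <- select_labeled_subset(ds, 25L, seed = 1)
  expect_identical(sub$labeled, sub2$labeled)
  # per_class = 0: everything unlabeled
  sub0 <- select_labeled_subset(ds, 0L, seed = 1)
  expect_length(sub0$labeled$items, 0L)
  expect_length(sub0$unlabeled, 120L)
  expect_error(select_labeled_subset(ds, 31L, seed = 1), "has 30 members")
})

test_that("supervised cross-entropy matches closed forms", {
  u <- matrix(0.25, 2, 4)
  expect_equal(supervised_loss(u, c(0L, 3L)), log(4), tolerance = 1e-9)
  # near-one-hot confident prediction -> loss near 0
  conf <- matrix(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 1)
  expect_lt(supervised_loss(conf, 0L), 1e-8)
  # batch of two with probabilities 0.5 and 0.25 on the true classes
  p <- rbind(c(0.5, 0.3, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(supervised_loss(p, c(0L, 1L)),
               mean(c(-log(0.5), -log(0.25))), tolerance = 1e-9)
  expect_equal(supervised_loss(p, c(0L, 1L)), 1.0397, tolerance = 1e-4)
  expect_error(supervised_loss(p, c(0L, 4L)), "out of range")
})

test_that("threshold state initializes at 1/C and follows the hand EMA", {
  st <- threshold_state(4L, ema_decay = 0.7)
  expect_equal(st$global_tau, 0.25)
  expect_equal(st$class_probs, rep(0.25, 4))
  batch <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.4, 0.3, 0.2, 0.1))
  st1 <- update_thresholds(st, batch)
  m <- mean(c(0.7, 0.4))
  expect_equal(st1$global_tau, 0.7 * 0.25 + 0.3 * m, tolerance = 1e-9)
  expect_equal(st1$class_probs, 0.7 * rep(0.25, 4) + 0.3 * colMeans(batch),
               tolerance = 1e-9)
  # ema_decay = 1 leaves the state unchanged by any batch
  stf <- threshold_state(4L, ema_decay = 1)
  expect_equal(update_thresholds(stf, batch)$global_tau, 0.25)
  # empty batch is a no-op
  expect_identical(update_thresholds(st, matrix(0, 0, 4)), st)
})

test_that("pseudo-labels take the argmax with lowest-index ties and gate by threshold", {
  st <- threshold_state(4L)
  st$global_tau <- 0.5
  st$class_probs <- rep(0.25, 4)  # equal modulation: tau_c = 0.5
  pl <- pseudo_label(c(0.9, 0.05, 0.03, 0.02), st)
  expect_equal(pl$labels, 0L)
  expect_true(pl$mask)
  # all below threshold
  pl2 <- pseudo_label(matrix(0.25, 2, 4), st)
  expect_false(any(pl2$mask))
  # exact tie at argmax -> lowest class index
  pl3 <- pseudo_label(c(0.4, 0.4, 0.1, 0.1), st)
  expect_equal(pl3$labels, 0L)
  # empty batch
  pl4 <- pseudo_label(matrix(0, 0, 4), st)
  expect_length(pl4$labels, 0L)
})

test_that("unsupervised loss averages over masked-in samples only", {
  p <- rbind(c(0.5, 0.3, 0.1, 0.1), c(0.1, 0.6, 0.2, 0.1))
  expect_equal(unsupervised_loss(p, c(0L, 1L), c(FALSE, FALSE)), 0)
  expect_equal(unsupervised_loss(p, c(0L, 1L), c(TRUE, TRUE)),
               cross_entropy(p, c(0L, 1L)), tolerance = 1e-12)
  expect_equal(unsupervised_loss(p, c(0L, 1L), c(TRUE, FALSE)), -log(0.5),
               tolerance = 1e-9)
  expect_error(unsupervised_loss(p, c(0L), c(TRUE, FALSE)), "misaligned")
})

test_that("global threshold stays in [1/C, 1] over random update sequences", {
  set.seed(77)
  for (rep in 1:50) {
    st <- threshold_state(4L, ema_decay = runif(1, 0.5, 0.999))
    for (i in 1:40) {
      n <- sample(1:8, 1)
      raw <- matrix(rexp(n * 4), n, 4)
      st <- update_thresholds(st, raw / rowSums(raw))
      expect_gte(st$global_tau, 0.25 - 1e-12)
      expect_lte(st$global_tau, 1 + 1e-12)
      expect_true(all(st$class_probs >= 0 & st$class_probs <= 1))
    }
  }
})

test_that("raising thresholds never admits more pseudo-labels", {
  set.seed(8)
  probs <- matrix(rexp(40), 10, 4)
  probs <- probs / rowSums(probs)
  st <- threshold_state(4L)
  st$class_probs <- rep(0.25, 4)
  n_pass <- sapply(seq(0.25, 1, by = 0.05), function(tau) {
    st$global_tau <- tau
    sum(pseudo_label(probs, st)$mask)
  })
  expect_true(all(diff(n_pass) <= 0))
})

test_that("train_step reports total = ls + lu and handles empty unlabeled batches", {
  ns <- asNamespace("wavevit")
  cfg <- micro_cfg()
  w <- wavevit_init(cfg, seed = 4)
  st <- threshold_state(4L, ema_decay = 0.9)
  opt <- ns$adamw_init(ns$trainable_params(w))
  lb <- list(images = lapply(1:4, function(i) rand_image(16, i)),
             labels = c(0L, 1L, 2L, 3L))
  r0 <- train_step(w, cfg, lb, list(), st, opt, augment_data = FALSE)
  expect_equal(r0$report$total, r0$report$ls)
  expect_equal(r0$report$lu, 0)
  ub <- lapply(5:8, function(i) rand_image(16, i))
  r1 <- train_step(w, cfg, lb, ub, st, opt, augment_data = FALSE)
  expect_equal(r1$report$total, r1$report$ls + r1$report$lu)
  expect_gte(r1$report$utilization, 0)
  expect_lte(r1$report$utilization, 1)
})

test_that("the supervised loss decreases over steps on a separable toy task", {
  ns <- asNamespace("wavevit")
  cfg <- micro_cfg()
  set.seed(15)
  mk <- function(cl) {
    x <- matrix(runif(256, 0, 0.2), 16, 16)
    quad <- list(1:8, 9:16)
    x[quad[[cl %/% 2 + 1]], quad[[cl %% 2 + 1]]] <-
      x[quad[[cl %/% 2 + 1]], quad[[cl %% 2 + 1]]] + 0.8
    x
  }
  lb <- list(images = lapply(0:7, function(i) mk(i %% 4L)),
             labels = as.integer(0:7 %% 4L))
  w <- wavevit_init(cfg, seed = 2)
  st <- threshold_state(4L, ema_decay = 0.9)
  opt <- ns$adamw_init(ns$trainable_params(w))
  ls_trace <- numeric(50)
  for (i in 1:50) {
    r <- train_step(w, cfg, lb, list(), st, opt, lr = 2e-3, seed = i,
                    augment_data = FALSE)
    w <- r$weights; st <- r$state; opt <- r$opt
    ls_trace[i] <- r$report$ls
  }
  expect_lt(mean(tail(ls_trace, 5)), mean(head(ls_trace, 5)))
})

test_that("train_supervised with zero epochs leaves weights unchanged and converges on a separable toy", {
  cfg <- micro_cfg()
  ds <- generate_dataset(2, synthetic_spec(image_size = 16L), seed = 5)
  w <- wavevit_init(cfg, seed = 3)
  r0 <- train_supervised(w, cfg, ds, epochs = 0)
  expect_identical(r0$weights, w)
  # linearly separable toy: bright left vs bright right half
  set.seed(20)
  mk <- function(cl) {
    x <- matrix(runif(256, 0, 0.2), 16, 16)
    if (cl == 0L) x[, 1:8] <- x[, 1:8] + 0.8 else x[, 9:16] <- x[, 9:16] + 0.8
    x
  }
  items <- lapply(1:10, function(i) list(image = mk(i %% 2L),
                                         label = i %% 2L, path = ""))
  toy <- wavevit:::new_dataset(items, c("a", "b", "c", "d"))
  r <- train_supervised(wavevit_init(cfg, seed = 3), cfg, toy, epochs = 15,
                        batch_size = 5, lr = 2e-3, seed = 4, augment_p = 0)
  expect_equal(evaluate_accuracy(r$weights, cfg, toy), 1.0)
})
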