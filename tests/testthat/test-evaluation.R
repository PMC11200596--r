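test_that("confusion matrix counts and conserves marginals", {
  cm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), 4L)
  expect_equal(cm[1, 1], 1L)
  expect_equal(cm[1, 2], 1L)
  expect_equal(cm[2, 2], 1L)
  expect_equal(sum(cm), 3L)
  # perfect predictions -> diagonal
  y <- rep(0:3, 5)
  cmd <- confusion_matrix(y, y, 4L)
  expect_true(all(cmd[row(cmd) != col(cmd)] == 0L))
  expect_equal(diag(cmd), setNames(rep(5L, 4), 0:3))
  # empty input -> zero matrix; marginal conservation on random labels
  expect_true(all(confusion_matrix(integer(0), integer(0), 4L) == 0L))
  set.seed(3)
  for (rep in 1:10) {
    t <- sample(0:3, 50, replace = TRUE)
    p <- sample(0:3, 50, replace = TRUE)
    cm <- confusion_matrix(t, p, 4L)
    expect_equal(as.integer(rowSums(cm)), as.integer(table(factor(t, 0:3))))
    expect_equal(as.integer(colSums(cm)), as.integer(table(factor(p, 0:3))))
  }
  expect_error(confusion_matrix(c(0L, 4L), c(0L, 0L), 4L), "out of range")
})

test_that("one-vs-rest metrics match hand arithmetic", {
  # binarized counts TP=8 FN=2 TN=9 FP=1 embedded in a 2-class matrix
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  m <- one_vs_rest_metrics(cm, 0L)
  expect_equal(unname(m), c(80, 90, 85))
  # perfect matrix
  perfect <- diag(c(5L, 5L, 5L, 5L))
  for (cl in 0:3)
    expect_equal(unname(one_vs_rest_metrics(perfect, cl)), c(100, 100, 100))
  # empty support is flagged, not silently zero
  cm0 <- matrix(c(0L, 0L, 3L, 4L), 2, 2, byrow = TRUE)
  expect_warning(m0 <- one_vs_rest_metrics(cm0, 0L), "no support")
  expect_true(is.na(m0["sensitivity"]))
})

test_that("macro mean reproduces the reference per-class accuracy table convention", {
  expect_equal(macro_mean(c(98.70, 93.32, 87.39, 86.46)), 91.4675,
               tolerance = 1e-9)
  expect_equal(round(macro_mean(c(98.70, 93.32, 87.39, 86.46)), 2), 91.47)
  # and for the sensitivity column of the same table
  expect_equal(round(macro_mean(c(98.04, 90.06, 78.33, 51.95)), 2), 79.60)
})

test_that("AUC equals the brute-force pairwise rank oracle", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(1, 1, 0, 0)), 0.0)
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), 2)  # rounding forces occasional ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    # permutation invariance
    perm <- sample(n)
    expect_equal(roc_auc(scores[perm], labels[perm]),
                 roc_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "undefined")
})

test_that("cross-validation aggregation uses sample sd and keeps the macro identity", {
  fold <- function(acc) {
    per <- data.frame(class = 0:3, sensitivity = acc, specificity = acc,
                      accuracy = acc, auc = acc / 100)
    structure(list(cm = diag(4L), per_class = per,
                   macro = c(sensitivity = acc, specificity = acc,
                             accuracy = acc, auc = acc / 100),
                   top1 = 1), class = "fold_metrics")
  }
  rep2 <- crossval_report(list(fold(80), fold(90)))
  expect_equal(unname(rep2$macro_mean["accuracy"]), 85)
  expect_equal(unname(rep2$macro_sd["accuracy"]), sd(c(80, 90)))
  expect_equal(round(unname(rep2$macro_sd["accuracy"]), 2), 7.07)
  ident <- crossval_report(list(fold(77), fold(77), fold(77)))
  expect_equal(unname(ident$macro_sd["accuracy"]), 0)
  # macro-mean identity for a real evaluation
  ds <- generate_dataset(4, tiny_spec(), seed = 5)
  cfg <- tiny_cfg()
  w <- wavevit_init(cfg, seed = 1)
  fm <- evaluate_model(w, cfg, ds)
  expect_equal(unname(fm$macro["accuracy"]),
               mean(fm$per_class$accuracy), tolerance = 1e-9)
  expect_equal(sum(fm$cm), 16L)
})

test_that("metrics are invariant to sample order", {
  set.seed(4)
  t <- sample(0:3, 30, replace = TRUE)
  p <- sample(0:3, 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(confusion_matrix(t, p, 4L), confusion_matrix(t[perm], p[perm], 4L))
})

test_that("gradcam maps are normalized, image-shaped, and localize a bright patch", {
  cfg <- micro_cfg()
  w <- wavevit_init(cfg, seed = 6)
  x <- rand_image(16, 2)
  hm <- gradcam(w, cfg, x, 1L)
  expect_equal(dim(hm), c(16L, 16L))
  expect_true(min(hm) >= 0 && max(hm) <= 1)
  expect_error(gradcam(w, cfg, x, 7L), "out of range")

  # constructed localization oracle: a hand-built 1-block model whose
  # attention keys grow with patch brightness, so it attends to the single
  # bright patch; the heatmap argmax must land inside that patch
  cfg1 <- wavevit_config(image_size = 16L, patch_size = 8L, embed_dim = 8L,
                         depth = 1L, heads = 1L, n_classes = 4L,
                         wefm_placement = "none")
  w1 <- wavevit:::par_map(wavevit_init(cfg1, seed = 1), function(p) p * 0)
  class(w1) <- "wavevit_weights"
  w1$encoder$We[, 1] <- 1 / 64          # token channel 1 = mean brightness
  w1$encoder$be[2] <- 0.5               # constant reference channel
  w1$encoder$cls[1, 2] <- 0.5           # reference channel in the cls stream
                                        # (keeps the final norm non-degenerate)
  blk <- w1$encoder$blocks[[1]]
  blk$ln1$g <- rep(1, 8)
  blk$ln2$g <- rep(1, 8)
  blk$attn$bq <- c(4, rep(0, 7))        # constant query, sharpness 4
  blk$attn$Wk[1, 1] <- 1                # key = normalized brightness
  blk$attn$Wv[1, 1] <- 1
  blk$attn$Wo[1, 1] <- 1
  w1$encoder$blocks[[1]] <- blk
  w1$encoder$lnf$g <- rep(1, 8)
  w1$head$W[1, ] <- c(1, -1, -1, -1)    # class 0 reads the attended value
  for (pid in 0:3) {
    probe <- matrix(0.05, 16, 16)
    rows <- if (pid %in% c(0, 1)) 1:8 else 9:16
    cols <- if (pid %% 2 == 0) 1:8 else 9:16
    probe[rows, cols] <- 0.9
    hm1 <- gradcam(w1, cfg1, probe, 0L)
    peak <- which(hm1 == max(hm1), arr.ind = TRUE)[1, ]
    expect_true(peak["row"] %in% rows && peak["col"] %in% cols)
  }
  # uniform input -> degenerate normalization handled as all-zero map
  expect_true(all(gradcam(w1, cfg1, matrix(0.3, 16, 16), 0L) == 0))
})
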