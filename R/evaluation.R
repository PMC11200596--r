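# Evaluation: confusion matrices, one-vs-rest clinical metrics, ROC/AUC,
# cross-validated aggregation, Grad-CAM relevance maps.
#
# Per-class "accuracy" here is ONE-VS-REST BINARY accuracy — the class
# against all others pooled — not top-1 multiclass accuracy. This is the
# convention under which a table of per-class accuracies and their macro
# mean are mutually consistent, and it is the convention used throughout
# this package's reports.

#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes (0-based labels).
#'
#' @param true_labels,predicted_labels Aligned integer vectors in
#'   `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @return n_classes x n_classes integer matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors are misaligned", call. = FALSE)
  all_l <- c(true_labels, predicted_labels)
  if (length(all_l) && (min(all_l) < 0L || max(all_l) >= n_classes))
    stop("label out of range [0, n_classes)", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels)) {
    r <- true_labels[i] + 1L; cc <- predicted_labels[i] + 1L
    cm[r, cc] <- cm[r, cc] + 1L
  }
  dimnames(cm) <- list(true = 0:(n_classes - 1L),
                       predicted = 0:(n_classes - 1L))
  cm
}

#' One-vs-rest sensitivity, specificity and accuracy for one class
#'
#' Binarizes the confusion matrix class-vs-rest: SN = TP/(TP+FN),
#' SP = TN/(TN+FP), ACC = (TP+TN)/total, reported as percentages. A class
#' with no support yields `NA` sensitivity with a warning rather than a
#' silent zero.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param class_id 0-based class index.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)` in
#'   percent.
#' @export
one_vs_rest_metrics <- function(cm, class_id) {
  i <- class_id + 1L
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  sn <- if (tp + fn == 0) {
    warning(sprintf("class %d has no support; sensitivity undefined", class_id),
            call. = FALSE)
    NA_real_
  } else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / sum(cm)
  c(sensitivity = sn, specificity = sp, accuracy = acc)
}

#' Macro mean of per-class metric values
#'
#' The arithmetic average across classes — the "Means" row convention of a
#' per-class metrics table.
#' @param values Numeric vector of per-class values.
#' @export
macro_mean <- function(values) mean(values)

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with tied scores contributing 1/2 per tied
#' pair.
#'
#' @param scores Numeric prediction scores.
#' @param binary_labels 0/1 (or logical) labels; needs at least one of
#'   each.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, binary_labels) {
  y <- as.integer(binary_labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a labeled dataset
#'
#' Runs the classifier over every item and assembles the confusion matrix,
#' per-class one-vs-rest metrics, one-vs-rest AUC per class on the softmax
#' scores, and the macro means.
#'
#' @param weights,cfg Model weights and config.
#' @param dataset A `wavevit_dataset`.
#' @return List of class `fold_metrics`: `cm`, `per_class` (data frame with
#'   class, sensitivity, specificity, accuracy, auc), `macro` (named
#'   vector), `top1` (multiclass accuracy, fraction).
#' @export
evaluate_model <- function(weights, cfg, dataset) {
  labs <- dataset_labels(dataset)
  probs <- t(vapply(dataset_images(dataset), function(im)
    classify(im, weights, cfg)$probs, numeric(cfg$n_classes)))
  preds <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(labs, preds, cfg$n_classes)
  per <- lapply(0:(cfg$n_classes - 1L), function(cl) {
    m <- one_vs_rest_metrics(cm, cl)
    auc <- tryCatch(roc_auc(probs[, cl + 1L], as.integer(labs == cl)),
                    error = function(e) NA_real_)
    data.frame(class = cl, sensitivity = m["sensitivity"],
               specificity = m["specificity"], accuracy = m["accuracy"],
               auc = auc, row.names = NULL)
  })
  per <- do.call(rbind, per)
  macro <- c(sensitivity = macro_mean(per$sensitivity),
             specificity = macro_mean(per$specificity),
             accuracy = macro_mean(per$accuracy),
             auc = macro_mean(per$auc))
  structure(list(cm = cm, per_class = per, macro = macro,
                 top1 = mean(preds == labs)),
            class = "fold_metrics")
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' Mean and sample (n-1) standard deviation of every per-class metric and
#' of the macro means across folds.
#'
#' @param per_fold_metrics List of `fold_metrics` from [evaluate_model()],
#'   one per fold.
#' @return List of class `crossval_report`: `per_class` (data frame with
#'   mean/sd columns), `macro_mean`, `macro_sd`, `n_folds`.
#' @export
crossval_report <- function(per_fold_metrics) {
  stopifnot(length(per_fold_metrics) >= 1L)
  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  classes <- per_fold_metrics[[1]]$per_class$class
  per <- lapply(classes, function(cl) {
    rows <- lapply(per_fold_metrics, function(f)
      f$per_class[f$per_class$class == cl, metrics])
    vals <- do.call(rbind, rows)
    out <- data.frame(class = cl)
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(vals[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(vals) > 1) stats::sd(vals[[m]]) else 0
    }
    out
  })
  macro <- do.call(rbind, lapply(per_fold_metrics, function(f) f$macro))
  structure(list(per_class = do.call(rbind, per),
                 macro_mean = colMeans(macro),
                 macro_sd = apply(macro, 2, function(v)
                   if (length(v) > 1) stats::sd(v) else 0),
                 n_folds = length(per_fold_metrics)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d folds (percent, mean +/- sd)\n", x$n_folds))
  print(x$per_class, digits = 4)
  cat(sprintf("macro: SN %.2f +/- %.2f  SP %.2f +/- %.2f  ACC %.2f +/- %.2f  AUC %.3f\n",
              x$macro_mean["sensitivity"], x$macro_sd["sensitivity"],
              x$macro_mean["specificity"], x$macro_sd["specificity"],
              x$macro_mean["accuracy"], x$macro_sd["accuracy"],
              x$macro_mean["auc"]))
  invisible(x)
}

#' Grad-CAM relevance heatmap for a target class
#'
#' Gradients of the target-class logit with respect to the token
#' activations entering the final transformer block (class token excluded)
#' are averaged per channel into weights, the weighted activation sum is
#' rectified, reshaped to the patch grid, bilinearly upsampled to image
#' size and min-max normalized. The gradient is taken at the final block's
#' input because, under class-token pooling, the logit depends on patch
#' tokens only through that block's attention. A degenerate (constant) map
#' returns zeros.
#'
#' @param weights,cfg Model weights and config.
#' @param image Image matrix.
#' @param target_class 0-based class index.
#' @return `image_size` x `image_size` matrix in `[0, 1]`.
#' @export
gradcam <- function(weights, cfg, image, target_class) {
  if (target_class < 0L || target_class >= cfg$n_classes)
    stop("target_class out of range", call. = FALSE)
  fwd <- model_forward(image, weights, cfg, cache = TRUE)
  run <- fwd$cache$run
  # d logit_t / d pooled
  dlogit <- weights$head$W[, target_class + 1L]
  N1 <- n_patches(cfg) + 1L
  dtok_out <- matrix(0, N1, cfg$embed_dim)
  if (cfg$pool == "cls") dtok_out[1L, ] <- dlogit
  else dtok_out[-1L, ] <- matrix(rep(dlogit / (N1 - 1L), N1 - 1L),
                                 N1 - 1L, cfg$embed_dim, byrow = TRUE)
  lb <- layernorm_backward(dtok_out, run$lnf, weights$encoder$lnf$g)
  last <- length(run$blocks)
  bb <- block_backward(lb$dx, run$blocks[[last]],
                       weights$encoder$blocks[[last]], cfg$heads)
  grad_tokens <- bb$dx[-1L, , drop = FALSE]     # at final block input
  act_tokens <- run$blocks[[last]]$x_in[-1L, , drop = FALSE]
  alpha <- colMeans(grad_tokens)
  # center activations per channel across the grid before weighting, so
  # constant feature channels cannot bias the rectification
  act_c <- sweep(act_tokens, 2, colMeans(act_tokens))
  cam <- pmax(act_c %*% alpha, 0)
  g <- cfg$image_size %/% cfg$patch_size
  cam_grid <- matrix(cam, g, g, byrow = TRUE)   # patches are row-major
  up <- resize(cam_grid, cfg$image_size)
  rng <- range(up)
  if (diff(rng) < 1e-12) return(matrix(0, cfg$image_size, cfg$image_size))
  (up - rng[1]) / diff(rng)
}

#' Export a metrics report as JSON and CSV
#'
#' @param report A `crossval_report`.
#' @param dir Output directory; writes `metrics.json` and
#'   `metrics_per_class.csv`.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(per_class = report$per_class,
                            macro_mean = as.list(report$macro_mean),
                            macro_sd = as.list(report$macro_sd),
                            n_folds = report$n_folds),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_class,
                   file.path(dir, "metrics_per_class.csv"), row.names = FALSE)
  invisible(dir)
}
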