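# Semi-supervised training with self-adaptive pseudo-label thresholds.
#
# Labeled images contribute a supervised cross-entropy Ls. Each unlabeled
# image is viewed twice: the prediction on the weakly augmented view
# proposes a pseudo-label, which is kept only if its confidence clears a
# class-modulated threshold; kept pseudo-labels supervise the strongly
# augmented view through an unsupervised cross-entropy Lu. The joint
# objective is L = Ls + Lu (unweighted sum). Thresholds self-adapt: a
# global level tracks the EMA of the batch-mean maximum confidence
# (initialized at 1/C) and is modulated per class by the EMA of the mean
# predicted distribution, as in self-adaptive-threshold SSL.

#' Select a labeled subset and strip the rest
#'
#' Draws `per_class` items per class uniformly (seeded) from a training
#' fold; everything else loses its label and becomes the unlabeled pool.
#'
#' @param dataset A `wavevit_dataset` (the training fold).
#' @param per_class Labeled samples to keep per class.
#' @param seed Integer seed.
#' @return List with `labeled` (a `wavevit_dataset`) and `unlabeled`
#'   (list of image matrices).
#' @export
select_labeled_subset <- function(dataset, per_class, seed = 0L) {
  labels <- dataset_labels(dataset)
  classes <- seq_along(dataset$class_names) - 1L
  set.seed(seed)
  chosen <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < per_class)
      stop(sprintf("class '%s' has %d members, need %d",
                   dataset$class_names[cl + 1L], length(idx), per_class),
           call. = FALSE)
    if (per_class > 0L)
      chosen <- c(chosen, sample(idx, per_class))
  }
  rest <- setdiff(seq_along(dataset$items), chosen)
  labeled <- new_dataset(dataset$items[chosen], dataset$class_names)
  unlabeled <- lapply(dataset$items[rest], `[[`, "image")
  list(labeled = labeled, unlabeled = unlabeled)
}

#' Supervised cross-entropy loss
#'
#' Mean cross-entropy of predicted probabilities against integer labels.
#' @param predictions N x C probability matrix.
#' @param labels Integer labels in `0..C-1`.
#' @export
supervised_loss <- function(predictions, labels) {
  cross_entropy(predictions, labels)
}

#' Initialize the self-adaptive threshold state
#'
#' The global threshold starts at `1/n_classes` and the per-class running
#' mean prediction at the uniform distribution.
#'
#' @param n_classes Number of classes.
#' @param ema_decay EMA decay in `(0, 1)` (default 0.999).
#' @return List of class `threshold_state`.
#' @export
threshold_state <- function(n_classes = 4L, ema_decay = 0.999) {
  stopifnot(ema_decay > 0, ema_decay <= 1)
  structure(list(global_tau = 1 / n_classes,
                 class_probs = rep(1 / n_classes, n_classes),
                 ema_decay = ema_decay, n_classes = as.integer(n_classes)),
            class = "threshold_state")
}

#' Per-class confidence thresholds
#'
#' The global level modulated by each class's running mean confidence:
#' `tau_c = global_tau * class_probs[c] / max(class_probs)`.
#' @param state A [threshold_state()].
#' @export
class_thresholds <- function(state) {
  state$global_tau * state$class_probs / max(state$class_probs)
}

#' Update thresholds from a batch of weak-view predictions
#'
#' `global_tau <- d * global_tau + (1 - d) * mean(max prob)` and
#' `class_probs <- d * class_probs + (1 - d) * colMeans(probs)` with
#' `d = ema_decay`. An empty batch leaves the state unchanged.
#'
#' @param state A [threshold_state()].
#' @param weak_predictions N x C probability matrix.
#' @export
update_thresholds <- function(state, weak_predictions) {
  if (is.vector(weak_predictions))
    weak_predictions <- matrix(weak_predictions, nrow = 1)
  if (is.null(weak_predictions) || nrow(weak_predictions) == 0L) return(state)
  d <- state$ema_decay
  state$global_tau <- d * state$global_tau +
    (1 - d) * mean(apply(weak_predictions, 1, max))
  state$class_probs <- d * state$class_probs +
    (1 - d) * colMeans(weak_predictions)
  state
}

#' Pseudo-labels with confidence gating
#'
#' Label = argmax of each weak-view prediction (ties to the lowest class
#' index); the mask is `TRUE` where the maximum probability reaches the
#' class-modulated threshold of the predicted class.
#'
#' @param weak_predictions N x C probability matrix (N may be 0).
#' @param state A [threshold_state()].
#' @return List with `labels` (0-based) and `mask` (logical).
#' @export
pseudo_label <- function(weak_predictions, state) {
  if (is.vector(weak_predictions))
    weak_predictions <- matrix(weak_predictions, nrow = 1)
  if (is.null(weak_predictions) || nrow(weak_predictions) == 0L)
    return(list(labels = integer(0), mask = logical(0)))
  labels <- apply(weak_predictions, 1, which.max) - 1L
  conf <- apply(weak_predictions, 1, max)
  tau <- class_thresholds(state)
  list(labels = as.integer(labels), mask = conf >= tau[labels + 1L])
}

#' Unsupervised (pseudo-label) cross-entropy
#'
#' Mean cross-entropy of strong-view predictions against pseudo-labels over
#' the confidence-masked samples; 0 when nothing passes the threshold.
#'
#' @param strong_predictions N x C probability matrix.
#' @param labels Pseudo-labels (0-based).
#' @param confidence_mask Logical vector from [pseudo_label()].
#' @export
unsupervised_loss <- function(strong_predictions, labels, confidence_mask) {
  if (is.vector(strong_predictions))
    strong_predictions <- matrix(strong_predictions, nrow = 1)
  if (nrow(strong_predictions) != length(labels) ||
      length(labels) != length(confidence_mask))
    stop("predictions, labels and mask are misaligned", call. = FALSE)
  if (!any(confidence_mask)) return(0)
  cross_entropy(strong_predictions[confidence_mask, , drop = FALSE],
                labels[confidence_mask])
}

#' One joint semi-supervised optimization step
#'
#' Computes Ls on the labeled batch (weakly augmented), proposes
#' pseudo-labels from weak views of the unlabeled batch, updates the
#' threshold state, computes Lu on the strong views of the samples passing
#' the threshold, and takes one AdamW step on L = Ls + Lu.
#'
#' @param weights Model `wavevit_weights`.
#' @param cfg The model's [wavevit_config()].
#' @param labeled_batch List with `images` (list of matrices) and `labels`.
#' @param unlabeled_batch List of image matrices (may be empty).
#' @param state A [threshold_state()].
#' @param opt AdamW state from [adamw_init()] over the trainable
#'   parameters.
#' @param lr Learning rate.
#' @param seed Seed for this step's augmentation draws.
#' @param augment_data Apply the weak/strong augmentation views (disable
#'   for deterministic unit tests).
#' @return List with updated `weights`, `state`, `opt`, and `report`
#'   (`ls`, `lu`, `total`, `utilization`, `global_tau`).
#' @export
train_step <- function(weights, cfg, labeled_batch, unlabeled_batch, state,
                       opt, lr = 1e-3, seed = 0L, augment_data = TRUE) {
  imgs <- labeled_batch$images
  if (augment_data)
    imgs <- lapply(seq_along(imgs), function(i)
      weak_augment(imgs[[i]], seed = seed + i))
  sup <- batch_loss_grads(imgs, labeled_batch$labels, weights, cfg)
  ls <- sup$loss
  grads <- sup$grads
  lu <- 0; utilization <- 0
  nu <- length(unlabeled_batch)
  if (nu > 0L) {
    weak <- if (augment_data)
      lapply(seq_len(nu), function(i)
        weak_augment(unlabeled_batch[[i]], seed = seed + 1000L + i))
    else unlabeled_batch
    weak_probs <- t(vapply(weak, function(im)
      model_forward(im, weights, cfg)$probs, numeric(cfg$n_classes)))
    pl <- pseudo_label(weak_probs, state)
    state <- update_thresholds(state, weak_probs)
    utilization <- mean(pl$mask)
    if (any(pl$mask)) {
      keep <- which(pl$mask)
      strong <- if (augment_data)
        lapply(keep, function(i)
          strong_augment(unlabeled_batch[[i]], seed = seed + 2000L + i))
      else unlabeled_batch[keep]
      uns <- batch_loss_grads(strong, pl$labels[keep], weights, cfg)
      # normalize over the FULL unlabeled batch (gated samples only in the
      # numerator), the consistency-regularization convention; this keeps
      # a handful of early threshold-passers from dominating the step
      lu <- uns$loss * length(keep) / nu
      grads <- par_add_scaled(grads, uns$grads, s = length(keep) / nu)
    }
  }
  r <- adamw_step(trainable_params(weights), grads, opt, lr = lr)
  weights <- set_trainable(weights, r$params)
  list(weights = weights, state = state, opt = r$state,
       report = list(ls = ls, lu = lu, total = ls + lu,
                     utilization = utilization,
                     global_tau = state$global_tau))
}

make_batches <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Semi-supervised training loop
#'
#' Iterates [train_step()] over epochs, cycling the unlabeled pool at the
#' configured labeled:unlabeled batch ratio. Returns the trained weights,
#' the final threshold state and a per-step log.
#'
#' @param weights Initial `wavevit_weights` (typically after
#'   [load_pretrained_encoder()]).
#' @param cfg Model config.
#' @param labeled A `wavevit_dataset` (the labeled subset).
#' @param unlabeled List of image matrices.
#' @param epochs Passes over the labeled set.
#' @param batch_size Labeled images per step.
#' @param unlabeled_ratio Unlabeled:labeled batch-size ratio (default 7).
#' @param lr Learning rate.
#' @param ema_decay Threshold EMA decay.
#' @param warmup_frac Fraction of epochs trained on the labeled loss only
#'   before the pseudo-label term activates (default 0.3). Confidence
#'   gating assumes a better-than-chance labeler; without a warm-up a
#'   freshly initialized model reinforces its own noise and can collapse
#'   to a single class.
#' @param seed Master seed.
#' @param augment_data Apply augmentation views.
#' @return List with `weights`, `state`, `log` (data frame: step, ls, lu,
#'   total, utilization, global_tau).
#' @export
train_ssl <- function(weights, cfg, labeled, unlabeled, epochs = 10L,
                      batch_size = 8L, unlabeled_ratio = 7L, lr = 1e-3,
                      ema_decay = 0.999, warmup_frac = 0.3, seed = 0L,
                      augment_data = TRUE) {
  state <- threshold_state(cfg$n_classes, ema_decay)
  opt <- adamw_init(trainable_params(weights))
  imgs <- dataset_images(labeled)
  labs <- dataset_labels(labeled)
  nu_pool <- length(unlabeled)
  log <- NULL
  step <- 0L
  u_cursor <- 0L
  warmup_epochs <- floor(warmup_frac * epochs)
  for (ep in seq_len(epochs)) {
    set.seed(seed + ep)
    ord <- sample.int(length(imgs))
    for (b in make_batches(length(imgs), batch_size)) {
      step <- step + 1L
      idx <- ord[b]
      ub <- list()
      if (nu_pool > 0L && ep > warmup_epochs) {
        nu <- min(nu_pool, unlabeled_ratio * length(idx))
        sel <- ((u_cursor + seq_len(nu) - 1L) %% nu_pool) + 1L
        u_cursor <- (u_cursor + nu) %% nu_pool
        ub <- unlabeled[sel]
      }
      r <- train_step(weights, cfg,
                      list(images = imgs[idx], labels = labs[idx]),
                      ub, state, opt, lr = lr, seed = seed + 31L * step,
                      augment_data = augment_data)
      weights <- r$weights; state <- r$state; opt <- r$opt
      log <- rbind(log, data.frame(step = step, ls = r$report$ls,
                                   lu = r$report$lu, total = r$report$total,
                                   utilization = r$report$utilization,
                                   global_tau = r$report$global_tau))
    }
  }
  list(weights = weights, state = state, log = log)
}

#' Fully supervised baseline training
#'
#' Cross-entropy training on a labeled set with the same augmentation
#' pipeline, for the SSL-versus-supervised comparison. Zero epochs return
#' the weights unchanged.
#'
#' @inheritParams train_ssl
#' @param dataset A `wavevit_dataset`.
#' @param augment_p Probability of augmenting each image each epoch.
#' @return List with `weights` and `log` (epoch, loss).
#' @export
train_supervised <- function(weights, cfg, dataset, epochs = 10L,
                             batch_size = 8L, lr = 1e-3, seed = 0L,
                             augment_p = 0.5) {
  opt <- adamw_init(trainable_params(weights))
  imgs <- dataset_images(dataset)
  labs <- dataset_labels(dataset)
  log <- NULL
  step <- 0L
  for (ep in seq_len(epochs)) {
    set.seed(seed + ep)
    ord <- sample.int(length(imgs))
    ep_loss <- 0; nb <- 0L
    for (b in make_batches(length(imgs), batch_size)) {
      step <- step + 1L
      idx <- ord[b]
      batch <- lapply(seq_along(idx), function(i)
        augment(imgs[[idx[i]]], p = augment_p,
                seed = seed + 131L * step + i))
      g <- batch_loss_grads(batch, labs[idx], weights, cfg)
      r <- adamw_step(trainable_params(weights), g$grads, opt, lr = lr)
      weights <- set_trainable(weights, r$params)
      opt <- r$state
      ep_loss <- ep_loss + g$loss; nb <- nb + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb))
  }
  list(weights = weights, log = log)
}

#' Validation accuracy of a model on a dataset
#'
#' Top-1 multiclass accuracy (fraction of items whose argmax prediction
#' matches the label).
#' @param weights,cfg Model weights and config.
#' @param dataset A `wavevit_dataset`.
#' @export
evaluate_accuracy <- function(weights, cfg, dataset) {
  labs <- dataset_labels(dataset)
  preds <- vapply(dataset_images(dataset), function(im)
    classify(im, weights, cfg)$class, integer(1))
  mean(preds == labs)
}
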