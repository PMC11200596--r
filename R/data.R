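# Image ingestion, preprocessing, augmentation and fold splitting.
#
# Images are plain matrices with intensities in [0, 1]. On disk the package
# reads and writes plain-text PGM (P2), the one image format that needs no
# binary decoder; datasets are laid out directory-per-class or described by
# a CSV manifest with columns path,label.

# ---- plain-text PGM ---------------------------------------------------------

#' Read / write plain PGM (P2) images
#'
#' @param path File path.
#' @return `read_pgm`: numeric matrix scaled to `[0, 1]` by the file's
#'   maxval (8- or 16-bit).
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tokens <- scan(text = paste(txt, collapse = " "), what = character(),
                 quiet = TRUE)
  if (length(tokens) < 4L || tokens[1] != "P2")
    stop("not a plain PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  px <- as.numeric(tokens[-(1:4)])
  if (length(px) != w * h)
    stop("corrupt PGM (pixel count mismatch): ", path, call. = FALSE)
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' @rdname read_pgm
#' @param x Matrix with values in `[0, 1]`.
#' @export
write_pgm <- function(x, path) {
  q <- round(pmin(pmax(x, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

# ---- dataset container ------------------------------------------------------

new_dataset <- function(items, class_names) {
  structure(list(items = items, class_names = class_names),
            class = "wavevit_dataset")
}

#' @export
print.wavevit_dataset <- function(x, ...) {
  labs <- vapply(x$items, `[[`, integer(1), "label")
  cat(sprintf("<wavevit_dataset> %d items, %d classes\n",
              length(x$items), length(x$class_names)))
  counts <- table(factor(labs, levels = seq_along(x$class_names) - 1L,
                         labels = x$class_names))
  print(counts)
  invisible(x)
}

dataset_labels <- function(d) vapply(d$items, `[[`, integer(1), "label")
dataset_images <- function(d) lapply(d$items, `[[`, "image")

#' Load a radiograph dataset from disk
#'
#' Accepts either a directory with one sub-directory per class (sorted
#' sub-directory names define the 0-based class ids) or a CSV manifest with
#' columns `path,label`. Images are plain PGM, loaded as grayscale in
#' `[0, 1]`. Unreadable files are excluded with an itemized warning.
#'
#' @param root Directory or manifest CSV path.
#' @return A `wavevit_dataset`.
#' @export
load_dataset <- function(root) {
  items <- list(); class_names <- character(0)
  excluded <- character(0)
  read_one <- function(path) {
    tryCatch(read_pgm(path), error = function(e) NULL)
  }
  if (dir.exists(root)) {
    dirs <- sort(list.dirs(root, recursive = FALSE))
    if (length(dirs) == 0L) stop("no class sub-directories under ", root, call. = FALSE)
    class_names <- basename(dirs)
    for (ci in seq_along(dirs)) {
      files <- sort(list.files(dirs[ci], pattern = "\\.pgm$", full.names = TRUE))
      if (length(files) == 0L)
        stop("class '", class_names[ci], "' has no images", call. = FALSE)
      for (f in files) {
        img <- read_one(f)
        if (is.null(img)) { excluded <- c(excluded, f); next }
        items[[length(items) + 1L]] <-
          list(image = img, label = ci - 1L, path = f)
      }
    }
  } else if (file.exists(root)) {
    man <- utils::read.csv(root, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(man)))
      stop("manifest must have columns path,label", call. = FALSE)
    base <- dirname(root)
    class_names <- sort(unique(as.character(man$label)))
    for (i in seq_len(nrow(man))) {
      p <- man$path[i]
      if (!file.exists(p)) p <- file.path(base, man$path[i])
      img <- if (file.exists(p)) read_one(p) else NULL
      if (is.null(img)) { excluded <- c(excluded, man$path[i]); next }
      items[[length(items) + 1L]] <-
        list(image = img,
             label = match(as.character(man$label[i]), class_names) - 1L,
             path = p)
    }
  } else {
    stop("no such directory or manifest: ", root, call. = FALSE)
  }
  if (length(excluded) > 0)
    warning("excluded unreadable files: ", paste(excluded, collapse = ", "),
            call. = FALSE)
  if (length(items) == 0L) stop("no decodable images found", call. = FALSE)
  new_dataset(items, class_names)
}

# ---- preprocessing ----------------------------------------------------------

#' Bilinear resize to a square
#'
#' @param x Image matrix.
#' @param size Target side length in pixels (> 0).
#' @return `size` x `size` matrix.
#' @export
resize <- function(x, size) {
  if (!is.numeric(size) || length(size) != 1L || size <= 0)
    stop("size must be a positive integer", call. = FALSE)
  size <- as.integer(size)
  H <- nrow(x); W <- ncol(x)
  if (H == size && W == size) return(x)
  map_axis <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1L)
    list(lo = as.integer(lo), frac = src - lo)
  }
  ry <- map_axis(size, H); rx <- map_axis(size, W)
  fy <- matrix(ry$frac, size, size)
  fx <- matrix(rx$frac, size, size, byrow = TRUE)
  x00 <- x[ry$lo, rx$lo, drop = FALSE]
  x01 <- x[ry$lo, rx$lo + 1L, drop = FALSE]
  x10 <- x[ry$lo + 1L, rx$lo, drop = FALSE]
  x11 <- x[ry$lo + 1L, rx$lo + 1L, drop = FALSE]
  x00 * (1 - fy) * (1 - fx) + x01 * (1 - fy) * fx +
    x10 * fy * (1 - fx) + x11 * fy * fx
}

#' Global histogram equalization
#'
#' Equalizes on 256 quantized intensity bins; a constant image maps to
#' itself.
#' @param x Image matrix in `[0, 1]`.
#' @export
hist_equalize <- function(x) {
  q <- pmin(pmax(round(x * 255), 0), 255)
  if (max(q) == min(q)) return(x)
  counts <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(cdf > 0)[1]]
  lut <- (cdf - cdf_min) / (length(x) - cdf_min)
  matrix(lut[q + 1L], nrow(x), ncol(x))
}

hflip <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

# Rotation by bilinear resampling about the image centre; out-of-frame
# samples clamp to the border.
rotate_image <- function(x, degrees) {
  if (degrees == 0) return(x)
  H <- nrow(x); W <- ncol(x)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  fy <- sy - y0; fx <- sx - x0
  at <- function(r, c) matrix(x[cbind(as.vector(r), as.vector(c))], H, W)
  at(y0, x0) * (1 - fy) * (1 - fx) + at(y0, x0 + 1) * (1 - fy) * fx +
    at(y0 + 1, x0) * fy * (1 - fx) + at(y0 + 1, x0 + 1) * fy * fx
}

random_crop_resize <- function(x, scale) {
  H <- nrow(x); W <- ncol(x)
  ch <- max(2L, as.integer(round(H * scale)))
  cw <- max(2L, as.integer(round(W * scale)))
  oy <- sample.int(H - ch + 1L, 1L)
  ox <- sample.int(W - cw + 1L, 1L)
  crop <- x[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
  out <- resize(crop, nrow(x))
  if (ncol(x) != nrow(x)) out <- out[, seq_len(ncol(x)), drop = FALSE]
  out
}

#' Augmentation operator configuration
#'
#' @param flip Allow horizontal flipping (probability 1/2 when active).
#' @param rotation Maximum absolute rotation in degrees.
#' @param crop_min Minimum crop scale (crop is resized back; 1 disables).
#' @param hist_eq Allow histogram equalization (probability 1/2).
#' @param jitter Maximum absolute additive intensity shift.
#' @export
augment_config <- function(flip = TRUE, rotation = 15, crop_min = 0.8,
                           hist_eq = TRUE, jitter = 0) {
  list(flip = flip, rotation = rotation, crop_min = crop_min,
       hist_eq = hist_eq, jitter = jitter)
}

#' Stochastic training augmentation
#'
#' With probability `p` the augmentation sequence (flip, rotation, crop,
#' histogram equalization, intensity jitter — each operator sampled
#' independently) is applied; otherwise the image is returned unchanged.
#' Deterministic for a fixed seed; dimensions never change.
#'
#' @param x Image matrix in `[0, 1]`.
#' @param p Application probability in `[0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @param ops An [augment_config()].
#' @export
augment <- function(x, p = 0.5, seed = 0L, ops = augment_config()) {
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  if (stats::runif(1) >= p) return(x)
  if (ops$flip && stats::runif(1) < 0.5) x <- hflip(x)
  if (ops$rotation > 0)
    x <- rotate_image(x, stats::runif(1, -ops$rotation, ops$rotation))
  if (ops$crop_min < 1)
    x <- random_crop_resize(x, stats::runif(1, ops$crop_min, 1))
  if (ops$hist_eq && stats::runif(1) < 0.5) x <- hist_equalize(x)
  if (ops$jitter > 0)
    x <- pmin(pmax(x + stats::runif(1, -ops$jitter, ops$jitter), 0), 1)
  x
}

# Weak view: flip + very gentle crop (content must stay nearly aligned
# with the positional grid, or the pseudo-label view decouples from the
# strong view at small image sizes). Strong view: the full operator set.
weak_augment <- function(x, seed = 0L) {
  augment(x, p = 1, seed = seed,
          ops = augment_config(flip = TRUE, rotation = 0, crop_min = 0.97,
                               hist_eq = FALSE, jitter = 0))
}

strong_augment <- function(x, seed = 0L) {
  augment(x, p = 1, seed = seed,
          ops = augment_config(flip = TRUE, rotation = 8, crop_min = 0.92,
                               hist_eq = TRUE, jitter = 0.05))
}

#' Expected number of augmented images over a training run
#'
#' Each epoch every training image has probability `p` of being augmented,
#' so the expectation over the run is `n_train * epochs * p`.
#' @param n_train Training-set size.
#' @param epochs Number of epochs.
#' @param p Augmentation probability.
#' @export
expected_augmented_count <- function(n_train, epochs, p) {
  stopifnot(n_train >= 0, epochs >= 0, p >= 0)
  n_train * epochs * p
}

# ---- stratified k-fold ------------------------------------------------------

#' Stratified k-fold split
#'
#' Shuffles each class independently (seeded) and deals its members across
#' the k validation folds; the leftover members per class are assigned to
#' folds cyclically with a counter shared across classes, so validation
#' sizes are as equal as arithmetic allows and per-class proportions are
#' preserved within one item.
#'
#' @param dataset A `wavevit_dataset`, or an integer label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` splits, each `list(fold, train, validation)` with
#'   1-based item indices.
#' @export
stratified_kfold <- function(dataset, k = 5L, seed = 0L) {
  labels <- if (inherits(dataset, "wavevit_dataset")) dataset_labels(dataset)
            else as.integer(dataset)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2 (k = 1 is degenerate)", call. = FALSE)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  small <- classes[counts < k]
  if (length(small) > 0)
    stop("class ", paste(small, collapse = ", "), " has fewer than k members",
         call. = FALSE)
  set.seed(seed)
  fold_of <- integer(length(labels))
  extra_cursor <- 0L
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    base <- m %/% k; extra <- m %% k
    sizes <- rep(base, k)
    if (extra > 0L) {
      who <- ((extra_cursor + seq_len(extra) - 1L) %% k) + 1L
      sizes[who] <- sizes[who] + 1L
      extra_cursor <- (extra_cursor + extra) %% k
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (sizes[f] == 0L) next
      fold_of[idx[pos:(pos + sizes[f] - 1L)]] <- f
      pos <- pos + sizes[f]
    }
  }
  lapply(seq_len(k), function(f) {
    list(fold = f,
         train = which(fold_of != f),
         validation = which(fold_of == f))
  })
}

#' Export fold splits as JSON
#'
#' @param splits Output of [stratified_kfold()].
#' @param path Target JSON file.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(splits, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
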