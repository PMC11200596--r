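# Seeded generator of panoramic-radiograph-like grayscale images in four
# classes: healthy (no lesion), AM-like (well-defined multilocular
# radiolucency), PC-like (small round well-defined periapical
# radiolucency at the arch margin), CSO-like (ill-defined mixed
# radiolucent/sclerotic texture). The geometry is deliberately schematic —
# smoothed unions of discs on a bright jaw-like arch — because the point is
# that the four phenotypes are separable by texture and border statistics,
# not anatomical realism.

#' Synthetic dataset specification
#'
#' All lesion geometry is parameterized as fractions of the image side so
#' the same spec renders at any resolution. Defaults encode the four
#' imaging phenotypes: AM draws 2-4 overlapping locules with sharp borders,
#' PC a single small sharp disc at the arch margin, CSO one large
#' blurred irregular radiolucency with bright sclerotic speckles.
#'
#' @param image_size Side length in pixels (default 128).
#' @param lesion_contrast Range of the radiolucent intensity drop.
#' @param am_locules Integer support of the AM locule count.
#' @param am_radius,pc_radius,cso_radius Lesion radius ranges (fractions
#'   of image size).
#' @param am_blur,pc_blur,cso_blur Border blur sigma ranges in pixels
#'   (small = well defined, large = ill defined).
#' @param cso_speckle_density Range of the sclerotic speckle density
#'   (fraction of lesion pixels turned bright).
#' @param bg_gradient Background arch contrast (band brightness above the
#'   dark field).
#' @param bg_noise Amplitude of the band-limited background noise.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 128L,
                           lesion_contrast = c(0.35, 0.50),
                           am_locules = 2:4,
                           am_radius = c(0.10, 0.15),
                           pc_radius = c(0.05, 0.08),
                           cso_radius = c(0.14, 0.20),
                           am_blur = c(0.4, 0.8),
                           pc_blur = c(0.4, 0.8),
                           cso_blur = c(2.0, 3.5),
                           cso_speckle_density = c(0.05, 0.10),
                           bg_gradient = c(0.38, 0.44),
                           bg_noise = c(0.01, 0.02)) {
  structure(list(image_size = as.integer(image_size),
                 lesion_contrast = lesion_contrast, am_locules = am_locules,
                 am_radius = am_radius, pc_radius = pc_radius,
                 cso_radius = cso_radius, am_blur = am_blur,
                 pc_blur = pc_blur, cso_blur = cso_blur,
                 cso_speckle_density = cso_speckle_density,
                 bg_gradient = bg_gradient, bg_noise = bg_noise),
            class = "synthetic_spec")
}

synth_class_names <- function() c("healthy", "am", "pc", "cso")

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge replication.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1L - r, n + r), 1L), n)
  xp <- x[pad_idx(nrow(x)), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
  xp <- out[, pad_idx(ncol(x)), drop = FALSE]
  out2 <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) out2 <- out2 + k[i] * xp[, i:(i + ncol(x) - 1L), drop = FALSE]
  out2
}

disc_mask <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Vertical centre of the jaw-like arch at each column (a shallow smile).
arch_centre <- function(n) {
  xs <- seq(0, 1, length.out = n)
  n * (0.55 + 0.12 * (2 * xs - 1)^2)
}

#' Generate a jaw-like background
#'
#' A bright curved horizontal band (the dental arch) over a darker field,
#' with a gentle vertical gradient and band-limited (smoothed white) noise.
#' Values are clipped to `[0, 1]`. Deterministic given the seed.
#'
#' @param size Image side length.
#' @param params A [synthetic_spec()] (only background fields used).
#' @param seed Integer seed.
#' @export
generate_background <- function(size, params = synthetic_spec(), seed = 0L) {
  set.seed(seed)
  n <- as.integer(size)
  grad <- stats::runif(1, params$bg_gradient[1], params$bg_gradient[2])
  noise_amp <- stats::runif(1, params$bg_noise[1], params$bg_noise[2])
  centre <- arch_centre(n)
  yy <- matrix(seq_len(n), n, n)
  cy <- matrix(centre, n, n, byrow = TRUE)
  band_hw <- n * 0.18
  band <- exp(-((yy - cy)^2) / (2 * (band_hw / 1.6)^2))
  base <- 0.22 + 0.06 * (1 - yy / n)       # slightly brighter toward the top
  img <- base + grad * band
  noise <- matrix(stats::rnorm(n * n), n, n)
  img <- img + noise_amp * gauss_blur(noise, 1.2) * 3
  pmin(pmax(img, 0), 1)
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

#' Generate one labelled synthetic sample
#'
#' Class 0 is background only; class 1 (AM-like) inserts 2-4 overlapping
#' sharp-bordered dark locules; class 2 (PC-like) one small sharp dark disc
#' at the arch margin; class 3 (CSO-like) one large irregular blurred dark
#' region studded with bright sclerotic speckles. The drawn lesion
#' parameters are attached as attribute `"params"`.
#'
#' @param class_id Integer in `0..3`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `image` (matrix in `[0, 1]`) and `label`.
#' @export
generate_sample <- function(class_id, spec = synthetic_spec(), seed = 0L) {
  class_id <- as.integer(class_id)
  if (class_id < 0L || class_id > 3L)
    stop("class_id must be in 0..3", call. = FALSE)
  img <- generate_background(spec$image_size, spec, seed = seed)
  set.seed(seed + 104729L)  # lesion stream independent of the background's
  n <- spec$image_size
  centre <- arch_centre(n)
  params <- list(class = class_id)
  if (class_id != 0L) {
    contrast <- runif1(spec$lesion_contrast)
    params$contrast <- contrast
    # blur sigmas are stated in pixels at the reference 128-px resolution;
    # scale them so lesion morphology is resolution-invariant
    blur_scale <- n / 128
    lesion <- matrix(0, n, n)
    if (class_id == 1L) {                         # AM: multilocular, sharp
      k <- sample(spec$am_locules, 1L)
      params$locules <- k
      blur <- runif1(spec$am_blur)
      params$blur <- blur
      cx0 <- stats::runif(1, 0.3, 0.7) * n
      cy0 <- centre[round(cx0)]
      radii <- numeric(k)
      for (i in seq_len(k)) {
        r <- runif1(spec$am_radius) * n
        radii[i] <- r
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.3, 0.9) * r
        lesion <- pmax(lesion,
                       disc_mask(n, cy0 + sin(ang) * d, cx0 + cos(ang) * d, r))
      }
      params$radius <- radii
      lesion <- gauss_blur(lesion, blur * blur_scale)
    } else if (class_id == 2L) {                  # PC: small, round, marginal
      r <- runif1(spec$pc_radius) * n
      blur <- runif1(spec$pc_blur)
      params$radius <- r; params$blur <- blur
      cx0 <- stats::runif(1, 0.25, 0.75) * n
      side <- sample(c(-1, 1), 1L)
      cy0 <- centre[round(cx0)] + side * n * 0.10   # at the arch margin
      lesion <- gauss_blur(disc_mask(n, cy0, cx0, r) * 1, blur * blur_scale)
    } else {                                      # CSO: irregular, ill-defined
      r <- runif1(spec$cso_radius) * n
      blur <- runif1(spec$cso_blur)
      params$radius <- r; params$blur <- blur
      cx0 <- stats::runif(1, 0.3, 0.7) * n
      cy0 <- centre[round(cx0)]
      for (i in seq_len(6L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0, 0.8) * r
        rr <- stats::runif(1, 0.35, 0.7) * r
        lesion <- pmax(lesion,
                       disc_mask(n, cy0 + sin(ang) * d, cx0 + cos(ang) * d, rr))
      }
      lesion <- gauss_blur(lesion, blur * blur_scale)
    }
    img <- img - contrast * lesion
    if (class_id == 3L) {                         # sclerotic speckle
      dens <- runif1(spec$cso_speckle_density)
      params$speckle_density <- dens
      core <- which(lesion > 0.5)
      n_speck <- max(1L, round(dens * length(core)))
      params$speckles <- n_speck
      pick <- sample(core, min(n_speck, length(core)))
      img[pick] <- pmin(img[pick] + 0.45, 1)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, label = class_id), params = params)
}

#' Generate a balanced synthetic dataset
#'
#' @param n_per_class Samples per class (>= 1).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the dataset (draws and shuffle order) is
#'   bit-identical for equal seeds.
#' @return A `wavevit_dataset` with classes healthy/am/pc/cso.
#' @export
generate_dataset <- function(n_per_class, spec = synthetic_spec(), seed = 0L) {
  stopifnot(n_per_class >= 1)
  items <- list()
  k <- 0L
  for (cl in 0:3) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- generate_sample(cl, spec, seed = seed + 7919L * cl + i)
      items[[k]] <- list(image = s$image, label = s$label,
                         path = sprintf("synthetic/%s/%04d",
                                        synth_class_names()[cl + 1L], i))
    }
  }
  set.seed(seed)
  items <- items[sample.int(length(items))]
  new_dataset(items, synth_class_names())
}

#' Write a dataset to disk as a PGM tree with manifest
#'
#' Directory-per-class layout readable by [load_dataset()], plus a
#' `manifest.csv` with columns `path,label`.
#'
#' @param dataset A `wavevit_dataset`.
#' @param dir Output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- data.frame(path = character(0), label = character(0))
  counter <- integer(length(dataset$class_names))
  for (it in dataset$items) {
    cl <- it$label + 1L
    cdir <- file.path(dir, dataset$class_names[cl])
    dir.create(cdir, showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    f <- file.path(cdir, sprintf("%s_%04d.pgm", dataset$class_names[cl],
                                 counter[cl]))
    write_pgm(it$image, f)
    rows <- rbind(rows, data.frame(path = f,
                                   label = dataset$class_names[cl]))
  }
  utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

# ---- simple pixel-statistic features (separability oracle) ------------------

#' Five summary features of a synthetic sample
#'
#' Lesion area, minimum intensity, mean border-gradient magnitude of the
#' dark region, bright-speckle count inside it, and a locule-count proxy
#' (connected dark components). Used by the baseline separability check
#' that keeps model-training tests meaningful.
#'
#' @param x Image matrix in `[0, 1]`.
#' @return Named numeric vector of length 5.
#' @export
synth_features <- function(x) {
  thr <- stats::median(x) - 0.15
  dark <- x < thr
  area <- mean(dark)
  gy <- rbind(diff(x), 0); gx <- cbind(t(diff(t(x))), 0)
  gmag <- sqrt(gy^2 + gx^2)
  border <- dark & !erode_mask(dark)
  border_grad <- if (any(border)) mean(gmag[border]) else 0
  bright <- x > stats::median(x) + 0.25
  speckle <- sum(bright & dilate_mask(dark))
  locules <- count_components(dark)
  c(area = area, min_int = min(x), border_grad = border_grad,
    speckles = speckle, locules = locules)
}

erode_mask <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  out[2:n, ] <- out[2:n, ] & m[1:(n - 1), ]
  out[1:(n - 1), ] <- out[1:(n - 1), ] & m[2:n, ]
  out[, 2:p] <- out[, 2:p] & m[, 1:(p - 1)]
  out[, 1:(p - 1)] <- out[, 1:(p - 1)] & m[, 2:p]
  out
}

dilate_mask <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  out[2:n, ] <- out[2:n, ] | m[1:(n - 1), ]
  out[1:(n - 1), ] <- out[1:(n - 1), ] | m[2:n, ]
  out[, 2:p] <- out[, 2:p] | m[, 1:(p - 1)]
  out[, 1:(p - 1)] <- out[, 1:(p - 1)] | m[, 2:p]
  out
}

# 4-connected component count by label propagation (images are small).
count_components <- function(mask) {
  if (!any(mask)) return(0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    n <- nrow(lab); p <- ncol(lab)
    cmp <- function(a, b) ifelse(a > 0L & b > 0L, pmin(a, b), pmax(a, b))
    new[2:n, ] <- ifelse(mask[2:n, ], cmp(new[2:n, ], new[1:(n - 1), ]), 0L)
    new[1:(n - 1), ] <- ifelse(mask[1:(n - 1), ], cmp(new[1:(n - 1), ], new[2:n, ]), 0L)
    new[, 2:p] <- ifelse(mask[, 2:p], cmp(new[, 2:p], new[, 1:(p - 1)]), 0L)
    new[, 1:(p - 1)] <- ifelse(mask[, 1:(p - 1)], cmp(new[, 1:(p - 1)], new[, 2:p]), 0L)
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[mask]))
}
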