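## Deterministic generator of labeled white-blood-cell-like images: an
## elliptical cytoplasm on a noisy near-white background, with `lobes`
## overlapping nucleus blobs sized so the nucleus covers a target fraction of
## the cell. Classes differ in lobe count, nucleus/cell area ratio, and stain
## hue — the morphology axes that distinguish real leukocyte subtypes — but
## make no claim of biological realism; they exist so the pipeline can be
## exercised end to end without external datasets.

default_morphology <- function(preset) {
  switch(preset,
    ## Raabin-like 5 classes: basophil, eosinophil, lymphocyte, monocyte,
    ## neutrophil; lobe multiset {2, 2, 1, 1, 3}
    wbc5 = tibble::tibble(
      class = c("B", "EO", "L", "M", "N"),
      lobes = c(2L, 2L, 1L, 1L, 3L),
      area_ratio = c(0.55, 0.40, 0.70, 0.45, 0.35),
      cell_hue = c(280, 15, 200, 35, 330),
      nucleus_hue = c(260, 350, 240, 265, 285),
      size_jitter = 0.10),
    ## BCCD-like 4 classes
    wbc4 = tibble::tibble(
      class = c("EO", "L", "M", "N"),
      lobes = c(2L, 1L, 1L, 3L),
      area_ratio = c(0.40, 0.70, 0.45, 0.35),
      cell_hue = c(15, 200, 35, 330),
      nucleus_hue = c(350, 240, 265, 285),
      size_jitter = 0.10),
    ## PBC-like 8 classes
    wbc8 = tibble::tibble(
      class = c("B", "EO", "ER", "IG", "L", "M", "N", "P"),
      lobes = c(2L, 2L, 1L, 2L, 1L, 1L, 3L, 1L),
      area_ratio = c(0.55, 0.40, 0.80, 0.50, 0.70, 0.45, 0.35, 0.25),
      cell_hue = c(280, 15, 0, 55, 200, 35, 330, 180),
      nucleus_hue = c(260, 350, 330, 300, 240, 265, 285, 220),
      size_jitter = 0.10),
    ## well-separated 3-class set used for learning-capability checks
    easy3 = tibble::tibble(
      class = c("A", "B", "C"),
      lobes = c(1L, 2L, 3L),
      area_ratio = c(0.30, 0.50, 0.70),
      cell_hue = c(0, 120, 240),
      nucleus_hue = c(30, 150, 270),
      size_jitter = 0.05),
    stop(sprintf("unknown preset '%s'", preset), call. = FALSE))
}

#' Specification of a synthetic cell-image dataset
#'
#' @param preset morphology preset: `"wbc5"` (Raabin-like 5 classes),
#'   `"wbc4"` (BCCD-like), `"wbc8"` (PBC-like), or `"easy3"` (three
#'   well-separated classes for capability checks).
#' @param images_per_class images rendered per class.
#' @param image_size image side in pixels.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (intensity units on the `[0, 1]` scale).
#' @param seed integer; the dataset is a pure function of this specification object.
#' @param morphology optional tibble overriding the preset (columns `class`,
#'   `lobes`, `area_ratio`, `cell_hue`, `nucleus_hue`, `size_jitter`).
#' @param class_weights optional per-class image-count multipliers.
#' @return a list of class `scmix_synthetic_spec`.
#' @export
synthetic_spec <- function(preset = "wbc5", images_per_class = 50L,
                           image_size = 112L, noise_sigma = 0.04, seed = 1L,
                           morphology = NULL, class_weights = NULL) {
  morph <- morphology %||% default_morphology(preset)
  if (any(morph$area_ratio <= 0 | morph$area_ratio >= 1))
    stop("area_ratio values must lie in (0, 1)", call. = FALSE)
  if (anyDuplicated(morph[, c("lobes", "area_ratio", "cell_hue", "nucleus_hue")]))
    stop("classes must differ in at least one morphology parameter", call. = FALSE)
  n_cl <- nrow(morph)
  if (n_cl < 2 || n_cl > 8) stop("2 to 8 classes supported", call. = FALSE)
  weights <- class_weights %||% rep(1, n_cl)
  structure(list(preset = preset, morphology = morph,
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 class_weights = weights),
            class = "scmix_synthetic_spec")
}

## binary search for the lobe radius that makes the nucleus cover
## `ratio` of the cell mask
fit_lobe_radius <- function(cell_mask, cx, cy, centers, ratio, xg, yg) {
  cell_area <- sum(cell_mask)
  measure <- function(r) {
    nuc <- Reduce(`|`, lapply(seq_len(nrow(centers)), function(i)
      (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= r^2))
    sum(nuc & cell_mask) / cell_area
  }
  lo <- 0.005; hi <- 0.6
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    if (measure(mid) < ratio) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Render a single synthetic cell image
#'
#' Draws an elliptical cytoplasm, `lobes` overlapping nucleus blobs whose
#' union is sized (by bisection on the pixel mask) to the target nucleus/cell
#' area ratio, then adds Gaussian noise and clips to `[0, 1]`.
#'
#' @param params one-row morphology table (columns as in [synthetic_spec()]).
#' @param image_size image side in pixels.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed optional integer; when given, the image is a pure function of
#'   `(params, seed)`.
#' @return array `(image_size, image_size, 3)` in `[0, 1]`, with attributes
#'   `nucleus_fraction` (measured within the cell mask) and `cell_fraction`.
#' @export
render_cell <- function(params, image_size = 112L, noise_sigma = 0.04,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- image_size
  xs <- (seq_len(s) - 0.5) / s
  xg <- matrix(xs, s, s)          # x varies along rows
  yg <- matrix(xs, s, s, byrow = TRUE)
  jit <- params$size_jitter
  cx <- 0.5 + stats::runif(1, -0.06, 0.06)
  cy <- 0.5 + stats::runif(1, -0.06, 0.06)
  a <- 0.30 * (1 + stats::runif(1, -jit, jit))
  b <- 0.30 * (1 + stats::runif(1, -jit, jit))
  th <- stats::runif(1, 0, pi)
  xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
  yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
  cell <- (xr / a)^2 + (yr / b)^2 <= 1
  nuc <- matrix(FALSE, s, s)
  if (params$area_ratio > 1e-3) {
    k <- params$lobes
    ring <- if (k == 1) 0 else 0.16 * min(a, b) * k / 2
    ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(k) / k
    centers <- cbind(cx + ring * cos(ang), cy + ring * sin(ang))
    r <- fit_lobe_radius(cell, cx, cy, centers, params$area_ratio, xg, yg)
    nuc <- Reduce(`|`, lapply(seq_len(k), function(i)
      (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= r^2)) & cell
  }
  cell_col <- grDevices::hsv(params$cell_hue %% 360 / 360, 0.45, 0.85)
  nuc_col <- grDevices::hsv(params$nucleus_hue %% 360 / 360, 0.75, 0.45)
  bg_col <- grDevices::hsv(0.08, 0.04, 0.97)
  img <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    plane <- matrix(grDevices::col2rgb(bg_col)[ch] / 255, s, s)
    plane[cell] <- grDevices::col2rgb(cell_col)[ch] / 255
    plane[nuc] <- grDevices::col2rgb(nuc_col)[ch] / 255
    img[, , ch] <- plane
  }
  if (noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sigma), dim(img))
  img <- pmin(pmax(img, 0), 1)
  attr(img, "nucleus_fraction") <- if (any(cell)) sum(nuc & cell) / sum(cell) else 0
  attr(img, "cell_fraction") <- mean(cell)
  img
}

#' Generate a labeled synthetic dataset
#'
#' Exactly `num_classes * images_per_class` images (scaled by `class_weights`
#' if given), balanced labels, fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `scmix_dataset`: list with `images` (list of
#'   `(H, W, 3)` arrays), `labels` (integer codes), `class_names`, and a
#'   `manifest` tibble (`filename`, `class`).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "scmix_synthetic_spec"))
  set.seed(spec$seed)
  morph <- spec$morphology
  images <- list()
  labels <- integer(0)
  files <- character(0)
  for (ci in seq_len(nrow(morph))) {
    n_i <- as.integer(round(spec$images_per_class * spec$class_weights[ci]))
    for (i in seq_len(n_i)) {
      img <- render_cell(morph[ci, ], spec$image_size, spec$noise_sigma)
      attributes(img) <- attributes(img)["dim"]
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci)
      files <- c(files, sprintf("%s/img_%05d.png", morph$class[ci], i))
    }
  }
  new_scmix_dataset(images, labels, morph$class,
                    manifest = tibble::tibble(filename = files,
                                              class = morph$class[labels]))
}

new_scmix_dataset <- function(images, labels, class_names, manifest = NULL) {
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names,
                 manifest = manifest,
                 image_size = dim(images[[1]])[1]),
            class = "scmix_dataset")
}

#' @export
print.scmix_dataset <- function(x, ...) {
  cat(sprintf("<scmix_dataset> %d images, %d classes (%s), %dx%d px\n",
              length(x$images), length(x$class_names),
              paste(x$class_names, collapse = ", "),
              x$image_size, x$image_size))
  invisible(x)
}

#' Number of images in a dataset
#' @param ds a `scmix_dataset`.
#' @return integer count.
#' @export
dataset_size <- function(ds) length(ds$images)

#' Stack dataset images into a batch tensor
#'
#' @param ds a `scmix_dataset`.
#' @param idx optional indices to select.
#' @return array `(n, H, W, 3)`.
#' @export
dataset_tensor <- function(ds, idx = NULL) {
  idx <- idx %||% seq_along(ds$images)
  s <- dim(ds$images[[idx[1]]])
  x <- array(0, c(length(idx), s))
  for (i in seq_along(idx)) x[i, , , ] <- ds$images[[idx[i]]]
  x
}

## one-hot targets for a dataset subset
one_hot <- function(labels, num_classes) {
  y <- matrix(0, length(labels), num_classes)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Write a dataset as a class-per-directory image tree
#'
#' Layout: `root/<class>/img_00001.png ...` plus a `manifest.csv`
#' (columns `filename`, `class`) — the same folder convention the dataset
#' readers consume.
#'
#' @param ds a `scmix_dataset`.
#' @param root target directory (created if missing).
#' @return invisibly, the root path.
#' @export
write_dataset <- function(ds, root) {
  ok <- dir.exists(root) || dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create directory '%s'", root), call. = FALSE)
  counters <- integer(length(ds$class_names))
  files <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    ci <- ds$labels[i]
    cls <- ds$class_names[ci]
    dir.create(file.path(root, cls), showWarnings = FALSE)
    counters[ci] <- counters[ci] + 1L
    files[i] <- sprintf("%s/img_%05d.png", cls, counters[ci])
    png::writePNG(ds$images[[i]], file.path(root, files[i]))
  }
  utils::write.csv(tibble::tibble(filename = files, class = ds$class_names[ds$labels]),
                   file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(root)
}
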