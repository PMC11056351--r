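## Reading class-per-directory image trees and stratified splitting.

#' Read a class-per-directory image folder
#'
#' Each subdirectory of `root` is one class (class order = lexicographic
#' directory names). Images are decoded as RGB, bilinearly resized to
#' `input_size`, and scaled to `[0, 1]`; grayscale images are replicated to 3
#' channels; undecodable files are skipped with a warning.
#'
#' @param root directory containing one subdirectory per class.
#' @param input_size target image side in pixels (`NULL` keeps native size;
#'   all images must then agree).
#' @return a `scmix_dataset`.
#' @export
read_image_folder <- function(root, input_size = 224L) {
  if (!dir.exists(root)) stop(sprintf("no such directory: '%s'", root), call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- classes[nzchar(classes)]
  if (length(classes) < 2)
    stop("need at least 2 class subdirectories", call. = FALSE)
  images <- list()
  labels <- integer(0)
  files <- character(0)
  skipped <- 0L
  for (ci in seq_along(classes)) {
    fns <- sort(list.files(file.path(root, classes[ci]),
                           pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE))
    decoded <- 0L
    for (fn in fns) {
      img <- tryCatch(decode_image(file.path(root, classes[ci], fn), input_size),
                      error = function(e) NULL)
      if (is.null(img)) {
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci)
      files <- c(files, file.path(classes[ci], fn))
      decoded <- decoded + 1L
    }
    if (decoded == 0L)
      stop(sprintf("class directory '%s' has no decodable image", classes[ci]),
           call. = FALSE)
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d undecodable file(s)", skipped), call. = FALSE)
  new_scmix_dataset(images, labels, classes,
                    manifest = tibble::tibble(filename = files,
                                              class = classes[labels]))
}

## decode one image file to a (H, W, 3) array in [0, 1]
decode_image <- function(path, input_size = NULL) {
  img <- EBImage::readImage(path)           # EBImage stores (x = W, y = H[, C])
  d <- dim(img)
  if (length(d) == 3L && d[3] > 3L) img <- img[, , 1:3]      # drop alpha
  if (!is.null(input_size) && (d[1] != input_size || d[2] != input_size))
    img <- EBImage::resize(img, w = input_size, h = input_size)  # bilinear
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))  # grayscale
  a <- aperm(a, c(2, 1, 3))                 # -> (H, W, C)
  pmin(pmax(a, 0), 1)
}

#' Stratified train/validation/test split
#'
#' Per class, indices are shuffled with the given seed and partitioned to the
#' target fractions; the subsets are disjoint and exhaustive, with per-class
#' sizes within one sample of the targets.
#'
#' @param ds a `scmix_dataset`.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer split seed.
#' @return list with `scmix_dataset` elements `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  set.seed(seed)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (ci in seq_along(ds$class_names)) {
    idx <- sample(which(ds$labels == ci))
    n <- length(idx)
    n_test <- round(n * fractions[3])
    n_val <- round(n * fractions[2])
    n_train <- n - n_test - n_val
    if (min(n_train, n_val, n_test) < 1)
      stop(sprintf("class '%s' (%d samples) is too small to stratify",
                   ds$class_names[ci], n), call. = FALSE)
    parts$train <- c(parts$train, idx[seq_len(n_train)])
    parts$val <- c(parts$val, idx[n_train + seq_len(n_val)])
    parts$test <- c(parts$test, idx[n_train + n_val + seq_len(n_test)])
  }
  lapply(parts, function(idx) subset_dataset(ds, idx))
}

#' Carve a validation subset out of a pre-split training set
#'
#' For datasets that ship with their own train/test directories: takes
#' `fraction` of each class of the provided training set for validation and
#' leaves the test data untouched.
#'
#' @param ds the training `scmix_dataset`.
#' @param fraction validation fraction of the training samples.
#' @param seed integer seed.
#' @return list with elements `train` and `val`.
#' @export
carve_validation <- function(ds, fraction = 0.15, seed = 1L) {
  set.seed(seed)
  tr <- integer(0); va <- integer(0)
  for (ci in seq_along(ds$class_names)) {
    idx <- sample(which(ds$labels == ci))
    n_val <- max(1L, round(length(idx) * fraction))
    if (length(idx) - n_val < 1)
      stop(sprintf("class '%s' is too small to carve validation from",
                   ds$class_names[ci]), call. = FALSE)
    va <- c(va, idx[seq_len(n_val)])
    tr <- c(tr, idx[-seq_len(n_val)])
  }
  list(train = subset_dataset(ds, tr), val = subset_dataset(ds, va))
}

#' Select a subset of a dataset by index
#'
#' @param ds a `scmix_dataset`. @param idx indices to keep.
#' @return a `scmix_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  new_scmix_dataset(ds$images[idx], ds$labels[idx], ds$class_names,
                    manifest = if (!is.null(ds$manifest)) ds$manifest[idx, ])
}
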