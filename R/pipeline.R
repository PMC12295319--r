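# Dataset loading and deterministic experiment planning. Image trees follow
# the class-per-subdirectory layout (as in the public CRC-VAL-HE-7K release):
# each subdirectory name is a class, its files are RGB patches. Images are
# decoded (PNG/TIFF/JPEG via EBImage), bilinear-resized, and scaled to
# [0, 1]; class indices are 0-based in lexicographic directory order.

#' Construct a patch dataset
#'
#' @param images List of (H, W, 3) arrays in `[0, 1]`.
#' @param labels Integer class ids (0-based).
#' @param class_names Ordered class names.
#' @param provenance Per-item source path or synthetic seed record.
#' @return A `pf_dataset`.
#' @export
patch_dataset <- function(images, labels, class_names, provenance = NULL) {
  stopifnot(length(images) == length(labels),
            all(labels >= 0), all(labels < length(class_names)))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names,
                 provenance = provenance %||% rep(NA_character_, length(images))),
            class = "pf_dataset")
}

#' @export
print.pf_dataset <- function(x, ...) {
  d <- if (length(x$images)) dim(x$images[[1]]) else c(NA, NA, NA)
  cat("<pf_dataset> ", length(x$images), " patches (",
      paste(d, collapse = "x"), "), ",
      length(x$class_names), " classes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Decode one image file to a (H, W, 3) array in [0, 1]. EBImage stores
# (x, y, channel); transpose to row = y. Grayscale is replicated to three
# channels; an alpha channel is dropped.
read_patch <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  aperm(img, c(2L, 1L, 3L))
}

# Bilinear resize of a (H, W, 3) array.
resize_patch <- function(img, size) {
  if (all(dim(img)[1:2] == size)) return(img)
  out <- EBImage::resize(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                        colormode = "Color"),
                         w = size, h = size)
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

#' Load a class-per-subdirectory image tree
#'
#' @param root Directory whose subdirectories are classes holding PNG, TIFF
#'   or JPEG patches.
#' @param size Target square size (default 224); images are bilinear-resized
#'   and values scaled to `[0, 1]`.
#' @return A `pf_dataset`. Unreadable files are skipped with a warning; an
#'   empty class directory is an error.
#' @export
load_patch_dataset <- function(root, size = 224L) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", root)
  images <- list()
  labels <- integer()
  prov <- character()
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[ci]),
                             pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("class directory '", classes[ci], "' contains no images")
    }
    for (f in files) {
      img <- tryCatch(read_patch(f), error = function(e) {
        warning("skipping unreadable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      img <- pmin(pmax(resize_patch(img, size), 0), 1)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci - 1L)
      prov <- c(prov, f)
    }
  }
  patch_dataset(images, labels, classes, prov)
}

#' One-hot encode labels
#'
#' @param labels Integer labels in `[0, k)`.
#' @param k Number of classes.
#' @return Matrix (n, k); each row has a single 1.
#' @export
one_hot <- function(labels, k) {
  if (any(labels < 0 | labels >= k)) stop("labels must lie in [0, ", k, ")")
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Deterministic train/test split plan
#'
#' A seeded uniform permutation; the test partition takes the ceiling of
#' `n * test_fraction` items (the rounding convention that reproduces the
#' published test-set sizes for all six dataset totals).
#'
#' @param n Number of items (> 0).
#' @param test_fraction Fraction held out (default 0.15).
#' @param seed Permutation seed.
#' @param labels Optional labels; when given, the split is stratified by
#'   class (ceiling applied per class) — useful for small synthetic sets.
#' @return A `pf_split_plan` with sorted `train_indices` and `test_indices`
#'   (1-based), `test_fraction`, `seed`.
#' @export
split_plan <- function(n, test_fraction = 0.15, seed = 1L, labels = NULL) {
  stopifnot(n > 0, test_fraction > 0, test_fraction < 1)
  test <- with_local_seed(seed, {
    if (is.null(labels)) {
      sample.int(n)[seq_len(ceiling(n * test_fraction))]
    } else {
      stopifnot(length(labels) == n)
      unlist(lapply(split(seq_len(n), labels), function(idx) {
        sample(idx)[seq_len(ceiling(length(idx) * test_fraction))]
      }), use.names = FALSE)
    }
  })
  structure(list(train_indices = setdiff(seq_len(n), test),
                 test_indices = sort(test),
                 n = as.integer(n), test_fraction = test_fraction,
                 seed = as.integer(seed),
                 stratified = !is.null(labels)),
            class = "pf_split_plan")
}

#' Deterministic K-fold plan
#'
#' A seeded shuffled partition into `k` folds whose sizes differ by at most
#' one.
#'
#' @param n Number of items.
#' @param k Number of folds (default 5; must not exceed `n`).
#' @param seed Shuffle seed.
#' @return A `pf_fold_plan` with `folds`: a list of `k` sorted validation
#'   index vectors (1-based).
#' @export
kfold_plan <- function(n, k = 5L, seed = 1L) {
  if (k > n) stop("k (", k, ") exceeds n (", n, ")")
  stopifnot(k >= 2)
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- split(perm, rep(seq_len(k), times = sizes))
  structure(list(folds = lapply(unname(folds), sort),
                 n = as.integer(n), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "pf_fold_plan")
}

#' Serialise a split or fold plan to JSON
#'
#' @param plan A `pf_split_plan` or `pf_fold_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(c(list(type = class(plan)[1]), unclass(plan)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plan written by [write_plan_json()]
#'
#' @param path JSON path.
#' @return The plan object.
#' @export
read_plan_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$type
  x$type <- NULL
  if (identical(type, "pf_fold_plan")) x$folds <- lapply(x$folds, as.integer)
  structure(x, class = type)
}

#' Published class-count profiles of the six patch datasets
#'
#' The per-class patch counts of the six hematoxylin-and-eosin colorectal
#' tissue datasets used as count profiles by the synthetic generator and the
#' split-size checks: three diagnostic classes (mucosa, debris, stroma) for
#' datasets 1, 3 and 5, and three staging classes (adipose, muscle, lymph)
#' for datasets 2, 4 and 6. The eighteen counts total 17,531 patches.
#'
#' @return A tibble with columns `dataset`, `class`, `count`.
#' @export
crc_dataset_profiles <- function() {
  tibble::tribble(
    ~dataset, ~class, ~count,
    1L, "mucosa", 1480L, 1L, "debris", 1030L, 1L, "stroma", 1119L,
    2L, "adipose", 1014L, 2L, "muscle", 1239L, 2L, "lymph", 1118L,
    3L, "mucosa", 1035L, 3L, "debris", 339L, 3L, "stroma", 421L,
    4L, "adipose", 1338L, 4L, "muscle", 592L, 4L, "lymph", 634L,
    5L, "mucosa", 1200L, 5L, "debris", 678L, 5L, "stroma", 842L,
    6L, "adipose", 1000L, 6L, "muscle", 1184L, 6L, "lymph", 1268L
  )
}
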