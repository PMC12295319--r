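# Synthetic H&E-palette texture patches. Six motif kinds echo, at the level
# of texture statistics only, the six colorectal tissue classes (glandular
# mucosa, fibrous stroma, granular debris, vacuolated adipose, wavy muscle
# bands, densely nucleated lymphoid tissue): each motif is a deterministic
# grayscale field mapped through a two-anchor hematoxylin-purple /
# eosin-pink palette plus Gaussian pixel noise. Every patch is generated
# from a counter-based seed stream (global seed, class, item index), so
# datasets are bit-reproducible item by item regardless of generation order.

#' Texture class specification
#'
#' @param name Class name.
#' @param motif One of `"glandular"`, `"fibrous"`, `"speckle"`, `"vacuole"`,
#'   `"wavy"`, `"nuclei"`.
#' @param palette 2 x 3 matrix of RGB anchors in `[0, 1]` (low-texture and
#'   high-texture colors).
#' @param scale Motif length scale in pixels at 224; rescaled with image
#'   size.
#' @param noise_sd Gaussian pixel noise standard deviation (>= 0).
#' @param seed_offset Per-class offset folded into the seed stream.
#' @return A `pf_texture_spec`.
#' @export
texture_class_spec <- function(name,
                               motif = c("glandular", "fibrous", "speckle",
                                         "vacuole", "wavy", "nuclei"),
                               palette, scale = 28, noise_sd = 0.03,
                               seed_offset = 0L) {
  motif <- match.arg(motif)
  palette <- as.matrix(palette)
  stopifnot(nrow(palette) == 2L, ncol(palette) == 3L,
            all(palette >= 0), all(palette <= 1), noise_sd >= 0)
  structure(list(name = name, motif = motif, palette = palette,
                 scale = scale, noise_sd = noise_sd,
                 seed_offset = as.integer(seed_offset)),
            class = "pf_texture_spec")
}

#' Default texture specifications
#'
#' Six named specs with distinct motifs and H&E-range palettes. The default
#' three-class set (mucosa, debris, stroma) mirrors the diagnostic grouping;
#' the staging trio (adipose, muscle, lymph) completes the six.
#'
#' @param classes Which classes to return (default the diagnostic trio).
#' @return A named list of `pf_texture_spec`.
#' @export
default_texture_specs <- function(classes = c("mucosa", "debris", "stroma")) {
  all <- list(
    mucosa = texture_class_spec("mucosa", "glandular",
      rbind(c(0.55, 0.35, 0.65), c(0.93, 0.76, 0.86)), scale = 36,
      seed_offset = 1L),
    debris = texture_class_spec("debris", "speckle",
      rbind(c(0.34, 0.20, 0.38), c(0.82, 0.62, 0.70)), scale = 18,
      seed_offset = 2L),
    stroma = texture_class_spec("stroma", "fibrous",
      rbind(c(0.96, 0.66, 0.76), c(0.99, 0.89, 0.93)), scale = 22,
      seed_offset = 3L),
    adipose = texture_class_spec("adipose", "vacuole",
      rbind(c(0.90, 0.64, 0.78), c(0.98, 0.94, 0.96)), scale = 44,
      seed_offset = 4L),
    muscle = texture_class_spec("muscle", "wavy",
      rbind(c(0.84, 0.44, 0.60), c(0.96, 0.76, 0.82)), scale = 30,
      seed_offset = 5L),
    lymph = texture_class_spec("lymph", "nuclei",
      rbind(c(0.38, 0.24, 0.58), c(0.72, 0.56, 0.80)), scale = 16,
      seed_offset = 6L)
  )
  missing <- setdiff(classes, names(all))
  if (length(missing)) stop("unknown texture classes: ",
                            paste(missing, collapse = ", "))
  all[classes]
}

# circular box blur along rows then columns
box_blur <- function(m, k) {
  if (k < 2) return(m)
  w <- rep(1 / k, k)
  m <- apply(m, 2L, function(col) {
    as.numeric(stats::filter(col, w, circular = TRUE))
  })
  t(apply(m, 1L, function(row) {
    as.numeric(stats::filter(row, w, circular = TRUE))
  }))
}

# distance from every pixel to the nearest of a set of centers
nearest_dist <- function(size, cx, cy) {
  xg <- matrix(rep(seq_len(size), each = size), size, size)
  yg <- matrix(rep(seq_len(size), times = size), size, size)
  d <- matrix(Inf, size, size)
  for (i in seq_along(cx)) {
    d <- pmin(d, sqrt((xg - cx[i])^2 + (yg - cy[i])^2))
  }
  d
}

# Grayscale motif fields in [0, 1]; RNG is already seeded by the caller.
motif_field <- function(motif, size, scale) {
  s <- max(scale, 4)
  switch(motif,
    glandular = {
      n <- max(4L, round((size / s)^2 * 2))
      d <- nearest_dist(size, stats::runif(n, 1, size),
                        stats::runif(n, 1, size))
      0.5 + 0.5 * cos(2 * pi * d / (s / 1.6))
    },
    fibrous = {
      theta <- stats::runif(1, 0, pi)
      xg <- matrix(rep(seq_len(size), each = size), size, size)
      yg <- matrix(rep(seq_len(size), times = size), size, size)
      phase <- stats::runif(1, 0, 2 * pi)
      0.5 + 0.5 * sin(2 * pi * (xg * cos(theta) + yg * sin(theta)) / (s / 2)
                      + phase)
    },
    speckle = {
      noise <- matrix(stats::runif(size^2), size, size)
      sm <- box_blur(noise, max(2L, round(s / 5)))
      1 * (sm > stats::median(sm))
    },
    vacuole = {
      n <- max(3L, round((size / s)^2 * 1.5))
      r <- s / 2.2
      d <- nearest_dist(size, stats::runif(n, 1, size),
                        stats::runif(n, 1, size))
      sigmoid((r - d) / (0.08 * s))
    },
    wavy = {
      xg <- matrix(rep(seq_len(size), each = size), size, size)
      yg <- matrix(rep(seq_len(size), times = size), size, size)
      amp <- s / 3
      phase <- stats::runif(1, 0, 2 * pi)
      0.5 + 0.5 * sin(2 * pi * (xg + amp * sin(2 * pi * yg / (2.5 * s))) /
                        (s / 1.5) + phase)
    },
    nuclei = {
      n <- max(10L, round((size / s)^2 * 6))
      r <- s / 3.5
      d <- nearest_dist(size, stats::runif(n, 1, size),
                        stats::runif(n, 1, size))
      sigmoid((d - r) / (0.12 * s))   # dark dots on light field
    },
    stop("unknown motif: ", motif)
  )
}

#' Generate one synthetic texture patch
#'
#' Deterministic given `(spec, seed, item)`: the RNG stream is derived from
#' the global seed, the spec's class offset and the item counter, never from
#' global state.
#'
#' @param spec A [texture_class_spec()].
#' @param seed Global seed.
#' @param size Square patch size in pixels (default 224).
#' @param item Item counter within the class.
#' @return A (size, size, 3) array in `[0, 1]`.
#' @export
generate_patch <- function(spec, seed = 1L, size = 224L, item = 0L) {
  stopifnot(inherits(spec, "pf_texture_spec"))
  with_local_seed(stream_seed(seed, spec$seed_offset, item), {
    scale <- spec$scale * size / 224
    t_field <- motif_field(spec$motif, size, scale)
    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) {
      img[, , ch] <- spec$palette[1, ch] * (1 - t_field) +
        spec$palette[2, ch] * t_field
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                         dim(img))
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a labelled synthetic dataset
#'
#' @param specs List of [texture_class_spec()], one per class (class order
#'   defines the 0-based label).
#' @param counts Integer vector of per-class patch counts (all > 0).
#' @param seed Global seed.
#' @param size Patch size (default 224).
#' @param shuffle Shuffle item order (seeded)?
#' @return A `pf_dataset`; per-class counts are exact and provenance records
#'   the seed stream of every item.
#' @export
generate_dataset <- function(specs, counts, seed = 1L, size = 224L,
                             shuffle = TRUE) {
  if (length(specs) != length(counts)) {
    stop("specs and counts differ in length")
  }
  if (any(counts <= 0)) stop("all class counts must be positive")
  images <- list()
  labels <- integer()
  prov <- character()
  for (ci in seq_along(specs)) {
    for (j in seq_len(counts[ci])) {
      images[[length(images) + 1L]] <-
        generate_patch(specs[[ci]], seed, size, item = j)
      labels <- c(labels, ci - 1L)
      prov <- c(prov, sprintf("synthetic:seed=%d:class=%d:item=%d",
                              seed, ci - 1L, j))
    }
  }
  if (shuffle) {
    ord <- with_local_seed(stream_seed(seed, 104729L, 0L),
                           sample.int(length(images)))
    images <- images[ord]
    labels <- labels[ord]
    prov <- prov[ord]
  }
  nms <- unname(vapply(specs, function(s) s$name, ""))
  patch_dataset(images, labels, nms, prov)
}

#' Planted-signal specification
#'
#' A binary disc region plus a contrast amplitude, used as ground truth for
#' Grad-CAM localization scoring.
#'
#' @param size Image size the mask is built for.
#' @param area_fraction Mask area as a fraction of the image, in (0, 0.5].
#' @param center Disc center `(row, col)`; defaults to the image center.
#' @param amplitude Contrast amplitude in `[0, 1]`.
#' @return A `pf_planted_signal` with fields `mask` (size x size, 0/1) and
#'   `amplitude`.
#' @export
planted_signal <- function(size, area_fraction = 0.1, center = NULL,
                           amplitude = 0.8) {
  stopifnot(area_fraction > 0, area_fraction <= 0.5)
  r <- sqrt(area_fraction * size^2 / pi)
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  rg <- matrix(rep(seq_len(size), times = size), size, size)
  cg <- matrix(rep(seq_len(size), each = size), size, size)
  mask <- 1 * (sqrt((rg - center[1])^2 + (cg - center[2])^2) <= r)
  structure(list(mask = mask, amplitude = amplitude),
            class = "pf_planted_signal")
}

#' Plant a contrasting signal region into a patch
#'
#' Pixels inside the mask are shifted toward a dense dark-nuclei motif by
#' the signal amplitude and clipped to `[0, 1]`; the mask is returned for
#' localization scoring. Amplitude 0 returns the image unchanged with a
#' warning.
#'
#' @param image (H, W, 3) array in `[0, 1]`.
#' @param signal A [planted_signal()] whose mask matches the image size.
#' @param seed Seed for the planted motif texture.
#' @return List with `image` and `mask`.
#' @export
plant_signal <- function(image, signal, seed = 1L) {
  stopifnot(inherits(signal, "pf_planted_signal"))
  size <- dim(image)[1]
  if (!all(dim(signal$mask) == dim(image)[1:2])) {
    stop("signal mask shape does not match the image")
  }
  if (signal$amplitude == 0) {
    warning("plant_signal: amplitude 0, image unchanged")
    return(list(image = image, mask = signal$mask))
  }
  target_spec <- texture_class_spec("planted", "nuclei",
    rbind(c(0.15, 0.05, 0.30), c(0.45, 0.25, 0.55)),
    scale = 12, noise_sd = 0, seed_offset = 7919L)
  target <- generate_patch(target_spec, seed, size)
  shifted <- image + signal$amplitude * (target - image) *
    array(signal$mask, dim(image))
  list(image = pmin(pmax(shifted, 0), 1), mask = signal$mask)
}

#' Write a dataset as a class-per-subdirectory PNG tree
#'
#' Produces the layout consumed by [load_patch_dataset()], plus a
#' `manifest.json` recording class names, counts and per-item provenance.
#'
#' @param dataset A `pf_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patch_tree <- function(dataset, dir) {
  for (cl in dataset$class_names) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  counters <- stats::setNames(rep(0L, length(dataset$class_names)),
                              dataset$class_names)
  for (i in seq_along(dataset$images)) {
    cl <- dataset$class_names[dataset$labels[i] + 1L]
    counters[cl] <- counters[cl] + 1L
    path <- file.path(dir, cl, sprintf("%s_%04d.png", cl, counters[cl]))
    EBImage::writeImage(
      EBImage::Image(aperm(dataset$images[[i]], c(2L, 1L, 3L)),
                     colormode = "Color"), path)
  }
  manifest <- list(class_names = dataset$class_names,
                   counts = as.integer(table(factor(
                     dataset$labels, levels = seq_along(dataset$class_names) - 1L))),
                   n = length(dataset$images),
                   provenance = dataset$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
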