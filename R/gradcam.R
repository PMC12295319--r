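# Grad-CAM interpretability. Channel weights are the spatial means of the
# gradient of a class score with respect to a convolutional activation; the
# heatmap is the ReLU of the weighted channel combination, normalized to
# [0, 1] (all-zero maps are left all-zero) and bilinear-upsampled to input
# resolution. The class score is the pre-softmax logit, so heatmaps are
# invariant to shifting all logits by a constant. For the two-branch fusion
# model the default target is each branch's attention-multiplied feature
# map; the two branch maps are combined into one display map weighted by the
# instance's fusion weights.

#' Combine activations with channel weights into a raw Grad-CAM map
#'
#' @param activations (H, W, C) activation array.
#' @param alpha Channel weight vector of length C.
#' @return List with `raw` (ReLU of the weighted sum) and `norm` (scaled to
#'   max 1 unless the raw map is all zero, in which case it stays all zero).
#' @export
gradcam_map <- function(activations, alpha) {
  d <- dim(activations)
  if (length(alpha) != d[3]) stop("alpha length does not match channels")
  raw <- matrix(matrix(activations, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  raw <- pmax(raw, 0)
  mx <- max(raw)
  list(raw = raw, norm = if (mx > 0) raw / mx else raw)
}

# Gradient of the class logit with respect to the GAP input map, divided by
# H*W: this is exactly the Grad-CAM channel weight vector for any map that
# feeds the GAP (the gradient is spatially uniform, so the spatial mean is
# the value itself).
head_channel_weights <- function(params, cache, class_index, prefix = NULL) {
  clf_W <- params[[paste0("clf", prefix, "_W")]]
  dense_W <- params[[paste0("dense", prefix, "_W")]]
  dact <- clf_W[class_index + 1L, ]
  dpre <- dact * (cache$pre_act > 0)
  dg <- as.vector(crossprod(dense_W, dpre))
  hw <- prod(dim(cache$feat)[1:2])
  dg / hw
}

#' Bilinear upsampling of a heatmap
#'
#' @param m Numeric matrix.
#' @param size Target square size.
#' @return A size x size matrix.
#' @export
upsample_bilinear <- function(m, size) {
  out <- EBImage::resize(EBImage::Image(t(m)), w = size, h = size)
  t(EBImage::imageData(out))
}

#' Grad-CAM heatmap for one image
#'
#' @param model A trained `pf_model` with a forward-capable backbone.
#' @param image (H, W, 3) array matching the backbone input.
#' @param class_index Zero-based class whose score is explained.
#' @param target `"combined"` (fusion default: branch maps merged with the
#'   instance's fusion weights), `"branch_a"`, or `"branch_b"`; baselines
#'   always target their backbone feature map.
#' @return A `pf_gradcam`: `heatmap` (feature-resolution, in `[0, 1]`),
#'   `upsampled` (input resolution), `alpha` (channel weights; a list for
#'   the combined target), `target_layer`, `class_index`, and the fusion
#'   `weights` when applicable.
#' @export
gradcam <- function(model, image, class_index,
                    target = c("combined", "branch_a", "branch_b")) {
  target <- match.arg(target)
  if (class_index < 0 || class_index >= model$config$num_classes) {
    stop("class_index out of range")
  }
  size <- dim(image)[1]
  if (inherits(model, "pf_baseline")) {
    fw <- baseline_forward(model, image, train = FALSE)
    alpha <- head_channel_weights(model$params, fw$cache, class_index)
    gm <- gradcam_map(fw$cache$feat, alpha)
    return(structure(list(heatmap = gm$norm,
                          upsampled = upsample_bilinear(gm$norm, size),
                          alpha = alpha, target_layer = "backbone_features",
                          class_index = class_index),
                     class = "pf_gradcam"))
  }
  fw <- fusion_forward(model, image, train = FALSE)
  branch_map <- function(pre) {
    cache <- fw$cache[[pre]]$cache
    alpha <- head_channel_weights(model$params, cache, class_index,
                                  prefix = paste0("_", pre))
    gm <- gradcam_map(cache$refined, alpha)
    list(alpha = alpha, norm = gm$norm,
         up = upsample_bilinear(gm$norm, size))
  }
  if (target == "branch_a" || target == "branch_b") {
    pre <- substr(target, 8L, 8L)
    bm <- branch_map(pre)
    return(structure(list(heatmap = bm$norm, upsampled = bm$up,
                          alpha = bm$alpha,
                          target_layer = paste0("attention_refined_", pre),
                          class_index = class_index, weights = fw$weights),
                     class = "pf_gradcam"))
  }
  a <- branch_map("a")
  b <- branch_map("b")
  comb <- fw$weights[1] * a$up + fw$weights[2] * b$up
  mx <- max(comb)
  if (mx > 0) comb <- comb / mx
  structure(list(heatmap = comb, upsampled = comb,
                 alpha = list(branch_a = a$alpha, branch_b = b$alpha),
                 target_layer = "attention_refined_combined",
                 class_index = class_index, weights = fw$weights),
            class = "pf_gradcam")
}

#' Fixed jet-style colormap table
#'
#' A 256-level piecewise-linear blue-cyan-yellow-red table, computed in
#' closed form so overlays are bit-reproducible across platforms.
#'
#' @param n Number of levels (default 256).
#' @return An n x 3 matrix of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function(n = 256L) {
  x <- seq(0, 1, length.out = n)
  ramp <- function(u) pmin(pmax(1.5 - 4 * abs(u), 0), 1)
  cbind(r = ramp(x - 0.75), g = ramp(x - 0.5), b = ramp(x - 0.25))
}

#' Overlay a heatmap on an image
#'
#' @param heatmap Matrix in `[0, 1]` with the image's spatial shape.
#' @param image (H, W, 3) array in `[0, 1]`.
#' @param alpha Blend factor: 0 returns the image, 1 the pure colormapped
#'   heatmap.
#' @param colormap An n x 3 RGB table (default [jet_colormap()]).
#' @return Blended (H, W, 3) array clipped to `[0, 1]`.
#' @export
overlay <- function(heatmap, image, alpha = 0.4, colormap = jet_colormap()) {
  if (!all(dim(heatmap) == dim(image)[1:2])) {
    stop("heatmap and image spatial shapes differ")
  }
  idx <- pmin(pmax(round(heatmap * (nrow(colormap) - 1L)) + 1L, 1L),
              nrow(colormap))
  cmapped <- array(colormap[idx, ], dim(image))
  pmin(pmax(alpha * cmapped + (1 - alpha) * image, 0), 1)
}

#' Intersection-over-union localization score
#'
#' Binarizes the heatmap at an upper quantile and scores the overlap with a
#' ground-truth mask.
#'
#' @param heatmap Numeric matrix.
#' @param truth_mask Binary matrix of the same shape with at least one
#'   positive pixel.
#' @param quantile Upper quantile threshold (default 0.9: top decile kept).
#' @return IoU in `[0, 1]`.
#' @export
localization_score <- function(heatmap, truth_mask, quantile = 0.9) {
  if (!all(dim(heatmap) == dim(truth_mask))) {
    stop("heatmap and mask shapes differ")
  }
  if (sum(truth_mask) == 0) stop("empty truth mask")
  thr <- stats::quantile(heatmap, quantile, names = FALSE)
  bin <- heatmap >= thr
  pos <- truth_mask > 0
  inter <- sum(bin & pos)
  union <- sum(bin | pos)
  if (union == 0) return(0)
  inter / union
}

#' Export a Grad-CAM triptych as PNG
#'
#' Writes original | colormapped heatmap | superimposed image side by side.
#'
#' @param result A `pf_gradcam`.
#' @param image The (H, W, 3) input the result was computed on.
#' @param path Output PNG path.
#' @param alpha Overlay blend factor.
#' @return `path`, invisibly.
#' @export
write_gradcam_png <- function(result, image, path, alpha = 0.4) {
  hm <- result$upsampled
  cm <- overlay(hm, image * 0, alpha = 1)      # pure colormapped heatmap
  ov <- overlay(hm, image, alpha = alpha)
  trip <- array(0, c(dim(image)[1], 3L * dim(image)[2], 3L))
  w <- dim(image)[2]
  trip[, seq_len(w), ] <- image
  trip[, w + seq_len(w), ] <- cm
  trip[, 2L * w + seq_len(w), ] <- ov
  EBImage::writeImage(EBImage::Image(aperm(trip, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}
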