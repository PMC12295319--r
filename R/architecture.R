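# Two-branch attention-fusion architecture.
#
# Per branch: backbone feature map (H, W, C) -> 1x1 sigmoid convolution
# producing a single-channel spatial-attention mask -> element-wise
# multiplication into the feature map -> global average pooling -> dense
# (head_width, ReLU) -> dropout -> dense (num_classes, softmax).
# Fusion: a dense layer with softmax over the concatenation
# [pred_a | pred_b | pooled_a | pooled_b] yields two non-negative weights
# summing to 1; the fused prediction is the weighted sum of the two branch
# probability vectors.

#' Compute a spatial-attention mask
#'
#' A 1x1 convolution with sigmoid activation collapses the channel dimension
#' of a feature map into a single-channel mask over the spatial grid.
#'
#' @param feature_map Numeric array (H, W, C).
#' @param weights Numeric vector of length C (one weight per channel).
#' @param bias Scalar bias.
#' @return Array (H, W, 1) with every value strictly inside (0, 1) for
#'   finite input.
#' @export
attention_mask <- function(feature_map, weights, bias = 0) {
  d <- dim(feature_map)
  if (length(d) != 3L) stop("feature_map must be a (H, W, C) array")
  if (length(weights) != d[3]) {
    stop("attention weights have length ", length(weights),
         " but the feature map has ", d[3], " channels")
  }
  fmat <- matrix(feature_map, nrow = d[1] * d[2], ncol = d[3])
  m <- sigmoid(as.vector(fmat %*% weights) + as.numeric(bias))
  array(m, c(d[1], d[2], 1L))
}

#' Apply an attention mask to a feature map
#'
#' The single-channel mask is broadcast across channels and multiplied
#' element-wise into the map.
#'
#' @param feature_map Array (H, W, C).
#' @param mask Array (H, W, 1) or matrix (H, W).
#' @return Refined array (H, W, C).
#' @export
apply_attention <- function(feature_map, mask) {
  d <- dim(feature_map)
  md <- dim(mask)
  if (!identical(as.integer(md[1:2]), as.integer(d[1:2]))) {
    stop("mask spatial dims (", md[1], ", ", md[2],
         ") do not match feature map (", d[1], ", ", d[2], ")")
  }
  feature_map * as.vector(mask)   # (H*W) recycles across the C slices
}

#' Global average pooling
#'
#' @param feature_map Array (H, W, C) with H, W >= 1.
#' @return Numeric vector of length C: the spatial mean of each channel.
#' @export
global_average_pool <- function(feature_map) {
  d <- dim(feature_map)
  if (length(d) != 3L || d[1] < 1L || d[2] < 1L) {
    stop("global_average_pool needs a non-empty (H, W, C) array")
  }
  colMeans(matrix(feature_map, nrow = d[1] * d[2], ncol = d[3]))
}

#' Instance-specific fusion weights
#'
#' A dense layer with softmax activation maps the concatenation of both
#' branch predictions and both pooled feature vectors to two weights on the
#' 2-simplex.
#'
#' @param pred_a,pred_b Branch probability vectors (length c each).
#' @param pooled_a,pooled_b Pooled feature vectors (length d_a, d_b).
#' @param W Weight matrix (2, 2c + d_a + d_b).
#' @param b Bias vector of length 2.
#' @return Numeric 2-vector, non-negative, summing to 1.
#' @export
attention_weights <- function(pred_a, pred_b, pooled_a, pooled_b, W, b = c(0, 0)) {
  u <- c(pred_a, pred_b, pooled_a, pooled_b)
  if (!is.matrix(W) || nrow(W) != 2L || ncol(W) != length(u)) {
    stop("fusion dense layer expects a 2 x ", length(u),
         " weight matrix (got ", paste(dim(W), collapse = " x "), ")")
  }
  softmax(as.vector(W %*% u) + b)
}

#' Fuse two branch predictions
#'
#' @param pred_a,pred_b Probability vectors of equal length.
#' @param w Fusion weight 2-vector on the simplex.
#' @return `w[1] * pred_a + w[2] * pred_b`.
#' @export
fuse_predictions <- function(pred_a, pred_b, w) {
  if (length(pred_a) != length(pred_b)) {
    stop("branch predictions have different lengths")
  }
  w[1] * pred_a + w[2] * pred_b
}

#' Parameter count of the fusion head
#'
#' Counts, for feature dimensions `d_a`, `d_b`, class count `c` and dense
#' width `h`: the two 1x1 attention convolutions (d + 1 each), the two
#' branch dense layers (h(d + 1) each), the two branch classifiers
#' (c(h + 1) each) and the fusion dense layer (2(2c + d_a + d_b + 1)).
#'
#' @param d_a,d_b Branch feature channel counts.
#' @param num_classes Number of classes c.
#' @param head_width Dense layer width h.
#' @return Integer-valued count.
#' @export
head_parameter_count <- function(d_a, d_b, num_classes, head_width) {
  stopifnot(d_a >= 1, d_b >= 1, num_classes >= 1, head_width >= 1)
  (d_a + 1) + (d_b + 1) +
    head_width * (d_a + 1) + head_width * (d_b + 1) +
    2 * num_classes * (head_width + 1) +
    2 * (2 * num_classes + d_a + d_b + 1)
}

#' Configuration of a two-branch fusion model
#'
#' @param branch_a,branch_b Registered backbone names.
#' @param num_classes Number of output classes (>= 2).
#' @param head_width Width of the per-branch dense layer (default 1024).
#' @param dropout_rate Dropout rate in `[0, 1)` (default 0.5).
#' @param freeze_lower_layers Freeze backbone layers below the fine-tuned top?
#' @param seed Seed for weight initialisation.
#' @return A `pf_fusion_config`.
#' @export
fusion_config <- function(branch_a, branch_b, num_classes,
                          head_width = 1024L, dropout_rate = 0.5,
                          freeze_lower_layers = TRUE, seed = 1L) {
  stopifnot(num_classes >= 2, head_width >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(branch_a = tolower(branch_a), branch_b = tolower(branch_b),
                 num_classes = as.integer(num_classes),
                 head_width = as.integer(head_width),
                 dropout_rate = dropout_rate,
                 freeze_lower_layers = isTRUE(freeze_lower_layers),
                 seed = as.integer(seed)),
            class = "pf_fusion_config")
}

#' Total parameter count of a configured fusion model
#'
#' The two no-top backbone counts plus [head_parameter_count()].
#'
#' @param config A `pf_fusion_config`.
#' @return Numeric count (exact integer value).
#' @export
total_parameter_count <- function(config) {
  sa <- backbone_spec(config$branch_a)
  sb <- backbone_spec(config$branch_b)
  sa$notop_params + sb$notop_params +
    head_parameter_count(sa$feature_shape[3], sb$feature_shape[3],
                         config$num_classes, config$head_width)
}

# Instantiated head parameters for a fusion model.
init_fusion_head <- function(d_a, d_b, c, h, seed) {
  with_local_seed(seed, list(
    att_a_w = as.vector(glorot_uniform(d_a, d_a, 1)), att_a_b = 0,
    att_b_w = as.vector(glorot_uniform(d_b, d_b, 1)), att_b_b = 0,
    dense_a_W = glorot_uniform(c(h, d_a), d_a, h), dense_a_b = rep(0, h),
    dense_b_W = glorot_uniform(c(h, d_b), d_b, h), dense_b_b = rep(0, h),
    clf_a_W = glorot_uniform(c(c, h), h, c), clf_a_b = rep(0, c),
    clf_b_W = glorot_uniform(c(c, h), h, c), clf_b_b = rep(0, c),
    fuse_W = glorot_uniform(c(2, 2 * c + d_a + d_b), 2 * c + d_a + d_b, 2),
    fuse_b = rep(0, 2)
  ))
}

#' Build a two-branch attention-fusion model
#'
#' Assembles the full architecture with instantiated head weights
#' (Glorot-uniform, zero biases, seeded). Backbones with trainable builders
#' (the `"tiny"` backbone) are instantiated with real weights and support
#' forward passes and training; the ImageNet backbones are carried as opaque
#' specs so the model can be assembled and counted without their weights.
#'
#' @param config A [fusion_config()].
#' @return A `pf_model` of subclass `pf_fusion`.
#' @export
build_fusion_model <- function(config) {
  stopifnot(inherits(config, "pf_fusion_config"))
  back_a <- instantiate_backbone(backbone_spec(config$branch_a), config$seed)
  back_b <- instantiate_backbone(backbone_spec(config$branch_b),
                                 config$seed + 1L)
  d_a <- back_a$spec$feature_shape[3]
  d_b <- back_b$spec$feature_shape[3]
  params <- init_fusion_head(d_a, d_b, config$num_classes,
                             config$head_width, config$seed + 2L)
  structure(list(config = config, backbone_a = back_a, backbone_b = back_b,
                 params = params, dropout_rate = config$dropout_rate),
            class = c("pf_fusion", "pf_model"))
}

#' Build a single-backbone baseline classifier
#'
#' Backbone -> global average pooling -> dense (`head_width`, ReLU) ->
#' dropout -> dense (`num_classes`, softmax). This is the transfer-learning
#' baseline the fusion model is compared against; it has no attention stage.
#'
#' @param backbone Registered backbone name.
#' @param num_classes Number of classes.
#' @param head_width Dense width (default 1024).
#' @param dropout_rate Dropout rate (default 0.5).
#' @param seed Seed for weight initialisation.
#' @return A `pf_model` of subclass `pf_baseline`.
#' @export
build_baseline <- function(backbone, num_classes, head_width = 1024L,
                           dropout_rate = 0.5, seed = 1L) {
  back <- instantiate_backbone(backbone_spec(backbone), seed)
  d <- back$spec$feature_shape[3]
  h <- as.integer(head_width)
  c <- as.integer(num_classes)
  params <- with_local_seed(seed + 2L, list(
    dense_W = glorot_uniform(c(h, d), d, h), dense_b = rep(0, h),
    clf_W = glorot_uniform(c(c, h), h, c), clf_b = rep(0, c)
  ))
  structure(list(config = list(backbone = tolower(backbone), num_classes = c,
                               head_width = h, seed = as.integer(seed)),
                 backbone_a = back, params = params,
                 dropout_rate = dropout_rate),
            class = c("pf_baseline", "pf_model"))
}

#' Count the parameters of an assembled model
#'
#' Instantiated weight arrays are counted directly by enumeration; opaque
#' backbones contribute their registered no-top counts.
#'
#' @param model A `pf_model`.
#' @return Numeric count.
#' @export
count_parameters <- function(model) {
  head_n <- sum(vapply(model$params, length, 0L))
  n <- backbone_param_count(model$backbone_a) + head_n
  if (!is.null(model$backbone_b)) n <- n + backbone_param_count(model$backbone_b)
  n
}

#' Layer-by-layer model summary
#'
#' @param model A `pf_model`.
#' @return A tibble with layer name, output shape and parameter count;
#'   serialise with [summary_to_json()].
#' @export
model_summary <- function(model) {
  rows <- list()
  add <- function(layer, shape, params) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = layer, output_shape = shape, params = params)
  }
  shp <- function(v) paste(v, collapse = "x")
  describe_branch <- function(back, tag, params, pre) {
    fs <- back$spec$feature_shape
    add(paste0("backbone_", tag, " (", back$spec$name, ")"), shp(fs),
        backbone_param_count(back))
    add(paste0("attention_conv_", tag), shp(c(fs[1], fs[2], 1)),
        length(params[[paste0("att_", pre, "_w")]]) + 1)
    add(paste0("gap_", tag), as.character(fs[3]), 0)
    add(paste0("dense_", tag), as.character(model$config$head_width),
        length(params[[paste0("dense_", pre, "_W")]]) +
          length(params[[paste0("dense_", pre, "_b")]]))
    add(paste0("classifier_", tag), as.character(model$config$num_classes),
        length(params[[paste0("clf_", pre, "_W")]]) +
          length(params[[paste0("clf_", pre, "_b")]]))
  }
  if (inherits(model, "pf_fusion")) {
    describe_branch(model$backbone_a, "a", model$params, "a")
    describe_branch(model$backbone_b, "b", model$params, "b")
    add("fusion_dense", "2",
        length(model$params$fuse_W) + length(model$params$fuse_b))
  } else {
    back <- model$backbone_a
    add(paste0("backbone (", back$spec$name, ")"), shp(back$spec$feature_shape),
        backbone_param_count(back))
    add("gap", as.character(back$spec$feature_shape[3]), 0)
    add("dense", as.character(model$config$head_width),
        length(model$params$dense_W) + length(model$params$dense_b))
    add("classifier", as.character(model$config$num_classes),
        length(model$params$clf_W) + length(model$params$clf_b))
  }
  dplyr::bind_rows(rows)
}

#' Serialise a model summary to JSON
#'
#' @param model A `pf_model`.
#' @return A JSON string (layer name, output shape, parameter count, total).
#' @export
summary_to_json <- function(model) {
  s <- model_summary(model)
  jsonlite::toJSON(list(layers = s, total_params = count_parameters(model)),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}

# ---- Forward passes ------------------------------------------------------

# Branch forward for one image: returns probabilities, pooled vector and
# every intermediate needed for the backward pass and Grad-CAM.
branch_forward <- function(backbone, x, params, pre, dropout_rate,
                           train = FALSE) {
  bf <- backbone_forward(backbone, x)
  feat <- bf$out
  mask <- attention_mask(feat, params[[paste0("att_", pre, "_w")]],
                         params[[paste0("att_", pre, "_b")]])
  refined <- apply_attention(feat, mask)
  pooled <- global_average_pool(refined)
  df <- dense_forward(pooled, params[[paste0("dense_", pre, "_W")]],
                      params[[paste0("dense_", pre, "_b")]])
  act <- relu(df$out)
  if (train && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    drop_mask <- (stats::runif(length(act)) < keep) / keep
  } else {
    drop_mask <- rep(1, length(act))
  }
  dropped <- act * drop_mask
  cf <- dense_forward(dropped, params[[paste0("clf_", pre, "_W")]],
                      params[[paste0("clf_", pre, "_b")]])
  prob <- softmax(cf$out)
  list(prob = prob, pooled = pooled, logits = cf$out,
       cache = list(backbone = bf$caches, feat = feat, mask = mask,
                    refined = refined, pooled = pooled, dense = df$cache,
                    pre_act = df$out, act = act, drop_mask = drop_mask,
                    dropped = dropped, clf = cf$cache))
}

# Full fusion forward for one image.
fusion_forward <- function(model, x, train = FALSE) {
  p <- model$params
  a <- branch_forward(model$backbone_a, x, p, "a", model$dropout_rate, train)
  b <- branch_forward(model$backbone_b, x, p, "b", model$dropout_rate, train)
  u <- c(a$prob, b$prob, a$pooled, b$pooled)
  wl <- as.vector(p$fuse_W %*% u) + p$fuse_b
  w <- softmax(wl)
  fused <- fuse_predictions(a$prob, b$prob, w)
  list(pred_a = a$prob, pred_b = b$prob, weights = w, fused = fused,
       cache = list(a = a, b = b, u = u, w = w))
}

baseline_forward <- function(model, x, train = FALSE) {
  p <- model$params
  bf <- backbone_forward(model$backbone_a, x)
  pooled <- global_average_pool(bf$out)
  df <- dense_forward(pooled, p$dense_W, p$dense_b)
  act <- relu(df$out)
  if (train && model$dropout_rate > 0) {
    keep <- 1 - model$dropout_rate
    drop_mask <- (stats::runif(length(act)) < keep) / keep
  } else {
    drop_mask <- rep(1, length(act))
  }
  dropped <- act * drop_mask
  cf <- dense_forward(dropped, p$clf_W, p$clf_b)
  prob <- softmax(cf$out)
  list(fused = prob, logits = cf$out,
       cache = list(backbone = bf$caches, feat = bf$out, pooled = pooled,
                    dense = df$cache, pre_act = df$out, act = act,
                    drop_mask = drop_mask, dropped = dropped, clf = cf$cache))
}

#' Predict class probabilities
#'
#' @param object A `pf_model`.
#' @param images A `pf_dataset`, or a list of (H, W, 3) arrays, or a single
#'   array.
#' @param ... Unused.
#' @return A `pf_prediction`: for fusion models it carries the per-branch
#'   probability matrices, the per-instance fusion weights and the fused
#'   probabilities; for baselines just the probabilities. `tidy()` turns it
#'   into a tibble.
#' @export
predict.pf_model <- function(object, images, ...) {
  imgs <- as_image_list(images)
  n <- length(imgs)
  c <- object$config$num_classes
  fused <- matrix(NA_real_, n, c)
  if (inherits(object, "pf_fusion")) {
    pred_a <- matrix(NA_real_, n, c)
    pred_b <- matrix(NA_real_, n, c)
    weights <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      fw <- fusion_forward(object, imgs[[i]], train = FALSE)
      fused[i, ] <- fw$fused
      pred_a[i, ] <- fw$pred_a
      pred_b[i, ] <- fw$pred_b
      weights[i, ] <- fw$weights
    }
    out <- list(fused = fused, pred_a = pred_a, pred_b = pred_b,
                weights = weights, class = max.col(fused) - 1L)
  } else {
    for (i in seq_len(n)) {
      fused[i, ] <- baseline_forward(object, imgs[[i]], train = FALSE)$fused
    }
    out <- list(fused = fused, class = max.col(fused) - 1L)
  }
  structure(out, class = "pf_prediction")
}

as_image_list <- function(images) {
  if (inherits(images, "pf_dataset")) return(images$images)
  if (is.list(images)) return(images)
  if (is.array(images) && length(dim(images)) == 3L) return(list(images))
  stop("images must be a pf_dataset, a list of arrays, or a single array")
}
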