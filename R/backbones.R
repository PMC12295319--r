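# Backbone registry. A backbone is a no-top convolutional feature extractor
# described by its input shape, final feature-map shape and no-top parameter
# count. The three ImageNet architectures are registered as opaque specs:
# their feature shapes and canonical no-top counts are what the fusion
# architecture and its parameter accounting need, and the counts are exactly
# recoverable from the published totals of the three assembled fusion models
# once the head is accounted for (see total_parameter_count()). The "tiny"
# backbone is a real two-layer convolutional stack with instantiated weights,
# used for desk-scale training, Grad-CAM and end-to-end tests.

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone specification
#'
#' @param name Registry key (lower case).
#' @param input_shape Integer triple (height, width, channels).
#' @param feature_shape Integer triple (H, W, C) of the final convolutional
#'   feature map at `input_shape`.
#' @param notop_params Parameter count of the no-top extractor.
#' @param builder Either `NULL` (opaque spec: parameter accounting only) or a
#'   `function(seed)` returning a list of convolution layers with instantiated
#'   weights, enabling forward/backward passes.
#' @param n_layers Number of weight layers, used by the freezing policy.
#' @return The spec, invisibly.
#' @export
register_backbone <- function(name, input_shape, feature_shape, notop_params,
                              builder = NULL, n_layers = NA_integer_) {
  spec <- list(name = name,
               input_shape = as.integer(input_shape),
               feature_shape = as.integer(feature_shape),
               notop_params = as.numeric(notop_params),
               builder = builder,
               n_layers = as.integer(n_layers))
  class(spec) <- "pf_backbone_spec"
  assign(name, spec, envir = .backbone_registry)
  invisible(spec)
}

#' Look up a registered backbone
#'
#' @param name Registry key, e.g. `"inceptionv3"`, `"xception"`,
#'   `"mobilenet"` or `"tiny"`.
#' @return A `pf_backbone_spec`.
#' @export
backbone_spec <- function(name) {
  name <- tolower(name)
  if (!exists(name, envir = .backbone_registry, inherits = FALSE)) {
    stop("unknown backbone '", name, "'; registered: ",
         paste(sort(ls(.backbone_registry)), collapse = ", "))
  }
  get(name, envir = .backbone_registry)
}

#' List registered backbones
#'
#' @return A tibble with one row per registered backbone: name, input and
#'   feature shapes, no-top parameter count, and whether a trainable builder
#'   is available.
#' @export
list_backbones <- function() {
  specs <- lapply(sort(ls(.backbone_registry)), backbone_spec)
  tibble::tibble(
    name = purrr::map_chr(specs, "name"),
    input_shape = purrr::map_chr(specs, ~ paste(.x$input_shape, collapse = "x")),
    feature_shape = purrr::map_chr(specs, ~ paste(.x$feature_shape, collapse = "x")),
    notop_params = purrr::map_dbl(specs, "notop_params"),
    trainable = purrr::map_lgl(specs, ~ !is.null(.x$builder))
  )
}

# Tiny backbone: two valid-padding stride-2 convolutions with ReLU,
# (32, 32, 3) -> (15, 15, 8) -> (7, 7, 16). 1,392 parameters.
tiny_backbone_builder <- function(seed = 1L) {
  with_local_seed(seed, {
    list(
      list(W = glorot_uniform(c(3, 3, 3, 8), 3 * 3 * 3, 8),
           b = rep(0, 8), stride = 2L),
      list(W = glorot_uniform(c(3, 3, 8, 16), 3 * 3 * 8, 16),
           b = rep(0, 16), stride = 2L)
    )
  })
}

# Instantiate a backbone for use inside a model. Opaque specs get no layers;
# the tiny backbone gets real weights.
instantiate_backbone <- function(spec, seed = 1L) {
  layers <- if (is.null(spec$builder)) NULL else spec$builder(seed)
  structure(list(spec = spec, layers = layers,
                 trainable = rep(FALSE, spec$n_layers %||% 0L)),
            class = "pf_backbone")
}

backbone_param_count <- function(backbone) {
  if (is.null(backbone$layers)) return(backbone$spec$notop_params)
  sum(vapply(backbone$layers, function(l) length(l$W) + length(l$b), 0))
}

# Forward through an instantiated backbone; caches per-layer inputs.
backbone_forward <- function(backbone, x) {
  if (is.null(backbone$layers)) {
    stop("backbone '", backbone$spec$name,
         "' is registered for parameter accounting only and has no ",
         "instantiated weights; use the 'tiny' backbone for forward passes")
  }
  caches <- vector("list", length(backbone$layers))
  for (i in seq_along(backbone$layers)) {
    l <- backbone$layers[[i]]
    cf <- conv2d_forward(x, l$W, l$b, l$stride)
    pre <- cf$out
    x <- relu(pre)
    caches[[i]] <- list(conv = cf$cache, pre = pre)
  }
  list(out = x, caches = caches)
}

# Backward through the backbone. Returns per-layer weight gradients (NULL
# for frozen layers unless `need_all`) and optionally the input gradient.
backbone_backward <- function(backbone, caches, dout) {
  grads <- vector("list", length(backbone$layers))
  for (i in rev(seq_along(backbone$layers))) {
    dpre <- dout * (caches[[i]]$pre > 0)
    cb <- conv2d_backward(caches[[i]]$conv, dpre)
    grads[[i]] <- list(dW = cb$dW, db = cb$db)
    dout <- cb$dx
  }
  list(grads = grads, dx = dout)
}

# Canonical registrations happen at load time.
register_default_backbones <- function() {
  register_backbone("inceptionv3", c(224, 224, 3), c(5, 5, 2048),
                    21802784, n_layers = 94L)
  register_backbone("xception", c(224, 224, 3), c(7, 7, 2048),
                    20861480, n_layers = 74L)
  register_backbone("mobilenet", c(224, 224, 3), c(7, 7, 1024),
                    3228864, n_layers = 27L)
  register_backbone("tiny", c(32, 32, 3), c(7, 7, 16),
                    1392, builder = tiny_backbone_builder, n_layers = 2L)
}

.onLoad <- function(libname, pkgname) {
  register_default_backbones()
}
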