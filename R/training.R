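# Training protocol: Adam at 1e-4, categorical cross-entropy, batch size 32,
# at most 50 epochs, step learning-rate decay (factor 10 every ten epochs
# from epoch 10, floored at 1e-6), early stopping on validation loss with
# patience 10 and best-weight restoration, and partial backbone freezing
# (the last `unfrozen_top_layers` of each backbone plus the whole head).

#' Training configuration
#'
#' Defaults are the protocol used throughout: Adam, initial learning rate
#' 1e-4, 50 epochs maximum, batch size 32, validation-loss early stopping
#' with patience 10 and best-weight restoration, minimum learning rate 1e-6,
#' 20 unfrozen top layers per backbone.
#'
#' @param learning_rate Initial learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param restore_best Restore the best-validation-loss weights at the end?
#' @param min_learning_rate Floor for the decayed learning rate.
#' @param unfrozen_top_layers Backbone layers left trainable from the top.
#' @param freeze_mode `"per_backbone"` unfreezes the top layers of each
#'   branch backbone; `"combined"` counts layers over the concatenated
#'   backbone layer list instead.
#' @param seed Seed controlling shuffling, dropout and validation split.
#' @return A `pf_training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, max_epochs = 50L,
                            batch_size = 32L, patience = 10L,
                            restore_best = TRUE, min_learning_rate = 1e-6,
                            unfrozen_top_layers = 20L,
                            freeze_mode = c("per_backbone", "combined"),
                            seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs > 0, batch_size > 0,
            patience > 0, patience < max_epochs, min_learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 min_learning_rate = min_learning_rate,
                 unfrozen_top_layers = as.integer(unfrozen_top_layers),
                 freeze_mode = match.arg(freeze_mode),
                 seed = as.integer(seed)),
            class = "pf_training_config")
}

#' Step-decay learning-rate schedule
#'
#' No change before epoch 10; thereafter the rate drops by a factor of 10
#' every ten epochs, floored at the configured minimum:
#' `max(base * 10^(-floor(epoch / 10)), min_learning_rate)`.
#'
#' @param epoch Zero-based epoch index.
#' @param config A [training_config()].
#' @return The learning rate for that epoch.
#' @export
learning_rate_at <- function(epoch, config = training_config()) {
  stopifnot(all(epoch >= 0))
  pmax(config$learning_rate * 10^(-(epoch %/% 10)), config$min_learning_rate)
}

#' Initial early-stopping state
#'
#' @return A `pf_early_stop` with infinite best loss.
#' @export
early_stop_state <- function() {
  structure(list(best_loss = Inf, best_epoch = NA_integer_,
                 epochs_since_improvement = 0L, stopped = FALSE),
            class = "pf_early_stop")
}

#' Update early-stopping state with one validation loss
#'
#' Strict improvement resets the counter and records the epoch; after
#' `patience` consecutive non-improving epochs `stopped` becomes `TRUE`.
#' A non-finite loss counts as non-improvement (with a warning).
#'
#' @param state A `pf_early_stop`.
#' @param epoch Zero-based epoch index.
#' @param val_loss Validation loss observed this epoch.
#' @param patience Number of non-improving epochs tolerated.
#' @return The updated state.
#' @export
early_stop_update <- function(state, epoch, val_loss, patience = 10L) {
  if (!is.finite(val_loss)) {
    warning("non-finite validation loss at epoch ", epoch,
            "; treated as non-improvement")
    val_loss <- Inf
  }
  if (val_loss < state$best_loss) {
    state$best_loss <- val_loss
    state$best_epoch <- as.integer(epoch)
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    if (state$epochs_since_improvement >= patience) state$stopped <- TRUE
  }
  state
}

#' Apply the layer-freezing policy
#'
#' Marks the last `unfrozen_top_layers` weight layers of each backbone as
#' trainable (mode `"per_backbone"`), or the last `unfrozen_top_layers` of
#' the concatenated layer list (mode `"combined"`); the custom head is
#' always trainable. Asking for more layers than exist leaves the whole
#' backbone trainable with a warning.
#'
#' @param model A `pf_model`.
#' @param unfrozen_top_layers Number of layers to leave trainable.
#' @param mode `"per_backbone"` or `"combined"`.
#' @return The model with updated trainable flags.
#' @export
freeze_policy <- function(model, unfrozen_top_layers,
                          mode = c("per_backbone", "combined")) {
  mode <- match.arg(mode)
  n <- as.integer(unfrozen_top_layers)
  mark <- function(depth, k) {
    if (k > depth) {
      warning("unfrozen_top_layers (", k, ") exceeds backbone depth (",
              depth, "); all layers trainable")
      k <- depth
    }
    c(rep(FALSE, depth - k), rep(TRUE, k))
  }
  backs <- c("backbone_a", if (!is.null(model$backbone_b)) "backbone_b")
  depths <- vapply(backs, function(bn) {
    b <- model[[bn]]
    if (is.null(b$layers)) b$spec$n_layers else length(b$layers)
  }, 0L)
  if (mode == "per_backbone" || length(backs) == 1L) {
    for (i in seq_along(backs)) {
      model[[backs[i]]]$trainable <- mark(depths[i], n)
    }
  } else {
    flags <- mark(sum(depths), n)
    split_at <- depths[1]
    model$backbone_a$trainable <- flags[seq_len(split_at)]
    model$backbone_b$trainable <- flags[-seq_len(split_at)]
  }
  model
}

# ---- Flattened parameter view (head + trainable backbone layers) --------

model_flat_params <- function(model) {
  flat <- model$params
  for (bn in c("backbone_a", "backbone_b")) {
    b <- model[[bn]]
    if (is.null(b) || is.null(b$layers)) next
    for (i in seq_along(b$layers)) {
      flat[[paste0(bn, "_", i, "_W")]] <- b$layers[[i]]$W
      flat[[paste0(bn, "_", i, "_b")]] <- b$layers[[i]]$b
    }
  }
  flat
}

model_set_params <- function(model, flat) {
  model$params <- flat[names(model$params)]
  for (bn in c("backbone_a", "backbone_b")) {
    b <- model[[bn]]
    if (is.null(b) || is.null(b$layers)) next
    for (i in seq_along(b$layers)) {
      model[[bn]]$layers[[i]]$W <- flat[[paste0(bn, "_", i, "_W")]]
      model[[bn]]$layers[[i]]$b <- flat[[paste0(bn, "_", i, "_b")]]
    }
  }
  model
}

trainable_param_names <- function(model) {
  nms <- names(model$params)   # the head is always trainable
  for (bn in c("backbone_a", "backbone_b")) {
    b <- model[[bn]]
    if (is.null(b) || is.null(b$layers)) next
    tr <- b$trainable
    if (length(tr) != length(b$layers)) tr <- rep(FALSE, length(b$layers))
    for (i in which(tr)) {
      nms <- c(nms, paste0(bn, "_", i, "_W"), paste0(bn, "_", i, "_b"))
    }
  }
  nms
}

# ---- Backward passes -----------------------------------------------------

cross_entropy <- function(fused, y, eps = 1e-12) {
  -sum(y * log(pmax(fused, eps)))
}

# Backward through one branch head given d(loss)/d(prob) and any extra
# gradient arriving at the pooled vector (from the fusion input). Returns
# head gradients plus the gradient flowing into the backbone feature map.
branch_backward <- function(cache, prob, dprob, dpooled_extra, params, pre,
                            backbone, need_backbone) {
  g <- list()
  dlogits <- softmax_backward(prob, dprob)
  cb <- dense_backward(cache$clf, dlogits)
  g[[paste0("clf_", pre, "_W")]] <- cb$dW
  g[[paste0("clf_", pre, "_b")]] <- cb$db
  dact <- cb$dx * cache$drop_mask
  dpre <- dact * (cache$pre_act > 0)
  db <- dense_backward(cache$dense, dpre)
  g[[paste0("dense_", pre, "_W")]] <- db$dW
  g[[paste0("dense_", pre, "_b")]] <- db$db
  dpooled <- db$dx + dpooled_extra
  fd <- dim(cache$feat)
  hw <- fd[1] * fd[2]
  # GAP backward: spread each channel gradient uniformly over the grid
  drefined <- aperm(array(rep(dpooled / hw, each = hw), fd), c(1, 2, 3))
  feat_mat <- matrix(cache$feat, hw, fd[3])
  dref_mat <- matrix(drefined, hw, fd[3])
  m <- as.vector(cache$mask)
  dmask <- rowSums(dref_mat * feat_mat)
  dfeat_mat <- dref_mat * m
  ds <- dmask * m * (1 - m)                     # through the sigmoid
  g[[paste0("att_", pre, "_w")]] <- as.vector(crossprod(feat_mat, ds))
  g[[paste0("att_", pre, "_b")]] <- sum(ds)
  dfeat_mat <- dfeat_mat + outer(ds, params[[paste0("att_", pre, "_w")]])
  out <- list(grads = g)
  if (need_backbone) {
    dfeat <- array(dfeat_mat, fd)
    bb <- backbone_backward(backbone, cache$backbone, dfeat)
    for (i in seq_along(bb$grads)) {
      out$grads[[paste0("__bk_", pre, "_", i, "_W")]] <- bb$grads[[i]]$dW
      out$grads[[paste0("__bk_", pre, "_", i, "_b")]] <- bb$grads[[i]]$db
    }
  }
  out
}

# Loss and gradients for one image through the fusion model.
fusion_loss_grad <- function(model, x, y, train = TRUE) {
  fw <- fusion_forward(model, x, train = train)
  loss <- cross_entropy(fw$fused, y)
  cc <- fw$cache
  c_ <- model$config$num_classes
  dfused <- -y / pmax(fw$fused, 1e-12)
  dw <- c(sum(dfused * fw$pred_a), sum(dfused * fw$pred_b))
  dpa <- cc$w[1] * dfused
  dpb <- cc$w[2] * dfused
  dwl <- softmax_backward(cc$w, dw)
  g <- list(fuse_W = outer(dwl, cc$u), fuse_b = dwl)
  du <- as.vector(crossprod(model$params$fuse_W, dwl))
  dpa <- dpa + du[seq_len(c_)]
  dpb <- dpb + du[c_ + seq_len(c_)]
  d_a <- length(cc$a$pooled)
  dga <- du[2 * c_ + seq_len(d_a)]
  dgb <- du[2 * c_ + d_a + seq_along(cc$b$pooled)]
  need_a <- any(model$backbone_a$trainable)
  need_b <- any(model$backbone_b$trainable)
  ba <- branch_backward(cc$a$cache, fw$pred_a, dpa, dga, model$params, "a",
                        model$backbone_a, need_a)
  bb <- branch_backward(cc$b$cache, fw$pred_b, dpb, dgb, model$params, "b",
                        model$backbone_b, need_b)
  g <- c(g, ba$grads, bb$grads)
  names(g) <- sub("^__bk_a_", "backbone_a_", names(g))
  names(g) <- sub("^__bk_b_", "backbone_b_", names(g))
  list(loss = loss, fused = fw$fused, grads = g)
}

baseline_loss_grad <- function(model, x, y, train = TRUE) {
  fw <- baseline_forward(model, x, train = train)
  loss <- cross_entropy(fw$fused, y)
  cache <- fw$cache
  dprob <- -y / pmax(fw$fused, 1e-12)
  dlogits <- softmax_backward(fw$fused, dprob)
  cb <- dense_backward(cache$clf, dlogits)
  g <- list(clf_W = cb$dW, clf_b = cb$db)
  dact <- cb$dx * cache$drop_mask
  dpre <- dact * (cache$pre_act > 0)
  db <- dense_backward(cache$dense, dpre)
  g$dense_W <- db$dW
  g$dense_b <- db$db
  if (any(model$backbone_a$trainable)) {
    fd <- dim(cache$feat)
    hw <- fd[1] * fd[2]
    dfeat <- array(rep(db$dx / hw, each = hw), fd)
    bbk <- backbone_backward(model$backbone_a, cache$backbone, dfeat)
    for (i in seq_along(bbk$grads)) {
      g[[paste0("backbone_a_", i, "_W")]] <- bbk$grads[[i]]$dW
      g[[paste0("backbone_a_", i, "_b")]] <- bbk$grads[[i]]$db
    }
  }
  list(loss = loss, fused = fw$fused, grads = g)
}

accumulate_grads <- function(total, g, scale = 1) {
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] * scale
                   else total[[nm]] + g[[nm]] * scale
  }
  total
}

# Mean loss / accuracy of a model over an index subset (no dropout).
evaluate_loss_acc <- function(model, images, onehot, idx) {
  loss <- 0
  correct <- 0L
  lg <- if (inherits(model, "pf_fusion")) fusion_forward else baseline_forward
  for (i in idx) {
    fw <- lg(model, images[[i]], train = FALSE)
    loss <- loss + cross_entropy(fw$fused, onehot[i, ])
    correct <- correct + (which.max(fw$fused) == which.max(onehot[i, ]))
  }
  list(loss = loss / length(idx), acc = correct / length(idx))
}

#' Train a model
#'
#' Runs the full protocol on a labelled dataset: a seeded validation split
#' carved from the training data, minibatch Adam with the step-decay
#' schedule, early stopping on validation loss, and best-weight restoration.
#' The run is deterministic given the configuration seed.
#'
#' @param model A `pf_model` (fusion or baseline) built on a trainable
#'   backbone.
#' @param dataset A `pf_dataset` whose image size matches the model's
#'   backbone input.
#' @param config A [training_config()].
#' @param val_fraction Fraction of `dataset` held out for the validation
#'   loss monitored by early stopping (default 0.15).
#' @return A `pf_fit`: the trained model, a per-epoch `history` tibble
#'   (epoch, lr, train_loss, train_acc, val_loss, val_acc), the best and
#'   stopping epochs.
#' @export
train_model <- function(model, dataset, config = training_config(),
                        val_fraction = 0.15) {
  stopifnot(inherits(model, "pf_model"), inherits(dataset, "pf_dataset"))
  n <- length(dataset$images)
  if (n == 0L) stop("cannot train on an empty dataset")
  k <- model$config$num_classes
  onehot <- one_hot(dataset$labels, k)
  model <- freeze_policy(model, config$unfrozen_top_layers, config$freeze_mode)
  trainable <- trainable_param_names(model)
  loss_grad <- if (inherits(model, "pf_fusion")) fusion_loss_grad
               else baseline_loss_grad

  with_local_seed(config$seed, {
    vplan <- split_plan(n, test_fraction = val_fraction, seed = config$seed)
    val_idx <- vplan$test_indices
    tr_idx <- vplan$train_indices
    params <- model_flat_params(model)
    opt <- adam_init(params)
    es <- early_stop_state()
    best_params <- params
    hist <- vector("list", config$max_epochs)
    last_epoch <- -1L
    for (epoch in 0:(config$max_epochs - 1L)) {
      lr <- learning_rate_at(epoch, config)
      order <- sample(tr_idx)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      ep_loss <- 0
      ep_correct <- 0L
      for (batch in batches) {
        grads <- list()
        for (i in batch) {
          lgi <- loss_grad(model, dataset$images[[i]], onehot[i, ],
                           train = TRUE)
          ep_loss <- ep_loss + lgi$loss
          ep_correct <- ep_correct +
            (which.max(lgi$fused) == which.max(onehot[i, ]))
          grads <- accumulate_grads(grads, lgi$grads, 1 / length(batch))
        }
        st <- adam_step(params, grads, opt, lr, trainable = trainable)
        params <- st$params
        opt <- st$state
        model <- model_set_params(model, params)
      }
      val <- evaluate_loss_acc(model, dataset$images, onehot, val_idx)
      hist[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / length(tr_idx),
        train_acc = ep_correct / length(tr_idx),
        val_loss = val$loss, val_acc = val$acc)
      prev_best <- es$best_loss
      es <- early_stop_update(es, epoch, val$loss, config$patience)
      if (val$loss < prev_best) best_params <- params
      last_epoch <- epoch
      if (es$stopped) break
    }
    if (config$restore_best && !is.na(es$best_epoch)) {
      model <- model_set_params(model, best_params)
    }
    structure(list(model = model,
                   history = dplyr::bind_rows(hist[!vapply(hist, is.null, TRUE)]),
                   best_epoch = es$best_epoch,
                   stopped_epoch = last_epoch,
                   stopped_early = es$stopped,
                   val_indices = val_idx),
              class = "pf_fit")
  })
}

#' Train only the fusion gate on fixed branch outputs
#'
#' Holds both branches frozen (their probability vectors and pooled feature
#' vectors are given) and fits only the fusion dense layer by Adam on the
#' cross-entropy of the fused prediction. This isolates the decision-fusion
#' mechanism: with one reliable and one unreliable branch, the learned
#' weights should concentrate on the reliable one.
#'
#' @param pred_a,pred_b Matrices (n, c) of branch probabilities.
#' @param pooled_a,pooled_b Matrices (n, d_a) and (n, d_b) of pooled
#'   features.
#' @param labels Integer class labels in `[0, c)`.
#' @param epochs Number of passes (default 100).
#' @param learning_rate Adam learning rate (default 0.05; the gate is a
#'   single small dense layer).
#' @param seed Initialisation/shuffling seed.
#' @return A list with the fitted `W`, `b`, per-instance `weights` matrix
#'   (n, 2), `fused` probabilities, `accuracy`, and `mean_weights`.
#' @export
train_fusion_gate <- function(pred_a, pred_b, pooled_a, pooled_b, labels,
                              epochs = 100L, learning_rate = 0.05,
                              seed = 1L) {
  n <- nrow(pred_a)
  c_ <- ncol(pred_a)
  u_all <- cbind(pred_a, pred_b, pooled_a, pooled_b)
  y <- one_hot(labels, c_)
  with_local_seed(seed, {
    params <- list(W = glorot_uniform(c(2, ncol(u_all)), ncol(u_all), 2),
                   b = rep(0, 2))
    opt <- adam_init(params)
    for (ep in seq_len(epochs)) {
      grads <- list(W = array(0, dim(params$W)), b = c(0, 0))
      for (i in seq_len(n)) {
        u <- u_all[i, ]
        w <- softmax(as.vector(params$W %*% u) + params$b)
        fused <- w[1] * pred_a[i, ] + w[2] * pred_b[i, ]
        dfused <- -y[i, ] / pmax(fused, 1e-12)
        dw <- c(sum(dfused * pred_a[i, ]), sum(dfused * pred_b[i, ]))
        dwl <- softmax_backward(w, dw)
        grads$W <- grads$W + outer(dwl, u) / n
        grads$b <- grads$b + dwl / n
      }
      st <- adam_step(params, grads, opt, learning_rate)
      params <- st$params
      opt <- st$state
    }
    weights <- t(apply(u_all, 1L, function(u) {
      softmax(as.vector(params$W %*% u) + params$b)
    }))
    fused <- weights[, 1] * pred_a + weights[, 2] * pred_b
    list(W = params$W, b = params$b, weights = weights, fused = fused,
         accuracy = mean(max.col(fused) - 1L == labels),
         mean_weights = colMeans(weights))
  })
}

#' Write a training history to CSV
#'
#' @param fit A `pf_fit` (or its `history` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(fit, path) {
  h <- if (inherits(fit, "pf_fit")) fit$history else fit
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
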