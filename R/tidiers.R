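# broom-style tidiers and ggplot2 autoplot methods for the package's result
# types, so results drop straight into dplyr/ggplot2 pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a confusion matrix into long form
#'
#' @param x A `pf_confusion`.
#' @param ... Unused.
#' @return Tibble with columns `actual`, `predicted`, `n`.
#' @export
tidy.pf_confusion <- function(x, ...) {
  m <- as.matrix(x)
  nms <- rownames(m) %||% paste0("class_", seq_len(nrow(m)) - 1L)
  tibble::tibble(
    actual = rep(nms, times = ncol(m)),
    predicted = rep(nms, each = nrow(m)),
    n = as.vector(m))
}

#' Tidy a metric report (per-class rates)
#'
#' @param x A `pf_metrics`.
#' @param ... Unused.
#' @return The per-class tibble in long form (`class`, `metric`, `value`).
#' @export
tidy.pf_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$per_class, -"class",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a metric report
#'
#' @param x A `pf_metrics`.
#' @param ... Unused.
#' @return The overall tibble (accuracy %, MCC, kappa, misclassification,
#'   macro averages).
#' @export
glance.pf_metrics <- function(x, ...) x$overall

#' Tidy a prediction into one row per instance
#'
#' @param x A `pf_prediction`.
#' @param ... Unused.
#' @return Tibble with the predicted class, the fused probabilities and —
#'   for fusion models — the two fusion weights.
#' @export
tidy.pf_prediction <- function(x, ...) {
  out <- tibble::tibble(instance = seq_len(nrow(x$fused)), class = x$class)
  probs <- tibble::as_tibble(x$fused, .name_repair = ~ paste0("p_", seq_along(.) - 1L))
  out <- dplyr::bind_cols(out, probs)
  if (!is.null(x$weights)) {
    out$weight_a <- x$weights[, 1]
    out$weight_b <- x$weights[, 2]
  }
  out
}

#' One-row training summary
#'
#' @param x A `pf_fit`.
#' @param ... Unused.
#' @return Tibble: epochs run, best epoch, whether early stopping fired,
#'   best validation loss and final training accuracy.
#' @export
glance.pf_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    stopped_early = x$stopped_early,
    best_val_loss = min(h$val_loss),
    final_train_acc = h$train_acc[nrow(h)],
    final_val_acc = h$val_acc[nrow(h)])
}

#' Tidy a model comparison
#'
#' @param x A `pf_comparison`.
#' @param ... Unused.
#' @return The test tibble (statistic, p-value, and post hoc pairs when an
#'   ANOVA was run).
#' @export
tidy.pf_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) {
    dplyr::bind_rows(
      dplyr::mutate(x$test, model_1 = NA_character_, model_2 = NA_character_),
      dplyr::mutate(x$posthoc, method = "pairwise t (bonferroni)",
                    statistic = NA_real_, p_value = .data$p_adjusted))
  } else {
    x$test
  }
}

#' One-row comparison summary
#'
#' @param x A `pf_comparison`.
#' @param ... Unused.
#' @return Tibble: number of models, normality p-value, main-test p-value,
#'   degeneracy flag.
#' @export
glance.pf_comparison <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    normality_p = x$normality_p,
    p_value = x$test$p_value[1],
    degenerate = x$degenerate)
}

#' Plot training curves
#'
#' @param object A `pf_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss and accuracy by epoch.
#' @export
autoplot.pf_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss", "train_acc", "val_acc"),
                           names_to = "series", values_to = "value")
  h <- tidyr::separate(h, "series", into = c("split", "metric"), sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat tile
#'
#' @param object A `pf_confusion`.
#' @param ... Unused.
#' @return A ggplot tile chart, rows = actual, columns = predicted.
#' @export
autoplot.pf_confusion <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$n, 1)),
                       color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "actual") +
    ggplot2::theme_minimal()
}

#' Plot a Grad-CAM heatmap
#'
#' @param object A `pf_gradcam`.
#' @param ... Unused.
#' @return A ggplot raster of the upsampled heatmap.
#' @export
autoplot.pf_gradcam <- function(object, ...) {
  m <- object$upsampled
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("class ", object$class_index)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
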