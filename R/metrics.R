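# Confusion-matrix machinery and multiclass evaluation metrics: overall
# accuracy, per-class one-vs-rest precision / sensitivity / specificity /
# F1, Matthews correlation (binary and multi-category), misclassification
# count and rate, and Cohen's kappa. Matrices follow the rows = actual,
# columns = predicted convention and may hold non-integer entries so that
# fold-averaged matrices share the same machinery.

#' Build a confusion matrix
#'
#' @param y_true,y_pred Integer class labels in `[0, k)`.
#' @param k Number of classes; inferred from the labels when missing.
#' @param class_names Optional class names for dimnames.
#' @return A `pf_confusion`: a k x k matrix, rows = actual, columns =
#'   predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, k = NULL, class_names = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(k)) k <- max(c(y_true, y_pred)) + 1L
  if (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k)) {
    stop("labels must lie in [0, ", k, ")")
  }
  cm <- matrix(0, k, k)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1
  }
  as_confusion(cm, class_names)
}

#' Mark a matrix as a confusion matrix
#'
#' @param m A square numeric matrix (rows = actual, columns = predicted).
#' @param class_names Optional class names.
#' @return A `pf_confusion`.
#' @export
as_confusion <- function(m, class_names = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix entries must be non-negative")
  if (!is.null(class_names)) dimnames(m) <- list(class_names, class_names)
  class(m) <- c("pf_confusion", class(m))
  m
}

#' One-vs-rest counts for a class
#'
#' @param cm A confusion matrix.
#' @param class_i Zero-based class index.
#' @return List with `TP`, `FP`, `FN`, `TN`; they always sum to the matrix
#'   total.
#' @export
binary_counts <- function(cm, class_i) {
  k <- nrow(cm)
  if (class_i < 0 || class_i >= k) stop("class index out of range")
  i <- class_i + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Overall accuracy (percent)
#'
#' @param cm A confusion matrix with positive total.
#' @return `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(cm))) / total
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, returning 0")
    return(0)
  }
  num / den
}

#' One-vs-rest rates
#'
#' Standard definitions: sensitivity (recall) TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), and F1 the harmonic mean of precision
#' and sensitivity. A zero denominator yields 0 with a warning.
#'
#' @param bc A [binary_counts()] list.
#' @return A rate in `[0, 1]`.
#' @name class_rates
NULL

#' @rdname class_rates
#' @export
sensitivity <- function(bc) safe_ratio(bc$TP, bc$TP + bc$FN, "sensitivity")

#' @rdname class_rates
#' @export
specificity <- function(bc) safe_ratio(bc$TN, bc$TN + bc$FP, "specificity")

#' @rdname class_rates
#' @export
precision <- function(bc) safe_ratio(bc$TP, bc$TP + bc$FP, "precision")

#' @rdname class_rates
#' @export
f1_score <- function(bc) {
  p <- precision(bc)
  s <- sensitivity(bc)
  if (p + s == 0) {
    warning("f1: zero denominator, returning 0")
    return(0)
  }
  2 * p * s / (p + s)
}

#' Matthews correlation coefficient
#'
#' For 2x2 matrices this is the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for k > 2 the
#' standard multi-category generalisation is computed from the full matrix
#' (trace, row and column marginals). A zero denominator returns 0.
#'
#' @param cm A confusion matrix.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  m <- as.matrix(cm)
  s <- sum(m)
  if (s == 0) stop("empty confusion matrix")
  tr <- sum(diag(m))
  rowm <- rowSums(m)
  colm <- colSums(m)
  num <- tr * s - sum(rowm * colm)
  den <- sqrt(s^2 - sum(colm^2)) * sqrt(s^2 - sum(rowm^2))
  if (den == 0) return(0)
  num / den
}

#' Misclassification count and rate
#'
#' @param cm A confusion matrix with positive total.
#' @return List with `count` (total minus trace) and `rate` in percent;
#'   the rate always equals `100 - accuracy(cm)`.
#' @export
misclassification <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  count <- total - sum(diag(as.matrix(cm)))
  list(count = count, rate = 100 * count / total)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)`, with `Po` the observed
#' accuracy and `Pe` the expected agreement from the marginals. The
#' `strict_printed` flag instead divides by `(1 - Po)` — a non-standard
#' variant kept for comparison only.
#'
#' @param cm A confusion matrix.
#' @param strict_printed Use the non-standard `(Po - Pe) / (1 - Po)` form?
#' @return Kappa; 1 for a diagonal matrix, 0 when `Po = Pe`.
#' @export
kappa_score <- function(cm, strict_printed = FALSE) {
  m <- as.matrix(cm)
  s <- sum(m)
  if (s == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / s
  pe <- sum(rowSums(m) * colSums(m)) / s^2
  den <- if (strict_printed) 1 - po else 1 - pe
  if (den == 0) {
    if (!strict_printed && po == 1 && pe == 1) {
      stop("kappa undefined: degenerate matrix with Pe = 1")
    }
    if (strict_printed) return(Inf)
  }
  (po - pe) / den
}

#' Element-wise mean of confusion matrices
#'
#' Averages a list of same-shaped matrices, as used for the mean matrix
#' over cross-validation folds.
#'
#' @param matrices Non-empty list of confusion matrices.
#' @return A `pf_confusion` of fold-averaged (possibly fractional) counts.
#' @export
mean_confusion <- function(matrices) {
  if (length(matrices) == 0L) stop("no matrices to average")
  dims <- unique(lapply(matrices, dim))
  if (length(dims) != 1L) stop("matrices differ in shape")
  out <- Reduce(`+`, lapply(matrices, as.matrix)) / length(matrices)
  as_confusion(out, rownames(matrices[[1]]))
}

#' Full metric report for a confusion matrix
#'
#' @param cm A confusion matrix.
#' @param class_names Optional class names.
#' @return A `pf_metrics` with a `per_class` tibble (one-vs-rest precision,
#'   sensitivity, specificity, F1, plus macro averages) and an `overall`
#'   tibble (accuracy %, MCC, kappa, misclassification count and rate %).
#' @export
metric_report <- function(cm, class_names = NULL) {
  k <- nrow(cm)
  if (is.null(class_names)) {
    class_names <- rownames(cm) %||% paste0("class_", seq_len(k) - 1L)
  }
  per <- purrr::map_dfr(seq_len(k) - 1L, function(i) {
    bc <- binary_counts(cm, i)
    tibble::tibble(class = class_names[i + 1L],
                   precision = precision(bc),
                   sensitivity = sensitivity(bc),
                   specificity = specificity(bc),
                   f1 = f1_score(bc))
  })
  mis <- misclassification(cm)
  overall <- tibble::tibble(
    accuracy = accuracy(cm),
    mcc = mcc(cm),
    kappa = kappa_score(cm),
    misclassified = mis$count,
    misclassification_rate = mis$rate,
    macro_precision = mean(per$precision),
    macro_sensitivity = mean(per$sensitivity),
    macro_specificity = mean(per$specificity),
    macro_f1 = mean(per$f1))
  structure(list(per_class = per, overall = overall, confusion = cm),
            class = "pf_metrics")
}

#' Write a confusion matrix to CSV
#'
#' Uses the `Actual\\Predicted` header convention: first column holds the
#' actual-class names, remaining columns the predicted classes.
#'
#' @param cm A confusion matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- as.matrix(cm)
  nms <- rownames(m) %||% paste0("class_", seq_len(nrow(m)) - 1L)
  df <- data.frame(`Actual.Predicted` = nms, m, check.names = FALSE)
  names(df) <- c("Actual\\Predicted", nms)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion_csv()]
#'
#' @param path CSV path.
#' @return A `pf_confusion`.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_confusion(m, df[[1]])
}

#' Write a metric report to CSV / JSON
#'
#' @param report A `pf_metrics`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              overall = report$overall),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    long <- dplyr::bind_rows(
      tidyr::pivot_longer(report$per_class, -"class",
                          names_to = "metric", values_to = "value"),
      tidyr::pivot_longer(
        dplyr::mutate(report$overall, class = "__overall__"), -"class",
        names_to = "metric", values_to = "value"))
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
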