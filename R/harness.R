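# Experiment harness: train/evaluate one or more models on a dataset with a
# deterministic 85/15 split, run K-fold cross-validation with mean confusion
# matrices and fold statistics, compare models with paired tests, and
# benchmark inference.

#' Describe a model for the harness
#'
#' @param name Display name.
#' @param type `"baseline"` or `"fusion"`.
#' @param backbones One backbone name (baseline) or two (fusion).
#' @param head_width Dense head width.
#' @param dropout_rate Dropout rate.
#' @param seed Build seed.
#' @return A `pf_model_spec`.
#' @export
model_spec <- function(name, type = c("baseline", "fusion"), backbones,
                       head_width = 16L, dropout_rate = 0.5, seed = 1L) {
  type <- match.arg(type)
  if (type == "fusion" && length(backbones) != 2L) {
    stop("fusion models need exactly two backbones")
  }
  if (type == "baseline" && length(backbones) != 1L) {
    stop("baseline models need exactly one backbone")
  }
  structure(list(name = name, type = type, backbones = tolower(backbones),
                 head_width = as.integer(head_width),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "pf_model_spec")
}

build_from_spec <- function(spec, num_classes) {
  if (spec$type == "fusion") {
    build_fusion_model(fusion_config(spec$backbones[1], spec$backbones[2],
                                     num_classes, spec$head_width,
                                     spec$dropout_rate, seed = spec$seed))
  } else {
    build_baseline(spec$backbones[1], num_classes, spec$head_width,
                   spec$dropout_rate, seed = spec$seed)
  }
}

#' Train and evaluate models on one dataset
#'
#' For each model: train on the 85% partition (with an inner validation
#' split for early stopping), evaluate on the held-out 15% partition, and
#' report the confusion matrix, full metric report and training history.
#' Identical seeds reproduce identical split indices and metrics.
#'
#' @param dataset A `pf_dataset`.
#' @param specs List of [model_spec()].
#' @param config A [training_config()].
#' @param split_seed Seed of the train/test split.
#' @param test_fraction Held-out fraction (default 0.15).
#' @param stratify Stratify the split by class (useful for small synthetic
#'   sets)?
#' @param frozen_baseline If `TRUE`, baseline models keep all backbone
#'   layers frozen (heads still train); the default fine-tunes baselines
#'   under the same freezing policy as fusion models.
#' @return A `pf_experiment`: tibble `results` (model, accuracy, mcc, kappa,
#'   misclassified, macro F1), plus per-model `reports`, `matrices`,
#'   `fits` and the `split` plan.
#' @export
run_experiment <- function(dataset, specs, config = training_config(),
                           split_seed = 1L, test_fraction = 0.15,
                           stratify = TRUE, frozen_baseline = FALSE) {
  stopifnot(length(specs) >= 1L)
  n <- length(dataset$images)
  k <- length(dataset$class_names)
  plan <- split_plan(n, test_fraction, split_seed,
                     labels = if (stratify) dataset$labels else NULL)
  train_set <- subset_dataset(dataset, plan$train_indices)
  test_set <- subset_dataset(dataset, plan$test_indices)
  reports <- list()
  matrices <- list()
  fits <- list()
  rows <- list()
  for (spec in specs) {
    model <- build_from_spec(spec, k)
    cfg <- config
    if (spec$type == "baseline" && frozen_baseline) {
      cfg$unfrozen_top_layers <- 0L
    }
    fit <- train_model(model, train_set, cfg)
    pred <- predict(fit$model, test_set)
    cm <- confusion_matrix(test_set$labels, pred$class, k,
                           dataset$class_names)
    rep <- metric_report(cm)
    reports[[spec$name]] <- rep
    matrices[[spec$name]] <- cm
    fits[[spec$name]] <- fit
    rows[[spec$name]] <- tibble::tibble(
      model = spec$name, type = spec$type,
      accuracy = rep$overall$accuracy, mcc = rep$overall$mcc,
      kappa = rep$overall$kappa,
      misclassified = rep$overall$misclassified,
      macro_f1 = rep$overall$macro_f1,
      best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch)
  }
  structure(list(results = dplyr::bind_rows(rows), reports = reports,
                 matrices = matrices, fits = fits, split = plan,
                 frozen_baseline = frozen_baseline),
            class = "pf_experiment")
}

subset_dataset <- function(dataset, idx) {
  patch_dataset(dataset$images[idx], dataset$labels[idx],
                dataset$class_names, dataset$provenance[idx])
}

#' K-fold cross-validation of one model
#'
#' Runs `k` train/evaluate rounds over a seeded [kfold_plan()], returning
#' the per-fold confusion matrices, their element-wise mean (whose cells sum
#' to n/k), and fold statistics: mean, SD and 95% confidence interval of
#' accuracy and macro F1.
#'
#' @param dataset A `pf_dataset`.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param config A [training_config()].
#' @param fold_seed Seed of the fold plan.
#' @return A `pf_crossval`: `fold_matrices`, `mean_matrix`, tibbles
#'   `fold_stats` (per fold) and `summary` (mean/sd/ci per metric).
#' @export
crossval <- function(dataset, spec, k = 5L, config = training_config(),
                     fold_seed = 1L) {
  n <- length(dataset$images)
  nc <- length(dataset$class_names)
  plan <- kfold_plan(n, k, fold_seed)
  fold_matrices <- vector("list", k)
  stats_rows <- vector("list", k)
  for (fi in seq_len(k)) {
    val_idx <- plan$folds[[fi]]
    if (length(unique(dataset$labels[val_idx])) < nc) {
      warning("fold ", fi, " does not contain every class")
    }
    train_set <- subset_dataset(dataset, setdiff(seq_len(n), val_idx))
    val_set <- subset_dataset(dataset, val_idx)
    model <- build_from_spec(spec, nc)
    cfg <- config
    cfg$seed <- stream_seed(config$seed, 53L, fi)
    fit <- train_model(model, train_set, cfg)
    pred <- predict(fit$model, val_set)
    cm <- confusion_matrix(val_set$labels, pred$class, nc,
                           dataset$class_names)
    rep <- metric_report(cm)
    fold_matrices[[fi]] <- cm
    stats_rows[[fi]] <- tibble::tibble(
      fold = fi, n = length(val_idx),
      accuracy = rep$overall$accuracy, macro_f1 = rep$overall$macro_f1)
  }
  fold_stats <- dplyr::bind_rows(stats_rows)
  ci <- function(x) {
    m <- mean(x)
    if (length(x) < 2L || stats::sd(x) == 0) return(c(m, m))
    m + c(-1, 1) * stats::qt(0.975, length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
  }
  acc_ci <- ci(fold_stats$accuracy)
  f1_ci <- ci(fold_stats$macro_f1)
  summary <- tibble::tibble(
    metric = c("accuracy", "macro_f1"),
    mean = c(mean(fold_stats$accuracy), mean(fold_stats$macro_f1)),
    sd = c(stats::sd(fold_stats$accuracy), stats::sd(fold_stats$macro_f1)),
    ci_lower = c(acc_ci[1], f1_ci[1]),
    ci_upper = c(acc_ci[2], f1_ci[2]))
  structure(list(fold_matrices = fold_matrices,
                 mean_matrix = mean_confusion(fold_matrices),
                 fold_stats = fold_stats, summary = summary,
                 plan = plan, spec = spec),
            class = "pf_crossval")
}

#' Paired statistical comparison of model accuracies
#'
#' For a long table of per-dataset model accuracies: Shapiro-Wilk normality
#' check on the paired differences (two models) or residuals, a two-sided
#' paired t-test for two models, and one-way ANOVA with Bonferroni-corrected
#' pairwise post hoc tests for three or more. Constant differences (zero
#' variance) are flagged as degenerate rather than tested. All tests are
#' thin wrappers around the standard stats routines.
#'
#' @param accuracy_table Tibble with columns `dataset`, `model`, `accuracy`
#'   and at least two models observed on at least two common datasets.
#' @return A `pf_comparison` with elements `normality_p`, `test` (tibble of
#'   statistic/p-value), `anova` and `posthoc` (for >= 3 models),
#'   `degenerate` flag and the input table.
#' @export
compare_models <- function(accuracy_table) {
  tb <- tibble::as_tibble(accuracy_table)
  stopifnot(all(c("dataset", "model", "accuracy") %in% names(tb)))
  models <- unique(tb$model)
  if (length(models) < 2L) stop("need at least two models to compare")
  wide <- tidyr::pivot_wider(tb, names_from = "model",
                             values_from = "accuracy")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 2L) stop("need at least two paired observations")
  out <- list(models = models, table = tb, degenerate = FALSE)
  if (length(models) == 2L) {
    d <- wide[[models[1]]] - wide[[models[2]]]
    if (stats::sd(d) == 0) {
      out$degenerate <- TRUE
      out$normality_p <- NA_real_
      out$test <- tibble::tibble(
        method = "paired t-test", statistic = NA_real_, p_value = NA_real_,
        mean_difference = mean(d),
        note = "constant paired differences; zero variance")
    } else {
      out$normality_p <- stats::shapiro.test(d)$p.value
      tt <- stats::t.test(wide[[models[1]]], wide[[models[2]]],
                          paired = TRUE)
      out$test <- tibble::tibble(
        method = "paired t-test",
        statistic = unname(tt$statistic), p_value = tt$p.value,
        mean_difference = unname(tt$estimate), note = NA_character_)
    }
  } else {
    long <- tidyr::pivot_longer(wide, -"dataset", names_to = "model",
                                values_to = "accuracy")
    fit <- stats::aov(accuracy ~ model, data = long)
    av <- summary(fit)[[1]]
    resid_sd <- stats::sd(stats::residuals(fit))
    out$normality_p <- if (resid_sd == 0) NA_real_ else
      stats::shapiro.test(stats::residuals(fit))$p.value
    out$anova <- tibble::tibble(
      method = "one-way ANOVA",
      statistic = av[["F value"]][1], p_value = av[["Pr(>F)"]][1])
    out$test <- out$anova
    ph <- stats::pairwise.t.test(long$accuracy, long$model,
                                 p.adjust.method = "bonferroni")
    pm <- ph$p.value
    out$posthoc <- tibble::as_tibble(as.data.frame(as.table(pm)),
                                     .name_repair = "minimal")
    names(out$posthoc) <- c("model_1", "model_2", "p_adjusted")
    out$posthoc <- out$posthoc[!is.na(out$posthoc$p_adjusted), ]
  }
  mean_sd <- dplyr::summarise(
    dplyr::group_by(tb, .data$model),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy), .groups = "drop")
  out$by_model <- mean_sd
  structure(out, class = "pf_comparison")
}

#' Benchmark inference timing
#'
#' Wall-clock time per single image and per batch, averaged over warm runs.
#' Values are hardware-dependent and reported for orientation only.
#'
#' @param model A forward-capable `pf_model`.
#' @param batch_size Batch size for the batched timing (default 32).
#' @param n_rep Timed repetitions after one warm-up (default 3).
#' @param seed Seed for the random benchmark images.
#' @return A tibble: single-image seconds, batch seconds, per-image batch
#'   seconds, peak memory (MB) if the platform exposes it.
#' @export
benchmark_model <- function(model, batch_size = 32L, n_rep = 3L, seed = 1L) {
  sz <- model$backbone_a$spec$input_shape
  imgs <- with_local_seed(seed, lapply(seq_len(batch_size), function(i) {
    array(stats::runif(prod(sz)), sz)
  }))
  predict(model, imgs[[1]])                 # warm-up
  t_single <- mean(vapply(seq_len(n_rep), function(i) {
    system.time(predict(model, imgs[[1]]))[["elapsed"]]
  }, 0))
  t_batch <- mean(vapply(seq_len(n_rep), function(i) {
    system.time(predict(model, imgs))[["elapsed"]]
  }, 0))
  peak <- tryCatch(sum(gc()[, 6]), error = function(e) NA_real_)
  tibble::tibble(batch_size = batch_size,
                 single_image_s = t_single,
                 batch_s = t_batch,
                 per_image_in_batch_s = t_batch / batch_size,
                 peak_memory_mb = peak)
}
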