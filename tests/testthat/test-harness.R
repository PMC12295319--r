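# Experiment orchestration: train/evaluate runs, cross-validation
# bookkeeping, statistical comparisons and benchmarking.

test_that("a single-model experiment yields one coherent report and is
           fully reproducible", {
  ds <- small_synth(10L)
  spec <- model_spec("base", "baseline", "tiny", head_width = 16L, seed = 2L)
  cfg <- quick_config(epochs = 4L, seed = 3L)

  exp1 <- suppressWarnings(run_experiment(ds, list(spec), cfg, split_seed = 4L))
  expect_equal(nrow(exp1$results), 1L)
  expect_equal(names(exp1$reports), "base")
  expect_equal(sum(exp1$matrices$base),
               length(exp1$split$test_indices))
  expect_equal(exp1$results$accuracy,
               accuracy(exp1$matrices$base))

  exp2 <- suppressWarnings(run_experiment(ds, list(spec), cfg, split_seed = 4L))
  expect_identical(exp1$split$test_indices, exp2$split$test_indices)
  expect_identical(unclass(exp1$matrices$base), unclass(exp2$matrices$base))
  expect_equal(exp1$results, exp2$results)
})

test_that("cross-validation obeys the N/k bookkeeping identities", {
  ds <- small_synth(12L, seed = 88L)        # n = 36
  spec <- model_spec("base", "baseline", "tiny", head_width = 8L, seed = 5L)
  cv <- suppressWarnings(
    crossval(ds, spec, k = 3L, config = quick_config(epochs = 3L),
             fold_seed = 6L))
  n <- length(ds$images)
  expect_equal(length(cv$fold_matrices), 3L)
  for (fi in 1:3) {
    expect_equal(sum(cv$fold_matrices[[fi]]),
                 length(cv$plan$folds[[fi]]))
  }
  expect_equal(sum(cv$mean_matrix), n / 3)
  expect_true(all(cv$summary$ci_lower <= cv$summary$ci_upper))
  expect_equal(nrow(cv$fold_stats), 3L)
})

test_that("a perfect classifier yields a diagonal mean matrix with a
           zero-width interval", {
  # hand-built fold matrices stand in for a perfect model
  folds <- replicate(5, as_confusion(diag(c(4, 3, 5))), simplify = FALSE)
  mm <- mean_confusion(folds)
  expect_equal(unclass(mm), diag(c(4, 3, 5)), ignore_attr = TRUE)
  accs <- vapply(folds, accuracy, 0)
  expect_equal(stats::sd(accs), 0)
})

test_that("model comparison runs the paired pipeline and flags degeneracy", {
  tb <- tibble::tibble(
    dataset = rep(1:6, 2),
    model = rep(c("fusion", "baseline"), each = 6),
    accuracy = c(99.1, 99.3, 99.1, 100, 99.2, 99.6,
                 97.9, 97.8, 95.9, 99.7, 96.5, 97.7))
  cmp <- compare_models(tb)
  expect_false(cmp$degenerate)
  expect_true(cmp$normality_p >= 0 && cmp$normality_p <= 1)
  expect_true(cmp$test$p_value >= 0 && cmp$test$p_value <= 1)
  # the thin wrapper agrees with a direct paired t-test
  direct <- t.test(tb$accuracy[1:6], tb$accuracy[7:12], paired = TRUE)
  expect_equal(cmp$test$statistic, unname(direct$statistic))
  expect_equal(cmp$test$p_value, direct$p.value)

  # identical vectors and constant shifts are degenerate, not significant
  same <- tibble::tibble(dataset = rep(1:4, 2),
                         model = rep(c("a", "b"), each = 4),
                         accuracy = rep(c(99, 98, 97, 96), 2))
  cs <- compare_models(same)
  expect_true(cs$degenerate)
  shift <- same
  shift$accuracy[shift$model == "b"] <- shift$accuracy[shift$model == "b"] - 1
  expect_true(compare_models(shift)$degenerate)

  expect_error(compare_models(same[same$model == "a", ]), "two models")
})

test_that("three or more models get an ANOVA with Bonferroni post hoc", {
  set.seed(40)
  tb <- tibble::tibble(
    dataset = rep(1:6, 3),
    model = rep(c("m1", "m2", "m3"), each = 6),
    accuracy = c(rnorm(6, 99, 0.3), rnorm(6, 98, 0.3), rnorm(6, 99.2, 0.3)))
  cmp <- compare_models(tb)
  expect_equal(cmp$anova$method, "one-way ANOVA")
  expect_true(cmp$anova$p_value >= 0 && cmp$anova$p_value <= 1)
  expect_equal(nrow(cmp$posthoc), 3L)
  expect_true(all(cmp$posthoc$p_adjusted <= 1))
  expect_equal(nrow(glance(cmp)), 1L)
  expect_true(nrow(tidy(cmp)) >= 4L)
})

test_that("the benchmark reports positive, internally consistent timings", {
  model <- build_baseline("tiny", 3L, head_width = 8L, seed = 41L)
  bm <- benchmark_model(model, batch_size = 4L, n_rep = 2L)
  expect_true(all(c("single_image_s", "batch_s", "per_image_in_batch_s")
                  %in% names(bm)))
  expect_gte(bm$batch_s, 0)
  expect_gte(bm$single_image_s, 0)
  # amortization: per-image batch cost does not exceed the single-image
  # cost by more than timing noise
  expect_lte(bm$per_image_in_batch_s, bm$single_image_s + 0.05)
})

test_that("tidiers and autoplot produce pipe-ready objects", {
  ds <- small_synth(10L)
  fit <- train_model(build_baseline("tiny", 3L, head_width = 8L, seed = 7L),
                     ds, quick_config(3L))
  g <- glance(fit)
  expect_equal(g$epochs, nrow(fit$history))
  expect_s3_class(autoplot(fit), "ggplot")

  pred <- predict(fit$model, ds)
  td <- tidy(pred)
  expect_equal(nrow(td), length(ds$images))
  expect_true(all(c("class", "p_0", "p_1", "p_2") %in% names(td)))

  cm <- confusion_matrix(ds$labels, pred$class, 3, ds$class_names)
  expect_s3_class(autoplot(cm), "ggplot")

  model <- build_fusion_model(fusion_config("tiny", "tiny", 3L,
                                            head_width = 8L, seed = 8L))
  gcam <- gradcam(model, ds$images[[1]], 0)
  expect_s3_class(autoplot(gcam), "ggplot")
})
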