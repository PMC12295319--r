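# Training protocol: schedule, early stopping, freezing, and a desk-scale
# training run.

test_that("learning rate steps down by factors of ten and is clamped", {
  cfg <- training_config()
  expect_equal(learning_rate_at(3, cfg), 1e-4)
  expect_equal(learning_rate_at(12, cfg), 1e-5)
  expect_equal(learning_rate_at(47, cfg), 1e-6)   # 1e-8 clamped at the floor
  lrs <- learning_rate_at(0:49, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= 1e-6))
})

test_that("early stopping tracks the running best and fires after the
           patience window", {
  # strictly decreasing: never stops, best is the last epoch
  st <- early_stop_state()
  losses <- seq(1, 0.02, length.out = 50)
  for (e in 0:49) st <- early_stop_update(st, e, losses[e + 1], patience = 10)
  expect_false(st$stopped)
  expect_equal(st$best_epoch, 49L)
  expect_equal(st$best_loss, losses[50])

  # one good epoch then a plateau: stops after the 10th non-improving epoch
  st <- early_stop_state()
  st <- early_stop_update(st, 0, 0.5)
  for (e in 1:10) {
    expect_false(st$stopped)
    st <- early_stop_update(st, e, 0.5 + 0.01 * (e %% 2))
  }
  expect_true(st$stopped)
  expect_equal(st$best_epoch, 0L)

  # improvement resets the counter
  st <- early_stop_state()
  st <- early_stop_update(st, 0, 0.5)
  st <- early_stop_update(st, 1, 0.6)
  expect_equal(st$epochs_since_improvement, 1L)
  st <- early_stop_update(st, 2, 0.4)
  expect_equal(st$epochs_since_improvement, 0L)
  expect_equal(st$best_epoch, 2L)

  expect_warning(early_stop_update(early_stop_state(), 0, NaN),
                 "non-finite")
})

test_that("early stopping can never fire before `patience` epochs", {
  set.seed(10)
  for (rep in 1:20) {
    st <- early_stop_state()
    stopped_at <- NA_integer_
    for (e in 0:14) {
      st <- early_stop_update(st, e, runif(1), patience = 5)
      if (st$stopped) { stopped_at <- e; break }
    }
    if (!is.na(stopped_at)) expect_gte(stopped_at, 5L)
  }
})

test_that("the freezing policy unfreezes the top layers of each backbone", {
  m <- build_fusion_model(fusion_config("tiny", "tiny", 3L, head_width = 4L))
  m0 <- freeze_policy(m, 0)
  expect_equal(m0$backbone_a$trainable, c(FALSE, FALSE))
  expect_equal(patchfuse:::trainable_param_names(m0),
               names(m0$params))   # only the head

  m1 <- freeze_policy(m, 1)
  expect_equal(m1$backbone_a$trainable, c(FALSE, TRUE))
  expect_equal(m1$backbone_b$trainable, c(FALSE, TRUE))

  mb <- build_baseline("tiny", 3L, head_width = 4L)
  expect_warning(mall <- freeze_policy(mb, 20), "exceeds backbone depth")
  expect_equal(mall$backbone_a$trainable, c(TRUE, TRUE))

  # combined mode counts over the concatenated layer list
  mc <- freeze_policy(m, 3, mode = "combined")
  expect_equal(mc$backbone_a$trainable, c(FALSE, TRUE))
  expect_equal(mc$backbone_b$trainable, c(TRUE, TRUE))
})

test_that("a desk-scale run learns, logs the schedule, and restores the
           best weights deterministically", {
  ds <- small_synth(10L)
  cfg <- quick_config(epochs = 6L, seed = 3L)
  model <- build_baseline("tiny", 3L, head_width = 16L, seed = 2L)
  fit <- train_model(model, ds, cfg)

  h <- fit$history
  expect_lte(nrow(h), 6L)
  # loss decreases over the first epochs on separable data
  expect_lt(h$train_loss[5], h$train_loss[1])
  # the logged schedule is exactly the configured one
  expect_equal(h$lr, learning_rate_at(h$epoch, cfg))
  # restored weights reproduce the minimum recorded validation loss
  k <- length(ds$class_names)
  val <- patchfuse:::evaluate_loss_acc(fit$model, ds$images,
                                       one_hot(ds$labels, k),
                                       fit$val_indices)
  expect_equal(val$loss, min(h$val_loss), tolerance = 1e-8)

  # bitwise determinism of the whole run
  fit2 <- train_model(build_baseline("tiny", 3L, head_width = 16L, seed = 2L),
                      ds, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(patchfuse:::model_flat_params(fit$model),
                   patchfuse:::model_flat_params(fit2$model))
})

test_that("training refuses an empty dataset", {
  empty <- patch_dataset(list(), integer(), c("a", "b"))
  m <- build_baseline("tiny", 2L, head_width = 4L)
  expect_error(train_model(m, empty, quick_config(3L)), "empty")
})

test_that("history CSV round-trips", {
  ds <- small_synth(10L)
  fit <- train_model(build_baseline("tiny", 3L, head_width = 8L, seed = 4L),
                     ds, quick_config(3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(fit, path)
  back <- utils::read.csv(path)
  expect_equal(back$val_loss, fit$history$val_loss, tolerance = 1e-12)
  expect_equal(back$epoch, fit$history$epoch)
})

test_that("the fusion gate learns to trust a reliable branch", {
  case <- oracle_noise_case(n = 80L, seed = 5L)
  gate <- train_fusion_gate(case$oracle, case$noise, case$pooled_a,
                            case$pooled_b, case$labels, epochs = 60L,
                            seed = 2L)
  expect_gt(gate$mean_weights[1], 0.8)
  expect_equal(rowSums(gate$weights), rep(1, 80L), tolerance = 1e-10)
})
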