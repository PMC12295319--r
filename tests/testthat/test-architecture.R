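# Spatial attention, fusion, and exact parameter accounting.

test_that("attention mask has the right shape, range and edge behavior", {
  set.seed(1)
  fm <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  m <- attention_mask(fm, rnorm(6), 0.3)
  expect_equal(dim(m), c(5L, 5L, 1L))
  expect_true(all(m > 0 & m < 1))

  zero_map <- array(0, c(4, 4, 3))
  expect_equal(as.vector(attention_mask(zero_map, rnorm(3), 0)),
               rep(0.5, 16))

  expect_error(attention_mask(fm, rnorm(5)), "channels")
})

test_that("applying a mask multiplies element-wise with channel broadcast", {
  set.seed(2)
  fm <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  ones <- array(1, c(3, 4, 1))
  expect_equal(apply_attention(fm, ones), fm)
  expect_equal(apply_attention(fm, array(0, c(3, 4, 1))),
               array(0, c(3, 4, 5)))

  fm2 <- array(c(2, 4), c(1, 1, 2))
  expect_equal(as.vector(apply_attention(fm2, array(0.5, c(1, 1, 1)))),
               c(1, 2))
  expect_error(apply_attention(fm, array(1, c(2, 4, 1))), "spatial")
})

test_that("global average pooling is the per-channel spatial mean", {
  const <- array(0.7, c(5, 5, 8))
  expect_equal(global_average_pool(const), rep(0.7, 8))
  one_ch <- array(c(1, 3, 2, 6), c(2, 2, 1))
  expect_equal(global_average_pool(one_ch), 3)
  set.seed(3)
  fm <- array(rnorm(6 * 7 * 4), c(6, 7, 4))
  expect_equal(global_average_pool(fm), apply(fm, 3, mean))
  expect_error(global_average_pool(matrix(1, 2, 2)), "array")
})

test_that("fusion weights come from a softmax dense layer over the
           concatenated predictions and pooled features", {
  c_ <- 3L; d <- 4L
  pa <- random_simplex(c_); pb <- random_simplex(c_)
  ga <- rnorm(d); gb <- rnorm(d)
  W0 <- matrix(0, 2, 2 * c_ + 2 * d)
  expect_equal(attention_weights(pa, pb, ga, gb, W0), c(0.5, 0.5))

  set.seed(4)
  W <- matrix(rnorm(2 * (2 * c_ + 2 * d)), 2)
  w <- attention_weights(pa, pb, ga, gb, W, c(0.1, -0.2))
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_error(attention_weights(pa, pb, ga, gb, W[, -1]), "weight matrix")
})

test_that("fused prediction is the weighted sum and stays on the simplex", {
  pa <- c(1, 0, 0); pb <- c(0, 1, 0)
  expect_equal(fuse_predictions(pa, pb, c(1, 0)), pa)
  expect_equal(fuse_predictions(pa, pb, c(0.5, 0.5)), c(0.5, 0.5, 0))
  p <- random_simplex(4)
  expect_equal(fuse_predictions(p, p, c(0.3, 0.7)), p)
  expect_error(fuse_predictions(c(1, 0), c(1, 0, 0), c(0.5, 0.5)), "length")
})

test_that("head parameter count follows the layer-by-layer formula", {
  # hand expansion: attention 2+2, dense 2+2, classifiers 4+4(=2c(h+1)=4), fusion 10
  expect_equal(head_parameter_count(1, 1, 1, 1), 22)
  expect_equal(head_parameter_count(2048, 2048, 3, 1024), 4214806)
  expect_equal(head_parameter_count(2048, 1024, 3, 1024), 3163158)
})

test_that("the three published totals pin down the backbone counts as the
           unique solution of a linear system", {
  h <- 1024L; c_ <- 3L
  totals <- c(
    total_parameter_count(fusion_config("inceptionv3", "xception", c_)),
    total_parameter_count(fusion_config("xception", "mobilenet", c_)),
    total_parameter_count(fusion_config("inceptionv3", "mobilenet", c_)))
  heads <- c(head_parameter_count(2048, 2048, c_, h),
             head_parameter_count(2048, 1024, c_, h),
             head_parameter_count(2048, 1024, c_, h))
  # unknowns (inception, xception, mobilenet); one equation per pairing
  A <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  expect_equal(det(A), 2)   # invertible: the solution is unique
  sol <- solve(A, totals - heads)
  expect_equal(sol, vapply(c("inceptionv3", "xception", "mobilenet"),
                           function(nm) backbone_spec(nm)$notop_params, 0),
               ignore_attr = TRUE)
})

test_that("assembled models count their parameters by enumeration", {
  tiny <- build_fusion_model(fusion_config("tiny", "tiny", 3L,
                                           head_width = 4L, seed = 1))
  d <- backbone_spec("tiny")$feature_shape[3]
  expect_equal(count_parameters(tiny),
               2 * 1392 + head_parameter_count(d, d, 3, 4))

  base <- build_baseline("tiny", 3L, head_width = 4L)
  # backbone + dense(h x d + h) + classifier(c x h + c)
  expect_equal(count_parameters(base), 1392 + (4 * d + 4) + (3 * 4 + 3))

  big <- build_baseline("inceptionv3", 3L)
  expect_equal(count_parameters(big), 21802784 + 1024 * 2049 + 3 * 1025)
})

test_that("model summaries enumerate layers and serialise to JSON", {
  m <- build_fusion_model(fusion_config("tiny", "tiny", 3L, head_width = 4L))
  s <- model_summary(m)
  expect_true(all(c("layer", "output_shape", "params") %in% names(s)))
  expect_equal(sum(s$params), count_parameters(m))
  js <- jsonlite::fromJSON(summary_to_json(m))
  expect_equal(js$total_params, count_parameters(m))
})

test_that("a forward pass conserves probability and exposes both branches", {
  model <- build_fusion_model(fusion_config("tiny", "tiny", 3L,
                                            head_width = 8L, seed = 5))
  set.seed(6)
  imgs <- lapply(1:4, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  pred <- predict(model, imgs)
  expect_equal(rowSums(pred$fused), rep(1, 4), tolerance = 1e-5)
  expect_equal(rowSums(pred$pred_a), rep(1, 4), tolerance = 1e-5)
  expect_equal(rowSums(pred$weights), rep(1, 4), tolerance = 1e-10)
  expect_true(all(pred$weights >= 0))
  expect_equal(pred$fused,
               pred$weights[, 1] * pred$pred_a + pred$weights[, 2] * pred$pred_b)
})

test_that("an extreme fusion logit gap collapses the fusion onto one branch", {
  model <- build_fusion_model(fusion_config("tiny", "tiny", 3L,
                                            head_width = 8L, seed = 7))
  model$params$fuse_W[] <- 0
  model$params$fuse_b <- c(60, -60)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- patchfuse:::fusion_forward(model, img)
  expect_equal(fw$fused, fw$pred_a, tolerance = 1e-10)
})

test_that("with the attention mask driven to 1 a branch reduces to the
           baseline head on the raw feature map", {
  model <- build_fusion_model(fusion_config("tiny", "tiny", 3L,
                                            head_width = 8L,
                                            dropout_rate = 0, seed = 8))
  model$params$att_a_w[] <- 0
  model$params$att_a_b <- 50          # sigmoid(50) ~ 1
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- patchfuse:::fusion_forward(model, img)
  feat <- patchfuse:::backbone_forward(model$backbone_a, img)$out
  pooled <- global_average_pool(feat)
  act <- pmax(as.vector(model$params$dense_a_W %*% pooled) +
                model$params$dense_a_b, 0)
  logits <- as.vector(model$params$clf_a_W %*% act) + model$params$clf_a_b
  expect_equal(fw$pred_a, softmax(logits), tolerance = 1e-8)
})

test_that("opaque ImageNet backbones refuse forward passes with a clear error", {
  m <- build_baseline("xception", 3L)
  img <- array(0.5, c(224, 224, 3))
  expect_error(predict(m, img), "parameter accounting only")
  expect_error(backbone_spec("resnet"), "unknown backbone")
})
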