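tiny_control <- function(...) {
  train_control(strategy = "single_lead", epochs = 2L, batch_size = 8L,
                window = 256L, windows_per_record = 2L, lr = 1e-3,
                seed = 7L, ...)
}

tiny_dataset <- function(n_subjects = 4, seed = 60, duration = 6) {
  simulate_dataset(sim_spec(n_subjects = n_subjects, duration = duration,
                            seed = seed))
}

test_that("jaccard loss is zero at identity and ~1 on disjoint masks", {
  t <- cbind(c(rep(1, 8), rep(0, 8)), rep(0, 16), rep(1, 16))
  expect_equal(jaccard_loss(t, t), 0)
  half <- cbind(rep(c(1, 0), 8), rep(c(0, 1), 8), rep(1, 16))
  flipped <- 1 - half
  expect_gt(jaccard_loss(half, flipped), 0.9)
  expect_error(jaccard_loss(t, t[1:8, ]), "shape")
  expect_error(jaccard_loss(t + 2, t), "0, 1")
})

test_that("jaccard loss equals the hand formula on a random 8-sample case", {
  set.seed(12)
  p <- matrix(runif(24), 8, 3)
  t <- matrix(rbinom(24, 1, 0.5), 8, 3)
  eps <- 1
  by_hand <- 1 - mean(vapply(1:3, function(c) {
    inter <- sum(p[, c] * t[, c])
    (inter + eps) / (sum(p[, c]) + sum(t[, c]) - inter + eps)
  }, numeric(1)))
  expect_equal(jaccard_loss(p, t), by_hand)
  ## bounds hold for random probabilistic inputs
  for (i in 1:20) {
    p2 <- matrix(runif(24), 8, 3)
    l <- jaccard_loss(p2, t)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("the analytic jaccard gradient matches finite differences", {
  set.seed(13)
  p <- matrix(runif(30, 0.1, 0.9), 10, 3)
  t <- matrix(rbinom(30, 1, 0.4), 10, 3)
  g <- ecgdelnet:::jaccard_loss_grad(p, t)
  eps <- 1e-6
  for (i in sample(30, 8)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (jaccard_loss(pp, t) - jaccard_loss(pm, t)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("folds partition subjects with no train/test overlap", {
  ids <- sprintf("s%02d", 1:10)
  fs <- make_folds(ids, k = 5, seed = 3)
  test_sets <- lapply(fs$folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), sort(ids))
  expect_equal(vapply(test_sets, length, integer(1)), rep(2L, 5))
  for (f in fs$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(make_folds(ids, 5, seed = 3), fs)
  expect_error(make_folds(ids[1:3], k = 5), "at least")
})

test_that("no subject leaks across folds for a thousand random seeds", {
  ids <- sprintf("s%02d", 1:17)
  for (seed in 1:1000) {
    fs <- make_folds(ids, k = 4, seed = seed)
    overlaps <- vapply(fs$folds, function(f)
      length(intersect(f$train, f$test)), integer(1))
    if (any(overlaps > 0)) fail(sprintf("leak at seed %d", seed))
    if (!setequal(unlist(lapply(fs$folds, `[[`, "test")), ids))
      fail(sprintf("tests do not cover subjects at seed %d", seed))
  }
  succeed()
})

test_that("training runs are bitwise seed-reproducible", {
  ds <- tiny_dataset()
  cfg <- tiny_config(seed = 5)
  m1 <- fit_delineator(ds$records, ds$fiducials, cfg, tiny_control())
  m2 <- fit_delineator(ds$records, ds$fiducials, cfg, tiny_control())
  expect_identical(m1$history, m2$history)
  expect_identical(coef(m1), coef(m2))
})

test_that("training never touches held-out subjects (fold isolation)", {
  ds <- tiny_dataset(n_subjects = 4)
  folds <- make_folds(names(ds$records), k = 2, seed = 9)
  cfg <- tiny_config(seed = 5)
  fits <- cv_delineator(ds$records, ds$fiducials, folds, cfg,
                        tiny_control())
  f1 <- folds$folds[[1]]
  ## deleting the test subjects entirely reproduces the same training run
  direct <- fit_delineator(ds$records[f1$train], ds$fiducials[f1$train],
                           cfg, tiny_control())
  expect_identical(fits[[1]]$model$history, direct$history)
  expect_identical(coef(fits[[1]]$model), coef(direct))
})

test_that("training loss decreases on an easy overfit problem", {
  out <- fixture_record(seed = 61, duration = 10)
  ctl <- train_control(strategy = "single_lead", epochs = 15,
                       batch_size = 8, window = 256,
                       windows_per_record = 4, lr = 2e-3, seed = 2)
  cfg <- suppressWarnings(unet_config(levels = 4, blocks_per_level = 2,
                                      base_width = 4, seed = 2))
  m <- fit_delineator(list(r = out$record), list(r = out$fiducials), cfg,
                      ctl)
  expect_lt(tail(m$history$loss, 1), head(m$history$loss, 1))
})

test_that("pre-training protocol enforces its contracts", {
  ds <- tiny_dataset(n_subjects = 4)
  low <- lapply(ds$fiducials, degrade_labels, onset_noise_sd = 8,
                miss_rate = 0.2, false_rate = 0.05, seed = 3)
  folds <- make_folds(names(ds$records), k = 2, seed = 1)
  cfg <- tiny_config(seed = 5)
  expect_error(
    pretrain_then_finetune(ds$records, ds$fiducials, low, folds, cfg,
                           tiny_control(augmentation = augmentation_policy()),
                           tiny_control()),
    "augmentation")
  fits <- pretrain_then_finetune(ds$records, ds$fiducials, low, folds, cfg,
                                 tiny_control(), tiny_control())
  expect_length(fits, 2)
  ## stage-1 model alone emits a valid 3-channel probability mask
  pre <- fits[[1]]$pretrained
  pm <- predict(pre, ds$records[[1]], strategy = "single_lead",
                window = 256L)
  expect_true(all(pm[[1]] >= 0 & pm[[1]] <= 1))
  expect_equal(ncol(pm[[1]]), 3)
  ## fine-tuning really starts from the pre-trained weights: it differs
  ## from the scratch run trained on the identical data stream
  scratch <- cv_delineator(ds$records, ds$fiducials, folds, cfg,
                           tiny_control())
  expect_false(identical(coef(fits[[1]]$model), coef(scratch[[1]]$model)))
  expect_equal(nrow(fits[[1]]$model$history),
               nrow(scratch[[1]]$model$history))
})

test_that("the experiment grid yields one row per config, fold and wave", {
  ds <- tiny_dataset(n_subjects = 4)
  folds <- make_folds(names(ds$records), k = 2, seed = 2)
  grid <- data.frame(spatial_dropout_p = c(0, 0.25))
  res <- run_experiment_grid(ds$records, ds$fiducials, folds, grid,
                             base_config = tiny_config(seed = 5),
                             base_control = tiny_control(),
                             window = 256L)
  expect_equal(nrow(res), 2 * 2 * 3)
  expect_setequal(unique(res$spatial_dropout_p), c(0, 0.25))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  ## reproducible per seed
  res2 <- run_experiment_grid(ds$records, ds$fiducials, folds, grid,
                              base_config = tiny_config(seed = 5),
                              base_control = tiny_control(),
                              window = 256L)
  expect_identical(res$f1, res2$f1)
  ## the SDo on/off contrast column supports paired fold differences
  d <- merge(res[res$spatial_dropout_p == 0.25, c("fold", "wave", "f1")],
             res[res$spatial_dropout_p == 0, c("fold", "wave", "f1")],
             by = c("fold", "wave"), suffixes = c("_sdo", "_base"))
  expect_equal(nrow(d), 6)
  expect_type(median(d$f1_sdo - d$f1_base), "double")
})
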