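test_that("configs outside the sweep warn and invalid ones error", {
  expect_warning(unet_config(levels = 3), "sweep")
  expect_warning(unet_config(blocks_per_level = 7), "sweep")
  expect_silent(unet_config(levels = 5, blocks_per_level = 3))
  expect_error(unet_config(kernel_size = 4), "odd")
  expect_error(unet_config(pool_size = 1), "pool")
  expect_error(make_block("mystery", 4, 4, tiny_config()), "unknown")
})

test_that("forward preserves length and emits 3 probability channels", {
  cfg <- unet_config(levels = 4, blocks_per_level = 3, base_width = 16,
                     seed = 2)
  m <- build_unet(cfg)
  X <- array(rnorm(512), c(512, 1, 1))
  out <- ecgdelnet:::unet_fwd(m, X)$out
  expect_equal(dim(out), c(512L, 3L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  ## encoder channel schedule 2^l * N
  ms <- model_summary(cfg, 512)
  expect_equal(ms$levels$channels, c(16, 32, 64, 128))
  expect_equal(ms$levels$length, c(512, 256, 128, 64))
})

test_that("indivisible input lengths raise a shape error naming the level", {
  cfg <- tiny_config()
  m <- build_unet(cfg)
  X <- array(rnorm(100), c(100, 1, 1))
  expect_error(ecgdelnet:::unet_fwd(m, X), "level 4")
})

test_that("multi-lead input maps 2 channels to 3 output channels", {
  cfg <- tiny_config(in_channels = 2)
  m <- build_unet(cfg)
  X <- array(rnorm(256 * 2 * 2), c(256, 2, 2))
  out <- ecgdelnet:::unet_fwd(m, X)$out
  expect_equal(dim(out), c(256L, 3L, 2L))
})

test_that("residual and xception blocks reduce to identity at zero weight", {
  for (bt in c("residual", "xception")) {
    cfg <- tiny_config(block_type = bt, use_batch_norm = FALSE)
    blk <- make_block(bt, 4, 4, cfg)
    blk$params <- rapply(blk$params, function(x)
      if (is.numeric(x)) x * 0 else x, how = "replace")
    X <- matrix(rnorm(32 * 2 * 4), 32 * 2, 4)  # two batch blocks of 32
    out <- ecgdelnet:::block_fwd(blk$params, blk$state, X, FALSE, cfg,
                                 B = 2L)$out
    expect_equal(out, X)
  }
})

test_that("xception blocks are lighter than vanilla at equal width", {
  cfg <- unet_config(levels = 4, blocks_per_level = 2, base_width = 16,
                     block_type = "vanilla", seed = 1)
  cfg_x <- unet_config(levels = 4, blocks_per_level = 2, base_width = 16,
                       block_type = "xception", seed = 1)
  n_v <- model_summary(cfg, 512)$n_params
  n_x <- model_summary(cfg_x, 512)$n_params
  expect_lt(n_x, n_v)
  ## block-level count formula: vanilla k*cin*cout vs dw k*cin + cin*cout
  c_ <- 16; k <- 3
  v_block <- (k * c_ * c_ + c_) * 2
  x_block <- (k * c_ + c_ * c_ + c_) * 2
  expect_lt(x_block, v_block)
})

test_that("weight initialization and inference are seed-deterministic", {
  cfg <- tiny_config(seed = 99)
  m1 <- build_unet(cfg); m2 <- build_unet(cfg)
  expect_identical(coef(m1), coef(m2))
  X <- array(rnorm(128), c(128, 1, 1))
  expect_identical(ecgdelnet:::unet_fwd(m1, X)$out,
                   ecgdelnet:::unet_fwd(m2, X)$out)
})

test_that("spatial dropout zeroes whole channels and rescales survivors", {
  X <- array(1, c(64, 8, 4))
  expect_identical(spatial_dropout(X, 0, training = TRUE), X)
  expect_identical(spatial_dropout(X, 0.5, training = FALSE), X)
  set.seed(1)
  Y <- spatial_dropout(X, 0.5, training = TRUE)
  for (c_ in 1:8) for (b in 1:4) {
    col <- Y[, c_, b]
    expect_true(all(col == 0) || all(col == 2))
  }
  expect_error(spatial_dropout(X, 1), "probability")
  ## rescaling keeps the expected mean
  set.seed(2)
  means <- replicate(400, mean(spatial_dropout(X, 0.25, training = TRUE)))
  expect_equal(mean(means), 1, tolerance = 0.05)
})

test_that("analytic gradients match finite differences for every block type", {
  set.seed(14)
  for (bt in c("vanilla", "residual", "xception")) {
    cfg <- tiny_config(block_type = bt, seed = 31)
    m <- build_unet(cfg)
    T <- 32; B <- 2
    X <- array(rnorm(T * B), c(T, 1, B))
    Yt <- array(rbinom(T * 3 * B, 1, 0.3), c(T, 3, B))
    fwd <- ecgdelnet:::unet_fwd(m, X, training = TRUE)
    dOut <- ecgdelnet:::jaccard_loss_grad(fwd$out, Yt)
    g <- ecgdelnet:::flatten_params(
      ecgdelnet:::unet_bwd(m, fwd$cache, dOut))
    theta <- coef(m)
    lossfn <- function(th) {
      mm <- m
      mm$params <- ecgdelnet:::unflatten_params(m$params, th)
      jaccard_loss(ecgdelnet:::unet_fwd(mm, X, training = TRUE)$out, Yt)
    }
    idx <- sample(length(theta), 12)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (lossfn(tp) - lossfn(tm)) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("stitched prediction equals a direct pass when window = record", {
  cfg <- tiny_config(seed = 3)
  m <- build_unet(cfg)
  sig <- matrix(rnorm(256), ncol = 1)
  rec <- ecg_record("r", sig, 250)
  pm <- predict(m, rec, strategy = "single_lead", window = 256L)
  X <- array(ecgdelnet:::normalize_lead_matrix(sig), c(256, 1, 1))
  direct <- ecgdelnet:::unet_fwd(m, X, training = FALSE)$out[, , 1]
  expect_equal(matrix(unclass(pm[[1]]), 256, 3), direct)
})

test_that("prediction strategies yield one mask per lead or one in total", {
  rec <- fixture_record(seed = 30, duration = 6)$record
  m1 <- build_unet(tiny_config(seed = 4))
  pm <- predict(m1, rec, strategy = "single_lead", window = 256L)
  expect_length(pm, 2)
  expect_s3_class(pm[[1]], "seg_mask")
  m2 <- build_unet(tiny_config(seed = 4, in_channels = 2))
  pm2 <- predict(m2, rec, strategy = "multi_lead", window = 256L)
  expect_s3_class(pm2, "seg_mask")
  expect_equal(nrow(pm2), nrow(rec$signal))
})

test_that("records shorter than the window are padded and cropped", {
  rec <- ecg_record("r", matrix(rnorm(100), ncol = 1), 250)
  m <- build_unet(tiny_config(seed = 5))
  expect_message(pm <- predict(m, rec, strategy = "single_lead",
                               window = 256L), "padded")
  expect_equal(nrow(pm[[1]]), 100)
})

test_that("overlap averaging is exact for constant outputs", {
  ## zero-weight head forces a constant sigmoid output regardless of tiling
  m <- build_unet(tiny_config(seed = 6))
  m$params$head$W <- m$params$head$W * 0
  m$params$head$b <- rep(0.3, 3)
  rec <- ecg_record("r", matrix(rnorm(700), ncol = 1), 250)
  pm <- predict(m, rec, strategy = "single_lead", window = 256L,
                overlap = 0.5)
  expect_equal(max(pm[[1]]) - min(pm[[1]]), 0, tolerance = 1e-12)
  expect_equal(unique(round(as.numeric(pm[[1]]), 10)),
               round(1 / (1 + exp(-0.3)), 10))
})
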