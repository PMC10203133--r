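test_that("network output is voxel-wise (same shape as input)", {
  cfg <- unet_config(depth = 3, base_channels = 2, patch_vox = 64)
  net <- build_network(cfg, seed = 1)
  x <- array(rnorm(64^3), rep(64, 3))
  y <- predict_patch(net, x)
  expect_equal(dim(y), rep(64, 3))
  cfg2 <- unet_preset("desk")
  net2 <- build_network(cfg2, seed = 1)
  x2 <- array(rnorm(32^3), rep(32, 3))
  expect_equal(dim(predict_patch(net2, x2)), rep(32, 3))
  expect_error(unet_config(depth = 3, patch_vox = 60), "divisible")
})

test_that("parameter counts are deterministic and grow with depth", {
  c2 <- unet_config(depth = 2, base_channels = 8, patch_vox = 32)
  c3 <- unet_config(depth = 3, base_channels = 8, patch_vox = 32)
  expect_identical(n_parameters(build_network(c2, seed = 1)),
                   n_parameters(build_network(c2, seed = 99)))
  expect_gt(n_parameters(build_network(c3, seed = 1)),
            n_parameters(build_network(c2, seed = 1)))
})

test_that("the conv kernels backpropagate exact gradients", {
  set.seed(2)
  vd <- c(6, 6, 6)
  x <- matrix(rnorm(prod(vd) * 2), ncol = 2)
  w <- matrix(rnorm(27 * 2 * 3, sd = 0.3), 27 * 2, 3)
  b <- rnorm(3)
  dy <- matrix(rnorm(prod(vd) * 3), ncol = 3)
  g <- tomorest:::cpp_conv3_backward(x, as.integer(vd), w, dy, 3L)
  eps <- 1e-3
  fW <- function(wm) sum(tomorest:::cpp_conv3_forward(x, as.integer(vd), wm, b, 3L) * dy)
  fX <- function(xm) sum(tomorest:::cpp_conv3_forward(xm, as.integer(vd), w, b, 3L) * dy)
  for (i in sample(length(w), 5)) {
    wp <- w; wp[i] <- w[i] + eps
    wm2 <- w; wm2[i] <- w[i] - eps
    expect_equal(g$dw[i], (fW(wp) - fW(wm2)) / (2 * eps), tolerance = 5e-3)
  }
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- x[i] + eps
    xm2 <- x; xm2[i] <- x[i] - eps
    expect_equal(g$dx[i], (fX(xp) - fX(xm2)) / (2 * eps), tolerance = 5e-3)
  }
})

test_that("training learns the identity task and is seed-deterministic", {
  set.seed(4)
  pairs <- lapply(1:30, function(i) {
    ph <- make_phantom(16, list(runif(3, 4, 12)), runif(1, 1.5, 3))
    v <- normalize_volume(ph)
    training_pair(v, v, normalized = TRUE)
  })
  cfg <- unet_config(depth = 2, base_channels = 8, patch_vox = 16)
  tc <- training_config(iterations = 150, batch_size = 4, seed = 3,
                        validation_fraction = 0.1, learning_rate = 2e-3)
  fit <- train_restorer(pairs, cfg, tc)
  expect_equal(nrow(fit$history), 150)
  val <- fit$history$val_loss[!is.na(fit$history$val_loss)]
  first_val <- val[1]; last_val <- val[length(val)]
  expect_lt(last_val, 0.5 * first_val)
  # early-vs-late smoothed training loss also drops
  expect_lt(mean(fit$history$loss[141:150]), 0.5 * mean(fit$history$loss[1:10]))
  # determinism: identical run, identical losses
  fit2 <- train_restorer(pairs, cfg, tc)
  expect_identical(fit$history$loss, fit2$history$loss)
  # prediction is deterministic
  x <- pairs[[1]]$input_vol$values
  expect_identical(predict_patch(fit, x), predict_patch(fit, x))
})

test_that("training on zero targets shrinks predictions toward zero", {
  set.seed(5)
  zero <- density_volume(array(0, rep(16, 3)), 1)
  pairs <- lapply(1:12, function(i) {
    ph <- normalize_volume(make_phantom(16, list(runif(3, 5, 11)), 2.5))
    training_pair(ph, zero, normalized = TRUE)
  })
  cfg <- unet_config(depth = 2, base_channels = 4, patch_vox = 16)
  x <- pairs[[1]]$input_vol$values
  before <- mean(abs(predict_patch(build_network(cfg, seed = 7), x)))
  checkpoints <- c(20, 60, 120)
  preds <- vapply(checkpoints, function(it) {
    fit <- train_restorer(pairs, cfg,
                          training_config(iterations = it, batch_size = 4,
                                          seed = 7, validation_fraction = 0,
                                          learning_rate = 2e-3))
    mean(abs(predict_patch(fit, x)))
  }, 0)
  expect_true(all(diff(c(before, preds)) < 0))
})

test_that("training rejects malformed pair sets", {
  v16 <- normalize_volume(default_phantom(16))
  v24 <- normalize_volume(default_phantom(24))
  p1 <- training_pair(v16, v16, normalized = TRUE)
  p2 <- training_pair(v24, v24, normalized = TRUE)
  cfg <- unet_config(depth = 2, base_channels = 4, patch_vox = 16)
  expect_error(train_restorer(list(), cfg, training_config()), "at least one")
  expect_error(train_restorer(list(p1, p2), cfg, training_config()),
               "mismatched shapes")
})

test_that("checkpoints round-trip through save/load", {
  set.seed(6)
  v <- normalize_volume(default_phantom(16))
  fit <- train_restorer(list(training_pair(v, v, normalized = TRUE)),
                        unet_config(2, 4, 16),
                        training_config(iterations = 2, batch_size = 1,
                                        seed = 1, validation_fraction = 0))
  path <- tempfile(fileext = ".rest")
  save_restorer(fit, path)
  back <- load_restorer(path)
  x <- v$values
  expect_identical(predict_patch(fit, x), predict_patch(back, x))
  bad <- tempfile(); saveRDS(list(1), bad)
  expect_error(load_restorer(bad), "checkpoint")
})

test_that("tiled restoration stitches without seams and handles any shape", {
  set.seed(7)
  pairs <- lapply(1:20, function(i) {
    ph <- normalize_volume(make_phantom(16, list(runif(3, 4, 12)),
                                        runif(1, 2, 3)))
    training_pair(ph, ph, normalized = TRUE)
  })
  cfg <- unet_config(depth = 2, base_channels = 8, patch_vox = 16)
  fit <- train_restorer(pairs, cfg,
                        training_config(iterations = 120, batch_size = 4,
                                        seed = 2, validation_fraction = 0,
                                        learning_rate = 2e-3))
  # single-tile volume: equals the direct prediction bit-exactly
  one <- normalize_volume(default_phantom(16))
  direct <- predict_patch(fit, one$values)
  tiled <- restore_volume(fit, one, patch = 16, overlap_vox = 4,
                          normalize = FALSE)
  expect_identical(tiled$values, direct)
  # a 16 x 16 x 48 volume: no discontinuity at tile seams
  long <- array(0, c(16, 16, 48))
  for (z0 in c(0, 16, 32))
    long[, , z0 + 1:16] <- make_phantom(16, list(c(8, 8, 8)), 2.5)$values
  long <- normalize_volume(density_volume(long, 1))
  rlong <- restore_volume(fit, long, patch = 16, overlap_vox = 8,
                          normalize = FALSE)
  expect_equal(dim(rlong$values), c(16, 16, 48))
  dz <- vapply(1:47, function(z)
    stats::median(abs(rlong$values[, , z + 1] - rlong$values[, , z])), 0)
  seams <- c(12, 20, 28, 36)   # stitch boundaries for patch 16 / overlap 8
  expect_lt(max(dz[seams]), 3 * stats::median(dz[-seams]))
  # smaller than a patch: pad-predict-crop
  tiny <- normalize_volume(default_phantom(12))
  rtiny <- restore_volume(fit, tiny, patch = 16, overlap_vox = 4,
                          normalize = FALSE)
  expect_equal(dim(rtiny$values), rep(12, 3))
  expect_error(restore_volume(fit, one, patch = 16, overlap_vox = 3),
               "even")
})
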