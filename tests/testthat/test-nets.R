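tiny_spec <- function(heads = c(affs = 3))
  model_spec(3, in_channels = 2, out_heads = heads, depth = 1,
             base_features = 4)

rand_batch <- function(heads, seed = 3) {
  withr::with_seed(seed, {
    input <- array(runif(2 * 4 * 8 * 8), c(2, 4, 8, 8))
    targets <- lapply(heads, function(ch)
      array(runif(ch * 4 * 8 * 8), c(ch, 4, 8, 8)))
    weights <- lapply(heads, function(ch)
      array(rbinom(ch * 4 * 8 * 8, 1, 0.8), c(ch, 4, 8, 8)))
    list(input = input, targets = targets, weights = weights)
  })
}

test_that("backpropagated gradients match central finite differences", {
  spec <- tiny_spec()
  m <- init_model(spec, seed = 7)
  b <- rand_batch(spec$out_heads)
  cs <- bootseg:::cpp_spec(spec)
  res <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                       b$weights)
  eps <- 1e-6
  set.seed(21)
  for (pi in seq_along(m$params)) {
    for (j in sample.int(length(m$params[[pi]]),
                         min(2, length(m$params[[pi]])))) {
      pp <- m$params
      pp[[pi]][j] <- pp[[pi]][j] + eps
      lp <- bootseg:::cpp_unet_train_step(cs, pp, b$input, b$targets,
                                          b$weights)$loss
      pp[[pi]][j] <- pp[[pi]][j] - 2 * eps
      lm <- bootseg:::cpp_unet_train_step(cs, pp, b$input, b$targets,
                                          b$weights)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- res$grads[[pi]][j]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-3)
    }
  }
})

test_that("zero-weight entries never influence loss or parameter updates", {
  spec <- tiny_spec()
  m <- init_model(spec, seed = 7)
  b <- rand_batch(spec$out_heads)
  cs <- bootseg:::cpp_spec(spec)
  r1 <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                      b$weights)
  # change targets wherever the weight is zero: nothing may move
  t2 <- b$targets
  z <- b$weights$affs == 0
  t2$affs[z] <- t2$affs[z] + 5
  r2 <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, t2, b$weights)
  expect_identical(r1$loss, r2$loss)
  for (i in seq_along(r1$grads)) expect_identical(r1$grads[[i]], r2$grads[[i]])
})

test_that("multi-head losses are additive with unit head weights", {
  spec <- tiny_spec(c(affs = 3, lsd = 4))
  m <- init_model(spec, seed = 5)
  b <- rand_batch(spec$out_heads, seed = 9)
  cs <- bootseg:::cpp_spec(spec)
  both <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                        b$weights)$loss
  # disabling one head (all-zero weights) leaves exactly the other term
  w_no_lsd <- b$weights; w_no_lsd$lsd[] <- 0
  only_affs <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                             w_no_lsd)$loss
  w_no_affs <- b$weights; w_no_affs$affs[] <- 0
  only_lsd <- bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                            w_no_affs)$loss
  expect_equal(both, only_affs + only_lsd, tolerance = 1e-12)
})

test_that("predictions are sigmoid-bounded and tiling-invariant", {
  spec <- tiny_spec(c(affs = 3, lsd = 4))
  m <- init_model(spec, seed = 11)
  set.seed(2)
  input <- array(runif(2 * 8 * 16 * 16), c(2, 8, 16, 16))
  full <- bootseg:::tile_predict(m, input)
  tiled <- bootseg:::tile_predict(m, input, tile = c(4, 8, 8))
  for (h in names(full)) {
    expect_true(all(full[[h]] >= 0 & full[[h]] <= 1))
    expect_lt(max(abs(full[[h]] - tiled[[h]])), 1e-4)
    expect_identical(dim(full[[h]])[2:4], dim(input)[2:4])
  }
})

test_that("zero-iteration training returns the initialized checkpoint", {
  lab <- label_volume(array(sample(0:2, 4 * 16 * 16, replace = TRUE),
                            c(4, 16, 16)), c(10, 10, 10))
  raw <- render_raw(lab, seed = 1)
  ann <- sparse_annotation(lab, array(TRUE, dim(lab$data)))
  spec <- model_spec(2, 1, c(lsd = 6), depth = 1, base_features = 4)
  cfg <- train_config(0, patch_shape = c(16, 16), master_seed = 4)
  rep <- train_sparse_2d(raw, ann, spec, cfg, sigma = 20)
  expect_length(rep$loss_trace, 0)
  expect_equal(rep$model$iteration, 0L)
  expect_identical(rep$model$params,
                   init_model(spec, derive_subseed(4, 0))$params)
})

test_that("a 2D model overfits one densely labeled section", {
  sp <- synth_params(c(8, 48, 48), num_objects = c(4, 8), seed = 5)
  lab <- generate_labels(sp)
  raw <- render_raw(lab, seed = 5)
  ann <- sparse_annotation(lab, array(TRUE, dim(lab$data)))
  spec <- model_spec(2, 1, c(lsd = 6), depth = 2, base_features = 8)
  cfg <- train_config(300, patch_shape = c(48, 48), learning_rate = 1e-3,
                      master_seed = 2)
  rep <- train_sparse_2d(raw, ann, spec, cfg, sigma = 20)
  expect_lt(mean(tail(rep$loss_trace, 10)), 0.1 * rep$loss_trace[1])
})

test_that("patch sampling rejects unannotatable configurations", {
  lab <- label_volume(array(0, c(4, 32, 32)), c(10, 10, 10))
  msk <- array(FALSE, dim(lab$data))
  msk[2, 1, 1] <- TRUE # single annotated voxel: fraction always < 5%
  ann <- sparse_annotation(lab, msk)
  raw <- volume_grid(array(0.5, dim(lab$data)), lab$voxel_size)
  spec <- model_spec(2, 1, c(lsd = 6), depth = 1, base_features = 4)
  cfg <- train_config(2, patch_shape = c(32, 32), master_seed = 1)
  expect_error(train_sparse_2d(raw, ann, spec, cfg, sigma = 20),
               "labeled fraction")
})

test_that("synthetic 3D training beats an untrained model on held-out data", {
  spec <- model_spec(3, 6, c(affs = 3), depth = 1, base_features = 6)
  synth <- synth_params(c(8, 16, 16), num_objects = c(3, 6), seed = 1)
  degrade <- degrade_params(seed = 1)
  cfg0 <- train_config(0, patch_shape = c(8, 16, 16), master_seed = 3)
  cfg <- train_config(80, patch_shape = c(8, 16, 16), learning_rate = 1e-3,
                      master_seed = 3)
  untrained <- train_3d_from_synthetic(spec, cfg0, synth, degrade,
                                       sigma = 20)$model
  trained <- train_3d_from_synthetic(spec, cfg, synth, degrade,
                                     sigma = 20)$model
  held <- synth; held$seed <- 99991L
  pair <- make_training_pair(held, 20, degrade_params(seed = 99991))
  loss_of <- function(m) {
    pred <- bootseg:::tile_predict(m, pair$input$data)$affs
    masked_mse(pred, pair$target$data, pair$weights)
  }
  expect_lt(loss_of(trained), loss_of(untrained))
})

test_that("training is bit-reproducible under a fixed master seed", {
  spec <- model_spec(3, 6, c(affs = 3), depth = 1, base_features = 4)
  synth <- synth_params(c(8, 16, 16), num_objects = c(3, 6), seed = 1)
  degrade <- degrade_params(seed = 1)
  cfg <- train_config(8, patch_shape = c(8, 16, 16), learning_rate = 1e-3,
                      master_seed = 5)
  r1 <- train_3d_from_synthetic(spec, cfg, synth, degrade, sigma = 20)
  r2 <- train_3d_from_synthetic(spec, cfg, synth, degrade, sigma = 20)
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("section inference is independent and permutation-equivariant", {
  spec <- model_spec(2, 1, c(lsd = 6), depth = 1, base_features = 4)
  m <- init_model(spec, seed = 3)
  m$sigma <- 20
  set.seed(4)
  vol <- volume_grid(array(runif(4 * 16 * 16), c(4, 16, 16)), c(10, 10, 10))
  out <- predict_2d_stack(m, vol)
  perm <- c(3, 1, 4, 2)
  vol2 <- volume_grid(vol$data[perm, , ], vol$voxel_size)
  out2 <- predict_2d_stack(m, vol2)
  expect_equal(out2$data, out$data[, perm, , ])
})

test_that("multi-task models return every configured head", {
  spec <- model_spec(3, 1, c(affs = 3, lsd = 10), depth = 1,
                     base_features = 4)
  m <- init_model(spec, seed = 2)
  m$sigma <- 20
  vol <- volume_grid(array(0.5, c(8, 16, 16)), c(10, 10, 10))
  out <- predict_3d(m, vol)
  expect_named(out, c("affs", "lsd"))
  expect_identical(dim(out$affs$data), c(3L, 8L, 16L, 16L))
  expect_identical(dim(out$lsd$data), c(10L, 8L, 16L, 16L))
  expect_s3_class(out$affs, "affinity_grid")
  expect_s3_class(out$lsd, "descriptor_grid")
  expect_error(predict_3d(m, array(0.5, c(2, 8, 16, 16))), "channels")
})

test_that("3D multi-task training overfits a small crop", {
  sp <- synth_params(c(16, 24, 24), num_objects = c(5, 9), seed = 7)
  lab <- generate_labels(sp)
  raw <- render_raw(lab, seed = 7)
  spec <- model_spec(3, 1, c(affs = 3, lsd = 10), depth = 1,
                     base_features = 8,
                     downsample_factors = list(c(1L, 2L, 2L)))
  cfg <- train_config(300, patch_shape = c(8, 16, 16), learning_rate = 1e-3,
                      master_seed = 6)
  rep <- train_3d_mtlsd(raw, lab, spec, cfg, sigma = 20)
  expect_lt(mean(tail(rep$loss_trace, 10)), 0.35 * rep$loss_trace[1])
  cfg0 <- train_config(0, patch_shape = c(8, 16, 16), master_seed = 6)
  rep0 <- train_3d_mtlsd(raw, lab, spec, cfg0, sigma = 20)
  expect_equal(rep0$model$iteration, 0L)
})

test_that("checkpoints round-trip through serialization", {
  spec <- tiny_spec()
  m <- init_model(spec, seed = 1)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m$params, m2$params)
  b <- rand_batch(spec$out_heads)
  cs <- bootseg:::cpp_spec(spec)
  expect_identical(
    bootseg:::cpp_unet_train_step(cs, m$params, b$input, b$targets,
                                  b$weights)$loss,
    bootseg:::cpp_unet_train_step(cs, m2$params, b$input, b$targets,
                                  b$weights)$loss)
})
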