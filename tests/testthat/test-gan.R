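test_that("smooth L1 matches its closed forms at the branch points", {
  expect_equal(smooth_l1(array(1, c(2, 2, 2)), array(1, c(2, 2, 2))), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)        # quadratic branch
  expect_equal(smooth_l1(2, 0), 1.5)            # linear branch
  expect_equal(smooth_l1(1, 0), 0.5)            # both branches agree at |d|=1
  expect_equal(smooth_l1(1 - 1e-9, 0), 0.5, tolerance = 1e-6)
  expect_error(smooth_l1(array(0, c(2, 2)), array(0, c(3, 3))), "shape")
})

test_that("adversarial and discriminator losses match closed forms", {
  expect_equal(adversarial_loss(0.5), log(2), tolerance = 1e-9)
  expect_lt(adversarial_loss(1 - 1e-7), 1e-5)
  d <- adversarial_loss(c(0.2, 0.4, 0.8))
  expect_true(all(diff(d) < 0))                 # decreasing in D(X)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  expect_lt(discriminator_loss(1 - 1e-7, 1e-7), 1e-5)
  # symmetry under (d_real, d_fake) -> (1 - d_fake, 1 - d_real)
  expect_equal(discriminator_loss(0.7, 0.2), discriminator_loss(0.8, 0.3))
})

test_that("generator loss is the linear combination of its two terms", {
  x <- array(0.3, c(4, 4, 4)); y <- x
  expect_equal(generator_loss(x, y, 0.5, alpha = 0.01), 0.01 * log(2),
               tolerance = 1e-9)
  expect_equal(generator_loss(x, y, 0.5, alpha = 0.01), 0.006931,
               tolerance = 1e-4)
  set.seed(1)
  x2 <- array(runif(64), c(4, 4, 4)); y2 <- array(runif(64), c(4, 4, 4))
  l1 <- smooth_l1(x2, y2)
  # linear in alpha
  a1 <- generator_loss(x2, y2, 0.3, alpha = 0.02) - l1
  a2 <- generator_loss(x2, y2, 0.3, alpha = 0.05) - l1
  expect_equal(a2 / a1, 0.05 / 0.02, tolerance = 1e-9)
  # ablation switches
  expect_equal(generator_loss(x2, y2, 0.3, alpha = 0),  l1)
  expect_equal(generator_loss(x2, y2, 0.3, alpha = 0.02, use_smooth_l1 = FALSE),
               0.02 * adversarial_loss(0.3))
})

test_that("default networks hit the published parameter budgets", {
  cfg <- gan_config()
  expect_equal(round(count_parameters(build_generator(cfg)) / 1e6, 1), 10.3)
  expect_equal(round(count_parameters(build_discriminator(cfg)) / 1e6, 1), 1.2)
})

test_that("parameter count increases strictly with base width", {
  counts <- vapply(c(2, 4, 8), function(w)
    count_parameters(build_generator(
      gan_config(base_width = w, depth = 2, convs_per_block = 2))),
    numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(gan_config(depth = 5), "depth")
})

test_that("network forward passes obey the shape and range contracts", {
  cfg <- gan_config(base_width = 2, depth = 2, convs_per_block = 1, seed = 10)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  x <- array(runif(32^3), c(32, 32, 32))
  y <- generator_forward(gen, x)
  expect_identical(dim(y), c(32L, 32L, 32L))
  p0 <- discriminator_forward(disc, array(0, c(32, 32, 32)))
  p1 <- discriminator_forward(disc, array(1, c(32, 32, 32)))
  expect_true(p0 > 0 && p0 < 1 && p1 > 0 && p1 < 1)
  expect_false(isTRUE(all.equal(p0, p1)))   # non-degenerate at init
})

test_that("training is seeded-deterministic and records loss history", {
  ds <- tiny_tile_dataset(4, seed = 7)
  cfg <- gan_config(base_width = 1, depth = 1, convs_per_block = 1,
                    epochs = 2, batch_size = 2, seed = 99,
                    disc_widths = c(2, 2, 4, 4), fc_widths = c(4, 2, 1))
  ck1 <- train_gan(ds, ds[1:2], cfg)
  ck2 <- train_gan(ds, ds[1:2], cfg)
  expect_identical(ck1$history, ck2$history)
  expect_equal(nrow(ck1$history), 2L)
  expect_true(all(is.finite(as.matrix(ck1$history))))
  expect_error(train_gan(list(), NULL, cfg), "empty")
})

test_that("checkpoint save -> load -> generate is bit-stable", {
  ds <- tiny_tile_dataset(2, seed = 8)
  cfg <- gan_config(base_width = 1, depth = 1, convs_per_block = 1,
                    epochs = 1, batch_size = 2, seed = 5,
                    disc_widths = c(2, 2, 4, 4), fc_widths = c(4, 2, 1))
  ck <- train_gan(ds, ds, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  x <- ds[[1]]$sim
  expect_identical(generator_forward(ck$generator, x),
                   generator_forward(ck2$generator, x))
  expect_identical(ck2$history, ck$history)
  # incompatible checkpoint: tamper with the architecture snapshot
  bad <- readRDS(f)
  bad$gen_values[["extra.w"]] <- 1
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, f2)
  expect_error(load_checkpoint(f2), "incompatible")
})

test_that("alpha = 0 isolates the generator from the discriminator", {
  # same seeds, same data: training with alpha = 0 must give identical
  # generator parameters whether the discriminator is sabotaged or not,
  # because G never reads D outputs
  ds <- tiny_tile_dataset(2, seed = 3)
  cfg <- gan_config(base_width = 1, depth = 1, convs_per_block = 1,
                    epochs = 1, batch_size = 2, seed = 21, alpha = 0,
                    disc_widths = c(2, 2, 4, 4), fc_widths = c(4, 2, 1))
  ck_a <- train_gan(ds, ds, cfg)
  # a completely different discriminator must leave G training untouched
  cfg_b <- cfg
  cfg_b$disc_widths <- c(3L, 5L, 7L, 9L)
  ck_b <- train_gan(ds, ds, cfg_b)
  expect_identical(
    lapply(ck_a$generator$params, function(p) p$value),
    lapply(ck_b$generator$params, function(p) p$value))
})

test_that("refine_map preserves the grid and clamps negatives", {
  cfg <- gan_config(base_width = 1, depth = 1, convs_per_block = 1, seed = 2)
  gen <- build_generator(cfg)
  m <- minmax_normalize(random_map(c(24, 21, 20), voxel = 1,
                                   origin = c(3, -1, 2), seed = 14))
  out <- refine_map(m, gen)
  expect_identical(dim(out$data), dim(m$data))
  expect_equal(out$voxel_size, m$voxel_size)
  expect_equal(out$origin, m$origin)
  expect_gte(min(out$data), 0)
  # deterministic
  expect_identical(refine_map(m, gen)$data, out$data)
})
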