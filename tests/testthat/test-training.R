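test_that("splits partition at the sequence level with floor allocation", {
  s25 <- split_dataset(as.list(1:25), seed = 1)
  expect_equal(lengths(s25), c(train = 15L, val = 5L, test = 5L))
  s10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(s10), c(train = 6L, val = 2L, test = 2L))
  # partition: union equals input, pairwise disjoint
  all_items <- sort(unname(unlist(s25)))
  expect_equal(all_items, 1:25)
  expect_identical(split_dataset(as.list(1:25), seed = 4),
                   split_dataset(as.list(1:25), seed = 4))
  # data-frame input gains a split column
  df <- split_dataset(data.frame(id = 1:20), seed = 2)
  expect_equal(unname(table(df$split)[c("train", "val", "test")]),
               array(c(12L, 4L, 4L)))
  expect_error(split_dataset(as.list(1:2)), class = "vt_split_error")
})

test_that("flip augmentation is an involution that preserves labels", {
  s <- tiny_sequence(seed = 4)
  f <- flip_sequence(s, vertical = TRUE, horizontal = TRUE)
  expect_identical(flip_sequence(f, vertical = TRUE, horizontal = TRUE), s)
  expect_identical(f$diameters, s$diameters)
  expect_identical(f$imt, s$imt)
  expect_false(identical(f$frames, s$frames))
  # the same flip is applied to every frame: flipping frame t individually
  # matches slice t of the flipped stack
  expect_equal(f$frames[, , 3], s$frames[dim(s$frames)[1]:1,
                                         dim(s$frames)[2]:1, 3])
  # forced no-flip is the identity
  expect_identical(flip_sequence(s), s)
  set.seed(1)
  a <- augment_sequence(s, p_flip = 0)
  expect_identical(a, s)
})

test_that("training with zero-effective step size leaves weights unchanged", {
  s <- tiny_sequence(seed = 2, n_frames = 8, size = 16)
  cfg <- model_config("custom", image_size = c(16L, 16L), conv_out = 2L,
                      conv_k = 3L, conv_s = 2L, conv_p = 1L, conv_pool = 2L,
                      fc_hidden = 4L)
  m <- init_model(cfg, seed = 2)
  fit <- train_model(m, list(s), list(s),
                     train_config(learning_rate = 1e-300, epochs = 1,
                                  lambda = 0, augment = FALSE, seed = 2))
  expect_equal(fit$model$theta, m$theta, tolerance = 1e-12)
  expect_equal(nrow(fit$history), 1)
})

test_that("short training runs learn, log a consistent decomposition, and select by validation", {
  set.seed(99)
  seqs <- lapply(1:6, function(i) tiny_sequence(seed = 100 + i, n_frames = 12,
                                                size = 16, mu_T = 5, sigma_T = 0.5))
  cfg <- model_config("custom", image_size = c(16L, 16L), conv_out = 4L,
                      conv_k = 3L, conv_s = 2L, conv_p = 1L, conv_pool = 2L,
                      fc_hidden = 8L)
  m <- init_model(cfg, seed = 1)
  tc <- train_config(learning_rate = 1e-2, epochs = 6, lambda = 1e-4,
                     augment = TRUE, seed = 1)
  fit <- train_model(m, seqs[1:4], seqs[5:6], tc)
  h <- fit$history
  expect_equal(nrow(h), 6)
  # loss decomposition holds at every epoch
  expect_equal(h$train_loss, h$train_mse + tc$lambda * h$train_cl,
               tolerance = 1e-9)
  # learning happened
  expect_lt(h$train_mse[6], h$train_mse[1])
  # best epoch is the validation argmin
  expect_equal(fit$best_epoch, which.min(h$val_mse))
  # reproducibility: same seed, same history
  fit2 <- train_model(m, seqs[1:4], seqs[5:6], tc)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
  # lambda = 0 differs only through the CL term of the objective
  fit0 <- train_model(m, seqs[1:4], seqs[5:6],
                      train_config(learning_rate = 1e-2, epochs = 2, lambda = 0,
                                   augment = TRUE, seed = 1))
  expect_equal(fit0$history$train_loss, fit0$history$train_mse)
  expect_gt(fit0$history$train_cl[1], 0)  # CL still logged, just unweighted
  # glance/tidy accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})

test_that("prediction denormalizes to data units", {
  s <- tiny_sequence(seed = 3, n_frames = 10, size = 16)
  cfg <- model_config("custom", image_size = c(16L, 16L), conv_out = 2L,
                      conv_k = 3L, conv_s = 2L, conv_p = 1L, conv_pool = 2L,
                      fc_hidden = 4L)
  fit <- train_model(init_model(cfg, seed = 4), list(s), list(s),
                     train_config(learning_rate = 1e-2, epochs = 3,
                                  lambda = 0, seed = 4))
  expect_gt(fit$model$normalization$scale, 0)
  p <- predict(fit, s)
  # after even a short fit, predictions live near the data scale, far from
  # the normalized origin
  expect_lt(abs(mean(p$diameter) - mean(s$diameters)),
            3 * sd(s$diameters) + 1)
})
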