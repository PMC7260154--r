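test_that("the four metrics match one-line formula oracles to 1e-12", {
  set.seed(13)
  for (i in 1:50) {
    K <- sample(3:40, 1)
    y <- runif(K, 5, 50)
    y_hat <- y + rnorm(K)
    expect_equal(vt_mse(y, y_hat), sum((y - y_hat)^2) / K, tolerance = 1e-12)
    expect_equal(vt_relative_error(y, y_hat),
                 100 * sum(abs(y - y_hat) / y) / K, tolerance = 1e-12)
    expect_equal(vt_mae(y, y_hat), sum(abs(y - y_hat)) / K, tolerance = 1e-12)
    expect_equal(vt_r_squared(y, y_hat),
                 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    # Jensen: mae^2 <= mse
    expect_lte(vt_mae(y, y_hat)^2, vt_mse(y, y_hat) + 1e-12)
  }
})

test_that("metrics have the expected fixed points and invariances", {
  y <- c(2, 4); y_hat <- c(3, 3)
  expect_equal(vt_mse(y, y_hat), 1.0)
  expect_equal(vt_mae(y, y_hat), 1.0)
  expect_equal(vt_relative_error(c(10, 20), c(9, 22)), 10.0)
  expect_equal(vt_mse(y, y), 0)
  expect_equal(vt_relative_error(y, y), 0)
  expect_equal(vt_r_squared(y, y), 1)
  expect_equal(vt_r_squared(y, rep(mean(y), 2)), 0)
  # permutation symmetry and RE scale invariance
  set.seed(2)
  a <- runif(9, 1, 2); b <- runif(9, 1, 2)
  expect_equal(vt_mse(rev(a), rev(b)), vt_mse(a, b))
  expect_equal(vt_relative_error(3 * a, 3 * b), vt_relative_error(a, b))
  expect_error(vt_mse(1:3, 1:4), class = "vt_contract_error")
  expect_error(vt_relative_error(c(0, 1), c(1, 1)), class = "vt_contract_error")
  expect_error(vt_r_squared(c(2, 2), c(1, 2)), class = "vt_contract_error")
})

test_that("KS comparison agrees with a hand-coded ECDF oracle", {
  set.seed(17)
  a <- rnorm(120); b <- rnorm(150, 0.4)
  got <- ks_compare(a, b)
  expect_equal(got$statistic, oracle_ks(a, b)$statistic, tolerance = 1e-12)
  expect_equal(ks_compare(a, a)$statistic, 0)
  expect_equal(ks_compare(1:50, 101:150)$statistic, 1)
  # p-value consistent with a permutation oracle within Monte-Carlo error
  set.seed(18)
  x <- rnorm(60); z <- rnorm(60, 0.5)
  perm <- oracle_ks(x, z, n_perm = 400)
  expect_lt(abs(ks_compare(x, z)$p_value - perm$p_value), 0.05)
  expect_error(ks_compare(numeric(0), a), class = "vt_contract_error")
})

test_that("KS p-values are roughly uniform under the null", {
  set.seed(19)
  p <- replicate(400, ks_compare(rnorm(40), rnorm(40))$p_value)
  # asymptotic two-sample KS is conservative at n = 40; the rejection rate
  # must sit near (below) the nominal level
  expect_lt(mean(p < 0.05), 0.08)
  expect_gt(mean(p < 0.5), 0.25)
})

test_that("model evaluation aggregates per-sequence metrics with units", {
  seqs <- lapply(1:3, function(i) tiny_sequence(seed = i, n_frames = 10))
  # an oracle predictor reproducing the ground truth is scored perfectly
  perfect <- evaluate_model(NULL, seqs, predict_fun = function(s) s$diameters)
  expect_equal(perfect$aggregate$mean[perfect$aggregate$metric == "mse"], 0)
  expect_equal(perfect$aggregate$mean[perfect$aggregate$metric == "re"], 0)
  expect_equal(perfect$aggregate$mean[perfect$aggregate$metric == "r2"], 1)
  # a single-sequence set has sd 0 and aggregate == per-sequence value
  noisy <- evaluate_model(NULL, seqs[1],
                          predict_fun = function(s) s$diameters + 0.1)
  expect_equal(noisy$aggregate$sd[noisy$aggregate$metric == "mse"], 0)
  expect_equal(noisy$aggregate$mean[noisy$aggregate$metric == "mae"],
               noisy$per_sequence$mae[1])
  expect_equal(noisy$per_sequence$mae[1], 0.1, tolerance = 1e-9)
  expect_equal(perfect$units, "pixel")
  expect_equal(evaluate_model(NULL, seqs, units = "mm",
                              predict_fun = function(s) s$diameters)$units, "mm")
  # pooled variant equals metrics on concatenated traces
  allc <- unlist(lapply(seqs, `[[`, "diameters"))
  expect_equal(noisy$pooled$value[noisy$pooled$metric == "mae"], 0.1,
               tolerance = 1e-9)
  expect_s3_class(glance(perfect), "tbl_df")
  expect_equal(glance(perfect)$n_sequences, 3)
})

test_that("model comparison reports KS on pooled absolute errors", {
  seqs <- lapply(1:2, function(i) tiny_sequence(seed = 10 + i, n_frames = 8))
  cfg <- model_config("custom", image_size = c(16L, 16L), conv_out = 2L,
                      conv_k = 3L, conv_s = 2L, conv_p = 1L, conv_pool = 2L,
                      fc_hidden = 4L)
  ma <- init_model(cfg, seed = 1)
  mb <- init_model(cfg, seed = 2)
  cmp <- compare_models(ma, mb, seqs)
  expect_named(cmp, c("metrics_a", "metrics_b", "ks"))
  expect_true(cmp$ks$statistic >= 0 && cmp$ks$statistic <= 1)
  expect_true(cmp$ks$p_value >= 0 && cmp$ks$p_value <= 1)
  # comparing a model with itself gives a zero KS distance
  self <- compare_models(ma, ma, seqs)
  expect_equal(self$ks$statistic, 0)
  expect_equal(self$ks$p_value, 1)
})
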