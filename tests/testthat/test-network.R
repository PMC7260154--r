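test_that("convolution and pooling match plain-loop oracles", {
  set.seed(11)
  cases <- list(
    list(h = 7, w = 9, cin = 2, cout = 3, k = 3, s = 2, p = 1),
    list(h = 8, w = 8, cin = 1, cout = 4, k = 5, s = 1, p = 2),
    list(h = 12, w = 10, cin = 3, cout = 2, k = 3, s = 3, p = 0),
    list(h = 6, w = 6, cin = 2, cout = 2, k = 1, s = 1, p = 0)
  )
  for (cs in cases) {
    x <- array(rnorm(cs$h * cs$w * cs$cin), c(cs$h, cs$w, cs$cin))
    Wa <- array(rnorm(cs$cout * cs$cin * cs$k^2), c(cs$cout, cs$cin, cs$k, cs$k))
    b <- rnorm(cs$cout)
    got <- vesseltrace:::cpp_conv2d(x, as_kernel_matrix(Wa), b, cs$k, cs$s, cs$p)
    want <- oracle_conv2d(x, Wa, b, cs$s, cs$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
  x <- array(rnorm(8 * 6 * 3), c(8, 6, 3))
  expect_equal(vesseltrace:::cpp_maxpool(x, 2L), oracle_maxpool(x, 2))
})

test_that("encoder presets produce the documented feature-map shapes", {
  # reduced: 64x64 -> 32 channels of 4x4
  m <- init_model(model_config("reduced"), seed = 1)
  fmap <- encode_frame(matrix(0.5, 64, 64), m)
  expect_equal(dim(fmap), c(4, 4, 32))
  expect_identical(fmap, encode_frame(matrix(0.5, 64, 64), m)) # deterministic
  # full-scale geometry: 128x128 -> 256 channels of 13x13 (small head so the
  # weight vector stays manageable; the conv chain is the preset's)
  big <- init_model(model_config("alexnet", fc_hidden = 8L), seed = 1)
  fbig <- encode_frame(matrix(0.1, 128, 128), big)
  expect_equal(dim(fbig), c(13, 13, 256))
  # the default head flattens 256*13*13 = 43264 features
  expect_equal(model_config("alexnet")$fc, c(43264L, 4096L, 1024L, 1L))
  # zero frame through zero-bias encoder stays zero (ReLU/pool preserve 0)
  mz <- m; mz$theta[] <- 0
  expect_true(all(encode_frame(matrix(0, 64, 64), mz) == 0))
  expect_error(encode_frame(matrix(0, 32, 32), m), class = "vt_contract_error")
})

test_that("C-GRU step matches a scalar-convolution oracle and fixed points", {
  set.seed(21)
  for (i in 1:5) {
    D <- sample(1:3, 1); fh <- sample(2:4, 1); fw <- sample(2:4, 1)
    x <- array(rnorm(fh * fw * D), c(fh, fw, D))
    h <- array(runif(fh * fw * D, -1, 1), c(fh, fw, D))
    p4 <- random_cgru_params(D, as_matrix = FALSE)
    got <- cgru_step(x, h, p4)
    want <- oracle_cgru_step(x, h, p4)
    expect_equal(got$h, want, tolerance = 1e-6)
  }
  # all-zero parameters: z = 0.5, tanh(0) = 0, so h' = 0.5 h
  D <- 2; fh <- 3; fw <- 3
  zp <- random_cgru_params(D); for (nm in names(zp)) zp[[nm]][] <- 0
  h0 <- array(rnorm(fh * fw * D), c(fh, fw, D))
  x0 <- array(rnorm(fh * fw * D), c(fh, fw, D))
  st <- cgru_step(x0, h0, zp)
  expect_equal(st$h, 0.5 * h0)
  expect_true(all(st$r == 0.5) && all(st$z == 0.5))
  # h = 0 is a fixed point when x cannot enter (W_x = W_xz = W_xr = 0)
  hz <- cgru_step(x0, 0 * h0, zp)
  expect_true(all(hz$h == 0))
  # large negative update-gate bias freezes the state
  fz <- zp; fz$b_z[] <- -50
  expect_equal(cgru_step(x0, h0, fz)$h, h0, tolerance = 1e-12)
})

test_that("gates stay in (0,1) and the state stays bounded in (-1,1)", {
  # weight scales kept where double precision can still represent the open
  # intervals (sigmoid saturates to exactly 1.0 beyond |x| ~ 37)
  set.seed(31)
  D <- 1; fh <- 2; fw <- 2
  h <- array(0, c(fh, fw, D))
  for (i in 1:500) {
    p <- random_cgru_params(D, sd = runif(1, 0.1, 1))
    x <- array(rnorm(fh * fw * D), c(fh, fw, D))
    st <- cgru_step(x, h, p)
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(st$z > 0 & st$z < 1))
    expect_true(all(abs(st$h) < 1))
    h <- st$h
  }
})

test_that("regression head reduces the state to one finite scalar", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 3)
  h <- array(rnorm(cfg$fh * cfg$fw * cfg$D), c(cfg$fh, cfg$fw, cfg$D))
  out <- regress_diameter(h, m)
  expect_length(out, 1)
  expect_true(is.finite(out))
  # zero state with zero biases gives exactly zero
  mz <- m; mz$theta[] <- 0
  expect_equal(regress_diameter(0 * h, mz), 0)
  # an identity-like single-layer head on a 1x1x1 state returns the state
  cfg1 <- model_config("custom", image_size = c(4L, 4L), conv_out = 1L,
                       conv_k = 3L, conv_s = 1L, conv_p = 1L, conv_pool = 4L,
                       fc_hidden = integer(0))
  m1 <- init_model(cfg1, seed = 1)
  w <- m1$spec
  m1$theta[w$offset[w$name == "fc1_W"] + 1] <- 1
  m1$theta[w$offset[w$name == "fc1_b"] + 1] <- 0
  expect_equal(regress_diameter(array(0.73, c(1, 1, 1)), m1), 0.73)
})

test_that("sequence forward pass is one chained, deterministic loop", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 8)
  set.seed(8)
  K <- 5
  frames <- array(runif(8 * 8 * K), c(8, 8, K))
  p1 <- forward_sequence(m, frames)
  expect_s3_class(p1, "tbl_df")
  expect_equal(nrow(p1), K)
  expect_equal(p1$frame, 0:(K - 1))
  expect_identical(p1, forward_sequence(m, frames))
  # streaming equivalence: composing the exported ops frame by frame with
  # carried state reproduces the fused pass elementwise
  h <- array(0, c(cfg$fh, cfg$fw, cfg$D))
  gru <- vesseltrace:::cgru_params_from_model(m)
  manual <- numeric(K)
  for (t in seq_len(K)) {
    xm <- encode_frame(frames[, , t], m)
    h <- cgru_step(xm, h, gru)$h
    manual[t] <- regress_diameter(h, m)
  }
  expect_equal(p1$diameter, manual, tolerance = 1e-12)
  # z == 0 freezes the state at h[0] = 0 so predictions are constant
  mf <- m
  sp <- mf$spec
  mf$theta[sp$offset[sp$name == "cgru_b_z"] + seq_len(cfg$D)] <- -50
  pf <- forward_sequence(mf, frames)
  expect_equal(diff(range(pf$diameter)), 0)
})

test_that("the flat parameter layout agrees between R and the compiled core", {
  for (cfg in list(tiny_model_config(), model_config("reduced"))) {
    sp <- param_spec(cfg)
    expect_equal(sum(sp$length), vesseltrace:::cpp_theta_length(unclass(cfg)))
    expect_equal(sp$offset, cumsum(c(0, sp$length[-nrow(sp)])))
  }
})
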