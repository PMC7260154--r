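test_that("parameter draws respect their distributions and truncations", {
  cfg <- sim_config()
  set.seed(101)
  p <- sample_params(cfg, 2000)
  expect_true(all(p$d0 > 0))
  expect_true(all(p$T >= 2))
  expect_true(all(p$A0 / p$d0 >= cfg$min_A_frac - 1e-12))
  expect_true(all(p$A0 / p$d0 <= cfg$max_A_frac + 1e-12))
  expect_true(all(p$alpha0 >= 0 & p$alpha0 <= 2 * pi))
  expect_true(all(p$imt0 > 0))
  # degenerate distributions collapse to their means
  dcfg <- sim_config(sigma_d = 0, sigma_T = 0, alpha_min = 0, alpha_max = 1e-12)
  pd <- sample_params(dcfg, 5)
  expect_equal(pd$d0, rep(30, 5))
  expect_equal(pd$T, rep(10, 5))
  # log-normal median of imt0 is exp(mu_imt) = 1
  expect_lt(abs(median(p$imt0) - 1), 0.1)
})

test_that("diameter series follows the sinusoid exactly when noiseless", {
  par <- list(d0 = 30, A0 = 3, T = 10, alpha0 = 0)
  d <- diameter_series(par, 12, sigma_eps = 0)
  expect_equal(d$frame, 0:11)
  expect_equal(d$diameter[1], 30)                       # sin(0) = 0
  expect_equal(d$diameter[2], 30 + 3 * sin(0.2 * pi))   # n = 1
  expect_true(all(abs(d$diameter - 30) <= 3 + 1e-12))   # sine bound
  # phase shift moves the whole curve
  par2 <- list(d0 = 30, A0 = 3, T = 10, alpha0 = pi / 2)
  expect_equal(diameter_series(par2, 1)$diameter, 33)
  expect_error(diameter_series(list(d0 = 1, A0 = 1, T = 0, alpha0 = 0), 5),
               class = "vt_param_error")
})

test_that("jittered series stays positive and within 5-sigma bounds", {
  par <- list(d0 = 3, A0 = 2.5, T = 7, alpha0 = 1)
  set.seed(7)
  for (i in 1:20) {
    d <- diameter_series(par, 200, sigma_eps = 0.1)$diameter
    expect_true(all(d > 0))
    expect_true(all(d >= par$d0 - par$A0 - 5 * 0.1))
    expect_true(all(d <= par$d0 + par$A0 + 5 * 0.1))
  }
})

test_that("wall thickness is anti-phase with the diameter", {
  par <- list(d0 = 30, A0 = 3, T = 10, alpha0 = 0, imt0 = 1)
  n <- 30  # three full periods
  d <- diameter_series(par, n, sigma_eps = 0)$diameter
  w <- imt_series(par, n)$imt
  # at frame 0 the diameter sine is 0 -> imt = 3 + imt0 = 4
  expect_equal(w[1], 4)
  # where the diameter sine is +1 the imt sine is -1: (3+1) * 0.8
  par_peak <- list(d0 = 30, A0 = 3, T = 4, alpha0 = pi / 2, imt0 = 1)
  expect_equal(imt_series(par_peak, 1)$imt, 4 * 0.8)
  expect_true(all(w >= (3 + 1) * 0.8 - 1e-12))
  expect_true(all(w <= (3 + 1) * 1.2 + 1e-12))
  expect_lt(cor(d, w), -0.99)
  # mean over whole periods recovers d0 to numerical precision
  expect_lt(abs(mean(d) - par$d0), 1e-9)
})

test_that("rendering places the three gray bands where expected", {
  cfg <- sim_config()
  f <- render_frame(30, 4, cfg)
  expect_equal(dim(f), c(128, 128))
  expect_equal(f[64, 64], 0.2)          # image center inside the lumen
  expect_equal(f[1, 1], 0.6)            # top row background
  expect_equal(f[64 - 17, 64], 0.8)     # 17 rows above center: wall band
  expect_true(all(apply(f, 2, function(col) identical(col, f[, 1]))))
  # empty vessel -> uniform background
  expect_true(all(render_frame(0, 0, cfg) == 0.6))
  # lumen-row fraction matches round(d)/H within one row
  for (d in c(11.2, 20.7, 33)) {
    frac <- mean(render_frame(d, 3, cfg) == cfg$gray_lumen)
    expect_lt(abs(frac - round(d) / 128), 1 / 128 + 1e-12)
  }
  expect_error(render_frame(100, 20, cfg), class = "vt_render_error")
})

test_that("noise model has the stated moments and clipping", {
  cfg0 <- sim_config(prop_noise_sigma = 0, noise_var = 1e-12)
  f <- matrix(0.5, 16, 16)
  out <- add_noise(f, cfg0)
  expect_equal(max(abs(out - (f + 5 / 255))), 0, tolerance = 1e-6)
  # Monte-Carlo: mean additive shift ~ noise_mu on the 0-255 scale
  set.seed(5)
  cfg <- sim_config()
  f6 <- matrix(0.6, 128, 128)
  shift <- mean(255 * add_noise(f6, cfg) - 255 * f6)
  expect_lt(abs(shift - 5), 0.5)
  out2 <- add_noise(matrix(runif(1000), 40, 25), cfg)
  expect_true(all(out2 >= 0 & out2 <= 1))
  expect_error(add_noise(matrix(2, 4, 4), cfg), class = "vt_param_error")
})

test_that("generate_sequence composes the pieces reproducibly", {
  cfg <- sim_config_desk()
  s1 <- generate_sequence(cfg, seed = 9)
  s2 <- generate_sequence(cfg, seed = 9)
  expect_identical(s1, s2)                  # bit-identical
  expect_equal(dim(s1$frames), c(64, 64, 50))
  expect_length(s1$diameters, 50)
  expect_true(all(s1$frames >= 0 & s1$frames <= 1))
  expect_true(all(s1$diameters > 0))
  expect_s3_class(tidy(s1), "tbl_df")
  expect_named(tidy(s1), c("frame", "diameter", "imt"))
  # full-scale default shape
  sf <- generate_sequence(sim_config(), seed = 3)
  expect_equal(dim(sf$frames), c(128, 128, 125))
})

test_that("dataset generation is manifest-driven and deterministic", {
  cfg <- sim_config_desk(n_frames = 8L, image_size = c(32L, 32L),
                         mu_d = 8, sigma_d = 1)
  d1 <- generate_dataset(cfg, 4, seed = 2)
  d2 <- generate_dataset(cfg, 4, seed = 2)
  expect_identical(d1$manifest, d2$manifest)
  expect_length(d1$sequences, 4)
  expect_identical(d1$sequences[[2]]$diameters, d2$sequences[[2]]$diameters)
  d3 <- generate_dataset(cfg, 1, seed = 5)
  expect_equal(nrow(d3$manifest), 1)
})
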