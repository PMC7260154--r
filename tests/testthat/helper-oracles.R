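# Independent reference implementations used as oracles. All are direct,
# loop-based evaluations kept deliberately separate from the package's code
# paths.

# plain-loop cross-correlation with zero padding; Wa indexed [cout, cin, ky, kx]
oracle_conv2d <- function(x, Wa, b, stride, pad) {
  k <- dim(Wa)[3]; cin <- dim(Wa)[2]; cout <- dim(Wa)[1]
  H <- dim(x)[1]; W <- dim(x)[2]
  ho <- (H + 2 * pad - k) %/% stride + 1
  wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  out <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) for (oy in seq_len(ho)) for (ox in seq_len(wo)) {
    acc <- b[co]
    for (ci in seq_len(cin))
      acc <- acc + sum(xp[(oy - 1) * stride + 1:k, (ox - 1) * stride + 1:k, ci] *
                         Wa[co, ci, , ])
    out[oy, ox, co] <- acc
  }
  out
}

oracle_maxpool <- function(x, p) {
  ho <- dim(x)[1] %/% p; wo <- dim(x)[2] %/% p
  out <- array(0, c(ho, wo, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) for (oy in seq_len(ho)) for (ox in seq_len(wo))
    out[oy, ox, c] <- max(x[(oy - 1) * p + 1:p, (ox - 1) * p + 1:p, c])
  out
}

# scalar-by-scalar C-GRU step built only on oracle_conv2d and base math
oracle_cgru_step <- function(x, h, pars4d) {
  sig <- function(a) 1 / (1 + exp(-a))
  cv <- function(Wa, inp, b) oracle_conv2d(inp, Wa, b, stride = 1, pad = 1)
  r <- sig(cv(pars4d$W_hr, h, pars4d$b_r) + cv(pars4d$W_xr, x, rep(0, dim(x)[3])))
  z <- sig(cv(pars4d$W_hz, h, pars4d$b_z) + cv(pars4d$W_xz, x, rep(0, dim(x)[3])))
  cand <- tanh(cv(pars4d$W_h, r * h, pars4d$b) + cv(pars4d$W_x, x, rep(0, dim(x)[3])))
  (1 - z) * h + z * cand
}

random_cgru_params <- function(D, as_matrix = TRUE, sd = 0.3) {
  a <- function() array(rnorm(D * D * 3 * 3, 0, sd), c(D, D, 3, 3))
  p <- list(W_hr = a(), W_xr = a(), W_hz = a(), W_xz = a(), W_h = a(), W_x = a(),
            b_r = rnorm(D, 0, sd), b_z = rnorm(D, 0, sd), b = rnorm(D, 0, sd))
  if (as_matrix)
    for (nm in c("W_hr", "W_xr", "W_hz", "W_xz", "W_h", "W_x"))
      p[[nm]] <- as_kernel_matrix(p[[nm]])
  p
}

# brute-force CyclicLoss: enumerate the printed double sum, skipping
# out-of-range pairs (0-based indices)
oracle_cyclic_loss <- function(y_hat, T_period, n_cycles) {
  s <- 0
  K <- length(y_hat)
  if (T_period >= 1 && n_cycles >= 1) {
    for (n in 0:(n_cycles - 1)) for (t in 0:T_period) {
      a <- t + n * T_period; b <- t + (n + 1) * T_period
      if (b <= K - 1) s <- s + (y_hat[b + 1] - y_hat[a + 1])^2
    }
  }
  sqrt(s)
}

# dominant-lag autocorrelation period estimate (independent of peak picking)
oracle_period_autocor <- function(y, max_lag = floor(length(y) / 2)) {
  ac <- stats::acf(y, lag.max = max_lag, plot = FALSE)$acf[-1]
  cand <- which(diff(sign(diff(ac))) == -2) + 1  # local maxima of acf
  if (length(cand) == 0) return(NA_integer_)
  cand[which.max(ac[cand])]
}

# two-sample KS statistic and permutation p-value, hand-coded
oracle_ks <- function(a, b, n_perm = 0) {
  pooled <- sort(unique(c(a, b)))
  fa <- ecdf(a)(pooled); fb <- ecdf(b)(pooled)
  stat <- max(abs(fa - fb))
  out <- list(statistic = stat)
  if (n_perm > 0) {
    all <- c(a, b); na <- length(a)
    cnt <- 0
    for (i in seq_len(n_perm)) {
      idx <- sample(length(all), na)
      s <- {
        pa <- all[idx]; pb <- all[-idx]
        g <- sort(unique(all))
        max(abs(ecdf(pa)(g) - ecdf(pb)(g)))
      }
      if (s >= stat - 1e-12) cnt <- cnt + 1
    }
    out$p_value <- (cnt + 1) / (n_perm + 1)
  }
  out
}

# small shared fixtures -----------------------------------------------------

tiny_model_config <- function() {
  model_config("custom", image_size = c(8L, 8L), conv_out = 2L, conv_k = 3L,
               conv_s = 2L, conv_p = 1L, conv_pool = 2L, fc_hidden = 4L)
}

tiny_sequence <- function(seed = 1, n_frames = 6, size = 16, ...) {
  generate_sequence(sim_config_desk(image_size = c(size, size),
                                    n_frames = n_frames,
                                    mu_d = size / 4, sigma_d = size / 20, ...),
                    seed = seed)
}
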