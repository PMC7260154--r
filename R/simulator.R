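# Synthetic ultrasound sequence simulator: a horizontal vessel spanning the
# image, lumen diameter following a jittered sinusoid, wall thickness (IMT)
# following an anti-phase sinusoid, rendered at three gray levels and
# corrupted by additive and intensity-proportional noise.

#' Simulation configuration
#'
#' Parameters controlling the synthetic pulsatile-vessel sequence generator.
#' Defaults are the reference simulation conditions: lumen diameter
#' `d0 ~ N(mu_d, sigma_d)` (pixels), pulsation amplitude
#' `A0 ~ U(0.05 d0, 0.35 d0)`, cardiac period `T ~ N(mu_T, sigma_T)`
#' (frames), phase `alpha0 ~ U(0, 2*pi)`, per-frame diameter jitter
#' `N(0, sigma_eps)`, and wall-amplitude parameter
#' `imt0 ~ logNormal(mu_imt, sigma_imt)`. Gray levels are on the unit scale;
#' the additive noise moments (`noise_mu`, `noise_var`) are on the 0-255
#' intensity scale.
#'
#' @param mu_d,sigma_d Mean and sd of the mean lumen diameter, in pixels.
#' @param min_A_frac,max_A_frac Amplitude bounds as fractions of `d0`.
#' @param mu_T,sigma_T Mean and sd of the cardiac period, in frames.
#' @param alpha_min,alpha_max Uniform bounds of the phase, radians.
#' @param sigma_eps Sd of the per-frame diameter jitter, pixels.
#' @param mu_imt,sigma_imt Log-normal parameters of `imt0`, pixels.
#' @param gray_lumen,gray_wall,gray_background Mean gray levels in `[0, 1]`.
#' @param noise_mu,noise_var Additive Gaussian noise mean and variance on the
#'   0-255 scale.
#' @param prop_noise_sigma Sd of the per-pixel multiplicative (intensity
#'   proportional, speckle-like) noise factor.
#' @param n_frames Frames per sequence.
#' @param image_size Integer vector `c(height, width)`.
#' @param seed Optional integer seed recorded with generated data.
#' @return A `vt_sim_config` list.
#' @examples
#' cfg <- sim_config(n_frames = 10, image_size = c(64, 64), mu_d = 15, sigma_d = 3)
#' @export
sim_config <- function(mu_d = 30, sigma_d = 6,
                       min_A_frac = 0.05, max_A_frac = 0.35,
                       mu_T = 10, sigma_T = 3,
                       alpha_min = 0, alpha_max = 2 * pi,
                       sigma_eps = 0.1,
                       mu_imt = 0, sigma_imt = 0.6,
                       gray_lumen = 0.2, gray_wall = 0.8, gray_background = 0.6,
                       noise_mu = 5, noise_var = 2,
                       prop_noise_sigma = 0.05,
                       n_frames = 125L, image_size = c(128L, 128L),
                       seed = NULL) {
  cfg <- list(
    mu_d = mu_d, sigma_d = sigma_d,
    min_A_frac = min_A_frac, max_A_frac = max_A_frac,
    mu_T = mu_T, sigma_T = sigma_T,
    alpha_min = alpha_min, alpha_max = alpha_max,
    sigma_eps = sigma_eps, mu_imt = mu_imt, sigma_imt = sigma_imt,
    gray_lumen = gray_lumen, gray_wall = gray_wall,
    gray_background = gray_background,
    noise_mu = noise_mu, noise_var = noise_var,
    prop_noise_sigma = prop_noise_sigma,
    n_frames = as.integer(n_frames),
    image_size = as.integer(image_size), seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "vt_sim_config")
}

validate_sim_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), c("seed", "image_size", "n_frames"))]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    abort("all simulation parameters must be finite scalars", class = "vt_config_error")
  with(cfg, {
    if (!(min_A_frac > 0 && min_A_frac < max_A_frac && max_A_frac < 1))
      abort("need 0 < min_A_frac < max_A_frac < 1", class = "vt_config_error")
    if (!(alpha_min < alpha_max))
      abort("need alpha_min < alpha_max", class = "vt_config_error")
    if (sigma_d < 0 || sigma_T < 0 || sigma_eps < 0 || sigma_imt < 0 ||
        noise_var < 0 || prop_noise_sigma < 0)
      abort("standard deviations must be >= 0", class = "vt_config_error")
    if (any(c(gray_lumen, gray_wall, gray_background) < 0) ||
        any(c(gray_lumen, gray_wall, gray_background) > 1))
      abort("gray levels must lie in [0, 1]", class = "vt_config_error")
    if (n_frames < 1) abort("n_frames must be >= 1", class = "vt_config_error")
    if (length(image_size) != 2 || any(image_size < 4))
      abort("image_size must be two integers >= 4", class = "vt_config_error")
  })
  invisible(cfg)
}

#' Desk-scale simulation preset
#'
#' The reduced-scale study conditions: 64x64 frames, 50 frames per sequence,
#' vessel geometry halved with the image (`mu_d = 15`, `sigma_d = 3`) so the
#' vessel occupies the same fraction of the field of view; all dynamics and
#' noise settings unchanged.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `vt_sim_config`.
#' @export
sim_config_desk <- function(...) {
  args <- utils::modifyList(
    list(mu_d = 15, sigma_d = 3, n_frames = 50L, image_size = c(64L, 64L)),
    list(...))
  do.call(sim_config, args)
}

#' Draw simulation parameters for one or more sequences
#'
#' Samples `(d0, A0, T, alpha0, imt0)` from the distributions in `config`.
#' `d0` is redrawn until positive and `T` until at least 2 frames (truncated
#' normals); `A0` is uniform on `[min_A_frac * d0, max_A_frac * d0]`.
#' Uses the current R random number generator state; call `set.seed()` first
#' for reproducibility.
#'
#' @param config A [sim_config()] object.
#' @param n Number of independent draws.
#' @return A tibble with `n` rows and columns `d0`, `A0`, `T`, `alpha0`, `imt0`.
#' @examples
#' set.seed(1)
#' sample_params(sim_config(), n = 3)
#' @export
sample_params <- function(config = sim_config(), n = 1) {
  validate_sim_config(config)
  d0 <- rtruncnorm_pos(n, config$mu_d, config$sigma_d, lower = 0)
  T_ <- rtruncnorm_pos(n, config$mu_T, config$sigma_T, lower = 2)
  A0 <- runif(n, config$min_A_frac * d0, config$max_A_frac * d0)
  alpha0 <- runif(n, config$alpha_min, config$alpha_max)
  imt0 <- rlnorm(n, config$mu_imt, config$sigma_imt)
  tibble(d0 = d0, A0 = A0, T = T_, alpha0 = alpha0, imt0 = imt0)
}

# normal draw redrawn until value > lower (strictly above for lower = 0,
# inclusive at 2 for the period); sigma = 0 collapses to the mean
rtruncnorm_pos <- function(n, mu, sigma, lower) {
  if (sigma == 0) {
    if (mu < lower) abort("degenerate distribution below truncation bound",
                          class = "vt_config_error")
    return(rep(mu, n))
  }
  x <- rnorm(n, mu, sigma)
  bad <- which(x < lower | (lower == 0 & x == 0))
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[x[bad] < lower | (lower == 0 & x[bad] == 0)]
  }
  x
}

#' Ground-truth diameter series
#'
#' Evaluates `d[n] = d0 + A0 * sin(2*pi*n/T + alpha0) + eps[n]` for frame
#' indices `n = 0, ..., n_frames - 1`, with `eps[n] ~ N(0, sigma_eps)`.
#' Values are clamped to stay strictly positive.
#'
#' @param params One-row tibble or list with `d0`, `A0`, `T`, `alpha0`.
#' @param n_frames Number of frames.
#' @param sigma_eps Jitter sd in pixels (0 for a noiseless trace).
#' @return A tibble with columns `frame` (0-based) and `diameter` (pixels).
#' @examples
#' diameter_series(list(d0 = 30, A0 = 3, T = 10, alpha0 = 0), 5, sigma_eps = 0)
#' @export
diameter_series <- function(params, n_frames, sigma_eps = 0) {
  if (params$T <= 0) abort("period T must be positive", class = "vt_param_error")
  if (n_frames < 1) abort("n_frames must be >= 1", class = "vt_param_error")
  n <- seq_len(n_frames) - 1
  d <- params$d0 + params$A0 * sin(2 * pi * n / params$T + params$alpha0)
  if (sigma_eps > 0) d <- d + rnorm(n_frames, 0, sigma_eps)
  tibble(frame = as.integer(n), diameter = pmax(d, 1e-6))
}

#' Ground-truth wall-thickness (IMT) series
#'
#' Evaluates `imt[n] = (3 + imt0) * (1 + 0.2 * sin(2*pi*n/T + alpha0 + pi))`,
#' a sinusoid in exact anti-phase with the diameter: the walls are thinnest
#' when the lumen is widest.
#'
#' @inheritParams diameter_series
#' @param params One-row tibble or list with `T`, `alpha0`, `imt0`.
#' @return A tibble with columns `frame` and `imt` (pixels).
#' @export
imt_series <- function(params, n_frames) {
  if (params$T <= 0) abort("period T must be positive", class = "vt_param_error")
  n <- seq_len(n_frames) - 1
  imt <- (3 + params$imt0) *
    (1 + 0.2 * sin(2 * pi * n / params$T + params$alpha0 + pi))
  tibble(frame = as.integer(n), imt = imt)
}

#' Render one noiseless frame
#'
#' Draws a horizontal vessel spanning the full image width, vertically
#' centered: a lumen band of height `round(diameter)` at `gray_lumen`, wall
#' bands of height `round(imt)` immediately above and below at `gray_wall`,
#' background elsewhere. Band heights are rounded to whole rows; the
#' ground-truth trace keeps sub-pixel values.
#'
#' @param diameter Lumen diameter in pixels.
#' @param imt Wall thickness in pixels.
#' @param config A [sim_config()] (gray levels and image size).
#' @return An `height x width` matrix of intensities in `[0, 1]`.
#' @export
render_frame <- function(diameter, imt, config = sim_config()) {
  h <- config$image_size[1]; w <- config$image_size[2]
  hd <- round(diameter); hw <- round(imt)
  if (hd + 2 * hw > h)
    abort(sprintf("vessel (%d + 2x%d rows) taller than image (%d rows)",
                  hd, hw, h), class = "vt_render_error")
  frame <- matrix(config$gray_background, h, w)
  top <- floor((h - hd) / 2) + 1          # first lumen row
  if (hd > 0) frame[top:(top + hd - 1), ] <- config$gray_lumen
  if (hw > 0) {
    above <- (top - hw):(top - 1)
    below <- (top + hd):(top + hd + hw - 1)
    frame[above[above >= 1], ] <- config$gray_wall
    frame[below[below <= h], ] <- config$gray_wall
  }
  frame
}

#' Add acquisition-like noise to a frame
#'
#' Scales the frame to the 0-255 intensity range, applies per-pixel
#' multiplicative noise `(1 + eta)`, `eta ~ N(0, prop_noise_sigma)`
#' (speckle-like, intensity proportional), adds per-pixel
#' `N(noise_mu, sqrt(noise_var))`, then clips to `[0, 255]` and rescales to
#' `[0, 1]`.
#'
#' @param frame Matrix of intensities in `[0, 1]`.
#' @param config A [sim_config()].
#' @return Matrix of the same shape, intensities in `[0, 1]`.
#' @export
add_noise <- function(frame, config = sim_config()) {
  if (min(frame) < 0 || max(frame) > 1)
    abort("frame intensities must lie in [0, 1]", class = "vt_param_error")
  x <- frame * 255
  n <- length(x)
  if (config$prop_noise_sigma > 0)
    x <- x * (1 + rnorm(n, 0, config$prop_noise_sigma))
  x <- x + rnorm(n, config$noise_mu, sqrt(config$noise_var))
  matrix(pmin(pmax(x, 0), 255) / 255, nrow(frame), ncol(frame))
}

#' Generate one synthetic ultrasound sequence
#'
#' Composes [sample_params()], [diameter_series()], [imt_series()],
#' [render_frame()] and [add_noise()] into a labeled sequence. Parameter
#' draws whose maximal vertical extent cannot fit the image are redrawn (a
#' physical-plausibility guard; the redraw count is recorded).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed making the sequence fully reproducible; defaults
#'   to `config$seed` (an unseeded draw otherwise).
#' @return A `vt_sequence`: list with `frames` (`H x W x K` array in
#'   `[0, 1]`), `diameters` (length `K`, pixels, sub-pixel exact),
#'   `imt` (length `K`), `params` (one-row tibble), `units`,
#'   `pixel_spacing`, `seed`.
#' @examples
#' s <- generate_sequence(sim_config(n_frames = 5, image_size = c(64, 64),
#'                                   mu_d = 15, sigma_d = 3), seed = 1)
#' dim(s$frames)
#' @export
generate_sequence <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  h <- config$image_size[1]
  for (try in seq_len(100)) {
    params <- sample_params(config, 1)
    extent <- params$d0 + params$A0 + 5 * config$sigma_eps +
      2 * 1.2 * (3 + params$imt0)
    if (extent < h) break
    if (try == 100)
      abort("could not draw a vessel fitting the image in 100 tries",
            class = "vt_render_error")
  }
  d <- diameter_series(params, config$n_frames, config$sigma_eps)$diameter
  imt <- imt_series(params, config$n_frames)$imt
  frames <- array(0, c(h, config$image_size[2], config$n_frames))
  for (t in seq_len(config$n_frames)) {
    frames[, , t] <- add_noise(render_frame(d[t], imt[t], config), config)
  }
  new_vt_sequence(frames, d, imt,
                  params = params, units = "pixel",
                  pixel_spacing = "pixel-native", seed = seed)
}

new_vt_sequence <- function(frames, diameters, imt = NULL, params = NULL,
                            units = "pixel", pixel_spacing = "pixel-native",
                            seed = NULL) {
  stopifnot(length(dim(frames)) == 3,
            dim(frames)[3] == length(diameters),
            all(diameters > 0))
  structure(list(frames = frames, diameters = diameters, imt = imt,
                 params = params, units = units,
                 pixel_spacing = pixel_spacing, seed = seed),
            class = "vt_sequence")
}

#' @export
print.vt_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vt_sequence> %d frames of %dx%d, diameters %.2f-%.2f %s\n",
              d[3], d[1], d[2], min(x$diameters), max(x$diameters), x$units))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vt_sequence <- function(x, ...) {
  out <- tibble(frame = seq_along(x$diameters) - 1L, diameter = x$diameters)
  if (!is.null(x$imt)) out$imt <- x$imt
  out
}

#' Generate a dataset of synthetic sequences
#'
#' Draws `n_sequences` independent sequences, each from its own seed derived
#' reproducibly from `seed`. If `dir` is given, sequences are written with
#' [save_sequence()] and only the manifest is returned; otherwise the
#' sequences are kept in memory.
#'
#' @param config A [sim_config()].
#' @param n_sequences Number of sequences.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return A list with `sequences` (list of `vt_sequence`, or `NULL` when
#'   written to disk) and `manifest` (tibble: `sequence_id`, `seed`,
#'   `n_frames`, `units`, and `path` when on disk).
#' @export
generate_dataset <- function(config = sim_config(), n_sequences, seed = 1,
                             dir = NULL) {
  stopifnot(n_sequences >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sequences)
  ids <- sprintf("seq_%04d", seq_len(n_sequences))
  manifest <- tibble(sequence_id = ids, seed = seeds,
                     n_frames = config$n_frames, units = "pixel")
  if (is.null(dir)) {
    seqs <- purrr::map(seeds, function(s) generate_sequence(config, seed = s))
    names(seqs) <- ids
    return(list(sequences = seqs, manifest = manifest))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_sequences)
  for (i in seq_len(n_sequences)) {
    s <- generate_sequence(config, seed = seeds[i])
    paths[i] <- save_sequence(s, file.path(dir, ids[i]))
  }
  manifest$path <- paths
  write_manifest(manifest, config, seed, dir)
  list(sequences = NULL, manifest = manifest)
}
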