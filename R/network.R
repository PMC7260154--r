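# Estimation architecture: per-frame convolutional encoder -> convolutional
# GRU -> fully connected head emitting one diameter per frame. All weights
# live in one flat parameter vector walked in a fixed canonical order shared
# with the compiled core (conv layers (W, b); C-GRU W_hr, W_xr, W_hz, W_xz,
# W_h, W_x, b_r, b_z, b; FC layers (W, b)). Conv kernel banks are stored as
# C_out x (C_in*k*k) matrices with column index c_in*k^2 + ky*k + kx
# (0-based, ky = row offset).

#' Model configuration
#'
#' Describes the encoder geometry, the C-GRU width and the fully connected
#' head. Two presets are provided: `"alexnet"`, the full-scale five-layer
#' encoder (kernels 11/5/3/3/3) producing `256 x 13 x 13` feature maps from
#' `128 x 128` frames, and `"reduced"`, a three-layer desk-scale encoder
#' (kernels 11/5/3, 32 channels) producing `32 x 4 x 4` maps from `64 x 64`
#' frames. The C-GRU always uses `3 x 3` kernels with stride 1 and zero
#' "same" padding so the state keeps the feature-map shape.
#'
#' @param encoder `"alexnet"`, `"reduced"`, or `"custom"` (then supply the
#'   `conv_*` vectors).
#' @param image_size `c(height, width)` of input frames.
#' @param conv_out,conv_k,conv_s,conv_p,conv_pool Per-layer output channels,
#'   kernel size, stride, zero padding, and post-ReLU max-pool size (0 or 1
#'   for none; pools are non-overlapping).
#' @param fc_hidden Widths of the hidden fully connected layers (the input
#'   width is the flattened state, the output is always 1).
#' @return A `vt_model_config` list, including the derived feature-map shape
#'   `D x fh x fw`.
#' @examples
#' cfg <- model_config("reduced")
#' c(cfg$D, cfg$fh, cfg$fw)
#' @export
model_config <- function(encoder = c("alexnet", "reduced", "custom"),
                         image_size = NULL,
                         conv_out = NULL, conv_k = NULL, conv_s = NULL,
                         conv_p = NULL, conv_pool = NULL,
                         fc_hidden = NULL) {
  encoder <- match.arg(encoder)
  if (encoder == "alexnet") {
    image_size <- image_size %||% c(128L, 128L)
    conv_out <- conv_out %||% c(64L, 192L, 384L, 256L, 256L)
    conv_k <- conv_k %||% c(11L, 5L, 3L, 3L, 3L)
    conv_s <- conv_s %||% c(2L, 1L, 1L, 1L, 1L)
    conv_p <- conv_p %||% c(1L, 2L, 1L, 1L, 0L)
    conv_pool <- conv_pool %||% c(2L, 2L, 0L, 0L, 0L)
    fc_hidden <- fc_hidden %||% c(4096L, 1024L)
  } else if (encoder == "reduced") {
    image_size <- image_size %||% c(64L, 64L)
    conv_out <- conv_out %||% c(32L, 32L, 32L)
    conv_k <- conv_k %||% c(11L, 5L, 3L)
    conv_s <- conv_s %||% c(4L, 2L, 1L)
    conv_p <- conv_p %||% c(5L, 2L, 1L)
    conv_pool <- conv_pool %||% c(2L, 0L, 0L)
    fc_hidden <- fc_hidden %||% c(64L)
  } else {
    if (is.null(image_size) || is.null(conv_out) || is.null(conv_k) ||
        is.null(conv_s) || is.null(conv_p) || is.null(conv_pool))
      abort("custom encoder needs image_size and all conv_* vectors",
            class = "vt_config_error")
    fc_hidden <- fc_hidden %||% c(64L)
  }
  nl <- length(conv_out)
  stopifnot(length(conv_k) == nl, length(conv_s) == nl,
            length(conv_p) == nl, length(conv_pool) == nl)
  # derive spatial chain (must mirror the compiled core exactly)
  h <- image_size[1]; w <- image_size[2]
  for (i in seq_len(nl)) {
    h <- (h + 2 * conv_p[i] - conv_k[i]) %/% conv_s[i] + 1
    w <- (w + 2 * conv_p[i] - conv_k[i]) %/% conv_s[i] + 1
    if (h < 1 || w < 1) abort("encoder collapses the image", class = "vt_config_error")
    if (conv_pool[i] > 1) {
      if (h %% conv_pool[i] != 0 || w %% conv_pool[i] != 0)
        abort(sprintf("pool %d does not divide %dx%d at layer %d",
                      conv_pool[i], h, w, i), class = "vt_config_error")
      h <- h %/% conv_pool[i]; w <- w %/% conv_pool[i]
    }
  }
  D <- conv_out[nl]
  cfg <- list(encoder = encoder,
              in_h = as.integer(image_size[1]), in_w = as.integer(image_size[2]),
              conv_out = as.integer(conv_out), conv_k = as.integer(conv_k),
              conv_s = as.integer(conv_s), conv_p = as.integer(conv_p),
              conv_pool = as.integer(conv_pool),
              D = as.integer(D), fh = as.integer(h), fw = as.integer(w),
              fc = as.integer(c(D * h * w, fc_hidden, 1L)))
  structure(cfg, class = "vt_model_config")
}

#' Parameter layout of a model configuration
#'
#' The canonical tensor-by-tensor layout of the flat parameter vector, shared
#' with the compiled core. Useful for inspecting or unpacking weights.
#'
#' @param config A [model_config()].
#' @return Tibble with `name`, `dims` (list column), `offset` (0-based) and
#'   `length`.
#' @export
param_spec <- function(config) {
  rows <- list()
  add <- function(name, dims) rows[[length(rows) + 1]] <<- list(name = name, dims = dims)
  cin <- 1L
  for (i in seq_along(config$conv_out)) {
    k <- config$conv_k[i]; cout <- config$conv_out[i]
    add(paste0("conv", i, "_W"), c(cout, cin * k * k))
    add(paste0("conv", i, "_b"), cout)
    cin <- cout
  }
  D <- config$D
  for (nm in c("W_hr", "W_xr", "W_hz", "W_xz", "W_h", "W_x"))
    add(paste0("cgru_", nm), c(D, D * 9L))
  for (nm in c("b_r", "b_z", "b")) add(paste0("cgru_", nm), D)
  widths <- config$fc
  for (j in seq_len(length(widths) - 1)) {
    add(paste0("fc", j, "_W"), c(widths[j + 1], widths[j]))
    add(paste0("fc", j, "_b"), widths[j + 1])
  }
  lens <- vapply(rows, function(r) prod(r$dims), 0)
  tibble(name = vapply(rows, `[[`, "", "name"),
         dims = lapply(rows, `[[`, "dims"),
         offset = cumsum(c(0, lens[-length(lens)])),
         length = lens)
}

#' Initialize a model
#'
#' Allocates and randomly initializes all weights of the encoder, C-GRU and
#' head. Convolution and hidden FC weights use He scaling
#' (`sd = sqrt(2/fan_in)`); C-GRU kernels use a conservative
#' `sd = sqrt(1/(2 * 9 * D))`; the output layer uses `sd = sqrt(1/fan_in)`.
#' Biases start at zero and the hidden state starts as the zero map.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the draw.
#' @return A `vt_model` with elements `config`, `theta` (flat parameter
#'   vector), `spec` ([param_spec()]), and `normalization` (`center`,
#'   `scale` applied to diameters during training; identity until trained).
#' @examples
#' m <- init_model(model_config("reduced"), seed = 1)
#' length(m$theta)
#' @export
init_model <- function(config = model_config(), seed = 1) {
  spec <- param_spec(config)
  n <- sum(spec$length)
  stopifnot(n == cpp_theta_length(unclass(config)))
  set.seed(seed)
  theta <- numeric(n)
  nfc <- length(config$fc) - 1
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]; len <- spec$length[i]; dims <- spec$dims[[i]]
    idx <- spec$offset[i] + seq_len(len)
    if (grepl("_b$|_b_r$|_b_z$", nm) || grepl("cgru_b", nm)) next  # biases stay 0
    if (grepl("^conv", nm)) {
      theta[idx] <- rnorm(len, 0, sqrt(2 / dims[2]))
    } else if (grepl("^cgru_W", nm)) {
      theta[idx] <- rnorm(len, 0, sqrt(1 / (2 * dims[2])))
    } else if (grepl("^fc", nm)) {
      last <- grepl(paste0("^fc", nfc, "_W"), nm)
      theta[idx] <- rnorm(len, 0, sqrt((if (last) 1 else 2) / dims[2]))
    }
  }
  structure(list(config = config, spec = spec, theta = theta,
                 normalization = list(center = 0, scale = 1),
                 meta = list(seed = seed)),
            class = "vt_model")
}

#' @export
print.vt_model <- function(x, ...) {
  cat(sprintf("<vt_model> %s encoder, %dx%d input, state %dx%dx%d, %d parameters\n",
              x$config$encoder, x$config$in_h, x$config$in_w,
              x$config$fh, x$config$fw, x$config$D, length(x$theta)))
  invisible(x)
}

#' Unpack the flat parameter vector into named tensors
#'
#' @param model A `vt_model`.
#' @return Named list of matrices/vectors following [param_spec()].
#' @export
vt_weights <- function(model) {
  out <- purrr::pmap(model$spec, function(name, dims, offset, length) {
    v <- model$theta[offset + seq_len(length)]
    if (base::length(dims) == 2) matrix(v, dims[1], dims[2]) else v
  })
  names(out) <- model$spec$name
  out
}

#' Convert a 4-D kernel array to the packed kernel matrix
#'
#' Kernel banks are stored as `C_out x (C_in*k*k)` matrices; this helper
#' packs an array indexed `[c_out, c_in, ky, kx]` into that layout.
#'
#' @param a Numeric array `c_out x c_in x k x k`.
#' @return Matrix `c_out x (c_in*k*k)`.
#' @export
as_kernel_matrix <- function(a) {
  stopifnot(length(dim(a)) == 4, dim(a)[3] == dim(a)[4])
  co <- dim(a)[1]; ci <- dim(a)[2]; k <- dim(a)[3]
  m <- matrix(0, co, ci * k * k)
  for (c_in in seq_len(ci))
    for (ky in seq_len(k))
      for (kx in seq_len(k))
        m[, (c_in - 1) * k * k + (ky - 1) * k + kx] <- a[, c_in, ky, kx]
  m
}

#' Encode one frame into feature maps
#'
#' Runs the convolutional encoder (conv + ReLU + optional max-pool per
#' layer) on a single frame.
#'
#' @param frame `H x W` matrix of intensities.
#' @param model A `vt_model`.
#' @return Array `fh x fw x D` of feature maps.
#' @examples
#' m <- init_model(model_config("reduced"), seed = 1)
#' dim(encode_frame(matrix(0, 64, 64), m))
#' @export
encode_frame <- function(frame, model) {
  cfg <- model$config
  if (!all(dim(frame) == c(cfg$in_h, cfg$in_w)))
    abort(sprintf("frame is %dx%d but the encoder expects %dx%d",
                  nrow(frame), ncol(frame), cfg$in_h, cfg$in_w),
          class = "vt_contract_error")
  w <- vt_weights(model)
  x <- array(frame, c(dim(frame), 1))
  for (i in seq_along(cfg$conv_out)) {
    x <- cpp_conv2d(x, w[[paste0("conv", i, "_W")]], w[[paste0("conv", i, "_b")]],
                    cfg$conv_k[i], cfg$conv_s[i], cfg$conv_p[i])
    x <- pmax(x, 0)
    if (cfg$conv_pool[i] > 1) x <- cpp_maxpool(x, cfg$conv_pool[i])
  }
  x
}

#' One step of the convolutional GRU
#'
#' Computes the reset gate `sigmoid(W_hr*h + W_xr*x + b_r)`, the update gate
#' `z = sigmoid(W_hz*h + W_xz*x + b_z)` and the new state
#' `(1 - z) (.) h + z (.) tanh(W_h*(r (.) h) + W_x*x + b)`, where `*` is
#' "same"-padded 3x3 convolution and `(.)` the elementwise product.
#'
#' @param x Feature-map array `fh x fw x D`.
#' @param h Previous state, same shape as `x`.
#' @param params Named list with kernel matrices `W_hr`, `W_xr`, `W_hz`,
#'   `W_xz`, `W_h`, `W_x` (each `D x (D*9)`, or `D x D x 3 x 3` arrays) and
#'   bias vectors `b_r`, `b_z`, `b` (length `D`).
#' @return List with the new state `h` and the gate maps `r`, `z`.
#' @export
cgru_step <- function(x, h, params) {
  km <- function(m) if (is.matrix(m)) m else as_kernel_matrix(m)
  cpp_cgru_step(x, h,
                km(params$W_hr), km(params$W_xr),
                km(params$W_hz), km(params$W_xz),
                km(params$W_h), km(params$W_x),
                params$b_r, params$b_z, params$b)
}

cgru_params_from_model <- function(model) {
  w <- vt_weights(model)
  list(W_hr = w$cgru_W_hr, W_xr = w$cgru_W_xr, W_hz = w$cgru_W_hz,
       W_xz = w$cgru_W_xz, W_h = w$cgru_W_h, W_x = w$cgru_W_x,
       b_r = w$cgru_b_r, b_z = w$cgru_b_z, b = w$cgru_b)
}

#' Regress a diameter from a C-GRU state
#'
#' Flattens the state and applies the fully connected head (ReLU between
#' hidden layers, linear output). The value is on the model's normalized
#' scale; [forward_sequence()] applies the stored denormalization.
#'
#' @param h State array `fh x fw x D`.
#' @param model A `vt_model`.
#' @return A single finite scalar.
#' @export
regress_diameter <- function(h, model) {
  w <- vt_weights(model)
  a <- as.vector(h)
  nfc <- length(model$config$fc) - 1
  for (j in seq_len(nfc)) {
    a <- w[[paste0("fc", j, "_W")]] %*% a + w[[paste0("fc", j, "_b")]]
    if (j < nfc) a <- pmax(a, 0)
  }
  out <- as.numeric(a)
  if (!is.finite(out))
    abort("non-finite activation in regression head", class = "vt_numeric_error")
  out
}

#' Predict a diameter trace for a sequence
#'
#' Runs the full chain (encode, C-GRU step, regression head) over the
#' frames of a sequence in one pass, carrying the recurrent state, with
#' `h[0] = 0`. Predictions are mapped back to data units via the model's
#' stored normalization.
#'
#' @param model A `vt_model` (or `vt_fit`).
#' @param x A `vt_sequence` or an `H x W x K` array of frames.
#' @return Tibble with columns `frame` (0-based) and `diameter`.
#' @export
forward_sequence <- function(model, x) {
  if (inherits(model, "vt_fit")) model <- model$model
  frames <- if (inherits(x, "vt_sequence")) x$frames else x
  stopifnot(length(dim(frames)) == 3)
  raw <- cpp_seq_forward(frames, model$theta, unclass(model$config))
  tibble(frame = seq_along(raw) - 1L,
         diameter = raw * model$normalization$scale + model$normalization$center)
}

#' @rdname forward_sequence
#' @param object A `vt_model`.
#' @param ... Unused.
#' @export
predict.vt_model <- function(object, x, ...) forward_sequence(object, x)
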