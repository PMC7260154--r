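# Training loop: sequence-level Adam steps on the combined loss, per-epoch
# validation, random flip augmentation, model selection by validation MSE.

#' Training configuration
#'
#' @param learning_rate Adam step size (reference value `1e-4`; the
#'   desk-scale preset in [train_config_desk()] uses `1e-3`).
#' @param epochs Number of passes over the training set.
#' @param lambda CyclicLoss weight (reference value `1e-6`).
#' @param augment Apply random vertical/horizontal flips per iteration.
#' @param seed Master seed for shuffling, augmentation and initialization.
#' @param beta1,beta2,eps Adam moment parameters (conventional defaults).
#' @param clip_norm Global gradient-norm clip; `Inf` disables.
#' @param normalize Standardize diameter targets by the training-set mean/sd
#'   (stored in the model and inverted at prediction).
#' @param min_prominence Peak-detector prominence override for the
#'   per-sequence period estimation (`NULL` = detector default).
#' @param verbose Print per-epoch progress.
#' @return A `vt_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L, lambda = 1e-6,
                         augment = TRUE, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         clip_norm = Inf, normalize = TRUE,
                         min_prominence = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 1, lambda >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 lambda = lambda, augment = augment, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 clip_norm = clip_norm, normalize = normalize,
                 min_prominence = min_prominence, verbose = verbose),
            class = "vt_train_config")
}

#' Desk-scale training preset
#'
#' The configuration used for the reduced-scale study (64x64 frames, 3-layer
#' encoder): 20 epochs at learning rate `1e-3`, otherwise as [train_config()].
#'
#' @param ... Overrides passed to [train_config()].
#' @export
train_config_desk <- function(...) {
  args <- utils::modifyList(list(learning_rate = 1e-3, epochs = 20L), list(...))
  do.call(train_config, args)
}

#' Split sequences into train / validation / test sets
#'
#' Random split at the sequence level (never at the frame level), with
#' counts `floor(fraction * n)` and the remainder assigned by largest
#' fractional part.
#'
#' @param x A list of sequences, or a data frame (e.g. a manifest) split by
#'   row.
#' @param fractions Three nonnegative fractions summing to 1.
#' @param seed Integer seed.
#' @return For a list: `list(train = , val = , test = )`. For a data frame:
#'   the same rows with an added `split` column.
#' @examples
#' s <- split_dataset(as.list(1:25), seed = 1)
#' lengths(s)  # 15, 5, 5
#' @export
split_dataset <- function(x, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  if (any(counts < 1))
    abort(sprintf("too few sequences (%d) for a %s split", n,
                  paste(fractions, collapse = "/")), class = "vt_split_error")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  groups <- rep(c("train", "val", "test"), counts)
  if (is.data.frame(x)) {
    x$split <- NA_character_
    x$split[idx] <- groups
    return(x)
  }
  list(train = x[idx[groups == "train"]],
       val = x[idx[groups == "val"]],
       test = x[idx[groups == "test"]])
}

#' Flip a sequence deterministically
#'
#' Flips every frame of the sequence vertically and/or horizontally (the
#' same flip for all frames, preserving temporal coherence). Diameter labels
#' are unchanged: a flip does not alter the vessel's width.
#'
#' @param seq A `vt_sequence`.
#' @param vertical,horizontal Logical flags.
#' @return The flipped `vt_sequence`.
#' @export
flip_sequence <- function(seq, vertical = FALSE, horizontal = FALSE) {
  if (vertical) seq$frames <- seq$frames[dim(seq$frames)[1]:1, , , drop = FALSE]
  if (horizontal) seq$frames <- seq$frames[, dim(seq$frames)[2]:1, , drop = FALSE]
  seq
}

#' Randomly flip a sequence (training augmentation)
#'
#' With independent probability 0.5 each, applies a vertical and/or a
#' horizontal flip to all frames via [flip_sequence()]. Uses the current RNG
#' state.
#'
#' @param seq A `vt_sequence`.
#' @param p_flip Per-axis flip probability.
#' @return A `vt_sequence`.
#' @export
augment_sequence <- function(seq, p_flip = 0.5) {
  flip_sequence(seq,
                vertical = runif(1) < p_flip,
                horizontal = runif(1) < p_flip)
}

#' Train a diameter-regression model
#'
#' Sequence-level Adam: each optimization step runs one full forward pass
#' over a training sequence, backpropagates the combined loss
#' `MSE + lambda * CL` through time, and updates all weights. One epoch
#' visits every training sequence once in random order. The cardiac period
#' of each training sequence is estimated once from its own ground truth;
#' sequences with no detectable period contribute MSE only. After each
#' epoch the validation MSE (normalized scale) is recorded and the weights
#' with the best validation MSE are kept. The test split must never be
#' passed to this function.
#'
#' @param model A `vt_model` from [init_model()].
#' @param train,val Lists of `vt_sequence` (e.g. from [split_dataset()]).
#' @param config A [train_config()].
#' @return A `vt_fit`: list with `model` (best weights, with normalization
#'   stored), `history` (tibble: epoch, train_loss, train_mse, train_cl,
#'   val_mse), `best_epoch`, `config`.
#' @export
train_model <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "vt_model"), length(train) >= 1, length(val) >= 1)
  set.seed(config$seed)
  cfg <- unclass(model$config)

  # target normalization from the training split only
  all_d <- unlist(lapply(train, `[[`, "diameters"))
  center <- if (config$normalize) mean(all_d) else 0
  scale <- if (config$normalize) max(sd(all_d), 1e-8) else 1
  model$normalization <- list(center = center, scale = scale)
  norm <- function(y) (y - center) / scale

  # per-sequence period info (period is scale-invariant)
  periods <- lapply(train, function(s) {
    tryCatch(estimate_period(s$diameters, min_prominence = config$min_prominence),
             vt_period_error = function(e) NULL)
  })

  theta <- model$theta
  m <- numeric(length(theta)); v <- numeric(length(theta))
  step <- 0L
  hist <- vector("list", config$epochs)
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train))
    ep_loss <- ep_mse <- ep_cl <- 0
    for (i in ord) {
      s <- train[[i]]
      if (config$augment) s <- augment_sequence(s)
      p <- periods[[i]]
      Tp <- if (is.null(p)) 0L else p$T_period
      Nc <- if (is.null(p)) 0L else p$n_cycles
      g <- cpp_seq_grad(s$frames, norm(s$diameters), theta, cfg,
                        config$lambda, Tp, Nc)
      if (!is.finite(g$loss))
        abort(sprintf("non-finite loss at epoch %d, sequence %d", epoch, i),
              class = "vt_numeric_error")
      grad <- g$grad
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(sum(grad^2))
        if (gn > config$clip_norm) grad <- grad * (config$clip_norm / gn)
      }
      step <- step + 1L
      m <- config$beta1 * m + (1 - config$beta1) * grad
      v <- config$beta2 * v + (1 - config$beta2) * grad^2
      mhat <- m / (1 - config$beta1^step)
      vhat <- v / (1 - config$beta2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + config$eps)
      ep_loss <- ep_loss + g$loss; ep_mse <- ep_mse + g$mse; ep_cl <- ep_cl + g$cl
    }
    nt <- length(train)
    val_mse <- mean(vapply(val, function(s) {
      pred <- cpp_seq_forward(s$frames, theta, cfg)
      mean((pred - norm(s$diameters))^2)
    }, 0))
    hist[[epoch]] <- tibble(epoch = epoch,
                            train_loss = ep_loss / nt,
                            train_mse = ep_mse / nt,
                            train_cl = ep_cl / nt,
                            val_mse = val_mse)
    if (val_mse < best_val) {
      best_val <- val_mse; best_theta <- theta; best_epoch <- epoch
    }
    if (config$verbose)
      message(sprintf("epoch %3d  train loss %.5f  val mse %.5f",
                      epoch, ep_loss / nt, val_mse))
  }
  model$theta <- best_theta
  model$meta$trained <- TRUE
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch, config = config),
            class = "vt_fit")
}

#' @export
print.vt_fit <- function(x, ...) {
  cat(sprintf("<vt_fit> %d epochs, best epoch %d (val mse %.5f, normalized)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_mse[x$best_epoch]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vt_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.vt_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_mse = x$history$val_mse[x$best_epoch],
         lambda = x$config$lambda,
         learning_rate = x$config$learning_rate,
         n_parameters = length(x$model$theta))
}

#' @export
predict.vt_fit <- function(object, x, ...) forward_sequence(object$model, x)
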