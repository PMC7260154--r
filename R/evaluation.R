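# Evaluation: per-sequence MSE, mean absolute relative error, MAE, R^2;
# aggregation as mean (sd) across sequences with a pooled per-frame variant;
# Kolmogorov-Smirnov comparison of residual distributions between models.

#' Mean squared error between two traces
#' @param y,y_hat Numeric traces of equal length.
#' @return Scalar, in squared length units.
#' @export
vt_mse <- function(y, y_hat) {
  check_lengths(y, y_hat)
  mean((y - y_hat)^2)
}

#' Mean absolute relative error, in percent
#'
#' `100 * mean(|y - y_hat| / y)`; requires strictly positive ground truth.
#' @inheritParams vt_mse
#' @return Scalar percentage.
#' @export
vt_relative_error <- function(y, y_hat) {
  check_lengths(y, y_hat)
  if (any(y <= 0)) abort("ground truth must be strictly positive",
                         class = "vt_contract_error")
  100 * mean(abs(y - y_hat) / y)
}

#' Mean absolute error
#' @inheritParams vt_mse
#' @return Scalar, in length units.
#' @export
vt_mae <- function(y, y_hat) {
  check_lengths(y, y_hat)
  mean(abs(y - y_hat))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares about `mean(y)`.
#' @inheritParams vt_mse
#' @return Scalar, at most 1.
#' @export
vt_r_squared <- function(y, y_hat) {
  check_lengths(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("constant ground truth: R^2 undefined",
                         class = "vt_contract_error")
  1 - sum((y - y_hat)^2) / ss_tot
}

check_lengths <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    abort("trace lengths differ", class = "vt_contract_error")
  invisible(TRUE)
}

#' Two-sample Kolmogorov-Smirnov comparison of error samples
#'
#' Compares two samples of per-frame absolute errors (one per model, pooled
#' over the test set) with the two-sample KS test.
#'
#' @param errors_a,errors_b Nonempty numeric samples.
#' @return List with `statistic` and `p_value`.
#' @export
ks_compare <- function(errors_a, errors_b) {
  if (length(errors_a) == 0 || length(errors_b) == 0)
    abort("error samples must be nonempty", class = "vt_contract_error")
  k <- suppressWarnings(ks.test(errors_a, errors_b))
  list(statistic = unname(k$statistic), p_value = unname(k$p.value))
}

#' Evaluate a model on a test set
#'
#' Predicts a diameter trace for every test sequence, computes MSE, RE, MAE
#' and R^2 per sequence, and aggregates them as mean (sd) across sequences.
#' A pooled per-frame variant (metrics on all frames concatenated) is also
#' reported, along with the prediction traces.
#'
#' @param object A `vt_fit` or `vt_model`; anything else works if
#'   `predict_fun` is given.
#' @param test List of labeled `vt_sequence` objects.
#' @param units Unit tag for the report; defaults to the first sequence's.
#' @param predict_fun Optional `function(sequence) -> numeric trace`
#'   overriding the model's predictions (e.g. an oracle).
#' @return A `vt_metrics`: list with `per_sequence` (tibble), `aggregate`
#'   (tibble: metric, mean, sd), `pooled` (tibble), `predictions` (list of
#'   tibbles), `units`.
#' @export
evaluate_model <- function(object, test, units = NULL, predict_fun = NULL) {
  stopifnot(length(test) >= 1)
  predict_fun <- predict_fun %||% function(s) forward_sequence(object, s)$diameter
  units <- units %||% (test[[1]]$units %||% "pixel")
  rows <- vector("list", length(test))
  preds <- vector("list", length(test))
  for (i in seq_along(test)) {
    s <- test[[i]]
    y <- s$diameters
    y_hat <- predict_fun(s)
    rows[[i]] <- tibble(sequence = i,
                        mse = vt_mse(y, y_hat),
                        re = vt_relative_error(y, y_hat),
                        mae = vt_mae(y, y_hat),
                        r2 = vt_r_squared(y, y_hat))
    preds[[i]] <- tibble(sequence = i, frame = seq_along(y) - 1L,
                         truth = y, estimate = y_hat)
  }
  per_seq <- dplyr::bind_rows(rows)
  all_pred <- dplyr::bind_rows(preds)
  aggregate <- tidyr::pivot_longer(per_seq, -sequence, names_to = "metric") |>
    dplyr::group_by(metric) |>
    dplyr::summarise(mean = mean(value),
                     sd = if (dplyr::n() > 1) stats::sd(value) else 0) |>
    dplyr::ungroup()
  pooled <- tibble(metric = c("mse", "re", "mae", "r2"),
                   value = c(vt_mse(all_pred$truth, all_pred$estimate),
                             vt_relative_error(all_pred$truth, all_pred$estimate),
                             vt_mae(all_pred$truth, all_pred$estimate),
                             vt_r_squared(all_pred$truth, all_pred$estimate)))
  structure(list(per_sequence = per_seq, aggregate = aggregate,
                 pooled = pooled, predictions = preds, units = units),
            class = "vt_metrics")
}

#' @export
print.vt_metrics <- function(x, ...) {
  a <- x$aggregate
  fmt <- function(m) {
    r <- a[a$metric == m, ]
    sprintf("%.4g (%.4g)", r$mean, if (is.na(r$sd)) 0 else r$sd)
  }
  u <- x$units
  cat(sprintf("<vt_metrics> %d sequences, mean (sd) across sequences\n",
              nrow(x$per_sequence)))
  cat(sprintf("  MSE %s %s^2 | RE %s %% | MAE %s %s | R^2 %s\n",
              fmt("mse"), u, fmt("re"), fmt("mae"), u, fmt("r2")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vt_metrics <- function(x, ...) x$per_sequence

#' @exportS3Method generics::glance
glance.vt_metrics <- function(x, ...) {
  a <- x$aggregate
  tibble(mse = a$mean[a$metric == "mse"], re = a$mean[a$metric == "re"],
         mae = a$mean[a$metric == "mae"], r2 = a$mean[a$metric == "r2"],
         mse_sd = a$sd[a$metric == "mse"], re_sd = a$sd[a$metric == "re"],
         mae_sd = a$sd[a$metric == "mae"], r2_sd = a$sd[a$metric == "r2"],
         n_sequences = nrow(x$per_sequence), units = x$units)
}

#' Compare two models on a shared test set
#'
#' Evaluates both models and applies [ks_compare()] to their pooled
#' per-frame absolute errors.
#'
#' @param object_a,object_b Models accepted by [evaluate_model()].
#' @param test Shared list of labeled test sequences.
#' @param units Unit tag.
#' @return List with `metrics_a`, `metrics_b`, `ks` (statistic, p_value).
#' @export
compare_models <- function(object_a, object_b, test, units = NULL) {
  ma <- evaluate_model(object_a, test, units = units)
  mb <- evaluate_model(object_b, test, units = units)
  abs_err <- function(m) {
    p <- dplyr::bind_rows(m$predictions)
    abs(p$truth - p$estimate)
  }
  list(metrics_a = ma, metrics_b = mb, ks = ks_compare(abs_err(ma), abs_err(mb)))
}
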