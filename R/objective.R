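# Training objective: cardiac-period estimation by peak detection on the
# ground-truth trace, the CyclicLoss penalty tying same-phase predictions in
# adjacent cycles, and the combined MSE + lambda * CL loss.

#' Detect local maxima with prominence and spacing constraints
#'
#' A deliberately simple peak detector: candidate peaks are samples strictly
#' greater than their left neighbor and at least as large as their right
#' neighbor (so a flat-topped peak is reported once, at its first sample);
#' candidates below the prominence threshold are dropped; remaining peaks
#' are kept highest-first subject to a minimum spacing.
#'
#' @param y Numeric series.
#' @param min_distance Minimum spacing between kept peaks, in samples.
#' @param min_prominence Minimum topographic prominence; default
#'   `0.25 * (max(y) - min(y)) / 2`, a quarter of the amplitude estimate.
#' @return Integer vector of 1-based peak positions, increasing.
#' @export
find_peaks <- function(y, min_distance = 2,
                       min_prominence = 0.25 * (max(y) - min(y)) / 2) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- y[i]; j <- i
    while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
    rmin <- y[i]; j <- i
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
    y[i] - max(lmin, rmin)
  }, 0)
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(integer(0))
  kept <- integer(0)
  for (i in cand[order(-y[cand])]) {
    if (all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Estimate the cardiac period of a diameter trace
#'
#' Runs [find_peaks()] on the ground-truth trace and takes the rounded mean
#' of consecutive peak-to-peak distances as the period `T_period` (frames);
#' the number of whole cycles is `floor(length(y) / T_period)`. Needed only
#' at training time: prediction is blind to periodicity.
#'
#' @param y Numeric ground-truth diameter trace (or a tibble with a
#'   `diameter` column, or a `vt_sequence`).
#' @param min_distance,min_prominence Passed to [find_peaks()].
#' @return List of class `vt_period` with `T_period` (integer, >= 2),
#'   `n_cycles` and `peaks`.
#' @examples
#' y <- 30 + 3 * sin(2 * pi * (0:124) / 10)
#' estimate_period(y)$T_period
#' @export
estimate_period <- function(y, min_distance = 2, min_prominence = NULL) {
  y <- as_trace(y)
  if (length(y) < 3)
    abort("trace too short for period estimation", class = "vt_period_error")
  min_prominence <- min_prominence %||% (0.25 * (max(y) - min(y)) / 2)
  peaks <- find_peaks(y, min_distance, min_prominence)
  if (length(peaks) < 2)
    abort("fewer than 2 peaks detected; cannot estimate a period",
          class = "vt_period_error")
  T_period <- as.integer(round(mean(diff(peaks))))
  if (T_period < 2)
    abort("estimated period below 2 frames", class = "vt_period_error")
  structure(list(T_period = T_period,
                 n_cycles = as.integer(floor(length(y) / T_period)),
                 peaks = peaks),
            class = "vt_period")
}

as_trace <- function(y) {
  if (inherits(y, "vt_sequence")) return(y$diameters)
  if (is.data.frame(y)) return(y$diameter)
  as.numeric(y)
}

#' CyclicLoss: periodicity penalty on a predicted trace
#'
#' The L2 norm of differences between predictions one cardiac period apart
#' at the same phase:
#' `CL = sqrt( sum_{n=0}^{Ncycles-1} sum_{t=0}^{Tperiod} (yhat[t+(n+1)T] - yhat[t+nT])^2 )`,
#' with the inner sum running to `Tperiod` inclusive as printed; index pairs
#' reaching past the end of the trace are skipped, and 0 is returned (with a
#' warning) when no valid pair exists.
#'
#' @param y_hat Numeric predicted trace (or tibble with `diameter`).
#' @param period A `vt_period` from [estimate_period()], or a list with
#'   `T_period` and `n_cycles`.
#' @return Nonnegative scalar.
#' @examples
#' cyclic_loss(1:6, list(T_period = 2, n_cycles = 3))  # sqrt(20)
#' @export
cyclic_loss <- function(y_hat, period) {
  y_hat <- as_trace(y_hat)
  K <- length(y_hat)
  Tp <- period$T_period; Nc <- period$n_cycles
  if (is.null(Tp) || Tp < 1 || is.null(Nc) || Nc < 1) {
    warn("degenerate period info; CyclicLoss is 0")
    return(0)
  }
  s <- 0; npairs <- 0L
  for (n in 0:(Nc - 1)) {
    for (t in 0:Tp) {
      a <- t + n * Tp; b <- t + (n + 1) * Tp   # 0-based
      if (b <= K - 1) {
        s <- s + (y_hat[b + 1] - y_hat[a + 1])^2
        npairs <- npairs + 1L
      }
    }
  }
  if (npairs == 0L) {
    warn("no in-range index pair; CyclicLoss is 0")
    return(0)
  }
  sqrt(s)
}

#' Combined training loss: MSE + lambda * CyclicLoss
#'
#' `Loss = (1/K) * sum_t (y[t] - yhat[t])^2 + lambda * CL(yhat)`. With
#' `lambda = 0` this is plain mean squared error.
#'
#' @param y_hat,y Predicted and target traces of equal length.
#' @param lambda Nonnegative CyclicLoss weight (reference value `1e-6`).
#' @param period Period info for the CL term; may be `NULL` when
#'   `lambda = 0`.
#' @return Scalar loss.
#' @export
combined_loss <- function(y_hat, y, lambda = 1e-6, period = NULL) {
  y_hat <- as_trace(y_hat); y <- as_trace(y)
  if (length(y_hat) != length(y))
    abort("trace lengths differ", class = "vt_contract_error")
  if (lambda < 0) abort("lambda must be >= 0", class = "vt_config_error")
  m <- mean((y - y_hat)^2)
  if (lambda == 0) return(m)
  if (is.null(period)) abort("period info needed when lambda > 0",
                             class = "vt_contract_error")
  m + lambda * cyclic_loss(y_hat, period)
}
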