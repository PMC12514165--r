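#' Hanning-window smoothing of a response trace
#'
#' Convolves a time series with a Hanning (raised-cosine) kernel normalised
#' to unit sum, so constant signals pass through unchanged. Edges are
#' handled by reflection so the output has the same length as the input.
#' Electrophysiology pipelines conventionally smooth spike-train PSTHs with
#' a 21 ms Hanning window; at 1 ms bins that is `window_bins = 21`, at
#' coarser resolutions round to the nearest odd bin count.
#'
#' @param series numeric vector.
#' @param window_bins odd integer `>= 1`; `1` is the identity.
#' @return numeric vector of the same length.
#' @examples
#' hanning_smooth(c(0, 0, 1, 0, 0), 3)
#' @export
hanning_smooth <- function(series, window_bins) {
  series <- as.numeric(series)
  if (length(window_bins) != 1L || window_bins < 1 || window_bins %% 2 == 0)
    stop_arg("window_bins must be an odd integer >= 1")
  if (window_bins == 1L) return(series)
  kern <- hanning_kernel(window_bins)
  reflect_convolve(series, kern)
}

# unit-sum Hanning kernel; endpoints of the raised cosine are zero
hanning_kernel <- function(n) {
  i <- seq_len(n) - 1
  w <- 0.5 * (1 - cos(2 * pi * i / (n - 1)))
  w / sum(w)
}

# "same"-length convolution with reflection padding at both edges
reflect_convolve <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1) / 2
  if (half >= n) stop_arg("kernel wider than the series")
  left <- x[seq(half + 1, 2, length.out = half)]
  right <- x[seq(n - 1, n - half, length.out = half)]
  padded <- c(left, x, right)
  out <- stats::filter(padded, kern, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Peri-stimulus time histogram (PSTH)
#'
#' Averages an `M x T` matrix of single-trial responses across trials and
#' optionally smooths the average with a Hanning window (see
#' [hanning_smooth()]). Averaging and linear smoothing commute, so applying
#' the window after the trial mean is equivalent to smoothing each trial.
#'
#' @param trials numeric `M x T` matrix (one row per trial).
#' @param smooth_window_bins odd integer `>= 1`; `1` disables smoothing.
#' @return length-`T` numeric vector.
#' @examples
#' compute_psth(rbind(c(0, 2), c(2, 0)))
#' @export
compute_psth <- function(trials, smooth_window_bins = 1L) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L || ncol(trials) < 1L)
    stop_arg("trials must be a non-empty M x T matrix")
  m <- colMeans(trials)
  hanning_smooth(m, smooth_window_bins)
}

#' Remove slow drift from a membrane-potential trace (MedGauss filter)
#'
#' Estimates the slow trend of a trace as a running median followed by
#' Gaussian smoothing, and subtracts it. Intended for intracellular
#' membrane-potential recordings where electrode or movement drift
#' contaminates the signal; spike-derived PSTHs do not need it.
#'
#' @param trace numeric vector.
#' @param median_width_bins odd integer width of the running median
#'   (default 201 bins).
#' @param gauss_sigma_bins standard deviation of the Gaussian smoother in
#'   bins (default 50).
#' @return the detrended trace (input minus estimated trend).
#' @examples
#' x <- sin(2 * pi * (1:2000) / 40) + seq(0, 3, length.out = 2000)
#' y <- detrend_medgauss(x)
#' @export
detrend_medgauss <- function(trace, median_width_bins = 201L,
                             gauss_sigma_bins = 50) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (median_width_bins < 1 || gauss_sigma_bins <= 0)
    stop_arg("filter widths must be positive")
  if (median_width_bins >= n)
    stop_arg("median_width_bins must be smaller than the trace length")
  if (median_width_bins %% 2 == 0) median_width_bins <- median_width_bins + 1
  trend <- stats::runmed(trace, k = median_width_bins, endrule = "median")
  # Gaussian smoothing of the median trend, reflection-padded
  half <- min(n - 1, ceiling(4 * gauss_sigma_bins))
  kern <- stats::dnorm(seq(-half, half), sd = gauss_sigma_bins)
  kern <- kern / sum(kern)
  trend <- reflect_convolve(as.numeric(trend), kern)
  trace - trend
}
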