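#' Raw correlation coefficient between prediction and PSTH
#'
#' Pearson's correlation `Cov(r, rhat) / sqrt(Var(r) Var(rhat))` computed
#' along time with population variances (divide by the bin count). If
#' either series has zero variance the correlation is undefined; the
#' package policy returns 0 with a warning so population averages remain
#' defined.
#'
#' @param pred,psth length-`T` numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
cc_raw <- function(pred, psth) {
  pred <- as.numeric(pred); psth <- as.numeric(psth)
  if (length(pred) != length(psth))
    stop_arg("pred and psth must have equal length")
  vp <- pop_var(pred); vr <- pop_var(psth)
  if (vp <= 0 || vr <= 0) {
    warning("degenerate (zero-variance) series in cc_raw; returning 0")
    return(0)
  }
  pop_cov(psth, pred) / sqrt(vr * vp)
}

pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Signal power of a multi-trial response
#'
#' The across-trial estimate of the reliable (stimulus-locked) response
#' variance:
#' `SP = (Var(sum_m r^(m)) - sum_m Var(r^(m))) / (M (M - 1))`,
#' with population variances along time. When all trials are identical to
#' `r` this reduces exactly to `Var(r)`; for pure noise its expectation is
#' 0 (it can be negative in samples).
#'
#' @param trials `M x T` matrix of single-trial responses, `M >= 2`.
#' @return scalar signal-power estimate.
#' @export
signal_power <- function(trials) {
  trials <- as.matrix(trials)
  M <- nrow(trials)
  if (M < 2) stop_arg("signal_power requires M >= 2 trials")
  v_sum <- pop_var(colSums(trials))
  sum_v <- sum(apply(trials, 1, pop_var))
  (v_sum - sum_v) / (M * (M - 1))
}

#' Noise-corrected (normalized) correlation coefficient
#'
#' `CC_norm = Cov(r, rhat) / sqrt(SP * Var(rhat))` where `r` is the trial
#' mean and `SP` the signal power of the trials: dividing by `sqrt(SP)`
#' rather than `sqrt(Var(r))` removes the downward bias that trial-to-trial
#' noise imposes on the raw correlation, making 1 the attainable ceiling
#' for a perfect model. With a single trial the recording is treated as
#' noise-free and `CC_norm = CC_raw`. If the signal-power estimate is not
#' positive (possible under heavy noise) the correction is undefined and
#' the policy value 0 is returned with a warning.
#'
#' @param pred length-`T` predicted rate.
#' @param trials `M x T` matrix of single-trial responses.
#' @return scalar.
#' @export
cc_norm <- function(pred, trials) {
  pred <- as.numeric(pred)
  trials <- as.matrix(trials)
  if (ncol(trials) != length(pred))
    stop_arg("pred and trials must share T")
  if (nrow(trials) == 1) return(cc_raw(pred, trials[1, ]))
  r <- colMeans(trials)
  sp <- signal_power(trials)
  vp <- pop_var(pred)
  if (sp <= 0) {
    warning("non-positive signal power; returning CC_norm = 0")
    return(0)
  }
  if (vp <= 0) {
    warning("degenerate (zero-variance) prediction in cc_norm; returning 0")
    return(0)
  }
  pop_cov(r, pred) / sqrt(sp * vp)
}

#' Mean squared error between prediction and target
#'
#' The training loss: the mean over all `N * T` bins of the squared
#' difference between the predicted time series and the recorded PSTH.
#'
#' @param pred,target `N x T` numeric matrices (or equal-length vectors).
#' @return scalar.
#' @export
mse_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target)))
    stop_arg("pred and target must have identical shape")
  mean((pred - target)^2)
}
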