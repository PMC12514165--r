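# Gradient-based reverse engineering of trained encoders. All routines
# run the model in inference mode (frozen batch-normalisation), so the
# maps are properties of the frozen model. Stateful models are unrolled in
# full over the probe length regardless of how they were trained.

# loss L = -mean over target units of predicted activity at the last bin;
# returns the N x T gradient seed
interp_dpred_seed <- function(model, target, Tlen) {
  N <- model$spec$n_neurons
  if (!length(target)) stop_arg("target neuron set must be non-empty")
  if (any(target < 1 | target > N))
    stop_arg("target indices must be in 1..%d", N)
  d <- matrix(0, N, Tlen)
  for (n in target) d[n, Tlen] <- d[n, Tlen] - 1 / length(target)
  d
}

#' GradMap: gradient of a response-maximisation loss on the input
#'
#' Computes `dL/dx` at a probe stimulus (by default the null stimulus, a
#' uniform all-zero spectrogram) where
#' `L = -mean of the target units' predicted activity at the final bin`.
#' The GradMap generalises the linear STRF to arbitrary differentiable
#' encoders: for a purely linear model it reproduces the model's own STRF
#' weights (up to the loss sign), laid out at the matching latencies
#' before the final bin; for nonlinear and recurrent models it is the
#' local linearisation of the neuron's input-output function around the
#' probe.
#'
#' @param model a `causal_encoder` or [encoder_fit].
#' @param target integer vector of target neuron indices (averaged).
#' @param T probe length in bins.
#' @param probe optional `F x T` probe stimulus (default all zeros).
#' @return object of class `gradmap`: the `F x T` gradient matrix with
#'   attributes `target`, `horizon` and `arch`. Latency `tau` (bins before
#'   the response) corresponds to column `T - tau`.
#' @export
gradmap <- function(model, target = 1L, T = 50L, probe = NULL) {
  if (inherits(model, "encoder_fit")) model <- model$model
  F <- model$spec$n_freqs
  if (T < 1) stop_arg("T must be >= 1")
  if (is.null(probe)) probe <- matrix(0, F, T)
  probe <- as.matrix(probe)
  if (nrow(probe) != F || ncol(probe) != T)
    stop_arg("probe must be an F x T matrix matching the model and horizon")
  fw <- encoder_forward(model, probe, training = FALSE)
  d_pred <- interp_dpred_seed(model, target, T)
  bw <- encoder_backward(model, fw$cache, d_pred)
  structure(bw$d_x, target = as.integer(target), horizon = as.integer(T),
            arch = model$spec$architecture,
            class = c("gradmap", "matrix", "array"))
}

#' @export
print.gradmap <- function(x, ...) {
  cat(sprintf("<gradmap (%s): %d x %d, target {%s}>\n", attr(x, "arch"),
              nrow(x), ncol(x),
              paste(attr(x, "target"), collapse = ",")))
  invisible(x)
}

# mean predicted activity of the target units at the final bin
target_activation <- function(model, target, x) {
  pred <- encoder_forward(model, x, training = FALSE)$pred
  mean(pred[target, ncol(pred)])
}

#' Dream: iterative gradient-ascent stimulus optimisation
#'
#' Starting from the null stimulus, repeatedly computes the GradMap and
#' takes an optimiser step on the stimulus so the target units' predicted
#' activity at the final bin increases (gradient descent on
#' `L = -activation`). AdamW-style updates with the training betas are
#' used; plain gradient steps are available via `optimizer = "sgd"`. The
#' stimulus is unconstrained (cochleagram non-negativity is not imposed).
#'
#' @param model a `causal_encoder` or [encoder_fit].
#' @param target integer vector of target neuron indices.
#' @param T dream length in bins.
#' @param n_iters fixed iteration budget (default 1500).
#' @param lr optimiser step size (default `1e-2`).
#' @param betas AdamW moment decays.
#' @param optimizer `"adamw"` or `"sgd"`.
#' @param converge_tol if non-`NULL`, stop early once the relative loss
#'   change over a 50-iteration window falls below this value ("loss
#'   convergence" mode).
#' @param keep_gradmaps retain the per-iteration GradMaps (memory-heavy).
#' @return object of class `dream`: list with `stimulus` (`F x T`),
#'   `loss_trajectory`, `n_iterations`, `target`, and optionally
#'   `gradmaps`.
#' @export
dream <- function(model, target = 1L, T = 50L, n_iters = 1500L, lr = 1e-2,
                  betas = c(0.9, 0.999), optimizer = c("adamw", "sgd"),
                  converge_tol = NULL, keep_gradmaps = FALSE) {
  optimizer <- match.arg(optimizer)
  if (inherits(model, "encoder_fit")) model <- model$model
  if (n_iters < 1) stop_arg("n_iters must be >= 1")
  F <- model$spec$n_freqs
  x <- matrix(0, F, T)
  d_seed <- interp_dpred_seed(model, target, T)
  m <- matrix(0, F, T); v <- matrix(0, F, T)
  losses <- numeric(0)
  maps <- if (keep_gradmaps) list() else NULL
  for (i in seq_len(n_iters)) {
    fw <- encoder_forward(model, x, training = FALSE)
    losses[i] <- -mean(fw$pred[target, T])
    g <- encoder_backward(model, fw$cache, d_seed)$d_x
    if (keep_gradmaps) maps[[i]] <- g
    if (optimizer == "adamw") {
      m <- betas[1] * m + (1 - betas[1]) * g
      v <- betas[2] * v + (1 - betas[2]) * g^2
      upd <- (m / (1 - betas[1]^i)) / (sqrt(v / (1 - betas[2]^i)) + 1e-8)
      x <- x - lr * upd
    } else {
      x <- x - lr * g
    }
    if (!is.null(converge_tol) && i >= 51) {
      prev <- losses[i - 50]
      if (abs(losses[i] - prev) <= converge_tol * max(abs(prev), 1e-12))
        break
    }
  }
  structure(list(stimulus = x, loss_trajectory = losses,
                 n_iterations = length(losses),
                 target = as.integer(target), lr = lr, betas = betas,
                 optimizer = optimizer, gradmaps = maps),
            class = "dream")
}

#' @export
print.dream <- function(x, ...) {
  cat(sprintf(
    "<dream: %d x %d stimulus, %d iterations, loss %.4g -> %.4g>\n",
    nrow(x$stimulus), ncol(x$stimulus), x$n_iterations,
    x$loss_trajectory[1], tail(x$loss_trajectory, 1)))
  invisible(x)
}

#' Latency energy trace of a GradMap
#'
#' `E[t] = mean over frequency bands of g[f, t]^2`, re-indexed by latency:
#' element 1 of the returned trace is latency 0 (the response bin, last
#' column of the map), element `tau + 1` is `tau` bins before the
#' response. Optionally normalised by its maximum.
#'
#' @param g a [gradmap] (or plain `F x T` matrix).
#' @param normalize divide by the maximum value (if positive).
#' @return object of class `energy_trace`: non-negative numeric vector of
#'   length `T` with attribute `normalized`.
#' @export
gradmap_energy <- function(g, normalize = FALSE) {
  g <- as.matrix(g)
  e <- rev(colMeans(g^2))
  if (normalize) {
    mx <- max(e)
    if (mx > 0) e <- e / mx
    else warning("all-zero gradmap; energy trace left at zero")
  }
  structure(e, normalized = isTRUE(normalize),
            class = c("energy_trace", "numeric"))
}

#' Cross-model GradMap similarity matrix
#'
#' For every pair of models and every neuron, the two `F x T` GradMaps are
#' flattened and compared with Pearson's correlation; coefficients are
#' then averaged across neurons. Correlation (rather than a pixel-wise
#' distance) makes the similarity invariant to affine rescaling of the
#' maps, matching how encoding models are themselves scored. The horizon
#' should sit slightly above the largest stateless window so bins beyond
#' every receptive field do not inflate the similarity.
#'
#' @param gradmaps nested list: `gradmaps[[model]][[neuron]]` is an
#'   `F x T` map; all maps must share dimensions. Model names are taken
#'   from the outer list names.
#' @return symmetric model-by-model matrix with unit diagonal.
#' @export
similarity_matrix <- function(gradmaps) {
  nm <- length(gradmaps)
  if (nm < 2) stop_arg("need at least two models to compare")
  dims <- dim(as.matrix(gradmaps[[1]][[1]]))
  for (mlist in gradmaps)
    for (g in mlist)
      if (!all(dim(as.matrix(g)) == dims))
        stop_arg("all gradmaps must share the same F x T shape")
  n_neu <- length(gradmaps[[1]])
  S <- matrix(1, nm, nm)
  labs <- names(gradmaps)
  if (is.null(labs)) labs <- paste0("model", seq_len(nm))
  dimnames(S) <- list(labs, labs)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      ccs <- vapply(seq_len(n_neu), function(n) {
        a <- as.numeric(gradmaps[[i]][[n]])
        b <- as.numeric(gradmaps[[j]][[n]])
        if (pop_var(a) <= 0 || pop_var(b) <= 0) return(0)
        pop_cov(a, b) / sqrt(pop_var(a) * pop_var(b))
      }, numeric(1))
      S[i, j] <- S[j, i] <- mean(ccs)
    }
  }
  S
}

#' Dream-length activation curve
#'
#' For each requested dream length, optimises a dream of that many bins
#' (until loss convergence, capped), feeds it back through the model, and
#' records the mean predicted activation of the target units at the final
#' bin. The curve, normalised by its maximum, shows how much each past
#' time step contributes to the attainable activation: stateless models
#' plateau once the length exceeds their receptive-field window, while
#' trained recurrent models keep increasing over much longer horizons.
#'
#' @param model a `causal_encoder` or [encoder_fit].
#' @param targets integer vector of neuron indices (averaged).
#' @param lengths dream lengths in bins (default `1:200`).
#' @param n_iters iteration cap per length (default 1500).
#' @param lr,betas dream optimiser settings.
#' @param converge_tol relative loss-change tolerance over 50 iterations
#'   (default `1e-4`).
#' @return data frame with columns `length`, `activation` (raw) and
#'   `normalized` (curve divided by its maximum).
#' @export
dream_length_curve <- function(model, targets = 1L, lengths = 1:200,
                               n_iters = 1500L, lr = 1e-2,
                               betas = c(0.9, 0.999),
                               converge_tol = 1e-4) {
  if (inherits(model, "encoder_fit")) model <- model$model
  if (any(lengths < 1)) stop_arg("lengths must be >= 1")
  act <- vapply(lengths, function(L) {
    d <- dream(model, target = targets, T = L, n_iters = n_iters, lr = lr,
               betas = betas, converge_tol = converge_tol)
    target_activation(model, targets, d$stimulus)
  }, numeric(1))
  mx <- max(act)
  data.frame(length = as.integer(lengths), activation = act,
             normalized = if (mx > 0) act / mx else act - mx + 1)
}
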