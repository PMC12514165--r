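#' Training configuration for the neural-response-fitting task
#'
#' Bundles the optimisation protocol: AdamW updates with constant learning
#' rate `1e-3` and betas `(0.9, 0.999)`, batch size 1 clip (16 for large
#' trial-limited layouts), early stopping after 50 epochs without
#' validation-loss improvement, and optional truncated backpropagation
#' through time for stateful models. No weight decay, dropout or data
#' augmentation is used.
#'
#' @param lr learning rate (default `1e-3`).
#' @param betas length-2 AdamW moment decays (default `c(0.9, 0.999)`).
#' @param batch_size clips per parameter update (default 1).
#' @param patience epochs without validation improvement before stopping
#'   (default 50).
#' @param max_epochs hard cap on epochs (default 500).
#' @param tbptt `NULL` for full backpropagation through time, or
#'   `list(K = <max graph length in bins>, warmup = <logical>)`. The loss
#'   is evaluated at every bin (`K1 = 1`); the gradient at bin `t` flows
#'   through at most `K` bins of history. With warmup, the state entering
#'   the graph is the forward-propagated state from the sequence start;
#'   without warmup the graph starts from the null state `K` bins before
#'   each loss evaluation.
#' @param weight_decay AdamW decoupled weight decay (default 0).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, betas = c(0.9, 0.999), batch_size = 1L,
                         patience = 50L, max_epochs = 500L, tbptt = NULL,
                         weight_decay = 0) {
  if (lr <= 0) stop_arg("lr must be > 0")
  if (patience < 1) stop_arg("patience must be >= 1")
  if (!is.null(tbptt)) {
    tbptt <- modifyList(list(K = 1L, warmup = TRUE), tbptt)
    if (tbptt$K < 1) stop_arg("tbptt K must be >= 1")
  }
  structure(list(lr = lr, betas = betas, batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), tbptt = tbptt,
                 weight_decay = weight_decay),
            class = "train_config")
}

# one AdamW step over a named parameter/gradient list
adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, weight_decay = 0,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - betas[1]^state$t
  bc2 <- 1 - betas[2]^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- betas[1] * state$m[[nm]] + (1 - betas[1]) * gr
    state$v[[nm]] <- betas[2] * state$v[[nm]] + (1 - betas[2]) * gr^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

#' Fit an encoder to a stimulus-response dataset
#'
#' The central model-fitting routine. A causal encoder built from `spec`
#' is trained by gradient descent to minimise the mean squared error
#' between its predicted rates and the PSTHs of the training clips, with
#' AdamW updates, per-epoch validation, checkpointing on validation-loss
#' improvement and early stopping. Stateful architectures are trained by
#' backpropagation through time, optionally truncated
#' (`config$tbptt`). The best checkpoint is evaluated on all three splits
#' with the raw and noise-corrected correlation coefficients.
#'
#' @param dataset an [encoding_dataset] with split labels (see
#'   [split_dataset()]).
#' @param spec a [model_spec] (its `n_freqs`/`n_neurons` must match the
#'   dataset), or an already-built `causal_encoder` to continue from.
#' @param config a [train_config].
#' @param seed integer seed controlling initialisation and clip shuffling;
#'   identical `(dataset, spec, config, seed)` give identical results.
#' @param verbose print per-epoch progress every `verbose` epochs (0 =
#'   silent).
#' @return object of class `encoder_fit` with elements `model` (the best
#'   checkpoint), `metrics` (data frame: neuron, split, cc_raw, cc_norm),
#'   `loss` (per-epoch train/validation losses), `best_epoch`, `seed`,
#'   `spec`, `config` and `split` (the labels used).
#' @seealso [evaluate_encoder()], [predict.encoder_fit()],
#'   [summary.encoder_fit()]
#' @export
fit_encoder <- function(dataset, spec, config = train_config(), seed = 1L,
                        verbose = 0L) {
  if (!inherits(dataset, "encoding_dataset"))
    stop_arg("dataset must be an encoding_dataset")
  if (is.null(dataset$split))
    stop_arg("dataset has no split labels; call split_dataset() first")
  if (inherits(spec, "causal_encoder")) {
    model <- spec
    spec <- model$spec
  } else {
    spec$seed <- as.integer(seed)
    model <- build_model(spec)
  }
  F <- nrow(dataset$stimuli[[1]])
  if (spec$n_freqs != F)
    stop_arg("spec n_freqs (%d) does not match dataset F (%d)",
             spec$n_freqs, F)
  if (spec$n_neurons != length(dataset$neurons))
    stop_arg("spec n_neurons (%d) does not match dataset N (%d)",
             spec$n_neurons, length(dataset$neurons))
  if (!is.null(config$tbptt) && spec$architecture != "statenet")
    stop_arg("tbptt training is supported for statenet architectures only")

  train_ids <- clip_ids(dataset, "train")
  valid_ids <- clip_ids(dataset, "valid")
  if (!length(train_ids) || !length(valid_ids))
    stop_arg("train and valid splits must be non-empty")
  xs <- lapply(dataset$stimuli, coch_values)
  ys <- lapply(names(dataset$stimuli), function(cid)
    dataset$psth[[cid]][dataset$neurons, , drop = FALSE])
  names(ys) <- names(dataset$stimuli)

  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)
  wait <- 0L
  hist_train <- numeric(0); hist_valid <- numeric(0)

  with_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      order_ids <- sample(train_ids)
      ep_loss <- 0
      batch <- NULL; batch_n <- 0L
      for (cid in order_ids) {
        fw <- encoder_forward(model, xs[[cid]], training = TRUE,
                              tbptt = config$tbptt)
        model$buffers <- fw$buffers
        target <- ys[[cid]]
        d_pred <- 2 * (fw$pred - target) / length(target)
        ep_loss <- ep_loss + mse_loss(fw$pred, target)
        bw <- encoder_backward(model, fw$cache, d_pred)
        batch <- accumulate_grads(batch, bw$d_params)
        batch_n <- batch_n + 1L
        if (batch_n >= config$batch_size || cid == order_ids[length(order_ids)]) {
          upd <- adam_step(model$params, scale_grads(batch, 1 / batch_n),
                           opt, config$lr, config$betas,
                           config$weight_decay)
          model$params <- upd$params
          opt <- upd$state
          batch <- NULL; batch_n <- 0L
        }
      }
      hist_train[epoch] <- ep_loss / length(train_ids)
      vloss <- mean(vapply(valid_ids, function(cid)
        mse_loss(encoder_forward(model, xs[[cid]])$pred, ys[[cid]]),
        numeric(1)))
      hist_valid[epoch] <- vloss
      if (vloss < best$loss) {
        best <- list(loss = vloss, params = model$params,
                     buffers = model$buffers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (verbose > 0 && epoch %% verbose == 0)
        message(sprintf("epoch %4d  train %.5f  valid %.5f", epoch,
                        hist_train[epoch], vloss))
      if (wait >= config$patience) break
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers

  metrics <- do.call(rbind, lapply(c("train", "valid", "test"), function(s) {
    m <- evaluate_encoder(model, dataset, s)
    m$split <- s
    m
  }))
  structure(list(model = model, metrics = metrics,
                 loss = data.frame(epoch = seq_along(hist_train),
                                   train = hist_train, valid = hist_valid),
                 best_epoch = best$epoch, seed = as.integer(seed),
                 spec = spec, config = config, split = dataset$split),
            class = "encoder_fit")
}

#' Evaluate an encoder on one split of a dataset
#'
#' Clips of the split are concatenated temporally into one long sequence
#' (prediction, PSTH and trials alike; the model's state is reset at each
#' clip boundary) before computing, per neuron, the raw and
#' noise-corrected correlation coefficients. Concatenating before
#' correlating is not equivalent to averaging per-clip correlations.
#'
#' @param model a `causal_encoder` or [encoder_fit].
#' @param dataset an [encoding_dataset] with split labels.
#' @param split `"train"`, `"valid"` or `"test"`.
#' @return data frame with columns `neuron`, `cc_raw`, `cc_norm`.
#' @export
evaluate_encoder <- function(model, dataset, split = "test") {
  if (inherits(model, "encoder_fit")) model <- model$model
  cs <- concat_split(dataset, split)
  pred <- do.call(cbind, lapply(cs$ids, function(cid)
    predict(model, dataset$stimuli[[cid]])))
  neurons <- dataset$neurons
  data.frame(
    neuron = neurons,
    cc_raw = vapply(seq_along(neurons), function(i)
      cc_raw(pred[i, ], cs$psth[neurons[i], ]), numeric(1)),
    cc_norm = vapply(seq_along(neurons), function(i)
      cc_norm(pred[i, ], cs$trials[[neurons[i]]]), numeric(1)),
    row.names = NULL)
}

# gradients of the full pipeline (model + MSE loss) for one clip; used by
# gradient-correctness tests and TBPTT equivalence checks
loss_gradients <- function(model, x, target, training = FALSE,
                           tbptt = NULL) {
  fw <- encoder_forward(model, x, training = training, tbptt = tbptt)
  d_pred <- 2 * (fw$pred - target) / length(target)
  bw <- encoder_backward(model, fw$cache, d_pred)
  list(loss = mse_loss(fw$pred, target), d_params = bw$d_params,
       d_x = bw$d_x)
}
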