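# Shared fixtures and numerical-oracle helpers. Expensive objects (trained
# models, simulated worlds) are memoised in `fix_env` so several test
# blocks can share them without re-computing.

fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fix_env)) assign(key, force(expr), envir = fix_env)
  get(key, envir = fix_env)
}

# small deterministic input matrix
tiny_x <- function(F = 8, T = 20, seed = 7) {
  set.seed(seed)
  matrix(rnorm(F * T), F, T)
}

# every architecture at toy sizes (F = 8), used by gradient/causality tests
toy_specs <- function(F = 8, N = 3) {
  list(
    linear = model_spec("linear", F, N, trf_bins = 4, seed = 1),
    ln = model_spec("ln", F, N, trf_bins = 4, seed = 2),
    nrf = model_spec("nrf", F, N, trf_bins = 4, hidden = 5, seed = 3),
    dnet = model_spec("dnet", F, N, hidden = 5, seed = 4),
    cnn2d = model_spec("cnn2d", F, N, channels = 4, seed = 5),
    transformer = model_spec("transformer", F, N, trf_bins = 5,
                             embed_dim = 8, n_heads = 2, ffn_dim = 16,
                             seed = 6),
    statenet_elman = model_spec("statenet", F, N, hidden = 6,
                                core = "elman", seed = 7),
    statenet_gru = model_spec("statenet", F, N, hidden = 6, core = "gru",
                              seed = 8),
    statenet_lstm = model_spec("statenet", F, N, hidden = 6,
                               core = "lstm", seed = 9),
    statenet_ssm = model_spec("statenet", F, N, hidden = 6, core = "ssm",
                              seed = 10)
  )
}

# central finite differences of the MSE loss wrt the input
num_grad_x <- function(model, x, target, training = FALSE, eps = 1e-5) {
  fwd <- audenc:::encoder_forward
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- xp[i, j] + eps
    xm <- x; xm[i, j] <- xm[i, j] - eps
    g[i, j] <- (mse_loss(fwd(model, xp, training = training)$pred, target) -
                mse_loss(fwd(model, xm, training = training)$pred,
                         target)) / (2 * eps)
  }
  g
}

# central finite differences wrt one named parameter
num_grad_param <- function(model, x, target, nm, training = FALSE,
                           eps = 1e-5) {
  fwd <- audenc:::encoder_forward
  p0 <- model$params[[nm]]
  g <- p0 * 0
  for (i in seq_along(p0)) {
    mp <- model; mp$params[[nm]][i] <- p0[i] + eps
    mm <- model; mm$params[[nm]][i] <- p0[i] - eps
    g[i] <- (mse_loss(fwd(mp, x, training = training)$pred, target) -
             mse_loss(fwd(mm, x, training = training)$pred, target)) /
      (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

# simulated linear-nonlinear world with a white-ish probe ensemble
# (reverse-correlation design: broad spectral coverage, no slow envelope)
ln_recovery_world <- function(n_neurons = 20, F = 16, W = 10, T = 500,
                              n_clips = 40, M = 10, ceiling = 0.8) {
  stims <- generate_stimuli(F, T, n_clips, smoothness = c(0.5, 0.5),
                            envelope = NULL, seed = 10)
  strfs <- random_strfs(n_neurons, F, W, seed = 11)
  noise_free <- synthetic_truth(strfs,
                                noise = list(type = "gaussian", sigma = 0),
                                seed = 12)
  rates <- do.call(cbind, lapply(stims, function(x)
    audenc:::noise_free_rates(audenc:::coch_values(x), noise_free)))
  sig <- calibrate_noise_sigma(rates, M, ceiling)
  truth <- synthetic_truth(strfs,
                           noise = list(type = "gaussian", sigma = sig),
                           seed = 12)
  ds <- split_dataset(simulate_neurons(stims, truth, M = M), seed = 13)
  list(dataset = ds, strfs = strfs, sigma = sig)
}

# simulated adaptive worlds (naturalistic stimuli with slow envelope)
adaptive_world <- function(type, tau, gamma, n_neurons = 6, F = 16,
                           T = 400, n_clips = 20, M = 8, ceiling = 0.95,
                           seed = 30) {
  stims <- generate_stimuli(F, T, n_clips, seed = seed)
  strfs <- random_strfs(n_neurons, F, 10, seed = seed + 1)
  adapt <- list(type = type, tau = tau, gamma = gamma)
  noise_free <- synthetic_truth(strfs, adaptation = adapt,
                                noise = list(type = "gaussian", sigma = 0),
                                seed = seed + 2)
  rates <- do.call(cbind, lapply(stims, function(x)
    audenc:::noise_free_rates(audenc:::coch_values(x), noise_free)))
  sig <- calibrate_noise_sigma(rates, M, ceiling)
  truth <- synthetic_truth(strfs, adaptation = adapt,
                           noise = list(type = "gaussian", sigma = sig),
                           seed = seed + 2)
  split_dataset(simulate_neurons(stims, truth, M = M), seed = seed + 3)
}

long_memory_world <- function() {
  memo("lm_world", adaptive_world("long_memory", tau = 50, gamma = 0.6,
                                  seed = 30))
}

gain_control_world <- function() {
  memo("gc_world", adaptive_world("gain_control", tau = 200, gamma = 0.3,
                                  T = 600, ceiling = 0.9, seed = 20))
}

# GRU statenet trained on the long-memory world (memoised per variant)
trained_gru <- function(seed, tbptt = NULL, max_epochs = 200) {
  key <- sprintf("gru_s%d_%s", seed,
                 if (is.null(tbptt)) "full"
                 else sprintf("K%d_%s", tbptt$K, tbptt$warmup))
  memo(key, {
    ds <- long_memory_world()
    fit_encoder(ds, model_spec("statenet", 16, length(ds$neurons),
                               hidden = 16, core = "gru"),
                train_config(max_epochs = max_epochs, tbptt = tbptt),
                seed = seed)
  })
}

mean_test_ccnorm <- function(fit) {
  mean(fit$metrics$cc_norm[fit$metrics$split == "test"])
}
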