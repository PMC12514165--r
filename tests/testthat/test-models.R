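# Architecture contracts: the output nonlinearity, LC layer geometry,
# build determinism, causality, stepwise equivalence, BN absorption,
# parameter-count scaling and the SSM discretisation oracle.

test_that("double_exponential matches its closed form and limits", {
  # x = s/k gives a * exp(-1) + b
  expect_equal(double_exponential(2, a = 1.5, b = 0.2, k = 3, s = 6),
               1.5 * exp(-1) + 0.2)
  # k > 0: f -> b as x -> +Inf, f -> a + b as x -> -Inf
  expect_equal(double_exponential(1e6, a = 2, b = 0.3, k = 1, s = 0), 0.3)
  expect_equal(double_exponential(-1e6, a = 2, b = 0.3, k = 1, s = 0),
               2.3)
  # overflow guard: huge inner exponents stay finite
  expect_true(is.finite(double_exponential(1e300, k = 1e10)))
})

test_that("locally connected projection degenerates to FC and identity", {
  F <- 6
  v <- rnorm(F)
  # k = F, stride = F, H = 1: one fully connected row
  w <- matrix(rnorm(F), 1, F)
  expect_equal(locally_connected_project(v, w, 0.5, stride = F),
               as.numeric(w %*% v) + 0.5)
  # k = 1, stride = 1, unit kernels, zero bias: identity
  expect_equal(locally_connected_project(v, matrix(1, F, 1), numeric(F)),
               v)
  expect_error(locally_connected_project(v, matrix(1, 1, F + 1), 0),
               class = "audenc_argument_error")
  # parameter count H*(k+1) sits strictly between CONV and FC
  k <- 3; stride <- 1
  H <- nrow(audenc:::lc_geometry(F, k, stride))
  lc_count <- H * (k + 1)
  expect_gt(lc_count, k + 1)          # shared-kernel convolution
  expect_lt(lc_count, H * (F + 1))    # fully connected
})

test_that("build_model is seed-deterministic and scalar linear maps are exact", {
  sp <- model_spec("nrf", 8, 3, trf_bins = 4, seed = 11)
  m1 <- build_model(sp); m2 <- build_model(sp)
  expect_identical(m1$params, m2$params)
  # linear model, W = 1, weight 2, bias 0: doubles the input
  m <- build_model(model_spec("linear", 1, 1, trf_bins = 1))
  m$params$W <- matrix(2, 1, 1); m$params$b <- 0
  expect_equal(predict(m, matrix(c(1, 3), 1)), matrix(c(2, 6), 1))
  # statenet ignores trf_bins: single-bin input window
  expect_equal(model_spec("statenet", 8, 2, trf_bins = 40)$trf_bins, 1L)
  expect_equal(model_spec("dnet", 8, 2, trf_bins = 40)$trf_bins, 5L)
})

test_that("every architecture is causal in inference mode", {
  x <- tiny_x(8, 30, seed = 1)
  t0 <- 17
  x2 <- x
  x2[, t0] <- x2[, t0] + 1
  for (nm in names(toy_specs())) {
    m <- build_model(toy_specs()[[nm]])
    p1 <- predict(m, x)
    p2 <- predict(m, x2)
    expect_identical(p1[, 1:(t0 - 1)], p2[, 1:(t0 - 1)],
                     label = paste("causality:", nm))
    expect_gt(max(abs(p1[, t0:30] - p2[, t0:30])), 0)
    expect_equal(dim(p1), c(3L, 30L))
  }
  # stateless model with window W: bins older than W cannot matter
  m <- build_model(model_spec("linear", 8, 2, trf_bins = 4, seed = 3))
  x3 <- x; x3[, 5] <- x3[, 5] + 1
  p1 <- predict(m, x)
  p3 <- predict(m, x3)
  expect_identical(p1[, 9:30], p3[, 9:30])
})

test_that("all-zero input with zero weights yields the Eq-1 constant", {
  m <- build_model(model_spec("ln", 4, 2, trf_bins = 3, seed = 2))
  m$params$W[] <- 0; m$params$b[] <- 0
  pred <- predict(m, matrix(0, 4, 10))
  a <- m$params$nl.a; b <- m$params$nl.b; s <- m$params$nl.s
  expect_equal(pred[, 1], a * exp(-exp(-s)) + b)
  expect_equal(pred, matrix(pred[, 1], 2, 10))
})

test_that("statenet stepping reproduces the whole-sequence forward exactly", {
  x <- tiny_x(8, 25, seed = 4)
  for (core in c("elman", "gru", "lstm", "ssm")) {
    m <- build_model(model_spec("statenet", 8, 3, hidden = 6, core = core,
                                seed = 5))
    full <- predict(m, x)
    st <- NULL
    step <- matrix(0, 3, 25)
    for (t in 1:25) {
      out <- encoder_step(m, x[, t], st)
      step[, t] <- out$rates
      st <- out$state
    }
    expect_lt(max(abs(full - step)), 1e-6, label = paste("step:", core))
  }
  # carrying the state across two clips differs from resetting it
  m <- build_model(model_spec("statenet", 8, 3, hidden = 6, core = "gru",
                              seed = 5))
  xa <- tiny_x(8, 20, seed = 6); xb <- tiny_x(8, 20, seed = 7)
  carried <- audenc:::fw_statenet(m, xb, training = FALSE,
                                  state0 = audenc:::fw_statenet(
                                    m, xa, training = FALSE)$final_state)$pred
  reset <- predict(m, xb)
  expect_gt(max(abs(carried - reset)), 0)
  # state-shape mismatch errors
  expect_error(encoder_step(m, x[, 1], list(h = numeric(2))),
               class = "audenc_argument_error")
  expect_error(encoder_step(m, numeric(3)),
               class = "audenc_argument_error")
})

test_that("inference-mode batch normalisation folds into plain linear weights", {
  ds <- split_dataset(local({
    stims <- generate_stimuli(6, 60, 6, seed = 8)
    strfs <- random_strfs(2, 6, 3, seed = 9)
    simulate_neurons(stims, synthetic_truth(
      strfs, noise = list(type = "gaussian", sigma = 0.1), seed = 10),
      M = 3)
  }), seed = 1)
  fit <- fit_encoder(ds, model_spec("linear", 6, 2, trf_bins = 3,
                                    use_bn = TRUE),
                     train_config(max_epochs = 10, patience = 10),
                     seed = 1)
  x <- audenc:::coch_values(ds$stimuli[[1]])
  plain <- absorb_bn(fit$model)
  expect_lt(max(abs(predict(fit$model, x) - predict(plain, x))), 1e-5)
})

test_that("parameter counts grow with W for stateless models but not statenet", {
  counts <- vapply(c(5, 10, 20), function(W)
    count_params(build_model(model_spec("linear", 16, 4, trf_bins = W))),
    numeric(1))
  expect_equal(diff(counts), c(5 * 16 * 4, 10 * 16 * 4))
  sn <- vapply(c(5, 10, 20), function(W)
    count_params(build_model(model_spec("statenet", 16, 4, trf_bins = W,
                                        hidden = 8, core = "gru"))),
    numeric(1))
  expect_equal(sn[1], sn[2])
  expect_equal(sn[2], sn[3])
})

test_that("the ssm core equals a naive discretised state-space recurrence", {
  G <- 5; In <- 4; Tn <- 10
  m <- build_model(model_spec("statenet", 8, 2, hidden = G, core = "ssm",
                              seed = 12))
  cp <- audenc:::core_params(m$params)
  set.seed(13)
  U <- matrix(rnorm(In * Tn), In, Tn)
  states <- audenc:::core_forward_cpp("ssm", cp, U)$states
  # independent oracle: zero-order-hold discretisation written as a plain
  # R loop over time
  lambda <- -exp(cp$a_log)
  Delta <- exp(cp$logdt)
  Abar <- exp(Delta * lambda)
  coef <- (Abar - 1) / lambda
  s <- numeric(G)
  Y <- matrix(0, G, Tn)
  for (t in seq_len(Tn)) {
    s <- Abar * s + coef * (cp$B %*% U[, t])
    Y[, t] <- cp$C %*% s + cp$D %*% U[, t]
  }
  expect_lt(max(abs(states - Y)), 1e-8)
})
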