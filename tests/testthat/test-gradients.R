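# Analytic gradients of the full pipeline (encoder + MSE loss) against
# central finite differences, for every architecture, in both inference
# and training (batch-statistics) mode. Full input gradients are checked
# everywhere; parameter gradients are checked for a rotating subset of
# parameters to keep the run fast.

test_that("analytic gradients match finite differences for every architecture", {
  x <- tiny_x(8, 14, seed = 21)
  set.seed(22)
  target <- matrix(rnorm(3 * 14), 3, 14)
  lg <- audenc:::loss_gradients
  specs <- toy_specs()
  for (nm in names(specs)) {
    m <- build_model(specs[[nm]])
    for (training in c(FALSE, TRUE)) {
      an <- lg(m, x, target, training = training)
      gx <- num_grad_x(m, x, target, training = training)
      expect_lt(rel_err(an$d_x, gx), 1e-4,
                label = sprintf("d_x %s (training=%s)", nm, training))
      pns <- names(m$params)
      check <- pns[seq(1, length(pns), length.out = min(4, length(pns)))]
      for (pn in check) {
        gp <- num_grad_param(m, x, target, pn, training = training)
        expect_lt(rel_err(an$d_params[[pn]], gp), 1e-4,
                  label = sprintf("%s / %s (training=%s)", nm, pn,
                                  training))
      }
    }
  }
})

test_that("TBPTT gradients are exact truncations of the unrolled graph", {
  x <- tiny_x(6, 30, seed = 23)
  set.seed(24)
  target <- matrix(rnorm(2 * 30), 2, 30)
  lg <- audenc:::loss_gradients
  for (core in c("gru", "ssm")) {
    m <- build_model(model_spec("statenet", 6, 2, hidden = 5, core = core,
                                seed = 25))
    # K = T with warmup: parameter gradients equal full BPTT
    full <- lg(m, x, target)
    ktw <- lg(m, x, target, tbptt = list(K = 30, warmup = TRUE))
    for (pn in names(full$d_params))
      expect_lt(max(abs(full$d_params[[pn]] - ktw$d_params[[pn]])), 1e-6,
                label = sprintf("K=T %s %s", core, pn))
    # no-warmup forward/backward agree with finite differences of the
    # truncated-forward loss
    tb <- list(K = 3, warmup = FALSE)
    an <- lg(m, x, target, tbptt = tb)
    fwd <- audenc:::encoder_forward
    eps <- 1e-5
    num <- matrix(0, 6, 30)
    for (i in 1:6) for (j in seq(1, 30, by = 3)) {
      xp <- x; xp[i, j] <- xp[i, j] + eps
      xm <- x; xm[i, j] <- xm[i, j] - eps
      num[i, j] <- (mse_loss(fwd(m, xp, tbptt = tb)$pred, target) -
                    mse_loss(fwd(m, xm, tbptt = tb)$pred, target)) /
        (2 * eps)
    }
    sel <- num != 0
    expect_lt(max(abs(an$d_x[sel] - num[sel])) / max(abs(num[sel])), 1e-4,
              label = paste("nowarmup d_x", core))
  }
})

test_that("K = 1 without warmup makes the gradient at bin t local to x_t", {
  m <- build_model(model_spec("statenet", 6, 2, hidden = 5, core = "gru",
                              seed = 26))
  x <- tiny_x(6, 20, seed = 27)
  fwd <- audenc:::encoder_forward
  tb <- list(K = 1, warmup = FALSE)
  base <- fwd(m, x, tbptt = tb)$pred
  # finite perturbation at bin 8 leaves every other bin untouched
  x2 <- x; x2[, 8] <- x2[, 8] + 0.5
  pert <- fwd(m, x2, tbptt = tb)$pred
  expect_identical(base[, -8], pert[, -8])
  expect_gt(max(abs(base[, 8] - pert[, 8])), 0)
})
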