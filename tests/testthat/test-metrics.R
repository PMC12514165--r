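# Raw and noise-corrected correlation metrics and their exact identities.

test_that("cc_raw matches Pearson correlation and handles degenerate input", {
  set.seed(51)
  a <- rnorm(100); b <- a + rnorm(100)
  expect_equal(cc_raw(a, b), cor(a, b))
  expect_equal(cc_raw(b, b), 1)
  expect_equal(cc_raw(-b, b), -1)
  # hand-computed small case
  expect_equal(cc_raw(c(1, 2, 3), c(1, 2, 4)), cor(1:3, c(1, 2, 4)))
  expect_warning(z <- cc_raw(rep(1, 5), 1:5))
  expect_equal(z, 0)
  expect_error(cc_raw(1:3, 1:4), class = "audenc_argument_error")
})

test_that("signal power obeys its analytic identities", {
  # identical trials: SP = Var(r) exactly (population variance)
  r <- c(0, 1, 2)
  expect_equal(signal_power(rbind(r, r)), audenc:::pop_var(r))
  tr <- matrix(rnorm(40), 4, 10)
  same <- tr[rep(1, 5), ]
  expect_equal(signal_power(same), audenc:::pop_var(tr[1, ]))
  expect_error(signal_power(matrix(1, 1, 5)),
               class = "audenc_argument_error")
  # pure iid noise: SP is centred on zero across replicates
  set.seed(52)
  sps <- replicate(100, signal_power(matrix(rnorm(10 * 2000), 10)))
  expect_lt(abs(mean(sps)), 3 * sd(sps) / sqrt(100))
})

test_that("cc_norm implements the single-trial rule and affine invariance", {
  set.seed(53)
  rate <- sin(seq_len(500) / 20)
  # M = 1: cc_norm == cc_raw by the single-trial convention
  one <- matrix(rate + rnorm(500, sd = 0.3), 1)
  pred <- rate + rnorm(500, sd = 0.1)
  expect_equal(cc_norm(pred, one), cc_raw(pred, one[1, ]))
  # noiseless trials, prediction = rate: exactly 1
  clean <- rbind(rate, rate, rate)
  expect_equal(cc_norm(rate, clean), 1)
  # affine invariance in the prediction
  noisy <- rbind(rate, rate) + matrix(rnorm(1000, sd = 0.5), 2)
  expect_equal(cc_norm(2 * pred + 5, noisy), cc_norm(pred, noisy))
  # non-positive signal power: flagged, policy value 0
  flat <- matrix(rnorm(2 * 50), 2)
  sp <- signal_power(flat)
  if (sp <= 0) {
    expect_warning(z <- cc_norm(rnorm(50), flat))
    expect_equal(z, 0)
  }
  expect_error(cc_norm(1:5, matrix(0, 2, 4)),
               class = "audenc_argument_error")
})

test_that("the noise correction recovers the ceiling on simulated neurons", {
  set.seed(54)
  Tn <- 5000; M <- 10
  rate <- as.numeric(audenc:::hanning_smooth(rnorm(Tn), 21))
  sigma <- 2 * sd(rate)
  trials <- matrix(rep(rate, each = M), M) +
    matrix(rnorm(M * Tn, sd = sigma), M)
  ccn <- cc_norm(rate, trials)
  ccr <- cc_raw(rate, colMeans(trials))
  expect_true(ccn >= 0.95 && ccn <= 1.05)
  expect_lt(ccr, 1)
  expect_gt(ccn, ccr)  # SP < Var(r) under noise, so the correction lifts
})
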