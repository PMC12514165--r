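# PSTH computation, Hanning smoothing, MedGauss detrending.

test_that("hanning_smooth is a unit-sum, symmetric, shape-preserving smoother", {
  # constant signals pass through unchanged (unit-sum kernel)
  expect_equal(hanning_smooth(rep(3.7, 50), 21), rep(3.7, 50))
  # window 1 is the identity
  v <- rnorm(30)
  expect_identical(hanning_smooth(v, 1), v)
  # unit impulse: response sums to 1 and is symmetric about the impulse
  imp <- numeric(101); imp[51] <- 1
  sm <- hanning_smooth(imp, 21)
  expect_equal(sum(sm), 1)
  expect_equal(sm[51 + 1:10], sm[51 - 1:10])
  # direct kernel computation: the impulse response IS the kernel
  i <- 0:20
  kern <- 0.5 * (1 - cos(2 * pi * i / 20))
  kern <- kern / sum(kern)
  expect_equal(sm[41:61], kern)
  expect_error(hanning_smooth(v, 4), class = "audenc_argument_error")
})

test_that("compute_psth averages trials and is linear in them", {
  expect_equal(compute_psth(rbind(c(0, 2), c(2, 0)), 1), c(1, 1))
  tr <- matrix(rnorm(5 * 40), 5)
  expect_equal(compute_psth(tr[1, , drop = FALSE], 1), tr[1, ])
  # linearity for window = 1
  expect_equal(compute_psth(3 * tr, 1), 3 * compute_psth(tr, 1))
  # Monte-Carlo: 200 unit-rate noisy trials, 21-bin window -> within 0.1
  set.seed(1)
  noisy <- matrix(1 + rnorm(200 * 300, sd = 0.5), 200)
  expect_true(all(abs(compute_psth(noisy, 21) - 1) < 0.1))
  expect_error(compute_psth(matrix(numeric(0), 0, 0)),
               class = "audenc_argument_error")
})

test_that("detrend_medgauss removes slow drift but preserves fast structure", {
  set.seed(2)
  n <- 3000
  fast <- sin(2 * pi * seq_len(n) / 40)
  # drift-free zero-mean trace passes through almost unchanged (edges
  # excluded: the running median's endrule distorts the first/last
  # window)
  out0 <- detrend_medgauss(fast, 201, 50)
  interior <- 202:(n - 201)
  expect_lt(max(abs(out0[interior] - fast[interior])), 0.1)
  # additive linear ramp: residual slope is < 5 percent of the original
  slope <- 5 / n
  ramp <- slope * seq_len(n)
  out <- detrend_medgauss(fast + ramp, 201, 50)
  fit <- coef(lm(out ~ seq_len(n)))[2]
  expect_lt(abs(fit), 0.05 * slope)
  # fast sinusoid (period 40 << median width 201) keeps >= 90 % amplitude
  amp_ratio <- sd(out - mean(out)) / sd(fast)
  expect_gt(amp_ratio, 0.9)
  expect_error(detrend_medgauss(fast, n + 1, 50),
               class = "audenc_argument_error")
})
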