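# Synthetic stimulus generator and ground-truth neuron simulator.

test_that("generate_stimuli honours its shape, determinism and smoothness contracts", {
  stims <- generate_stimuli(16, 500, 5, seed = 0)
  expect_length(stims, 5)
  for (s in stims) {
    expect_s3_class(s, "cochleagram")
    expect_equal(dim(s), c(16L, 500L))
    expect_true(all(is.finite(s)))
    expect_gt(sd(s), 0)
  }
  # same seed twice -> bit-identical
  again <- generate_stimuli(16, 500, 5, seed = 0)
  expect_identical(lapply(stims, audenc:::coch_values),
                   lapply(again, audenc:::coch_values))
  # temporal correlation decays: lag-1 autocorrelation > lag-20, averaged
  # over frequency bands
  ac <- function(v, lag) cor(v[seq_len(length(v) - lag)], v[-seq_len(lag)])
  v <- audenc:::coch_values(stims[[1]])
  lag1 <- mean(vapply(seq_len(16), function(f) ac(v[f, ], 1), numeric(1)))
  lag20 <- mean(vapply(seq_len(16), function(f) ac(v[f, ], 20), numeric(1)))
  expect_gt(lag1, lag20)
  expect_error(generate_stimuli(0, 10, 1), class = "audenc_argument_error")
  expect_error(generate_stimuli(4, 10, 1, smoothness = c(0, 1)),
               class = "audenc_argument_error")
})

test_that("simulate_neurons reproduces the LN pipeline and its degenerate cases", {
  stims <- generate_stimuli(6, 80, 2, seed = 1)
  # all-zero STRF: noise-free rate constant at double_exponential(0)
  tr0 <- synthetic_truth(list(matrix(0, 6, 4)),
                         noise = list(type = "gaussian", sigma = 0))
  ds0 <- simulate_neurons(stims, tr0, M = 2)
  p <- tr0$output_params[1, ]
  expect_equal(as.numeric(ds0$psth[[1]]),
               rep(unname(double_exponential(0, p["a"], p["b"], p["k"],
                                             p["s"])), 80))
  # sigma = 0: all trials identical and equal to the PSTH
  strfs <- random_strfs(3, 6, 4, seed = 2)
  tr <- synthetic_truth(strfs, noise = list(type = "gaussian", sigma = 0))
  ds <- simulate_neurons(stims, tr, M = 3)
  trials <- ds$responses[[1]][[1]]
  expect_equal(trials[1, ], trials[2, ])
  expect_equal(trials[1, ], ds$psth[[1]][1, ])
  # simulator consistency: with adaptation none / sigma 0 the PSTH equals
  # the STRF convolution + double exponential evaluated directly
  x <- audenc:::coch_values(stims[[1]])
  xl <- audenc:::lag_design(x, 4)
  for (n in 1:3) {
    L <- as.numeric(t(as.numeric(strfs[[n]])) %*% xl)
    pp <- tr$output_params[n, ]
    direct <- double_exponential(L, pp["a"], pp["b"], pp["k"], pp["s"])
    expect_lt(max(abs(ds$psth[[1]][n, ] - direct)), 1e-10)
  }
  # Monte-Carlo: trial mean converges to the noise-free rate
  sig <- 0.5; M <- 20
  trn <- synthetic_truth(strfs, noise = list(type = "gaussian", sigma = sig),
                         seed = 5)
  dsn <- simulate_neurons(stims, trn, M = M)
  for (n in 1:3)
    expect_lt(max(abs(dsn$psth[[1]][n, ] - ds$psth[[1]][n, ])),
              3 * sig / sqrt(M) * 4)  # 3 sigma/sqrt(M) per bin, slack for max
  # STRF wider than the clip errors
  expect_error(simulate_neurons(stims,
                                synthetic_truth(list(matrix(0, 6, 99))),
                                M = 2),
               class = "audenc_argument_error")
})

test_that("gain-control gain is depressed during high-contrast epochs", {
  # two-epoch stimulus: quiet then loud; mean gain must drop in the loud
  # epoch (gamma > 0)
  x <- rbind(matrix(0.2, 1, 400))
  x[1, 201:400] <- 2
  g <- audenc:::gain_trace(x, tau = 100, gamma = 0.5)
  expect_lt(mean(g[201:400]), mean(g[1:200]))
  expect_true(all(g >= 0))
})

test_that("long-memory component extends dependence beyond the STRF window", {
  stims <- generate_stimuli(6, 300, 1, seed = 3)
  strfs <- random_strfs(1, 6, 4, seed = 4)
  tr <- synthetic_truth(strfs,
                        adaptation = list(type = "long_memory", tau = 40,
                                          gamma = 0.8),
                        noise = list(type = "gaussian", sigma = 0))
  x <- audenc:::coch_values(stims[[1]])
  r1 <- audenc:::noise_free_rates(x, tr)
  # perturb the stimulus 100 bins in the past (far beyond W = 4)
  x2 <- x
  x2[, 50] <- x2[, 50] + 5
  r2 <- audenc:::noise_free_rates(x2, tr)
  expect_gt(max(abs(r2[, 150] - r1[, 150])), 0)
})

test_that("poisson noise produces integer counts around the rate", {
  stims <- generate_stimuli(6, 120, 1, seed = 6)
  strfs <- random_strfs(1, 6, 4, seed = 7)
  tr <- synthetic_truth(strfs, noise = list(type = "poisson"), seed = 8)
  ds <- simulate_neurons(stims, tr, M = 50)
  trials <- ds$responses[[1]][[1]]
  expect_true(all(trials == round(trials)))
  rate <- ds$true_rates[[1]][1, ]
  expect_lt(mean(abs(colMeans(trials) - pmax(rate, 0))),
            3 * sqrt(mean(rate)) / sqrt(50))
})

test_that("calibrate_noise_sigma hits the requested raw-correlation ceiling", {
  set.seed(9)
  rate <- sin(seq_len(4000) / 30) + 0.3 * rnorm(4000)
  M <- 10
  sig <- calibrate_noise_sigma(rate, M, target_ceiling = 0.8)
  psth <- rate + colMeans(matrix(rnorm(M * 4000, sd = sig), M))
  expect_equal(cc_raw(rate, psth), 0.8, tolerance = 0.05)
})
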