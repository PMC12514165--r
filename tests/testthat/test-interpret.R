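# GradMaps, Dreams, energy traces, similarity matrices and dream-length
# curves.

# a small trained-ish linear model with known weights
known_linear <- function(F = 6, W = 4, N = 2, seed = 61) {
  m <- build_model(model_spec("linear", F, N, trf_bins = W, seed = seed))
  set.seed(seed)
  m$params$W <- matrix(rnorm(N * F * W, sd = 0.3), N, F * W)
  m
}

# expected gradmap of a linear model: minus the STRF laid out so lag w-1
# lands at column T - (w - 1)
linear_oracle_map <- function(m, n, T) {
  F <- m$spec$n_freqs; W <- m$spec$trf_bins
  g <- matrix(0, F, T)
  strf <- matrix(m$params$W[n, ], F, W)
  for (w in seq_len(min(W, T)))
    g[, T - w + 1] <- g[, T - w + 1] - strf[, w]
  g
}

test_that("the GradMap of a linear model is its STRF layout, zero beyond W", {
  m <- known_linear()
  Tn <- 12
  g <- gradmap(m, target = 1, T = Tn)
  expect_equal(unclass(g), linear_oracle_map(m, 1, Tn),
               ignore_attr = TRUE)
  # zero at latencies beyond the window
  expect_true(all(g[, 1:(Tn - m$spec$trf_bins)] == 0))
  # probe independence for a purely linear model
  set.seed(62)
  g2 <- gradmap(m, target = 1, T = Tn,
                probe = matrix(rnorm(6 * Tn), 6, Tn))
  expect_equal(unclass(g), unclass(g2))
  # duplicated targets average to the same map
  expect_equal(unclass(gradmap(m, target = c(1, 1), T = Tn)),
               unclass(g), ignore_attr = TRUE)
  expect_error(gradmap(m, target = integer(0)),
               class = "audenc_argument_error")
})

test_that("gradmaps match finite differences of the activation loss", {
  # finite-difference oracle on the interpretation loss itself (not the
  # training loss): L = -mean target activation at the last bin
  probe_T <- 10
  for (nm in c("ln", "cnn2d", "statenet_gru")) {
    m <- build_model(toy_specs()[[nm]])
    g <- gradmap(m, target = 2, T = probe_T)
    num <- matrix(0, 8, probe_T)
    eps <- 1e-4
    for (i in 1:8) for (j in 1:probe_T) {
      xp <- matrix(0, 8, probe_T); xp[i, j] <- eps
      xm <- matrix(0, 8, probe_T); xm[i, j] <- -eps
      num[i, j] <- (-predict(m, xp)[2, probe_T] +
                    predict(m, xm)[2, probe_T]) / (2 * eps)
    }
    expect_lt(rel_err(unclass(g), num), 1e-4, label = nm)
  }
})

test_that("one plain gradient dream step equals the closed-form update", {
  m <- known_linear()
  alpha <- 0.05
  d <- dream(m, target = 1, T = 10, n_iters = 1, lr = alpha,
             optimizer = "sgd")
  expect_equal(d$stimulus, -alpha * linear_oracle_map(m, 1, 10))
  expect_equal(d$n_iterations, 1)
})

test_that("dreams increase the target activation and default to 1500 iterations", {
  m <- build_model(toy_specs()$statenet_gru)
  d <- dream(m, target = 1, T = 15, n_iters = 40)
  act0 <- predict(m, matrix(0, 8, 15))[1, 15]
  actn <- predict(m, d$stimulus)[1, 15]
  expect_gt(actn, act0)
  expect_length(d$loss_trajectory, 40)
  # loss records the objective: first entry is the null-stimulus loss
  expect_equal(d$loss_trajectory[1], -act0)
  expect_equal(formals(dream)$n_iters, 1500L)
  # monotone non-increasing loss for plain gradient descent on a linear
  # model with a small step
  lm2 <- known_linear()
  dl <- dream(lm2, target = 1, T = 10, n_iters = 30, lr = 1e-3,
              optimizer = "sgd")
  expect_true(all(diff(dl$loss_trajectory) <= 1e-12))
})

test_that("gradmap energy matches the per-latency mean-square definition", {
  z <- matrix(0, 4, 6)
  expect_equal(as.numeric(gradmap_energy(z)), rep(0, 6))
  expect_warning(gradmap_energy(z, normalize = TRUE))
  # single entry v at (f0, t0): E = v^2 / F at that latency
  z[3, 2] <- 2
  e <- gradmap_energy(z)
  # v^2 / F = 4/4 = 1 at column 2, i.e. latency 4 (element 5 of the trace)
  expect_equal(as.numeric(e), c(0, 0, 0, 0, 1, 0))
  set.seed(63)
  g <- matrix(rnorm(24), 4, 6)
  # brute-force two-loop oracle
  ref <- numeric(6)
  for (t in 1:6) {
    acc <- 0
    for (f in 1:4) acc <- acc + g[f, t]^2
    ref[t] <- acc / 4
  }
  expect_equal(as.numeric(gradmap_energy(g)), rev(ref))
  en <- gradmap_energy(g, normalize = TRUE)
  expect_equal(max(en), 1)
})

test_that("gradmap similarity is affine-invariant, symmetric, unit-diagonal", {
  set.seed(64)
  base <- lapply(1:3, function(i) matrix(rnorm(40), 5, 8))
  maps <- list(a = base,
               b = lapply(base, function(m) 2.5 * m + 1),   # affine
               c = lapply(base, function(m) -m),            # negation
               d = lapply(1:3, function(i) matrix(rnorm(40), 5, 8)))
  S <- similarity_matrix(maps)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(S, t(S))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  expect_lt(abs(S["a", "d"]), 0.5)
  bad <- maps
  bad$d <- lapply(1:3, function(i) matrix(0, 4, 8))
  expect_error(similarity_matrix(bad), class = "audenc_argument_error")
})

test_that("stateless dream-length curves are flat beyond the window", {
  m <- build_model(model_spec("ln", 6, 2, trf_bins = 4, seed = 65))
  cur <- dream_length_curve(m, targets = 1, lengths = c(2, 4, 6, 9),
                            n_iters = 300, converge_tol = 1e-5)
  expect_equal(max(cur$normalized), 1)
  # beyond W = 4, adding older bins cannot change the attainable
  # activation
  plateau <- cur$activation[cur$length >= 4]
  expect_lt(diff(range(plateau)) / max(abs(plateau)), 1e-3)
})
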