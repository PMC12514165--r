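#' Generate naturalistic synthetic cochleagrams
#'
#' Draws Gaussian white noise on an `F x T` grid, smooths it separably in
#' frequency and time with Gaussian kernels, standardises it and passes it
#' through a softplus to enforce non-negativity. The result has the two
#' statistics that matter for encoding-model benchmarks on natural sounds:
#' smooth local correlations that decay with frequency and time separation,
#' and strictly positive "compressed power" values.
#'
#' @param F number of frequency bands.
#' @param T number of time bins per clip.
#' @param n_clips number of clips to generate.
#' @param smoothness length-2 numeric `(freq_scale, time_scale)`: Gaussian
#'   smoothing standard deviations in bins. Defaults `c(1.5, 2)`.
#' @param broadband fraction (as a standard-deviation weight in `[0, 1)`)
#'   of unsmoothed white noise mixed into the field before the softplus.
#'   Natural cochleagrams carry broadband fine structure ("speckle") on
#'   top of their smooth envelope; a strictly low-pass Gaussian field
#'   would have a rank-deficient second-order structure that no real
#'   stimulus ensemble has. Default `0.3` (9 percent of the variance).
#' @param envelope `NULL` to disable, or
#'   `list(scale_bins = <smoothing sd>, depth = <log-amplitude sd>)`
#'   describing a slow multiplicative amplitude envelope shared by all
#'   frequency bands (default 60 bins, depth 0.5). Natural sounds have
#'   pronounced slow amplitude modulation; the envelope makes stimulus
#'   contrast fluctuate on adaptation timescales, which is what renders
#'   gain-control dynamics observable.
#' @param dt time-bin duration in seconds.
#' @param seed integer seed; the same seed yields bit-identical clips.
#' @return list of `n_clips` [cochleagram] objects.
#' @examples
#' stims <- generate_stimuli(16, 200, 2, seed = 1)
#' @export
generate_stimuli <- function(F, T, n_clips, smoothness = c(1.5, 2),
                             broadband = 0.3,
                             envelope = list(scale_bins = 60, depth = 0.5),
                             dt = 0.005, seed = 1L) {
  if (F < 1 || T < 1 || n_clips < 1)
    stop_arg("F, T and n_clips must all be >= 1")
  if (any(smoothness <= 0)) stop_arg("smoothness scales must be > 0")
  if (broadband < 0 || broadband >= 1)
    stop_arg("broadband must be in [0, 1)")
  with_seed(seed, {
    lapply(seq_len(n_clips), function(i) {
      z <- matrix(rnorm(F * T), F, T)
      z <- gauss_smooth_mat(z, smoothness[1], along = "rows")
      z <- gauss_smooth_mat(z, smoothness[2], along = "cols")
      z <- (z - mean(z)) / max(sd(z), 1e-12)
      if (broadband > 0)
        z <- sqrt(1 - broadband^2) * z +
          broadband * matrix(rnorm(F * T), F, T)
      vals <- log1p(exp(pmin(z, 30)))  # softplus
      if (!is.null(envelope)) {
        e <- rnorm(T)
        half <- max(1L, min(T - 1L, ceiling(3 * envelope$scale_bins)))
        kern <- stats::dnorm(seq(-half, half), sd = envelope$scale_bins)
        e <- reflect_convolve(e, kern / sum(kern))
        e <- (e - mean(e)) / max(sd(e), 1e-12)
        vals <- vals * rep(exp(envelope$depth * e), each = F)
      }
      cochleagram(vals, dt = dt, clip_id = sprintf("clip%03d", i))
    })
  })
}

# separable Gaussian smoothing of a matrix along rows (frequency) or
# columns (time), reflection-padded
gauss_smooth_mat <- function(z, sigma, along = c("rows", "cols")) {
  along <- match.arg(along)
  n <- if (along == "rows") nrow(z) else ncol(z)
  half <- max(1L, min(n - 1L, ceiling(3 * sigma)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  if (along == "rows") apply(z, 2, reflect_convolve, kern = kern)
  else t(apply(z, 1, reflect_convolve, kern = kern))
}

#' Ground truth for simulated linear-nonlinear neurons
#'
#' Bundles everything the simulator needs to produce responses with a known
#' generative model: per-neuron STRFs, double-exponential output
#' nonlinearity parameters, an optional adaptation mechanism and a trial
#' noise model. The object is stored alongside the simulated dataset so
#' recovery tests can compare fitted models against the truth.
#'
#' @param strfs list of `F x W` STRF matrices, one per neuron (column `w`
#'   is lag `w - 1` bins in the past).
#' @param output_params `N x 4` matrix (columns `a`, `b`, `k`, `s`) of
#'   double-exponential parameters, or `NULL` for the package default
#'   `a = 2, b = 0.05, k = -1, s = 0` (an increasing saturating rate).
#' @param adaptation list with `type` in `"none"`, `"gain_control"`,
#'   `"long_memory"`, time constant `tau` (bins) and strength
#'   `gamma` in `[0, 1]`.
#' @param noise list with `type` in `"gaussian"`, `"poisson"` and, for
#'   Gaussian noise, the standard deviation `sigma`.
#' @param seed integer seed used when simulating trials.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(strfs,
                            output_params = NULL,
                            adaptation = list(type = "none", tau = 100,
                                              gamma = 0),
                            noise = list(type = "gaussian", sigma = 0.2),
                            seed = 1L) {
  if (!is.list(strfs) || !length(strfs)) stop_arg("strfs must be a list")
  n <- length(strfs)
  if (is.null(output_params))
    output_params <- matrix(rep(c(2, 0.05, -1, 0), each = n), n, 4,
                            dimnames = list(NULL, c("a", "b", "k", "s")))
  output_params <- as.matrix(output_params)
  colnames(output_params) <- c("a", "b", "k", "s")
  adaptation <- modifyList(list(type = "none", tau = 100, gamma = 0),
                           adaptation)
  if (!adaptation$type %in% c("none", "gain_control", "long_memory"))
    stop_arg("unknown adaptation type '%s'", adaptation$type)
  if (adaptation$tau <= 0) stop_arg("adaptation tau must be > 0")
  if (adaptation$gamma < 0 || adaptation$gamma > 1)
    stop_arg("adaptation gamma must be in [0, 1]")
  noise <- modifyList(list(type = "gaussian", sigma = 0.2), noise)
  if (!noise$type %in% c("gaussian", "poisson"))
    stop_arg("unknown noise type '%s'", noise$type)
  structure(list(strfs = strfs, output_params = output_params,
                 adaptation = adaptation, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Random ground-truth STRFs
#'
#' Convenience generator of smooth random STRFs (Gabor-like: a Gaussian
#' spectro-temporal envelope times an oriented cosine), normalised so the
#' linear drive on unit-variance stimuli has approximately unit scale.
#'
#' @param n_neurons number of neurons.
#' @param F,W STRF dimensions (frequency bands, lag bins).
#' @param seed integer seed.
#' @return list of `F x W` matrices.
#' @export
random_strfs <- function(n_neurons, F, W, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      f0 <- runif(1, 2, F - 1)
      t0 <- runif(1, 1, max(1, W / 2))
      sf <- runif(1, 1, F / 3)
      st <- runif(1, 1, W / 2.5)
      th <- runif(1, 0, pi)
      om <- runif(1, 0.2, 0.9)
      fg <- outer(seq_len(F), seq_len(W) - 1, function(f, t) {
        env <- exp(-((f - f0)^2 / (2 * sf^2) + (t - t0)^2 / (2 * st^2)))
        env * cos(om * ((f - f0) * cos(th) + (t - t0) * sin(th)))
      })
      fg / sqrt(sum(fg^2))
    })
  })
}

#' Simulate multi-trial neural responses to cochleagram stimuli
#'
#' The noise-free rate of each neuron is a causal STRF convolution of the
#' stimulus passed through the double-exponential output nonlinearity (see
#' [double_exponential()]), optionally modulated by an adaptation
#' mechanism:
#'
#' * `gain_control`: the rate is multiplied by a gain `g[t]` following
#'   `dg/dt = (1 - g)/tau - gamma * g * drive[t]`, where `drive` is the
#'   mean stimulus power normalised to unit mean. High-contrast epochs pull
#'   the gain down (contrast gain control).
#' * `long_memory`: a slow additive component is added, obtained by
#'   convolving the drive with an exponential kernel of time constant `tau`
#'   (length `3 tau` bins) and scaled so its standard deviation equals
#'   `gamma` times that of the noise-free rate. Responses then depend on
#'   stimulus history far beyond the STRF window.
#'
#' Trials are independent noise realisations around the adapted rate
#' (additive Gaussian with standard deviation `sigma`, or Poisson counts
#' treating the rate as expected events per bin). The PSTH is the trial
#' mean, stored per clip.
#'
#' @param stimuli list of [cochleagram] objects (shared across neurons:
#'   population layout).
#' @param truth a [synthetic_truth] object.
#' @param M number of trials per clip.
#' @param psth_smooth_bins odd Hanning window (bins) applied to the PSTH.
#' @return an [encoding_dataset] with the ground truth attached as
#'   `$truth` and the noise-free rates as `$true_rates`.
#' @export
simulate_neurons <- function(stimuli, truth, M = 10L,
                             psth_smooth_bins = 1L) {
  if (M < 1) stop_arg("M must be >= 1")
  if (!inherits(truth, "synthetic_truth"))
    stop_arg("truth must be a synthetic_truth object")
  n_neu <- length(truth$strfs)
  W <- ncol(truth$strfs[[1]])
  Tmin <- min(vapply(stimuli, ncol, 1L))
  if (W > Tmin) stop_arg("STRF width W (%d) exceeds clip length (%d)", W, Tmin)
  neurons <- sprintf("n%03d", seq_len(n_neu))
  rates <- lapply(stimuli, function(x) {
    noise_free_rates(coch_values(x), truth)
  })
  with_seed(truth$seed, {
    responses <- lapply(rates, function(r) {
      out <- lapply(seq_len(n_neu), function(n) {
        tr <- switch(truth$noise$type,
          gaussian = {
            sig <- truth$noise$sigma
            matrix(r[n, ], M, ncol(r), byrow = TRUE) +
              if (sig > 0) matrix(rnorm(M * ncol(r), sd = sig), M) else 0
          },
          poisson = {
            lam <- pmax(r[n, ], 0)
            matrix(rpois(M * ncol(r), rep(lam, each = M)), M)
          })
        tr
      })
      names(out) <- neurons
      out
    })
  })
  ds <- encoding_dataset(stimuli, responses, neurons = neurons,
                         population_mode = TRUE,
                         psth_smooth_bins = psth_smooth_bins)
  ds$truth <- truth
  names(rates) <- names(ds$stimuli)
  ds$true_rates <- rates
  ds
}

# N x T matrix of noise-free (adapted) rates for one stimulus matrix
noise_free_rates <- function(x, truth) {
  n_neu <- length(truth$strfs)
  Tlen <- ncol(x)
  W <- ncol(truth$strfs[[1]])
  xl <- lag_design(x, W)
  out <- matrix(0, n_neu, Tlen)
  for (n in seq_len(n_neu)) {
    L <- as.numeric(t(as.numeric(truth$strfs[[n]])) %*% xl)
    p <- truth$output_params[n, ]
    r <- double_exponential(L, a = p["a"], b = p["b"], k = p["k"],
                            s = p["s"])
    ad <- truth$adaptation
    if (ad$type == "gain_control") {
      r <- r * gain_trace(x, ad$tau, ad$gamma)
    } else if (ad$type == "long_memory") {
      r <- r + long_memory_component(x, ad$tau, ad$gamma, r)
    }
    out[n, ] <- r
  }
  out
}

# Multiplicative gain g[t]: recovery towards 1 with time constant tau,
# divisive drive from stimulus power. The drive is normalised so that at
# the mean stimulus power gamma * drive = 1 / tau: depletion and recovery
# then balance at an operating point g* = 1/2 and the gain state relaxes
# with a time constant of order tau/2, i.e. the mechanism genuinely
# carries memory of order tau. (Normalising the drive to unit mean
# instead would make gamma * drive >> 1/tau, collapsing the dynamics to a
# near-instantaneous divisive nonlinearity.)
gain_trace <- function(x, tau, gamma) {
  drive <- colMeans(x)
  drive <- drive / max(mean(drive), 1e-12) / (gamma * tau)
  Tlen <- length(drive)
  g <- numeric(Tlen)
  gprev <- 1
  for (t in seq_len(Tlen)) {
    gprev <- gprev + (1 - gprev) / tau - gamma * gprev * drive[t]
    gprev <- max(gprev, 0)
    g[t] <- gprev
  }
  g
}

# slow additive component: exponential-kernel convolution of the drive,
# zero-mean, scaled to gamma * sd(rate)
long_memory_component <- function(x, tau, gamma, rate) {
  drive <- colMeans(x)
  len <- max(2L, ceiling(3 * tau))
  kern <- exp(-(seq_len(len) - 1) / tau)
  kern <- kern / sum(kern)
  Tlen <- length(drive)
  slow <- as.numeric(stats::filter(c(rep(0, len - 1), drive), kern,
                                   method = "convolution", sides = 1))
  slow <- slow[len:(len + Tlen - 1)]
  slow <- slow - mean(slow)
  s <- sd(slow)
  if (s < 1e-12) return(rep(0, Tlen))
  gamma * sd(rate) * slow / s
}

#' Gaussian trial-noise level for a target correlation ceiling
#'
#' For additive Gaussian trial noise of standard deviation `sigma` and `M`
#' trials, the expected raw correlation between the true rate and the PSTH
#' is approximately `sqrt(Vs / (Vs + sigma^2 / M))` with `Vs` the signal
#' variance. This helper inverts that relation: it returns the `sigma`
#' for which even a perfect model would reach `CC_raw` of about
#' `target_ceiling`.
#'
#' @param rates numeric vector or matrix of noise-free rates.
#' @param M number of trials.
#' @param target_ceiling desired raw-correlation ceiling in `(0, 1)`.
#' @return Gaussian noise standard deviation.
#' @export
calibrate_noise_sigma <- function(rates, M, target_ceiling = 0.8) {
  if (target_ceiling <= 0 || target_ceiling >= 1)
    stop_arg("target_ceiling must be in (0, 1)")
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  vs <- mean(apply(rates, 1, function(r) mean((r - mean(r))^2)))
  sqrt(M * vs * (1 / target_ceiling^2 - 1))
}

# evaluate a function under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
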