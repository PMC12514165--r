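---
title: "Modelling auditory neural responses with stateless and recurrent encoders"
author: "audenc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling auditory neural responses with stateless and recurrent encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Auditory neurons transform sound into time-varying firing rates. The
classical computational account is the spectro-temporal receptive field
(STRF): the stimulus cochleagram $x \in \mathbb{R}^{F\times T}$ is
convolved causally in time with a learned $F \times W$ weight matrix, and
the result (optionally passed through static nonlinearities) predicts the
neuron's peri-stimulus time histogram (PSTH). The window length $W$ is a
hyperparameter, and everything the neuron remembers must fit inside it.
Real auditory neurons, however, adapt: stimulus-specific adaptation,
short-term plasticity and contrast gain control all modulate responses on
timescales far beyond a plausible synaptic delay line.

`audenc` implements both model families under one causal contract — every
encoder is a differentiable map $\mathbb{R}^{F\times T} \to
\mathbb{R}^{N\times T}$ in which the output at bin $t$ depends only on
input bins $\le t$ — together with the training protocol, the
noise-corrected evaluation metrics, a gradient-based interpretation
engine, and a synthetic stimulus–response simulator that provides ground
truth for every claim the test suite makes.

## Architectures

Stateless encoders read a sliding window of `trf_bins` past input
columns, implemented as a lagged design matrix with left zero padding so
the output has the input's length:

* **linear** — per-neuron $F \times W$ STRF weights (optionally batch
  normalised; after training the normalisation folds back into plain
  weights, see `absorb_bn()`);
* **ln** — linear followed by the per-neuron double exponential
  $f(x) = a\,e^{-e^{kx - s}} + b$ (baseline $b$, saturation $a$, gain
  $k$, threshold $s$);
* **nrf** — a bank of hidden STRF filters with batch normalisation and
  sigmoids, a linear readout, and $f$;
* **dnet** — the same topology but each hidden unit carries a leaky state
  $h_t = (1-\lambda)h_{t-1} + \lambda\,\sigma(\mathrm{drive}_t)$ with
  learnable per-unit $\lambda$, reading a fixed 5-bin window;
* **cnn2d** — stacked 3×3 2-D convolutions over (frequency, time) with
  batch normalisation and sigmoids, then a dense readout and $f$;
* **transformer** — per-timestep frequency-vector tokens over a causal
  sliding window, a learned positional embedding, one standard encoder
  layer (4 heads, embedding 48 by default), mean pooling over tokens, a
  linear readout and $f$.

The recurrent **statenet** family consumes a single time bin per step: a
locally connected (LC) layer downsamples each frequency vector with
position-specific weights (preserving tonotopic order, cheaper than fully
connected, more expressive than a shared-kernel convolution), batch
normalisation, one recurrent core — Elman, GRU, LSTM, or a diagonal
state-space model — and a per-neuron linear readout of the state vector.
The SSM core is a deliberately minimal stand-in for structured
state-space layers: a learned diagonal continuous system
$\dot{x} = Ax + Bu$, $y = Cx + Du$ discretised by zero-order hold with a
learned per-state step size; the test suite checks it against a naive
discretised recurrence written independently in R.

Two genuinely open design points and how we resolved them:

* The printed double exponential is *decreasing* in $x$ for $k > 0$
  (large $kx - s$ sends the inner exponential to $+\infty$ and $f \to
  b$). We leave the signs of $a$ and $k$ unconstrained so fitting can
  adopt either orientation, and the simulator's default output uses
  $k < 0$ so that firing increases with drive. The inner exponent is
  clamped to $\pm 30$ before exponentiation.
* Whether the statenet readout carries the double exponential is
  ambiguous between the architecture figure (linear readout) and the
  methods text; we default to a linear readout, with `output_nl = TRUE`
  available.

Because no automatic-differentiation library is available in this R
stack, forward *and* backward passes are written by hand: vectorised
matrix algebra for the stateless models, C++ (RcppArmadillo) kernels for
the recurrent cores. Every architecture's gradients — with respect to
parameters and to the input — are validated against central finite
differences in the test suite (relative error below $10^{-4}$; in
practice around $10^{-9}$).

## Training protocol

`fit_encoder()` minimises the mean squared error between predicted rates
and the PSTH (the trial-averaged response), with AdamW updates
($\beta = (0.9, 0.999)$), a constant learning rate of $10^{-3}$, batch
size 1 clip, no weight decay, dropout or augmentation. After each epoch
the model is evaluated on the validation clips; the best checkpoint is
kept and training stops after 50 epochs without improvement (both
defaults configurable via `train_config()`). Splits are assigned at the
clip level (70–10–20 by default) — never within a clip — to avoid
temporal leakage. PSTH smoothing, when requested, is a unit-sum Hanning
window applied after trial averaging (averaging and linear smoothing
commute). Batch normalisation in training mode uses the current clip's
statistics, as with batch-of-one training in the reference protocol;
inference mode uses frozen running statistics, and causality is a
property of inference mode.

Stateful models support truncated backpropagation through time via
`train_config(tbptt = list(K, warmup))`. The loss is evaluated at every
bin; the gradient of the loss at bin $t$ flows through at most $K$ bins
of history. With warmup, the state entering the truncated graph is the
true forward-propagated state from the sequence start (computed without
gradients); without warmup, the forward pass for the loss at bin $t$
itself restarts from the null state $K$ bins earlier, so the model sees
no context at all beyond the graph — the fair comparison to stateless
models. `TBPTT(K = T, warmup)` reproduces full-BPTT parameter gradients
to machine precision (a dedicated test asserts $<10^{-6}$), and
`K = 1` without warmup is verified to make bin $t$'s prediction a
function of $x_t$ alone.

## Evaluation metrics

With $M$ trials $r^{(m)}$ and their mean $r$, model quality is the raw
Pearson correlation $\mathrm{CC}_{raw} =
\mathrm{Cov}(r,\hat r)/\sqrt{\mathrm{Var}(r)\mathrm{Var}(\hat r)}$ and
the noise-corrected
$\mathrm{CC}_{norm} = \mathrm{Cov}(r,\hat r)/\sqrt{SP \cdot
\mathrm{Var}(\hat r)}$, where the signal power
$SP = [\mathrm{Var}(\sum_m r^{(m)}) - \sum_m \mathrm{Var}(r^{(m)})] /
[M(M-1)]$ estimates the trial-reliable response variance. All variances
are population variances (divide by the count): this convention makes the
identical-trials identity $SP = \mathrm{Var}(r)$ *exact*, which the tests
assert. Metrics are computed after temporally concatenating the clips of
a split. Policy decisions: a single trial sets
$\mathrm{CC}_{norm} = \mathrm{CC}_{raw}$; a zero-variance series or a
non-positive $SP$ estimate yields 0 with a warning, keeping population
averages defined.

## Interpretation: GradMaps and Dreams

For a frozen model, the GradMap is the gradient of
$L = -\frac{1}{|\mathcal N|}\sum_{n\in\mathcal N}\hat r_n[T]$ with
respect to the input, evaluated at the null (all-zero) stimulus — the
local linearisation of the neuron's input–output function, and exactly
the (sign-flipped) STRF for a linear model. Iterating optimiser updates
on the stimulus produces a Dream, the input that maximises the target's
activation at the final bin. Conventions: batch normalisation runs in
inference mode; stateful models are unrolled in full over the probe
length regardless of how they were trained; Dreams use AdamW with the
training betas and a default step of $10^{-2}$ (the optimiser family is
fixed by the protocol, the step size is not — it is exposed); stimuli are
not constrained to non-negative cochleagram values; the default budget is
1500 iterations, with an optional "loss convergence" mode (relative
change below $10^{-4}$ over 50 iterations) used by the dream-length
analysis. Latency indexing on energy traces puts latency 0 at the loss
bin. The GradMap similarity matrix flattens two models' maps per neuron,
correlates them (correlation, not distance, so affine rescalings of maps
are equivalent) and averages over neurons; horizons slightly above the
largest stateless window avoid inflating similarity with untouched zero
bins.

## The synthetic world

The simulator exists so every pipeline claim can be tested against known
ground truth; it emulates, deliberately simply:

* **Stimuli**: Gaussian fields smoothed separably in frequency and time
  (defaults 1.5 and 2 bins), mixed with a broadband white component
  (weight 0.3) and passed through a softplus; an optional slow
  multiplicative amplitude envelope (60-bin scale, depth 0.5) gives the
  stimulus the pronounced slow level fluctuations of natural sounds.
  The broadband component matters scientifically: a strictly low-pass
  field has an (almost) rank-deficient covariance, which would make STRF
  identification ill-posed for *any* estimator — real stimulus ensembles
  are never singular.
* **Neurons**: known random Gabor-like STRFs, the double-exponential
  output (increasing orientation), and optional adaptation. *Gain
  control* multiplies the rate by a state $g$ with
  $\dot g = (1-g)/\tau - \gamma\,g\,d_t$; the drive $d_t$ is normalised
  so that at mean stimulus power $\gamma d = 1/\tau$, i.e. depletion and
  recovery balance at $g^\ast = 1/2$ and the gain genuinely carries
  memory of order $\tau$ (normalising the drive to unit mean instead
  collapses the dynamics to a near-instantaneous divisive
  nonlinearity — the stated time constant would be meaningless).
  *Long memory* adds a slow component: the drive convolved with an
  exponential kernel of time constant $\tau$ (length $3\tau$), scaled to
  $\gamma$ times the rate's standard deviation.
* **Trials**: additive Gaussian noise (default), or Poisson counts
  treating the rate as expected events per bin.
  `calibrate_noise_sigma()` chooses $\sigma$ so a perfect model's raw
  correlation ceiling sits at a requested level.

What a green test does *not* establish: the simulator has stationary
single-mechanism neurons, Gaussian noise and modest dimensions; real
recordings add non-stationarity, correlated noise across trials and
neurons, spike-sorting artifacts and drift (the MedGauss detrender —
running median then Gaussian smoothing, defaults 201 and 50 bins, decided
here since only the filter's name and purpose are documented publicly —
addresses only the last of these). Absolute benchmark scores on real
recordings are therefore out of scope for the test suite; the suite
asserts *relationships* (recurrent beats stateless on adaptive neurons,
truncating gradients degrades gracefully with $K$ and warmup, the noise
correction recovers the ceiling) that mirror the reference findings.

For the STRF-recovery test specifically, the probe ensemble uses mild
smoothing (0.5 bins) and no envelope — the classical reverse-correlation
design: unregularised recovery from strongly low-pass stimuli is
information-limited no matter how much data is collected, which is
precisely why experimenters map receptive fields with spectrally broad
probes. The adaptive-neuron worlds keep the naturalistic defaults.

## A worked example

```{r, eval = FALSE}
library(audenc)

stims <- generate_stimuli(F = 16, T = 400, n_clips = 16, seed = 1)
truth <- synthetic_truth(random_strfs(4, 16, 10, seed = 2),
                         adaptation = list(type = "gain_control",
                                           tau = 200, gamma = 0.3),
                         noise = list(type = "gaussian", sigma = 0.3),
                         seed = 3)
ds <- split_dataset(simulate_neurons(stims, truth, M = 8), seed = 4)

fit <- fit_encoder(ds, model_spec("statenet", 16, 4, hidden = 16,
                                  core = "gru"),
                   train_config(max_epochs = 150), seed = 1)
summary(fit)
plot(fit, "loss")

g <- gradmap(fit, target = 1, T = 50)
plot(gradmap_energy(g, normalize = TRUE))
```

## Numerical choices and limitations

Initialisation follows the uniform $\pm 1/\sqrt{\mathrm{fan_{in}}}$
convention; SSM decay rates are log-spaced and step sizes log-uniform in
$[10^{-3}, 10^{-1}]$, spreading memory over decades. All randomness is
seeded; training is single-threaded and bit-reproducible for identical
inputs. Known limitations: no Mamba-style selective scan (the diagonal
SSM stands in), single recurrent layers only, TBPTT is implemented for
the statenet cores (DNet trains by full backpropagation through its leaky
scan), and the dataset container is a documented plain-text directory
(JSON metadata plus TSV matrices) rather than HDF5, for which no binding
is available in this environment; converters for the public
electrophysiology archives are documented stubs
(`convert_public_dataset()`).
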