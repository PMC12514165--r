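#' Specify an encoder architecture
#'
#' A `model_spec` fully determines an encoder: its architecture, geometry
#' and initialisation seed. Two builds from the same spec have identical
#' initial parameters.
#'
#' Architectures:
#' * `"linear"`: per-neuron STRF weights over an `F x W` window (optional
#'   batch normalisation, absorbable after training).
#' * `"ln"`: linear plus a per-neuron double-exponential output.
#' * `"nrf"`: a bank of `hidden` STRF filters, batch-normalised and passed
#'   through sigmoids, then a linear readout and the double-exponential.
#' * `"dnet"`: the NRF topology whose hidden units carry a leaky state
#'   `h_t = (1 - lambda) h_{t-1} + lambda * sigmoid(drive_t)` (per-unit
#'   learnable `lambda` in `(0, 1)`) and read a fixed 5-bin input window.
#' * `"cnn2d"`: stacked 2-D convolutions over (frequency, time) with batch
#'   normalisation and sigmoids, then a dense readout and the
#'   double-exponential.
#' * `"transformer"`: per-timestep frequency-vector tokens over a sliding
#'   `W`-bin window, learned positional embedding, one multi-head
#'   self-attention encoder layer, mean pooling over tokens, linear
#'   readout and the double-exponential.
#' * `"statenet"`: a tonotopic locally connected downsampling layer, batch
#'   normalisation, one recurrent core (`"elman"`, `"gru"`, `"lstm"` or a
#'   diagonal `"ssm"`), and a per-neuron linear readout of the state
#'   vector. Consumes a single time bin per step; `trf_bins` is ignored.
#'
#' @param architecture one of `"linear"`, `"ln"`, `"nrf"`, `"dnet"`,
#'   `"cnn2d"`, `"transformer"`, `"statenet"`.
#' @param n_freqs number of input frequency bands `F`.
#' @param n_neurons number of output units `N`.
#' @param trf_bins temporal window length `W` for stateless architectures
#'   (ignored by `statenet`, fixed at 5 for `dnet`).
#' @param hidden hidden width: filter-bank size for `nrf`/`dnet`, state
#'   size for `statenet` cores.
#' @param core recurrent core for `statenet`.
#' @param lc_kernel,lc_stride locally connected window length and stride
#'   (`statenet`).
#' @param channels,conv_kernel,conv_layers 2-D CNN geometry.
#' @param embed_dim,n_heads,n_layers,ffn_dim transformer geometry
#'   (defaults: 48, 4, 1, 96).
#' @param output_nl logical: append the double-exponential output to
#'   `statenet` (other nonlinear architectures always carry it; the
#'   `statenet` readout is linear by default).
#' @param use_bn logical: batch-normalise the `linear` model's output
#'   channels.
#' @param seed integer initialisation seed.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("linear", "ln", "nrf", "dnet",
                                        "cnn2d", "transformer", "statenet"),
                       n_freqs, n_neurons, trf_bins = 10L, hidden = NULL,
                       core = c("gru", "elman", "lstm", "ssm"),
                       lc_kernel = 5L, lc_stride = 2L,
                       channels = 10L, conv_kernel = c(3L, 3L),
                       conv_layers = 2L,
                       embed_dim = 48L, n_heads = 4L, n_layers = 1L,
                       ffn_dim = 96L,
                       output_nl = FALSE, use_bn = FALSE, seed = 1L) {
  architecture <- match.arg(architecture)
  core <- match.arg(core)
  if (missing(n_freqs) || missing(n_neurons))
    stop_arg("n_freqs and n_neurons are required")
  if (is.null(hidden))
    hidden <- switch(architecture, nrf = 20L, dnet = 20L, statenet = 32L,
                     16L)
  stateless <- !architecture %in% c("statenet", "dnet")
  if (architecture == "dnet") trf_bins <- 5L
  if (architecture == "statenet") trf_bins <- 1L
  if (stateless && trf_bins < 1) stop_arg("trf_bins must be >= 1")
  if (embed_dim %% n_heads != 0)
    stop_arg("embed_dim must be divisible by n_heads")
  structure(list(architecture = architecture, n_freqs = as.integer(n_freqs),
                 n_neurons = as.integer(n_neurons),
                 trf_bins = as.integer(trf_bins),
                 hidden = as.integer(hidden), core = core,
                 lc_kernel = as.integer(lc_kernel),
                 lc_stride = as.integer(lc_stride),
                 channels = as.integer(channels),
                 conv_kernel = as.integer(conv_kernel),
                 conv_layers = as.integer(conv_layers),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 ffn_dim = as.integer(ffn_dim),
                 output_nl = isTRUE(output_nl), use_bn = isTRUE(use_bn),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# uniform(-1/sqrt(fan_in), +) init, the PyTorch default for linear layers
init_mat <- function(nr, nc, fan_in = nc) {
  s <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -s, s), nr, nc)
}
init_vec <- function(n, fan_in = n) {
  s <- 1 / sqrt(fan_in)
  runif(n, -s, s)
}

#' Build a causal encoder from a specification
#'
#' Instantiates the architecture's parameters (seeded) and returns a
#' `causal_encoder`: a differentiable causal map from `F x T` cochleagrams
#' to `N x T` predicted rate time series. Use [predict.causal_encoder()]
#' for the forward pass and [encoder_step()] to advance stateful models
#' one bin at a time.
#'
#' @param spec a [model_spec].
#' @return object of class `causal_encoder` (fields `spec`, `params`,
#'   `buffers`).
#' @export
build_model <- function(spec) {
  if (!inherits(spec, "model_spec")) stop_arg("spec must be a model_spec")
  F <- spec$n_freqs; N <- spec$n_neurons; W <- spec$trf_bins
  params <- list(); buffers <- list()
  with_seed(spec$seed, {
    nl_params <- function() {
      params$nl.a <<- rep(1, N); params$nl.b <<- rep(0, N)
      params$nl.k <<- rep(-1, N); params$nl.s <<- rep(0, N)
    }
    switch(spec$architecture,
      linear = {
        params$W <- init_mat(N, F * W)
        if (spec$use_bn) {
          params$bn.gamma <- rep(1, N); params$bn.beta <- numeric(N)
          buffers <- bn_init_buffers(buffers, "bn", N)
        } else params$b <- init_vec(N, F * W)
      },
      ln = {
        params$W <- init_mat(N, F * W)
        params$b <- init_vec(N, F * W)
        nl_params()
      },
      nrf = {
        J <- spec$hidden
        params$Wh <- init_mat(J, F * W)
        params$bn.gamma <- rep(1, J); params$bn.beta <- numeric(J)
        buffers <- bn_init_buffers(buffers, "bn", J)
        params$Wo <- init_mat(N, J)
        params$bo <- init_vec(N, J)
        nl_params()
      },
      dnet = {
        J <- spec$hidden
        params$Wh <- init_mat(J, F * 5L)
        params$bn.gamma <- rep(1, J); params$bn.beta <- numeric(J)
        buffers <- bn_init_buffers(buffers, "bn", J)
        params$rho <- numeric(J)        # lambda = sigmoid(rho) = 0.5
        params$Wo <- init_mat(N, J)
        params$bo <- init_vec(N, J)
        nl_params()
      },
      cnn2d = {
        C <- spec$channels; kf <- spec$conv_kernel[1]
        kt <- spec$conv_kernel[2]
        cin <- 1L
        for (l in seq_len(spec$conv_layers)) {
          fan <- cin * kf * kt
          params[[sprintf("conv%d.W", l)]] <-
            array(runif(C * cin * kf * kt, -1 / sqrt(fan), 1 / sqrt(fan)),
                  c(C, cin, kf, kt))
          params[[sprintf("bn%d.gamma", l)]] <- rep(1, C)
          params[[sprintf("bn%d.beta", l)]] <- numeric(C)
          buffers <- bn_init_buffers(buffers, sprintf("bn%d", l), C)
          cin <- C
        }
        params$Wro <- init_mat(N, C * F)
        params$bro <- init_vec(N, C * F)
        nl_params()
      },
      transformer = {
        E <- spec$embed_dim
        params$tok.W <- init_mat(E, F)
        params$tok.b <- init_vec(E, F)
        params$pos <- matrix(0.02 * rnorm(E * W), E, W)
        for (nm in c("Wq", "Wk", "Wv", "Wo"))
          params[[paste0("attn.", nm)]] <- init_mat(E, E)
        for (nm in c("bq", "bk", "bv", "bo"))
          params[[paste0("attn.", nm)]] <- init_vec(E, E)
        params$ln1.gamma <- rep(1, E); params$ln1.beta <- numeric(E)
        params$ffn.W1 <- init_mat(spec$ffn_dim, E)
        params$ffn.b1 <- init_vec(spec$ffn_dim, E)
        params$ffn.W2 <- init_mat(E, spec$ffn_dim)
        params$ffn.b2 <- init_vec(E, spec$ffn_dim)
        params$ln2.gamma <- rep(1, E); params$ln2.beta <- numeric(E)
        params$Wro <- init_mat(N, E)
        params$bro <- init_vec(N, E)
        nl_params()
      },
      statenet = {
        k <- spec$lc_kernel
        idx <- lc_geometry(F, k, spec$lc_stride)
        H <- nrow(idx)
        G <- spec$hidden
        params$lc.kern <- init_mat(H, k, fan_in = k)
        params$lc.bias <- init_vec(H, k)
        params$bn.gamma <- rep(1, H); params$bn.beta <- numeric(H)
        buffers <- bn_init_buffers(buffers, "bn", H)
        cp <- init_core_params(spec$core, in_dim = H, G = G)
        for (nm in names(cp)) params[[paste0("core.", nm)]] <- cp[[nm]]
        params$Wro <- init_mat(N, G)
        params$bro <- init_vec(N, G)
        if (spec$output_nl) nl_params()
      })
  })
  structure(list(spec = spec, params = params, buffers = buffers),
            class = "causal_encoder")
}

init_core_params <- function(core, in_dim, G) {
  s <- 1 / sqrt(G)
  rmat <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
  rvec <- function(n) runif(n, -s, s)
  switch(core,
    elman = list(W = rmat(G, in_dim), U = rmat(G, G), b = rvec(G)),
    gru = list(Wz = rmat(G, in_dim), Wr = rmat(G, in_dim),
               Wn = rmat(G, in_dim), Uz = rmat(G, G), Ur = rmat(G, G),
               Un = rmat(G, G), bwz = rvec(G), bwr = rvec(G),
               bwn = rvec(G), buz = rvec(G), bur = rvec(G),
               bun = rvec(G)),
    lstm = list(Wi = rmat(G, in_dim), Wf = rmat(G, in_dim),
                Wg = rmat(G, in_dim), Wo = rmat(G, in_dim),
                Ui = rmat(G, G), Uf = rmat(G, G), Ug = rmat(G, G),
                Uo = rmat(G, G), bi = rvec(G), bf = rvec(G),
                bg = rvec(G), bo = rvec(G)),
    ssm = list(a_log = log(seq(0.05, 1, length.out = G)),
               logdt = runif(G, log(1e-3), log(1e-1)),
               B = rmat(G, in_dim), C = rmat(G, G), D = rmat(G, in_dim)))
}

#' @export
print.causal_encoder <- function(x, ...) {
  sp <- x$spec
  extra <- switch(sp$architecture,
    statenet = sprintf(", core=%s, state=%d", sp$core, sp$hidden),
    nrf = , dnet = sprintf(", hidden=%d", sp$hidden),
    transformer = sprintf(", E=%d, heads=%d", sp$embed_dim, sp$n_heads),
    "")
  cat(sprintf("<causal_encoder %s: F=%d -> N=%d, W=%d%s, %d parameters>\n",
              sp$architecture, sp$n_freqs, sp$n_neurons, sp$trf_bins,
              extra, count_params(x)))
  invisible(x)
}

#' Number of learnable parameters of an encoder
#' @param model a `causal_encoder`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# extract the "core." sub-list with the prefix stripped
core_params <- function(params) {
  nm <- names(params)
  sel <- startsWith(nm, "core.")
  out <- params[sel]
  names(out) <- substring(nm[sel], 6L)
  out
}

#' Absorb inference-mode batch normalisation into linear weights
#'
#' After training, a batch-normalised linear model in inference mode is an
#' affine map, so the normalisation can be folded into plain weights and
#' biases. Returns an equivalent `linear` model with `use_bn = FALSE`.
#'
#' @param model a `linear` `causal_encoder` built with `use_bn = TRUE`.
#' @return an equivalent plain linear `causal_encoder`.
#' @export
absorb_bn <- function(model) {
  sp <- model$spec
  if (sp$architecture != "linear" || !sp$use_bn)
    stop_arg("absorb_bn expects a linear model with use_bn = TRUE")
  g <- model$params$bn.gamma
  be <- model$params$bn.beta
  mu <- model$buffers$bn.running_mean
  std <- sqrt(model$buffers$bn.running_var + 1e-5)
  sp$use_bn <- FALSE
  out <- build_model(sp)
  out$params$W <- model$params$W * (g / std)
  out$params$b <- be - g * mu / std
  out
}
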