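# Forward and backward passes for every encoder architecture.
#
# encoder_forward(model, x, training) -> list(pred = N x T, cache, buffers)
# encoder_backward(model, cache, d_pred) -> list(d_params, d_x)
#
# d_params is a named list congruent with model$params; d_x is F x T.
# Stateless passes are fully vectorised (lagged-design matrix products);
# the recurrent statenet cores run in C++ (src/cores.cpp); the transformer
# loops over output bins with a sliding token window.

encoder_forward <- function(model, x, training = FALSE, state0 = NULL,
                            tbptt = NULL) {
  x <- coch_unpack(model, x)
  switch(model$spec$architecture,
    linear = fw_linear(model, x, training),
    ln = fw_ln(model, x, training),
    nrf = fw_nrf(model, x, training),
    dnet = fw_dnet(model, x, training),
    cnn2d = fw_cnn2d(model, x, training),
    transformer = fw_transformer(model, x, training),
    statenet = fw_statenet(model, x, training, state0, tbptt))
}

encoder_backward <- function(model, cache, d_pred) {
  switch(model$spec$architecture,
    linear = bw_linear(model, cache, d_pred),
    ln = bw_ln(model, cache, d_pred),
    nrf = bw_nrf(model, cache, d_pred),
    dnet = bw_dnet(model, cache, d_pred),
    cnn2d = bw_cnn2d(model, cache, d_pred),
    transformer = bw_transformer(model, cache, d_pred),
    statenet = bw_statenet(model, cache, d_pred))
}

coch_unpack <- function(model, x) {
  if (is_cochleagram(x)) x <- coch_values(x)
  x <- as.matrix(x)
  if (nrow(x) != model$spec$n_freqs)
    stop_arg("input has %d frequency bands; model expects %d", nrow(x),
             model$spec$n_freqs)
  x
}

# -------------------------------------------------------------- linear ----

fw_linear <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  xl <- lag_design(x, sp$trf_bins)
  z <- p$W %*% xl
  if (sp$use_bn) {
    bn <- bn_forward(z, p$bn.gamma, p$bn.beta, model$buffers, "bn",
                     training)
    list(pred = bn$out, buffers = bn$buffers,
         cache = list(xl = xl, bn = bn$cache))
  } else {
    list(pred = z + p$b, buffers = model$buffers,
         cache = list(xl = xl))
  }
}

bw_linear <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  g <- list()
  if (sp$use_bn) {
    bnb <- bn_backward(cache$bn, d_pred)
    d_z <- bnb$d_z
    g$bn.gamma <- bnb$d_gamma; g$bn.beta <- bnb$d_beta
  } else {
    d_z <- d_pred
    g$b <- rowSums(d_pred)
  }
  g$W <- d_z %*% t(cache$xl)
  d_x <- lag_design_backward(crossprod(p$W, d_z), sp$n_freqs, sp$trf_bins)
  list(d_params = g, d_x = d_x)
}

# ------------------------------------------------------------------ ln ----

fw_ln <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  xl <- lag_design(x, sp$trf_bins)
  z <- p$W %*% xl + p$b
  de <- dexp_forward(z, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
  list(pred = de$out, buffers = model$buffers,
       cache = list(xl = xl, dexp = de$cache))
}

bw_ln <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  db <- dexp_backward(cache$dexp, d_pred)
  d_z <- db$d_x
  g <- list(W = d_z %*% t(cache$xl), b = rowSums(d_z),
            nl.a = db$d_a, nl.b = db$d_b, nl.k = db$d_k, nl.s = db$d_s)
  d_x <- lag_design_backward(crossprod(p$W, d_z), sp$n_freqs, sp$trf_bins)
  list(d_params = g, d_x = d_x)
}

# ----------------------------------------------------------------- nrf ----

fw_nrf <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  xl <- lag_design(x, sp$trf_bins)
  zh <- p$Wh %*% xl
  bn <- bn_forward(zh, p$bn.gamma, p$bn.beta, model$buffers, "bn",
                   training)
  hs <- sigmoid(bn$out)
  y <- p$Wo %*% hs + p$bo
  de <- dexp_forward(y, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
  list(pred = de$out, buffers = bn$buffers,
       cache = list(xl = xl, bn = bn$cache, hs = hs, dexp = de$cache))
}

bw_nrf <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  db <- dexp_backward(cache$dexp, d_pred)
  d_y <- db$d_x
  g <- list(Wo = d_y %*% t(cache$hs), bo = rowSums(d_y),
            nl.a = db$d_a, nl.b = db$d_b, nl.k = db$d_k, nl.s = db$d_s)
  d_hs <- crossprod(p$Wo, d_y)
  d_zb <- d_hs * cache$hs * (1 - cache$hs)
  bnb <- bn_backward(cache$bn, d_zb)
  g$bn.gamma <- bnb$d_gamma; g$bn.beta <- bnb$d_beta
  g$Wh <- bnb$d_z %*% t(cache$xl)
  d_x <- lag_design_backward(crossprod(p$Wh, bnb$d_z), sp$n_freqs,
                             sp$trf_bins)
  list(d_params = g, d_x = d_x)
}

# ---------------------------------------------------------------- dnet ----
# NRF topology with per-unit leaky hidden state over a fixed 5-bin window:
# h_t = (1 - lambda) h_{t-1} + lambda * sigmoid(BN(conv(x)))_t.

fw_dnet <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  xl <- lag_design(x, 5L)
  zh <- p$Wh %*% xl
  bn <- bn_forward(zh, p$bn.gamma, p$bn.beta, model$buffers, "bn",
                   training)
  sg <- sigmoid(bn$out)
  lam <- sigmoid(p$rho)
  J <- nrow(sg); Tlen <- ncol(sg)
  h <- matrix(0, J, Tlen)
  hprev <- numeric(J)
  for (t in seq_len(Tlen)) {
    hprev <- (1 - lam) * hprev + lam * sg[, t]
    h[, t] <- hprev
  }
  y <- p$Wo %*% h + p$bo
  de <- dexp_forward(y, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
  list(pred = de$out, buffers = bn$buffers,
       cache = list(xl = xl, bn = bn$cache, sg = sg, h = h, lam = lam,
                    dexp = de$cache))
}

bw_dnet <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  db <- dexp_backward(cache$dexp, d_pred)
  d_y <- db$d_x
  g <- list(Wo = d_y %*% t(cache$h), bo = rowSums(d_y),
            nl.a = db$d_a, nl.b = db$d_b, nl.k = db$d_k, nl.s = db$d_s)
  d_h <- crossprod(p$Wo, d_y)
  sg <- cache$sg; h <- cache$h; lam <- cache$lam
  J <- nrow(sg); Tlen <- ncol(sg)
  d_sg <- matrix(0, J, Tlen)
  d_lam <- numeric(J)
  acc <- numeric(J)
  for (t in rev(seq_len(Tlen))) {
    tot <- d_h[, t] + acc
    hp <- if (t == 1) numeric(J) else h[, t - 1]
    d_sg[, t] <- tot * lam
    d_lam <- d_lam + tot * (sg[, t] - hp)
    acc <- tot * (1 - lam)
  }
  g$rho <- d_lam * lam * (1 - lam)
  d_zb <- d_sg * sg * (1 - sg)
  bnb <- bn_backward(cache$bn, d_zb)
  g$bn.gamma <- bnb$d_gamma; g$bn.beta <- bnb$d_beta
  g$Wh <- bnb$d_z %*% t(cache$xl)
  d_x <- lag_design_backward(crossprod(p$Wh, bnb$d_z), sp$n_freqs, 5L)
  list(d_params = g, d_x = d_x)
}

# --------------------------------------------------------------- cnn2d ----

fw_cnn2d <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  F <- nrow(x); Tlen <- ncol(x)
  A <- array(x, c(1L, F, Tlen))
  buffers <- model$buffers
  layers <- list()
  for (l in seq_len(sp$conv_layers)) {
    Wl <- p[[sprintf("conv%d.W", l)]]
    Z <- conv2d_forward(A, Wl, numeric(dim(Wl)[1]))
    C <- dim(Z)[1]
    Zm <- matrix(Z, C, F * Tlen)
    bn <- bn_forward(Zm, p[[sprintf("bn%d.gamma", l)]],
                     p[[sprintf("bn%d.beta", l)]], buffers,
                     sprintf("bn%d", l), training)
    buffers <- bn$buffers
    S <- sigmoid(bn$out)
    layers[[l]] <- list(A_in = A, bn = bn$cache, S = S)
    A <- array(S, c(C, F, Tlen))
  }
  feat <- matrix(A, dim(A)[1] * F, Tlen)
  y <- p$Wro %*% feat + p$bro
  de <- dexp_forward(y, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
  list(pred = de$out, buffers = buffers,
       cache = list(layers = layers, feat = feat, dims = c(F, Tlen),
                    dexp = de$cache))
}

bw_cnn2d <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  F <- cache$dims[1]; Tlen <- cache$dims[2]
  db <- dexp_backward(cache$dexp, d_pred)
  d_y <- db$d_x
  g <- list(Wro = d_y %*% t(cache$feat), bro = rowSums(d_y),
            nl.a = db$d_a, nl.b = db$d_b, nl.k = db$d_k, nl.s = db$d_s)
  C <- sp$channels
  d_A <- array(crossprod(p$Wro, d_y), c(C, F, Tlen))
  for (l in rev(seq_len(sp$conv_layers))) {
    lay <- cache$layers[[l]]
    Cl <- nrow(lay$S)
    d_S <- matrix(d_A, Cl, F * Tlen)
    d_zb <- d_S * lay$S * (1 - lay$S)
    bnb <- bn_backward(lay$bn, d_zb)
    g[[sprintf("bn%d.gamma", l)]] <- bnb$d_gamma
    g[[sprintf("bn%d.beta", l)]] <- bnb$d_beta
    d_Z <- array(bnb$d_z, c(Cl, F, Tlen))
    cb <- conv2d_backward(lay$A_in, p[[sprintf("conv%d.W", l)]], d_Z)
    g[[sprintf("conv%d.W", l)]] <- cb$d_kern
    d_A <- cb$d_A
  }
  list(d_params = g, d_x = matrix(d_A, F, Tlen))
}

# ---------------------------------------------------------- transformer ----
# Sliding causal window of W per-timestep tokens; one post-norm encoder
# layer (multi-head attention -> add & layer norm -> feed-forward -> add &
# layer norm), mean pooling over tokens, linear readout, Eq-1 output.

layernorm_fwd <- function(Z, gamma, beta, eps = 1e-5) {
  mu <- colMeans(Z)
  zc <- sweep(Z, 2, mu)
  v <- colMeans(zc^2)
  std <- sqrt(v + eps)
  zhat <- sweep(zc, 2, std, "/")
  list(out = gamma * zhat + beta,
       cache = list(zhat = zhat, std = std, gamma = gamma))
}

layernorm_bwd <- function(cache, d_out) {
  zhat <- cache$zhat
  d_gamma <- rowSums(d_out * zhat)
  d_beta <- rowSums(d_out)
  d_zhat <- d_out * cache$gamma
  cm1 <- colMeans(d_zhat)
  cm2 <- colMeans(d_zhat * zhat)
  d_z <- sweep(sweep(d_zhat, 2, cm1) - sweep(zhat, 2, cm2, "*"), 2,
               cache$std, "/")
  list(d_z = d_z, d_gamma = d_gamma, d_beta = d_beta)
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

fw_transformer <- function(model, x, training) {
  p <- model$params; sp <- model$spec
  W <- sp$trf_bins; E <- sp$embed_dim; Hh <- sp$n_heads
  dh <- E %/% Hh
  F <- nrow(x); Tlen <- ncol(x)
  xp <- cbind(matrix(0, F, W - 1L), x)
  TK <- p$tok.W %*% xp + p$tok.b
  pooled <- matrix(0, E, Tlen)
  steps <- vector("list", Tlen)
  for (t in seq_len(Tlen)) {
    Z0 <- TK[, t:(t + W - 1L), drop = FALSE] + p$pos
    Q <- p$attn.Wq %*% Z0 + p$attn.bq
    K <- p$attn.Wk %*% Z0 + p$attn.bk
    V <- p$attn.Wv %*% Z0 + p$attn.bv
    O <- matrix(0, E, W)
    alphas <- vector("list", Hh)
    for (h in seq_len(Hh)) {
      rows <- ((h - 1L) * dh + 1L):(h * dh)
      S <- crossprod(Q[rows, , drop = FALSE],
                     K[rows, , drop = FALSE]) / sqrt(dh)
      al <- softmax_rows(S)
      O[rows, ] <- V[rows, , drop = FALSE] %*% t(al)
      alphas[[h]] <- al
    }
    M <- p$attn.Wo %*% O + p$attn.bo
    R1 <- Z0 + M
    l1 <- layernorm_fwd(R1, p$ln1.gamma, p$ln1.beta)
    P1 <- p$ffn.W1 %*% l1$out + p$ffn.b1
    Fh <- pmax(P1, 0)
    F2 <- p$ffn.W2 %*% Fh + p$ffn.b2
    R2 <- l1$out + F2
    l2 <- layernorm_fwd(R2, p$ln2.gamma, p$ln2.beta)
    pooled[, t] <- rowMeans(l2$out)
    steps[[t]] <- list(Z0 = Z0, Q = Q, K = K, V = V, O = O,
                       alphas = alphas, l1 = l1$cache, L1 = l1$out,
                       P1 = P1, Fh = Fh, l2 = l2$cache)
  }
  y <- p$Wro %*% pooled + p$bro
  de <- dexp_forward(y, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
  list(pred = de$out, buffers = model$buffers,
       cache = list(xp = xp, TK = TK, steps = steps, pooled = pooled,
                    dims = c(F, Tlen), dexp = de$cache))
}

bw_transformer <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  W <- sp$trf_bins; E <- sp$embed_dim; Hh <- sp$n_heads
  dh <- E %/% Hh
  F <- cache$dims[1]; Tlen <- cache$dims[2]
  db <- dexp_backward(cache$dexp, d_pred)
  d_y <- db$d_x
  g <- zero_like(model$params)
  g$nl.a <- db$d_a; g$nl.b <- db$d_b; g$nl.k <- db$d_k; g$nl.s <- db$d_s
  g$Wro <- d_y %*% t(cache$pooled)
  g$bro <- rowSums(d_y)
  d_pooled <- crossprod(p$Wro, d_y)
  d_TK <- matrix(0, E, ncol(cache$TK))
  active <- which(colSums(abs(d_pooled)) > 0)
  for (t in active) {
    st <- cache$steps[[t]]
    d_L2 <- matrix(d_pooled[, t] / W, E, W)
    l2b <- layernorm_bwd(st$l2, d_L2)
    g$ln2.gamma <- g$ln2.gamma + l2b$d_gamma
    g$ln2.beta <- g$ln2.beta + l2b$d_beta
    d_R2 <- l2b$d_z
    d_F2 <- d_R2
    g$ffn.W2 <- g$ffn.W2 + d_F2 %*% t(st$Fh)
    g$ffn.b2 <- g$ffn.b2 + rowSums(d_F2)
    d_Fh <- crossprod(p$ffn.W2, d_F2)
    d_P1 <- d_Fh * (st$P1 > 0)
    g$ffn.W1 <- g$ffn.W1 + d_P1 %*% t(st$L1)
    g$ffn.b1 <- g$ffn.b1 + rowSums(d_P1)
    d_L1 <- d_R2 + crossprod(p$ffn.W1, d_P1)
    l1b <- layernorm_bwd(st$l1, d_L1)
    g$ln1.gamma <- g$ln1.gamma + l1b$d_gamma
    g$ln1.beta <- g$ln1.beta + l1b$d_beta
    d_R1 <- l1b$d_z
    d_M <- d_R1
    g$attn.Wo <- g$attn.Wo + d_M %*% t(st$O)
    g$attn.bo <- g$attn.bo + rowSums(d_M)
    d_O <- crossprod(p$attn.Wo, d_M)
    d_Q <- matrix(0, E, W); d_K <- matrix(0, E, W); d_V <- matrix(0, E, W)
    for (h in seq_len(Hh)) {
      rows <- ((h - 1L) * dh + 1L):(h * dh)
      al <- st$alphas[[h]]
      Vh <- st$V[rows, , drop = FALSE]
      d_Oh <- d_O[rows, , drop = FALSE]
      d_al <- t(crossprod(Vh, d_Oh))           # W x W
      d_V[rows, ] <- d_Oh %*% al
      d_S <- (d_al - rowSums(d_al * al)) * al
      d_S <- d_S / sqrt(dh)
      d_Q[rows, ] <- st$K[rows, , drop = FALSE] %*% t(d_S)
      d_K[rows, ] <- st$Q[rows, , drop = FALSE] %*% d_S
    }
    g$attn.Wq <- g$attn.Wq + d_Q %*% t(st$Z0)
    g$attn.bq <- g$attn.bq + rowSums(d_Q)
    g$attn.Wk <- g$attn.Wk + d_K %*% t(st$Z0)
    g$attn.bk <- g$attn.bk + rowSums(d_K)
    g$attn.Wv <- g$attn.Wv + d_V %*% t(st$Z0)
    g$attn.bv <- g$attn.bv + rowSums(d_V)
    d_Z0 <- d_R1 + crossprod(p$attn.Wq, d_Q) +
      crossprod(p$attn.Wk, d_K) + crossprod(p$attn.Wv, d_V)
    g$pos <- g$pos + d_Z0
    d_TK[, t:(t + W - 1L)] <- d_TK[, t:(t + W - 1L)] + d_Z0
  }
  g$tok.W <- d_TK %*% t(cache$xp)
  g$tok.b <- rowSums(d_TK)
  d_xp <- crossprod(p$tok.W, d_TK)
  list(d_params = g, d_x = d_xp[, W:(W + Tlen - 1L), drop = FALSE])
}

# ------------------------------------------------------------- statenet ----

fw_statenet <- function(model, x, training, state0 = NULL, tbptt = NULL) {
  p <- model$params; sp <- model$spec
  idx <- lc_geometry(sp$n_freqs, sp$lc_kernel, sp$lc_stride)
  u0 <- lc_forward(x, p$lc.kern, p$lc.bias, idx)
  bn <- bn_forward(u0, p$bn.gamma, p$bn.beta, model$buffers, "bn",
                   training)
  U <- bn$out
  cp <- core_params(p)
  nowarmup <- !is.null(tbptt) && !isTRUE(tbptt$warmup)
  if (nowarmup) {
    cf <- core_nowarmup_forward_cpp(sp$core, cp, U, as.integer(tbptt$K))
    final <- NULL
  } else {
    cf <- core_forward_cpp(sp$core, cp, U, state0)
    final <- cf$final
  }
  states <- cf$states
  y <- p$Wro %*% states + p$bro
  if (sp$output_nl) {
    de <- dexp_forward(y, p$nl.a, p$nl.b, p$nl.k, p$nl.s)
    pred <- de$out; dexp_cache <- de$cache
  } else {
    pred <- y; dexp_cache <- NULL
  }
  list(pred = pred, buffers = bn$buffers, final_state = final,
       cache = list(x = x, idx = idx, bn = bn$cache, U = U,
                    core_cache = cf, states = states,
                    dexp = dexp_cache, tbptt = tbptt))
}

bw_statenet <- function(model, cache, d_pred) {
  p <- model$params; sp <- model$spec
  g <- list()
  if (sp$output_nl) {
    db <- dexp_backward(cache$dexp, d_pred)
    d_y <- db$d_x
    g$nl.a <- db$d_a; g$nl.b <- db$d_b; g$nl.k <- db$d_k; g$nl.s <- db$d_s
  } else d_y <- d_pred
  g$Wro <- d_y %*% t(cache$states)
  g$bro <- rowSums(d_y)
  d_states <- crossprod(p$Wro, d_y)
  cp <- core_params(p)
  tb <- cache$tbptt
  if (is.null(tb)) {
    cb <- core_backward_cpp(sp$core, cp, cache$core_cache, cache$U,
                            d_states, K = 0L)
  } else if (isTRUE(tb$warmup)) {
    cb <- core_backward_cpp(sp$core, cp, cache$core_cache, cache$U,
                            d_states, K = as.integer(tb$K))
  } else {
    cb <- core_nowarmup_backward_cpp(sp$core, cp, cache$U, d_states,
                                     as.integer(tb$K))
  }
  for (nm in names(cb$d_params))
    g[[paste0("core.", nm)]] <- cb$d_params[[nm]]
  bnb <- bn_backward(cache$bn, cb$d_U)
  g$bn.gamma <- bnb$d_gamma; g$bn.beta <- bnb$d_beta
  lcb <- lc_backward(cache$x, p$lc.kern, cache$idx, bnb$d_z)
  g$lc.kern <- lcb$d_kern; g$lc.bias <- lcb$d_bias
  list(d_params = g, d_x = lcb$d_x)
}

# a gradient accumulator with the same shapes as a parameter list
zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.array(p)) array(0, dim(p)) else numeric(length(p))
  })
}

#' Predict rate time series from a cochleagram
#'
#' Runs the encoder forward in inference mode (frozen batch-normalisation
#' statistics) and returns the `N x T` matrix of predicted rates. The map
#' is causal: the prediction at bin `t` depends only on input bins `<= t`.
#'
#' @param object a `causal_encoder`.
#' @param x a [cochleagram] or plain `F x T` matrix.
#' @param ... unused.
#' @return `N x T` numeric matrix.
#' @export
predict.causal_encoder <- function(object, x, ...) {
  encoder_forward(object, x, training = FALSE)$pred
}

#' Advance a stateful encoder by one time bin
#'
#' Feeds a single frequency vector to a `statenet` encoder and returns the
#' predicted rates for that bin together with the updated hidden state.
#' Iterating over the bins of a clip starting from `state = NULL` (the
#' null state `h0 = 0`) reproduces [predict.causal_encoder()] exactly.
#' Carrying the returned state across clips instead of resetting it lets
#' the model integrate context beyond clip boundaries.
#'
#' @param model a `statenet` `causal_encoder`.
#' @param x_t length-`F` numeric vector (one cochleagram column).
#' @param state `NULL` for the default null state, or the `state` element
#'   of a previous call.
#' @return list with `rates` (length-`N` vector) and `state`.
#' @export
encoder_step <- function(model, x_t, state = NULL) {
  sp <- model$spec
  if (sp$architecture != "statenet")
    stop_arg("encoder_step supports statenet architectures")
  x_t <- as.numeric(x_t)
  if (length(x_t) != sp$n_freqs)
    stop_arg("x_t must have length F = %d", sp$n_freqs)
  if (!is.null(state)) check_state_shape(sp, state)
  fw <- fw_statenet(model, matrix(x_t, ncol = 1), training = FALSE,
                    state0 = state)
  list(rates = as.numeric(fw$pred), state = fw$final_state)
}

check_state_shape <- function(sp, state) {
  G <- sp$hidden
  need <- switch(sp$core, lstm = c("h", "c"), ssm = "s", "h")
  for (nm in need) {
    if (is.null(state[[nm]]) || length(state[[nm]]) != G)
      stop_arg("state component '%s' must have length %d", nm, G)
  }
  invisible(TRUE)
}

#' Extract model coefficients
#'
#' For `linear` and `ln` encoders returns the STRF weights as an
#' `F x W x N` array (lag 0 in column 1); for other architectures returns
#' the raw parameter list.
#'
#' @param object a `causal_encoder`.
#' @param ... unused.
#' @export
coef.causal_encoder <- function(object, ...) {
  sp <- object$spec
  if (sp$architecture %in% c("linear", "ln")) {
    arr <- array(0, c(sp$n_freqs, sp$trf_bins, sp$n_neurons))
    for (n in seq_len(sp$n_neurons))
      arr[, , n] <- matrix(object$params$W[n, ], sp$n_freqs, sp$trf_bins)
    arr
  } else object$params
}
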