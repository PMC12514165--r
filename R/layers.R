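# Differentiable building blocks shared by the encoder architectures.
# Every layer has a forward returning (out, cache) and a matching backward
# mapping d_out to parameter gradients and d_in. Shapes follow the
# channels-by-time convention used throughout: a C x T matrix per clip.

# ---------------------------------------------------------------------------
# Lagged design ("im2col" for causal temporal convolution): stacks W lagged
# copies of an F x T input into an (F*W) x T matrix, left zero-padded, so a
# causal STRF convolution is a single matrix product.
# ---------------------------------------------------------------------------

lag_design <- function(x, W) {
  F <- nrow(x); T <- ncol(x)
  if (W < 1) stop_arg("window W must be >= 1")
  out <- matrix(0, F * W, T)
  for (w in seq_len(min(W, T))) {
    rows <- ((w - 1) * F + 1):(w * F)
    out[rows, w:T] <- x[, 1:(T - w + 1), drop = FALSE]
  }
  out
}

# scatter the gradient of a lagged design back onto the input
lag_design_backward <- function(d_lag, F, W) {
  T <- ncol(d_lag)
  d_x <- matrix(0, F, T)
  for (w in seq_len(min(W, T))) {
    rows <- ((w - 1) * F + 1):(w * F)
    d_x[, 1:(T - w + 1)] <- d_x[, 1:(T - w + 1)] +
      d_lag[rows, w:T, drop = FALSE]
  }
  d_x
}

# ---------------------------------------------------------------------------
# Batch normalization over the time axis, one statistic per channel (row).
# Training mode normalises with the current clip's statistics (population
# variance) and updates running buffers; inference mode applies the frozen
# affine map. Training-mode statistics make the output depend on the whole
# clip, so causality contracts hold in inference mode.
# ---------------------------------------------------------------------------

bn_forward <- function(z, gamma, beta, buffers, prefix, training,
                       momentum = 0.1, eps = 1e-5) {
  rm_name <- paste0(prefix, ".running_mean")
  rv_name <- paste0(prefix, ".running_var")
  if (training) {
    mu <- rowMeans(z)
    v <- rowMeans((z - mu)^2)
    buffers[[rm_name]] <- (1 - momentum) * buffers[[rm_name]] + momentum * mu
    buffers[[rv_name]] <- (1 - momentum) * buffers[[rv_name]] + momentum * v
  } else {
    mu <- buffers[[rm_name]]
    v <- buffers[[rv_name]]
  }
  std <- sqrt(v + eps)
  zhat <- (z - mu) / std
  out <- gamma * zhat + beta
  list(out = out, buffers = buffers,
       cache = list(zhat = zhat, std = std, gamma = gamma,
                    training = training))
}

bn_backward <- function(cache, d_out) {
  zhat <- cache$zhat
  d_gamma <- rowSums(d_out * zhat)
  d_beta <- rowSums(d_out)
  d_zhat <- d_out * cache$gamma
  if (cache$training) {
    d_z <- (d_zhat - rowMeans(d_zhat) - zhat * rowMeans(d_zhat * zhat)) /
      cache$std
  } else {
    d_z <- d_zhat / cache$std
  }
  list(d_z = d_z, d_gamma = d_gamma, d_beta = d_beta)
}

bn_init_buffers <- function(buffers, prefix, n) {
  buffers[[paste0(prefix, ".running_mean")]] <- numeric(n)
  buffers[[paste0(prefix, ".running_var")]] <- rep(1, n)
  buffers
}

# ---------------------------------------------------------------------------
# Locally connected (LC) frequency-downsampling layer: convolution-like
# windows over the frequency axis with position-specific (unshared)
# weights, preserving tonotopic order. The frequency axis is zero-padded at
# both ends so H = ceil(F / stride) windows fit.
# ---------------------------------------------------------------------------

lc_geometry <- function(F, k, stride) {
  if (k > F) stop_arg("LC kernel length k (%d) exceeds F (%d)", k, F)
  H <- ceiling(F / stride)
  pad_total <- max(0L, (H - 1L) * stride + k - F)
  pad_left <- pad_total %/% 2L
  idx <- matrix(0L, H, k)
  for (h in seq_len(H)) {
    pos <- (h - 1L) * stride + seq_len(k) - pad_left
    pos[pos < 1L | pos > F] <- 0L
    idx[h, ] <- pos
  }
  idx
}

# kern: H x k, bias: H, idx: H x k index map (0 = padded), x: F x T
lc_forward <- function(x, kern, bias, idx) {
  H <- nrow(idx); T <- ncol(x)
  out <- matrix(bias, H, T)
  for (j in seq_len(ncol(idx))) {
    sel <- idx[, j] > 0L
    if (!any(sel)) next
    out[sel, ] <- out[sel, ] + kern[sel, j] * x[idx[sel, j], , drop = FALSE]
  }
  out
}

lc_backward <- function(x, kern, idx, d_out) {
  d_kern <- matrix(0, nrow(kern), ncol(kern))
  d_x <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(idx))) {
    sel <- idx[, j] > 0L
    if (!any(sel)) next
    rows <- idx[sel, j]
    d_kern[sel, j] <- rowSums(d_out[sel, , drop = FALSE] *
                                x[rows, , drop = FALSE])
    d_x[rows, ] <- d_x[rows, ] + kern[sel, j] * d_out[sel, , drop = FALSE]
  }
  list(d_kern = d_kern, d_bias = rowSums(d_out), d_x = d_x)
}

#' Locally connected spectral projection
#'
#' Projects a single frequency vector through a locally connected layer:
#' `H` restricted receptive-field windows over frequency, each with its own
#' (unshared) weights, preserving tonotopic order. With `k = F`,
#' `stride = F` it degenerates to one fully connected row; with `k = 1`,
#' `stride = 1` and unit kernels it is the identity. Its parameter count
#' `H * (k + 1)` sits strictly between a shared-kernel convolution
#' (`k + 1`) and a fully connected layer (`H * (F + 1)`) for `1 < k < F`.
#'
#' @param freq_vector length-`F` numeric vector.
#' @param kernels `H x k` weight matrix.
#' @param biases length-`H` bias vector.
#' @param stride window stride over frequency.
#' @return length-`H` numeric vector.
#' @export
locally_connected_project <- function(freq_vector, kernels, biases,
                                      stride = 1L) {
  F <- length(freq_vector)
  k <- ncol(kernels)
  idx <- lc_geometry(F, k, stride)
  if (nrow(kernels) != nrow(idx))
    stop_arg("kernels has %d rows; geometry requires H = %d",
             nrow(kernels), nrow(idx))
  as.numeric(lc_forward(matrix(freq_vector, F, 1), kernels, biases, idx))
}

# ---------------------------------------------------------------------------
# 2-D convolution over (frequency, time) via shift-and-add, causal in time
# (left zero padding), "same" zero padding in frequency. Tensors are 3-D
# arrays (channels, F, T); kernels are (C_out, C_in, kf, kt) with kt time
# offsets 0 .. kt-1 bins into the past.
# ---------------------------------------------------------------------------

conv2d_forward <- function(A, kern, bias) {
  dA <- dim(A); C_in <- dA[1]; F <- dA[2]; T <- dA[3]
  dk <- dim(kern); C_out <- dk[1]; kf <- dk[3]; kt <- dk[4]
  pf <- (kf - 1L) %/% 2L
  out <- array(0, c(C_out, F, T))
  for (jt in seq_len(kt)) {
    dt_off <- jt - 1L                       # bins into the past
    t_dst <- (1L + dt_off):T
    t_src <- 1L:(T - dt_off)
    if (dt_off >= T) next
    for (jf in seq_len(kf)) {
      df <- jf - 1L - pf
      f_dst <- max(1L, 1L + df):min(F, F + df)
      f_src <- f_dst - df
      Wm <- matrix(kern[, , jf, jt], C_out, C_in)
      Asub <- A[, f_src, t_src, drop = FALSE]
      contrib <- Wm %*% matrix(Asub, C_in, length(f_src) * length(t_src))
      out[, f_dst, t_dst] <- out[, f_dst, t_dst, drop = FALSE] +
        array(contrib, c(C_out, length(f_dst), length(t_dst)))
    }
  }
  out <- out + array(rep(bias, F * T), c(C_out, F, T))
  out
}

conv2d_backward <- function(A, kern, d_out) {
  dA <- dim(A); C_in <- dA[1]; F <- dA[2]; T <- dA[3]
  dk <- dim(kern); C_out <- dk[1]; kf <- dk[3]; kt <- dk[4]
  pf <- (kf - 1L) %/% 2L
  d_A <- array(0, dim(A))
  d_kern <- array(0, dim(kern))
  for (jt in seq_len(kt)) {
    dt_off <- jt - 1L
    if (dt_off >= T) next
    t_dst <- (1L + dt_off):T
    t_src <- 1L:(T - dt_off)
    for (jf in seq_len(kf)) {
      df <- jf - 1L - pf
      f_dst <- max(1L, 1L + df):min(F, F + df)
      f_src <- f_dst - df
      L <- length(f_dst) * length(t_dst)
      Dsub <- matrix(d_out[, f_dst, t_dst, drop = FALSE], C_out, L)
      Asub <- matrix(A[, f_src, t_src, drop = FALSE], C_in, L)
      d_kern[, , jf, jt] <- matrix(d_kern[, , jf, jt], C_out, C_in) +
        Dsub %*% t(Asub)
      Wm <- matrix(kern[, , jf, jt], C_out, C_in)
      d_A[, f_src, t_src] <- d_A[, f_src, t_src, drop = FALSE] +
        array(t(Wm) %*% Dsub, c(C_in, length(f_src), length(t_src)))
    }
  }
  d_bias <- apply(d_out, 1, sum)
  list(d_A = d_A, d_kern = d_kern, d_bias = d_bias)
}

# elementwise sigmoid with backward
sigmoid <- function(x) 1 / (1 + exp(-x))
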