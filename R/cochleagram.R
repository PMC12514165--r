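#' Cochleagram stimulus container
#'
#' A cochleagram is the universal model input: an `F x T` non-negative real
#' matrix of compressed spectral power, with `F` ascending frequency bands
#' (rows) and `T` time bins of duration `dt` seconds (columns). It is the
#' spectrogram-like representation produced by cochlear filterbank models
#' (log-spaced mel or gammatone filters followed by a compressive
#' nonlinearity).
#'
#' @param values numeric `F x T` matrix of finite values.
#' @param freqs length-`F` strictly increasing vector of positive centre
#'   frequencies in Hz. Defaults to an octave-spaced ladder starting at
#'   500 Hz.
#' @param dt time-bin duration in seconds (default `0.005`, i.e. 5 ms).
#' @param clip_id character identifier for the stimulus clip.
#'
#' @return An object of class `cochleagram`: the value matrix with
#'   attributes `freqs`, `dt` and `clip_id`.
#' @examples
#' x <- cochleagram(matrix(abs(rnorm(16 * 100)), 16, 100))
#' dim(x)
#' @export
cochleagram <- function(values, freqs = NULL, dt = 0.005,
                        clip_id = "clip") {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop_arg("cochleagram values must be a finite numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_arg("cochleagram must have F >= 1 and T >= 1")
  if (is.null(freqs))
    freqs <- 500 * 2^(seq_len(nrow(values)) / 4)
  if (length(freqs) != nrow(values))
    stop_arg("length(freqs) must equal nrow(values)")
  if (any(freqs <= 0) || any(diff(freqs) <= 0))
    stop_arg("freqs must be strictly increasing and positive")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_arg("dt must be a positive scalar")
  structure(values, freqs = as.numeric(freqs), dt = as.numeric(dt),
            clip_id = as.character(clip_id),
            class = c("cochleagram", "matrix", "array"))
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram '%s': %d frequency bands x %d bins of %.1f ms>\n",
              attr(x, "clip_id"), nrow(x), ncol(x), 1000 * attr(x, "dt")))
  invisible(x)
}

# strip class/attributes down to a plain matrix
coch_values <- function(x) {
  y <- unclass(x)
  attr(y, "freqs") <- NULL
  attr(y, "dt") <- NULL
  attr(y, "clip_id") <- NULL
  y
}

is_cochleagram <- function(x) inherits(x, "cochleagram")
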