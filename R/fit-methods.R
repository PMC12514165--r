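# S3 methods for fitted encoders.

#' @export
print.encoder_fit <- function(x, ...) {
  sp <- x$spec
  test <- x$metrics[x$metrics$split == "test", ]
  cat(sprintf("Encoder fit: %s%s (%d neurons, seed %d)\n",
              sp$architecture,
              if (sp$architecture == "statenet")
                paste0("-", sp$core) else "",
              sp$n_neurons, x$seed))
  cat(sprintf("  best epoch %d (validation MSE %.5f, %d epochs run)\n",
              x$best_epoch, min(x$loss$valid), nrow(x$loss)))
  cat(sprintf("  test CC_raw %.3f, test CC_norm %.3f (means over neurons)\n",
              mean(test$cc_raw), mean(test$cc_norm)))
  invisible(x)
}

#' Summarise a fitted encoder
#'
#' @param object an [encoder_fit].
#' @param ... unused.
#' @return object of class `summary.encoder_fit`: per-split mean metrics
#'   and the per-neuron test table.
#' @export
summary.encoder_fit <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object$metrics,
                                     object$metrics$split), function(d)
    data.frame(split = d$split[1], cc_raw = mean(d$cc_raw),
               cc_norm = mean(d$cc_norm))))
  structure(list(aggregate = agg[c("train", "valid", "test"), ],
                 test = object$metrics[object$metrics$split == "test", ],
                 spec = object$spec, best_epoch = object$best_epoch,
                 n_epochs = nrow(object$loss)),
            class = "summary.encoder_fit")
}

#' @export
print.summary.encoder_fit <- function(x, ...) {
  cat(sprintf("%s encoder, %d epochs (best %d)\n",
              x$spec$architecture, x$n_epochs, x$best_epoch))
  cat("Mean correlation per split:\n")
  print(x$aggregate, row.names = FALSE, digits = 3)
  cat("Per-neuron test metrics:\n")
  print(head(x$test, 10), row.names = FALSE, digits = 3)
  if (nrow(x$test) > 10) cat(sprintf("  ... %d more neurons\n",
                                     nrow(x$test) - 10))
  invisible(x)
}

#' @export
coef.encoder_fit <- function(object, ...) coef(object$model, ...)

#' Predict from a fitted encoder
#'
#' @param object an [encoder_fit].
#' @param newdata a [cochleagram], plain `F x T` matrix, or an
#'   [encoding_dataset] (returns a list of predictions per clip).
#' @param ... unused.
#' @return `N x T` matrix, or a named list of them.
#' @export
predict.encoder_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "encoding_dataset"))
    lapply(newdata$stimuli, function(x) predict(object$model, x))
  else predict(object$model, newdata)
}

#' Fitted values on the training split
#'
#' @param object an [encoder_fit].
#' @param dataset the [encoding_dataset] the model was fitted to.
#' @param split which split to reproduce (default `"train"`).
#' @param ... unused.
#' @return list per clip of `N x T` predicted-rate matrices.
#' @export
fitted.encoder_fit <- function(object, dataset, split = "train", ...) {
  ids <- clip_ids(dataset, split)
  out <- lapply(ids, function(cid) predict(object$model,
                                           dataset$stimuli[[cid]]))
  names(out) <- ids
  out
}

#' Residuals of a fitted encoder
#'
#' Prediction minus PSTH, per clip of the chosen split.
#'
#' @inheritParams fitted.encoder_fit
#' @return list per clip of `N x T` residual matrices.
#' @export
residuals.encoder_fit <- function(object, dataset, split = "train", ...) {
  ids <- clip_ids(dataset, split)
  out <- lapply(ids, function(cid)
    predict(object$model, dataset$stimuli[[cid]]) -
      dataset$psth[[cid]][dataset$neurons, , drop = FALSE])
  names(out) <- ids
  out
}

#' Simulate trial responses from a fitted encoder
#'
#' Draws Gaussian trial noise around the model's predicted rates, giving
#' surrogate multi-trial recordings. The noise standard deviation defaults
#' to the residual standard deviation on the training split.
#'
#' @param object an [encoder_fit].
#' @param nsim number of trials per clip.
#' @param seed integer seed.
#' @param dataset the [encoding_dataset] providing stimuli (and the
#'   residual scale).
#' @param sigma trial-noise standard deviation (default: residual sd).
#' @param ... unused.
#' @return list per clip of per-neuron `nsim x T` trial matrices.
#' @export
simulate.encoder_fit <- function(object, nsim = 10, seed = 1L,
                                 dataset, sigma = NULL, ...) {
  if (is.null(sigma)) {
    res <- residuals(object, dataset)
    sigma <- sd(unlist(res))
  }
  preds <- predict(object, dataset)
  with_seed(seed, {
    lapply(preds, function(p) {
      out <- lapply(seq_len(nrow(p)), function(n)
        matrix(p[n, ], nsim, ncol(p), byrow = TRUE) +
          matrix(rnorm(nsim * ncol(p), sd = sigma), nsim))
      names(out) <- dataset$neurons
      out
    })
  })
}

#' Plot a fitted encoder
#'
#' `type = "loss"` draws the train/validation loss trajectories;
#' `type = "strf"` images the STRF (linear/ln) or GradMap (other
#' architectures) of one neuron, frequency by latency.
#'
#' @param x an [encoder_fit].
#' @param type `"loss"` or `"strf"`.
#' @param neuron neuron index for `type = "strf"`.
#' @param T gradmap horizon for non-linear architectures.
#' @param ... passed to the underlying plotting function.
#' @export
plot.encoder_fit <- function(x, type = c("loss", "strf"), neuron = 1L,
                             T = 50L, ...) {
  type <- match.arg(type)
  if (type == "loss") {
    matplot(x$loss$epoch, cbind(x$loss$train, x$loss$valid), type = "l",
            lty = 1, col = c("grey40", "firebrick"), xlab = "epoch",
            ylab = "MSE", ...)
    abline(v = x$best_epoch, lty = 3)
    legend("topright", c("train", "valid"), lty = 1,
           col = c("grey40", "firebrick"), bty = "n")
  } else {
    if (x$spec$architecture %in% c("linear", "ln")) {
      m <- coef(x)[, , neuron]
      m <- m[, rev(seq_len(ncol(m))), drop = FALSE]  # latency left = old
    } else {
      m <- as.matrix(gradmap(x, target = neuron, T = T))
    }
    image(t(m), xlab = "time (old -> recent)", ylab = "frequency band",
          col = hcl.colors(64, "RdBu", rev = TRUE), axes = FALSE, ...)
  }
  invisible(x)
}
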