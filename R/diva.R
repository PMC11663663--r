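#' Construct a DIVA model
#'
#' The divergent autoencoder (DIVA) is a three-layer network with a shared
#' hidden layer and one decoder "channel" per category. Inputs are encoded
#' through a sigmoid hidden layer; each channel tries to reconstruct the
#' input through its own sigmoid output layer; a stimulus is classified into
#' the category whose channel reconstructs it with least error. Learning is
#' one online backpropagation step per trial, on the true category's channel
#' only. The default architecture is 3 input units, 2 hidden units and
#' 3 output units per channel (6 total for two categories), with every
#' weight (biases included) initialised uniformly on
#' `[-weight_range, +weight_range]`.
#'
#' @param n_inputs Number of input features (default 3).
#' @param n_hidden Number of hidden (bottleneck) units (default 2).
#' @param n_categories Number of category channels (default 2).
#' @param weight_range Half-width of the uniform initialisation interval
#'   (default 0.5, i.e. weights in plus/minus 0.5).
#' @param learning_rate Gradient-descent step size (default 1).
#' @param sensitivity Scale on the squared feature errors (default 1).
#' @param attention_breadth Uniform feature-attention weight; the hook is a
#'   no-op at its default of 1.
#' @param seed Optional integer; if supplied the initial weights are drawn
#'   after `set.seed(seed)` so identical seeds give identical models.
#' @return An object of class `diva`: a list with `W_enc`
#'   (`(n_inputs+1) x n_hidden`, last row the bias), `W_dec` (a list of
#'   `(n_hidden+1) x n_inputs` matrices, one per channel) and the
#'   hyperparameters.
#' @examples
#' m <- diva(seed = 1)
#' diva_forward(m, c(0, 1, 1))$channel_errors
#' @export
diva <- function(n_inputs = 3L, n_hidden = 2L, n_categories = 2L,
                 weight_range = 0.5, learning_rate = 1, sensitivity = 1,
                 attention_breadth = 1, seed = NULL) {
  .check_dims(n_inputs, n_hidden, n_categories)
  if (!is.numeric(weight_range) || length(weight_range) != 1L || weight_range < 0) {
    stop("`weight_range` must be a single nonnegative number", call. = FALSE)
  }
  if (learning_rate < 0 || sensitivity <= 0) {
    stop("`learning_rate` must be >= 0 and `sensitivity` > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  W_enc <- matrix(stats::runif((n_inputs + 1L) * n_hidden, -weight_range, weight_range),
                  n_inputs + 1L, n_hidden)
  W_dec <- lapply(seq_len(n_categories), function(k) {
    matrix(stats::runif((n_hidden + 1L) * n_inputs, -weight_range, weight_range),
           n_hidden + 1L, n_inputs)
  })
  structure(
    list(W_enc = W_enc, W_dec = W_dec,
         n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
         n_categories = as.integer(n_categories),
         learning_rate = learning_rate, sensitivity = sensitivity,
         attention_breadth = attention_breadth, seed = seed),
    class = "diva"
  )
}

.check_dims <- function(n_inputs, n_hidden, n_categories) {
  ok <- function(n) is.numeric(n) && length(n) == 1L && !is.na(n) && n >= 1
  if (!ok(n_inputs) || !ok(n_hidden) || !ok(n_categories)) {
    stop("network dimensions must be positive integers", call. = FALSE)
  }
  invisible(TRUE)
}

.check_stimulus <- function(model, stimulus) {
  if (!is.numeric(stimulus) || length(stimulus) != model$n_inputs) {
    stop(sprintf("stimulus must be a numeric vector of length %d", model$n_inputs),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Forward pass of a DIVA model
#'
#' Propagates one stimulus through the encoder and every category channel.
#' Hidden activations are `sigmoid(W_enc' [x, 1])`; each channel's
#' reconstruction is `sigmoid(W_dec_k' [h, 1])`, so every activation lies
#' strictly in (0, 1) for finite weights.
#'
#' @param model A `diva` object.
#' @param stimulus Numeric feature vector of length `n_inputs`.
#' @return A list with `hidden` (length `n_hidden`), `reconstructions`
#'   (`n_categories x n_inputs` matrix) and `channel_errors` (one
#'   sensitivity-scaled summed squared error per channel).
#' @export
diva_forward <- function(model, stimulus) {
  .check_stimulus(model, stimulus)
  stimulus <- unname(as.numeric(stimulus))
  xb <- c(stimulus, 1)
  hidden <- stats::plogis(drop(xb %*% model$W_enc))
  zb <- c(hidden, 1)
  recon <- t(vapply(model$W_dec,
                    function(W) stats::plogis(drop(zb %*% W)),
                    numeric(model$n_inputs)))
  errs <- apply(recon, 1L, reconstruction_error, stimulus = stimulus,
                sensitivity = model$sensitivity,
                attention = model$attention_breadth)
  list(hidden = hidden, reconstructions = recon, channel_errors = errs)
}

#' Channel reconstruction error
#'
#' Sum over features of `sensitivity * attention * (reconstruction - stimulus)^2`.
#' Zero exactly when the reconstruction equals the stimulus. `attention` is
#' the uniform feature-attention weight (a no-op at 1).
#'
#' @param reconstruction Numeric vector, a channel's output.
#' @param stimulus Numeric vector of the same length.
#' @param sensitivity Positive scalar error scale.
#' @param attention Uniform feature weight (default 1).
#' @return A single nonnegative number.
#' @examples
#' reconstruction_error(rep(0.5, 3), c(0, 1, 0))  # 0.75
#' @export
reconstruction_error <- function(reconstruction, stimulus, sensitivity = 1,
                                 attention = 1) {
  if (length(reconstruction) != length(stimulus)) {
    stop("reconstruction and stimulus must have the same length", call. = FALSE)
  }
  if (sensitivity <= 0) stop("`sensitivity` must be positive", call. = FALSE)
  sum(sensitivity * attention * (reconstruction - stimulus)^2)
}

#' Classify from channel errors
#'
#' Returns the index of the channel with least reconstruction error. Exact
#' ties are broken uniformly at random using the current RNG stream;
#' non-finite errors are treated as infinitely bad, and if every channel is
#' non-finite the response is a uniform random guess.
#'
#' @param channel_errors Numeric vector of per-channel errors (length >= 2).
#' @return An integer channel index.
#' @export
classify <- function(channel_errors) {
  if (length(channel_errors) < 1L) stop("no channel errors supplied", call. = FALSE)
  e <- channel_errors
  e[!is.finite(e)] <- Inf
  if (all(e == Inf)) return(sample.int(length(e), 1L))
  m <- which(e == min(e))
  if (length(m) > 1L) m[sample.int(length(m), 1L)] else m
}

#' One DIVA learning trial
#'
#' Performs a single gradient-descent step (step size `learning_rate`) on
#' the reconstruction error of the true category's channel. Only the encoder
#' weights and that channel's decoder weights change; the other channels'
#' weights are untouched, which is what lets each channel become
#' category-specific.
#'
#' @param model A `diva` object.
#' @param stimulus Numeric feature vector.
#' @param true_category Integer index of the supervised category.
#' @return The updated `diva` object.
#' @export
diva_learn <- function(model, stimulus, true_category) {
  .check_stimulus(model, stimulus)
  stimulus <- unname(as.numeric(stimulus))
  k <- as.integer(true_category)
  if (is.na(k) || k < 1L || k > model$n_categories) {
    stop("`true_category` out of range", call. = FALSE)
  }
  xb <- c(stimulus, 1)
  h <- stats::plogis(drop(xb %*% model$W_enc))
  zb <- c(h, 1)
  W <- model$W_dec[[k]]
  r <- stats::plogis(drop(zb %*% W))
  # dE/dpre at the outputs: E = sum s*a*(r - x)^2, r = sigmoid(pre)
  dpre <- 2 * model$sensitivity * model$attention_breadth * (r - stimulus) * r * (1 - r)
  grad_dec <- outer(zb, dpre)
  dh <- drop(W[seq_len(model$n_hidden), , drop = FALSE] %*% dpre)
  da <- dh * h * (1 - h)
  grad_enc <- outer(xb, da)
  model$W_dec[[k]] <- W - model$learning_rate * grad_dec
  model$W_enc <- model$W_enc - model$learning_rate * grad_enc
  model
}

#' @export
print.diva <- function(x, ...) {
  cat(sprintf("DIVA model: %d-%d-%dx%d (inputs-hidden-outputs x channels)\n",
              x$n_inputs, x$n_hidden, x$n_inputs, x$n_categories))
  cat(sprintf("  learning_rate = %g, sensitivity = %g, attention_breadth = %g\n",
              x$learning_rate, x$sensitivity, x$attention_breadth))
  invisible(x)
}

#' Predict categories for stimuli
#'
#' @param object A `diva` object.
#' @param newdata Matrix of stimuli (one row each) or a single stimulus vector.
#' @param type `"class"` for category indices (deterministic argmin, first
#'   index on ties) or `"error"` for the matrix of channel errors.
#' @param ... Unused.
#' @return Integer vector of category indices, or a matrix of channel errors.
#' @export
predict.diva <- function(object, newdata, type = c("class", "error"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  errs <- t(apply(newdata, 1L, function(x) diva_forward(object, x)$channel_errors))
  if (type == "error") return(errs)
  apply(errs, 1L, which.min)
}
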