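#' Construct a BR-DIVA model
#'
#' BR-DIVA is the boundedly rational, variational extension of DIVA. The
#' encoder maps a stimulus to two independent Gaussian latents: means are an
#' affine function of the input (`mu_weights`) and standard deviations come
#' from an affine log-variance map (`sigma = exp(logvar / 2)`), so `sigma`
#' is always positive. A latent sample `z = mu + sigma * epsilon`
#' (reparameterisation trick, `epsilon ~ N(0, 1)`) is used directly -- no
#' squashing -- as the hidden activation feeding every sigmoid decoder
#' channel. The training loss on a trial is the true channel's
#' reconstruction error plus `beta` times the Kullback-Leibler divergence of
#' the encoder's posterior from the fixed standard-normal prior. `beta` is
#' the capacity parameter: larger values bias representations more strongly
#' toward the prior.
#'
#' Note that with the conventional learning rate of 1, plain gradient
#' descent on the KL term is only stable for `beta` below roughly 0.5 (the
#' mean-path curvature is `beta * ||x~||^2`, up to `4 * beta` here). Larger
#' `beta` values make the weights oscillate and eventually overflow; such
#' runs are tolerated (classification falls back to guessing) but learn
#' nothing. The default `beta = 0.1` is the largest decade-scale value on
#' the standard 0.01-100 grid for which optimisation is stable.
#'
#' @inheritParams diva
#' @param beta Nonnegative weight on the KL penalty (default 0.1).
#' @return An object of class `brdiva`: a list with `W_mu`, `W_logvar`
#'   (each `(n_inputs+1) x n_hidden`), `W_dec` (list of
#'   `(n_hidden+1) x n_inputs` matrices) and the hyperparameters. The prior
#'   is the fixed standard normal and is not a learned quantity.
#' @examples
#' m <- br_diva(beta = 0.1, seed = 1)
#' brdiva_encode(m, c(1, 0, 1))
#' @export
br_diva <- function(n_inputs = 3L, n_hidden = 2L, n_categories = 2L,
                    beta = 0.1, weight_range = 0.5, learning_rate = 1,
                    sensitivity = 1, attention_breadth = 1, seed = NULL) {
  .check_dims(n_inputs, n_hidden, n_categories)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("`beta` must be a single nonnegative number", call. = FALSE)
  }
  if (learning_rate < 0 || sensitivity <= 0) {
    stop("`learning_rate` must be >= 0 and `sensitivity` > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  W_mu <- matrix(stats::runif((n_inputs + 1L) * n_hidden, -weight_range, weight_range),
                 n_inputs + 1L, n_hidden)
  W_logvar <- matrix(stats::runif((n_inputs + 1L) * n_hidden, -weight_range, weight_range),
                     n_inputs + 1L, n_hidden)
  W_dec <- lapply(seq_len(n_categories), function(k) {
    matrix(stats::runif((n_hidden + 1L) * n_inputs, -weight_range, weight_range),
           n_hidden + 1L, n_inputs)
  })
  structure(
    list(W_mu = W_mu, W_logvar = W_logvar, W_dec = W_dec, beta = beta,
         n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
         n_categories = as.integer(n_categories),
         learning_rate = learning_rate, sensitivity = sensitivity,
         attention_breadth = attention_breadth, seed = seed),
    class = "brdiva"
  )
}

#' Encode a stimulus to its latent Gaussian parameters
#'
#' @param model A `brdiva` object.
#' @param stimulus Numeric feature vector.
#' @return A list with `mu` and `sigma`, each of length `n_hidden`;
#'   `sigma = exp(logvar / 2)` is strictly positive for finite weights.
#' @export
brdiva_encode <- function(model, stimulus) {
  .check_stimulus(model, stimulus)
  stimulus <- unname(as.numeric(stimulus))
  xb <- c(stimulus, 1)
  mu <- drop(xb %*% model$W_mu)
  logvar <- drop(xb %*% model$W_logvar)
  list(mu = mu, sigma = exp(logvar / 2))
}

#' Reparameterised latent sample
#'
#' `z = mu + sigma * epsilon`, componentwise. For fixed `epsilon` the sample
#' is a differentiable function of `mu` and `sigma`, which is what lets the
#' encoder be trained by gradient descent through the sampling step.
#'
#' @param mu,sigma,epsilon Numeric vectors of equal length.
#' @return The latent sample `z`.
#' @examples
#' reparameterize(c(0, 0), c(1, 1), c(1, -1))  # c(1, -1)
#' @export
reparameterize <- function(mu, sigma, epsilon) {
  if (length(mu) != length(sigma) || length(mu) != length(epsilon)) {
    stop("`mu`, `sigma` and `epsilon` must have equal lengths", call. = FALSE)
  }
  mu + sigma * epsilon
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I))
#'   = 0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))`.
#' Nonnegative everywhere; zero exactly when `mu = 0` and `sigma = 1`.
#'
#' @param mu Numeric vector of posterior means.
#' @param sigma Numeric vector of positive posterior standard deviations.
#' @return A single nonnegative number.
#' @examples
#' kl_divergence(c(0, 0), c(1, 1))  # 0
#' kl_divergence(c(1, 0), c(1, 1))  # 0.5
#' @export
kl_divergence <- function(mu, sigma) {
  if (length(mu) != length(sigma)) {
    stop("`mu` and `sigma` must have equal lengths", call. = FALSE)
  }
  if (any(!is.na(sigma) & sigma <= 0)) {
    stop("`sigma` must be strictly positive", call. = FALSE)
  }
  0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

#' Capacity-weighted training loss
#'
#' The per-trial objective: reconstruction error plus `beta` times the KL
#' divergence.
#'
#' @param recon_error Nonnegative reconstruction error.
#' @param kl Nonnegative KL divergence.
#' @param beta Nonnegative capacity weight.
#' @return `recon_error + beta * kl`.
#' @export
total_loss <- function(recon_error, kl, beta) {
  if (any(beta < 0)) stop("`beta` must be nonnegative", call. = FALSE)
  recon_error + beta * kl
}

#' Stochastic forward pass of a BR-DIVA model
#'
#' Draws one `epsilon` per latent unit (from the current RNG stream, unless
#' an `epsilon` is supplied), forms `z = mu + sigma * epsilon`, and decodes
#' `z` through every category channel. A single draw is shared by all
#' channels, and the KL divergence is computed once from the shared encoder.
#'
#' @param model A `brdiva` object.
#' @param stimulus Numeric feature vector.
#' @param epsilon Optional fixed noise vector (length `n_hidden`); pass
#'   `rep(0, n_hidden)` for a deterministic pass through `mu`.
#' @return A list with `latent` (`mu`, `sigma`, `epsilon`, `z`),
#'   `reconstructions` (`n_categories x n_inputs`), `channel_errors` and
#'   `kl`.
#' @export
brdiva_forward <- function(model, stimulus, epsilon = NULL) {
  enc <- brdiva_encode(model, stimulus)
  if (is.null(epsilon)) epsilon <- stats::rnorm(model$n_hidden)
  z <- reparameterize(enc$mu, enc$sigma, epsilon)
  zb <- c(z, 1)
  recon <- t(vapply(model$W_dec,
                    function(W) stats::plogis(drop(zb %*% W)),
                    numeric(model$n_inputs)))
  errs <- apply(recon, 1L, reconstruction_error, stimulus = stimulus,
                sensitivity = model$sensitivity,
                attention = model$attention_breadth)
  list(latent = list(mu = enc$mu, sigma = enc$sigma, epsilon = epsilon, z = z),
       reconstructions = recon, channel_errors = errs,
       kl = kl_divergence(enc$mu, enc$sigma))
}

#' One BR-DIVA learning trial
#'
#' A single gradient-descent step on
#' `total_loss(true channel's reconstruction error, KL, beta)`. The
#' reconstruction gradient flows through the sampled `z` back to both
#' `mu_weights` and `logvar_weights` via the reparameterisation; the
#' `beta * KL` gradient applies to the encoder weights only. Only the true
#' category's decoder channel is updated.
#'
#' @param model A `brdiva` object.
#' @param stimulus Numeric feature vector.
#' @param true_category Integer index of the supervised category.
#' @param epsilon Optional fixed noise vector; drawn from the current RNG
#'   stream if `NULL`. Supplying the `epsilon` from the forward pass that
#'   produced the response reuses the same sample for learning.
#' @return The updated `brdiva` object.
#' @export
brdiva_learn <- function(model, stimulus, true_category, epsilon = NULL) {
  .check_stimulus(model, stimulus)
  stimulus <- unname(as.numeric(stimulus))
  k <- as.integer(true_category)
  if (is.na(k) || k < 1L || k > model$n_categories) {
    stop("`true_category` out of range", call. = FALSE)
  }
  xb <- c(stimulus, 1)
  mu <- drop(xb %*% model$W_mu)
  logvar <- drop(xb %*% model$W_logvar)
  sigma <- exp(logvar / 2)
  if (is.null(epsilon)) epsilon <- stats::rnorm(model$n_hidden)
  z <- mu + sigma * epsilon
  zb <- c(z, 1)
  W <- model$W_dec[[k]]
  r <- stats::plogis(drop(zb %*% W))
  dpre <- 2 * model$sensitivity * model$attention_breadth * (r - stimulus) * r * (1 - r)
  grad_dec <- outer(zb, dpre)
  dz <- drop(W[seq_len(model$n_hidden), , drop = FALSE] %*% dpre)
  # dz/dmu = 1; dz/dlogvar = epsilon * sigma / 2
  # dKL/dmu = mu; dKL/dlogvar = (sigma^2 - 1) / 2
  dmu <- dz + model$beta * mu
  dlogvar <- dz * epsilon * sigma / 2 + model$beta * (sigma^2 - 1) / 2
  model$W_dec[[k]] <- W - model$learning_rate * grad_dec
  model$W_mu <- model$W_mu - model$learning_rate * outer(xb, dmu)
  model$W_logvar <- model$W_logvar - model$learning_rate * outer(xb, dlogvar)
  model
}

#' @export
print.brdiva <- function(x, ...) {
  cat(sprintf("BR-DIVA model: %d-%d-%dx%d (inputs-latents-outputs x channels)\n",
              x$n_inputs, x$n_hidden, x$n_inputs, x$n_categories))
  cat(sprintf("  beta = %g, learning_rate = %g, sensitivity = %g\n",
              x$beta, x$learning_rate, x$sensitivity))
  invisible(x)
}

#' Predict categories with a BR-DIVA model
#'
#' @param object A `brdiva` object.
#' @param newdata Matrix of stimuli (one row each) or a single stimulus vector.
#' @param type `"class"` or `"error"` as in [predict.diva()].
#' @param deterministic If `TRUE` (default) uses the noiseless `mu` pass
#'   (`epsilon = 0`); if `FALSE` draws fresh latent noise per stimulus.
#' @param ... Unused.
#' @return Integer vector of category indices, or a matrix of channel errors.
#' @export
predict.brdiva <- function(object, newdata, type = c("class", "error"),
                           deterministic = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  eps0 <- if (deterministic) rep(0, object$n_hidden) else NULL
  errs <- t(apply(newdata, 1L, function(x) {
    brdiva_forward(object, x, epsilon = eps0)$channel_errors
  }))
  if (type == "error") return(errs)
  apply(errs, 1L, which.min)
}
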