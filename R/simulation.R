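#' Logarithmically spaced capacity grid
#'
#' `n` values equally spaced in log10 between `lo` and `hi` inclusive; the
#' default reproduces the standard 50-value grid from 0.01 to 100.
#'
#' @param n Number of grid points (>= 2).
#' @param lo,hi Positive endpoints, `lo < hi`.
#' @return Numeric vector of length `n` with first element exactly `lo` and
#'   last exactly `hi`.
#' @examples
#' beta_grid(3)  # 0.01 1 100
#' @export
beta_grid <- function(n = 50L, lo = 0.01, hi = 100) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    stop("need 0 < lo < hi", call. = FALSE)
  }
  g <- 10^seq(log10(lo), log10(hi), length.out = n)
  g[1L] <- lo
  g[n] <- hi
  g
}

#' Simulation configuration
#'
#' Bundles and validates the protocol parameters for [run_experiment()].
#' The defaults are the study conditions: 100 simulated participants, 20
#' blocks of all eight stimuli in random order, all six problem types, a
#' 50-value log-spaced capacity grid from 0.01 to 100 for BR-DIVA, and the
#' conventional hyperparameters (learning rate, sensitivity and attention
#' breadth all 1; weights initialised uniformly in plus/minus 0.5; two
#' hidden units).
#'
#' @param model `"DIVA"` or `"BRDIVA"`.
#' @param types Subset of 1:6.
#' @param n_participants Number of simulated participants per cell.
#' @param n_blocks Number of blocks per participant.
#' @param betas Capacity grid (BR-DIVA only; ignored for DIVA).
#' @param base_seed Integer master seed; every random quantity in the
#'   experiment derives from it.
#' @param learning_rate,sensitivity,attention_breadth,weight_range,n_hidden
#'   Model hyperparameters shared by both models.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("BRDIVA", "DIVA"), types = 1:6,
                       n_participants = 100L, n_blocks = 20L,
                       betas = beta_grid(), base_seed = 1L,
                       learning_rate = 1, sensitivity = 1,
                       attention_breadth = 1, weight_range = 0.5,
                       n_hidden = 2L) {
  model <- match.arg(toupper(model[1L]), c("BRDIVA", "DIVA"))
  if (!all(types %in% 1:6) || length(types) < 1L) {
    stop("`types` must be a nonempty subset of 1:6", call. = FALSE)
  }
  if (n_participants < 1L || n_blocks < 1L) {
    stop("`n_participants` and `n_blocks` must be >= 1", call. = FALSE)
  }
  if (model == "BRDIVA" && length(betas) < 1L) {
    stop("`betas` must be nonempty for BRDIVA", call. = FALSE)
  }
  structure(
    list(model = model, types = as.integer(sort(unique(types))),
         n_participants = as.integer(n_participants),
         n_blocks = as.integer(n_blocks),
         betas = if (model == "BRDIVA") as.numeric(betas) else numeric(0),
         base_seed = as.integer(base_seed),
         learning_rate = learning_rate, sensitivity = sensitivity,
         attention_breadth = attention_breadth, weight_range = weight_range,
         n_hidden = as.integer(n_hidden)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s, types %s, %d participants x %d blocks",
              x$model, paste(x$types, collapse = ","), x$n_participants, x$n_blocks))
  if (x$model == "BRDIVA") cat(sprintf(", %d betas in [%g, %g]",
                                       length(x$betas), min(x$betas), max(x$betas)))
  cat(sprintf(", base_seed %d\n", x$base_seed))
  invisible(x)
}

# Deterministic per-cell seed derivation. Two independent streams per
# participant: the trial-order stream depends only on (base_seed, type,
# participant), so DIVA and BR-DIVA -- and every beta -- see identical
# stimulus orders for matched participants (enabling paired comparisons);
# the init/noise stream additionally depends on model and beta index. The
# multipliers keep distinct design cells on distinct seeds for the design
# sizes in use (types <= 6, betas <= 99, participants <= 9999), and all
# seeds stay below 2^31 - 1.
#' Derive the two RNG seeds of one simulated participant
#'
#' @param base_seed Integer master seed.
#' @param model `"DIVA"` or `"BRDIVA"`.
#' @param type_id Problem type 1..6.
#' @param beta_index Position of beta on the grid (0 for DIVA).
#' @param participant Participant index (1-based).
#' @return A list with `order_seed` (stimulus-order stream) and `init_seed`
#'   (weight-initialisation and latent-noise stream).
#' @export
participant_seeds <- function(base_seed, model, type_id, beta_index, participant) {
  model_code <- match(toupper(model), c("DIVA", "BRDIVA"))
  if (is.na(model_code)) stop("unknown model", call. = FALSE)
  m <- 2147483647
  order_seed <- (abs(base_seed) + 1000003 * type_id + participant) %% m
  init_seed <- (abs(base_seed) + 500000 + 7000003 * model_code +
                  1000003 * type_id + 10007 * beta_index + participant) %% m
  list(order_seed = as.integer(order_seed), init_seed = as.integer(init_seed))
}

# Fast inner loop, DIVA. Identical arithmetic and RNG consumption to
# diva() + diva_forward() + classify() + diva_learn(), without S3 overhead.
.sim_diva_one <- function(assignment, n_blocks, order_seed, init_seed,
                          lr, sens, att, wr, n_hidden) {
  X <- shj_stimuli()
  dimnames(X) <- NULL
  set.seed(order_seed)
  orders <- vapply(seq_len(n_blocks), function(b) sample.int(8L), integer(8L))
  set.seed(init_seed)
  W_enc <- matrix(stats::runif(4L * n_hidden, -wr, wr), 4L, n_hidden)
  Wd1 <- matrix(stats::runif((n_hidden + 1L) * 3L, -wr, wr), n_hidden + 1L, 3L)
  Wd2 <- matrix(stats::runif((n_hidden + 1L) * 3L, -wr, wr), n_hidden + 1L, 3L)
  n <- n_blocks * 8L
  stim_v <- integer(n); resp_v <- integer(n); corr_v <- integer(n)
  hseq <- seq_len(n_hidden)
  k <- 0L
  for (b in seq_len(n_blocks)) {
    ord <- orders[, b]
    for (t in 1:8) {
      s <- ord[t]; x <- X[s, ]; xb <- c(x, 1)
      h <- stats::plogis(drop(xb %*% W_enc)); zb <- c(h, 1)
      r1 <- stats::plogis(drop(zb %*% Wd1)); r2 <- stats::plogis(drop(zb %*% Wd2))
      e1 <- sum(sens * att * (r1 - x)^2); e2 <- sum(sens * att * (r2 - x)^2)
      if (is.finite(e1) && is.finite(e2)) {
        resp <- if (e1 < e2) 1L else if (e2 < e1) 2L else sample.int(2L, 1L)
      } else if (is.finite(e1)) resp <- 1L
      else if (is.finite(e2)) resp <- 2L
      else resp <- sample.int(2L, 1L)
      k <- k + 1L
      tc <- assignment[s]
      stim_v[k] <- s; resp_v[k] <- resp; corr_v[k] <- as.integer(resp == tc)
      r <- if (tc == 1L) r1 else r2
      W <- if (tc == 1L) Wd1 else Wd2
      dpre <- 2 * sens * att * (r - x) * r * (1 - r)
      dh <- drop(W[hseq, , drop = FALSE] %*% dpre)
      if (tc == 1L) Wd1 <- Wd1 - lr * outer(zb, dpre) else Wd2 <- Wd2 - lr * outer(zb, dpre)
      W_enc <- W_enc - lr * outer(xb, dh * h * (1 - h))
    }
  }
  list(stimulus = stim_v, response = resp_v, correct = corr_v,
       W_enc = W_enc, W_dec = list(Wd1, Wd2))
}

# Fast inner loop, BR-DIVA. One epsilon draw per trial, shared by the
# response and the learning update. Matches brdiva_forward() + classify() +
# brdiva_learn() step for step.
.sim_brdiva_one <- function(assignment, beta, n_blocks, order_seed, init_seed,
                            lr, sens, att, wr, n_hidden) {
  X <- shj_stimuli()
  dimnames(X) <- NULL
  set.seed(order_seed)
  orders <- vapply(seq_len(n_blocks), function(b) sample.int(8L), integer(8L))
  set.seed(init_seed)
  W_mu <- matrix(stats::runif(4L * n_hidden, -wr, wr), 4L, n_hidden)
  W_lv <- matrix(stats::runif(4L * n_hidden, -wr, wr), 4L, n_hidden)
  Wd1 <- matrix(stats::runif((n_hidden + 1L) * 3L, -wr, wr), n_hidden + 1L, 3L)
  Wd2 <- matrix(stats::runif((n_hidden + 1L) * 3L, -wr, wr), n_hidden + 1L, 3L)
  n <- n_blocks * 8L
  stim_v <- integer(n); resp_v <- integer(n); corr_v <- integer(n)
  kl_v <- numeric(n)
  hseq <- seq_len(n_hidden)
  k <- 0L
  for (b in seq_len(n_blocks)) {
    ord <- orders[, b]
    for (t in 1:8) {
      s <- ord[t]; x <- X[s, ]; xb <- c(x, 1)
      mu <- drop(xb %*% W_mu); lv <- drop(xb %*% W_lv)
      sig <- exp(lv / 2)
      eps <- stats::rnorm(n_hidden)
      z <- mu + sig * eps; zb <- c(z, 1)
      r1 <- stats::plogis(drop(zb %*% Wd1)); r2 <- stats::plogis(drop(zb %*% Wd2))
      e1 <- sum(sens * att * (r1 - x)^2); e2 <- sum(sens * att * (r2 - x)^2)
      if (is.finite(e1) && is.finite(e2)) {
        resp <- if (e1 < e2) 1L else if (e2 < e1) 2L else sample.int(2L, 1L)
      } else if (is.finite(e1)) resp <- 1L
      else if (is.finite(e2)) resp <- 2L
      else resp <- sample.int(2L, 1L)
      k <- k + 1L
      tc <- assignment[s]
      stim_v[k] <- s; resp_v[k] <- resp; corr_v[k] <- as.integer(resp == tc)
      kl_v[k] <- 0.5 * sum(mu^2 + sig^2 - 1 - lv)
      r <- if (tc == 1L) r1 else r2
      W <- if (tc == 1L) Wd1 else Wd2
      dpre <- 2 * sens * att * (r - x) * r * (1 - r)
      dz <- drop(W[hseq, , drop = FALSE] %*% dpre)
      if (tc == 1L) Wd1 <- Wd1 - lr * outer(zb, dpre) else Wd2 <- Wd2 - lr * outer(zb, dpre)
      W_mu <- W_mu - lr * outer(xb, dz + beta * mu)
      W_lv <- W_lv - lr * outer(xb, dz * eps * sig / 2 + beta * (sig^2 - 1) / 2)
    }
  }
  list(stimulus = stim_v, response = resp_v, correct = corr_v, kl = kl_v,
       W_mu = W_mu, W_logvar = W_lv, W_dec = list(Wd1, Wd2))
}

#' Simulate one participant
#'
#' Runs a freshly initialised model through `n_blocks` blocks, each an
#' independent uniform random permutation of the eight stimuli. On every
#' trial the response is scored from the forward pass *before* the learning
#' update (supervised feedback follows the response), and for BR-DIVA the
#' single latent-noise draw of that forward pass is reused by the update.
#'
#' @param type_id Problem type 1..6.
#' @param model `"DIVA"` or `"BRDIVA"`.
#' @param beta Capacity weight (BR-DIVA only).
#' @param n_blocks Number of blocks (default 20).
#' @param order_seed Seed of the stimulus-order stream.
#' @param init_seed Seed of the weight-initialisation / latent-noise stream.
#' @param learning_rate,sensitivity,attention_breadth,weight_range,n_hidden
#'   Hyperparameters, defaulting to the study conditions.
#' @param return_state If `TRUE` the trained model is attached as attribute
#'   `"state"` (a `diva` or `brdiva` object).
#' @return A data.frame with one row per trial: `model`, `beta`, `type`,
#'   `block`, `trial`, `stimulus` (lexicographic index 1..8), `response`
#'   (1 = A, 2 = B) and `correct`.
#' @export
run_participant <- function(type_id, model = c("DIVA", "BRDIVA"), beta = NA_real_,
                            n_blocks = 20L, order_seed = 1L, init_seed = 2L,
                            learning_rate = 1, sensitivity = 1,
                            attention_breadth = 1, weight_range = 0.5,
                            n_hidden = 2L, return_state = FALSE) {
  model <- match.arg(toupper(model[1L]), c("DIVA", "BRDIVA"))
  problem <- shj_assignment(type_id)
  if (model == "BRDIVA") {
    if (is.na(beta) || beta < 0) stop("BRDIVA needs a nonnegative `beta`", call. = FALSE)
    res <- .sim_brdiva_one(problem$assignment, beta, n_blocks, order_seed, init_seed,
                           learning_rate, sensitivity, attention_breadth,
                           weight_range, n_hidden)
  } else {
    beta <- NA_real_
    res <- .sim_diva_one(problem$assignment, n_blocks, order_seed, init_seed,
                         learning_rate, sensitivity, attention_breadth,
                         weight_range, n_hidden)
  }
  n <- n_blocks * 8L
  out <- data.frame(
    model = rep(model, n), beta = rep(beta, n), type = rep(as.integer(type_id), n),
    block = rep(seq_len(n_blocks), each = 8L), trial = rep(1:8, n_blocks),
    stimulus = res$stimulus, response = res$response, correct = res$correct
  )
  if (return_state) {
    state <- if (model == "BRDIVA") {
      m <- br_diva(n_hidden = n_hidden, beta = beta, weight_range = weight_range,
                   learning_rate = learning_rate, sensitivity = sensitivity,
                   attention_breadth = attention_breadth)
      m$W_mu <- res$W_mu; m$W_logvar <- res$W_logvar; m$W_dec <- res$W_dec
      m
    } else {
      m <- diva(n_hidden = n_hidden, weight_range = weight_range,
                learning_rate = learning_rate, sensitivity = sensitivity,
                attention_breadth = attention_breadth)
      m$W_enc <- res$W_enc; m$W_dec <- res$W_dec
      m
    }
    attr(out, "state") <- state
  }
  out
}

#' Run a full simulated experiment
#'
#' Crosses participants x types (x the capacity grid for BR-DIVA) and
#' simulates every cell, deriving each participant's seeds from the config's
#' `base_seed` via [participant_seeds()]. Two runs with the same config are
#' bit-identical.
#'
#' @param config A [sim_config()] object.
#' @param verbose Print per-type progress.
#' @return A trial table of class `shj_trials` (a data.frame as in
#'   [run_participant()], plus a `participant` column).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  betas <- if (config$model == "BRDIVA") config$betas else NA_real_
  n_beta <- length(betas)
  per <- config$n_blocks * 8L
  n_cells <- length(config$types) * n_beta * config$n_participants
  N <- n_cells * per
  beta_col <- numeric(N); type_col <- integer(N); part_col <- integer(N)
  stim_col <- integer(N); resp_col <- integer(N); corr_col <- integer(N)
  pos <- 0L
  for (ty in config$types) {
    problem <- shj_assignment(ty)
    for (bi in seq_len(n_beta)) {
      beta <- betas[bi]
      for (p in seq_len(config$n_participants)) {
        seeds <- participant_seeds(config$base_seed, config$model, ty,
                                   if (config$model == "BRDIVA") bi else 0L, p)
        res <- if (config$model == "BRDIVA") {
          .sim_brdiva_one(problem$assignment, beta, config$n_blocks,
                          seeds$order_seed, seeds$init_seed,
                          config$learning_rate, config$sensitivity,
                          config$attention_breadth, config$weight_range,
                          config$n_hidden)
        } else {
          .sim_diva_one(problem$assignment, config$n_blocks,
                        seeds$order_seed, seeds$init_seed,
                        config$learning_rate, config$sensitivity,
                        config$attention_breadth, config$weight_range,
                        config$n_hidden)
        }
        idx <- pos + seq_len(per)
        beta_col[idx] <- beta; type_col[idx] <- ty; part_col[idx] <- p
        stim_col[idx] <- res$stimulus; resp_col[idx] <- res$response
        corr_col[idx] <- res$correct
        pos <- pos + per
      }
    }
    if (verbose) message(sprintf("[%s] type %d done (%d trials so far)",
                                 config$model, ty, pos))
  }
  out <- data.frame(
    model = rep(config$model, N), beta = beta_col, type = type_col,
    participant = part_col,
    block = rep(rep(seq_len(config$n_blocks), each = 8L), n_cells),
    trial = rep(1:8, n_cells * config$n_blocks),
    stimulus = stim_col, response = resp_col, correct = corr_col
  )
  class(out) <- c("shj_trials", "data.frame")
  attr(out, "config") <- config
  out
}

#' Convenience wrapper: configure and run in one call
#'
#' @param ... Passed to [sim_config()].
#' @param verbose Passed to [run_experiment()].
#' @return An `shj_trials` trial table.
#' @export
shj_experiment <- function(..., verbose = FALSE) {
  run_experiment(sim_config(...), verbose = verbose)
}

#' @export
summary.shj_trials <- function(object, ...) {
  agg <- aggregate_accuracy(object, by = c("model", "type"))
  cat(sprintf("Simulated trial table: %d trials\n", nrow(object)))
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
print.shj_trials <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("shj_trials: %d trials", nrow(x)))
  if (!is.null(cfg)) {
    cat(sprintf(" (%s, types %s, %d participants, %d blocks, base_seed %d)",
                cfg$model, paste(cfg$types, collapse = ","),
                cfg$n_participants, cfg$n_blocks, cfg$base_seed))
  }
  cat("\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
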