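# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Central finite-difference gradient of a scalar loss with respect to one
# weight matrix inside a model object.
fd_gradient <- function(model, field, loss_fn, h = 1e-6, channel = NULL) {
  W <- if (is.null(channel)) model[[field]] else model[[field]][[channel]]
  G <- W
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    up <- model; dn <- model
    if (is.null(channel)) {
      up[[field]][i, j] <- W[i, j] + h
      dn[[field]][i, j] <- W[i, j] - h
    } else {
      up[[field]][[channel]][i, j] <- W[i, j] + h
      dn[[field]][[channel]][i, j] <- W[i, j] - h
    }
    G[i, j] <- (loss_fn(up) - loss_fn(dn)) / (2 * h)
  }
  G
}

# DIVA loss (true channel's scaled squared reconstruction error), written
# from the definition without reusing diva_forward.
diva_loss_oracle <- function(model, x, k) {
  sig <- function(a) 1 / (1 + exp(-a))
  h <- sig(drop(c(x, 1) %*% model$W_enc))
  r <- sig(drop(c(h, 1) %*% model$W_dec[[k]]))
  sum(model$sensitivity * model$attention_breadth * (r - x)^2)
}

# BR-DIVA per-trial loss with frozen noise.
brdiva_loss_oracle <- function(model, x, k, eps) {
  sig <- function(a) 1 / (1 + exp(-a))
  xb <- c(x, 1)
  mu <- drop(xb %*% model$W_mu)
  lv <- drop(xb %*% model$W_logvar)
  s <- exp(lv / 2)
  z <- mu + s * eps
  r <- sig(drop(c(z, 1) %*% model$W_dec[[k]]))
  recon <- sum(model$sensitivity * model$attention_breadth * (r - x)^2)
  kl <- 0.5 * sum(mu^2 + s^2 - 1 - lv)
  recon + model$beta * kl
}

# Closed-form classical t statistics, written from the textbook formulas.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1,
       p.value = 2 * pt(-abs(t), n - 1))
}

two_sample_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2,
       p.value = 2 * pt(-abs(t), na + nb - 2))
}

# All 48 symmetries of the stimulus cube: dimension permutations x value
# flips. Returns, for an assignment (length-8 vector over the lexicographic
# stimulus order), the canonical (lexicographically minimal) form of its
# equivalence class, used to test structural distinctness by brute force.
canonical_class <- function(assignment) {
  stim <- as.matrix(expand.grid(f3 = 0:1, f2 = 0:1, f1 = 0:1))[, 3:1]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (pm in perms) for (fl in 0:7) {
    flips <- c(fl %/% 4, (fl %/% 2) %% 2, fl %% 2)
    # where each stimulus lands under the symmetry
    moved <- t(apply(stim, 1, function(x) abs(x[pm] - flips)))
    idx <- moved %*% c(4, 2, 1) + 1
    new_assign <- integer(8)
    new_assign[idx] <- assignment
    for (lab in list(new_assign, 3L - new_assign)) {  # category relabeling
      key <- paste(lab, collapse = "")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

# Small balanced trial table for analysis unit tests.
toy_trials <- function() {
  tr <- expand.grid(trial = 1:8, block = 1:2, participant = 1:2,
                    type = c(1L, 2L), stringsAsFactors = FALSE)
  tr$model <- "DIVA"
  tr$beta <- NA_real_
  tr$stimulus <- tr$trial
  tr$response <- 1L
  tr$correct <- as.integer(tr$stimulus <= 4)  # accuracy 0.5 in every cell
  class(tr) <- c("shj_trials", "data.frame")
  tr
}
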