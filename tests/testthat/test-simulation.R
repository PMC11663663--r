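test_that("beta grid is log-spaced with exact endpoints", {
  g <- beta_grid()
  expect_equal(length(g), 50L)
  expect_equal(g[1], 0.01)
  expect_equal(g[50], 100)
  expect_equal(beta_grid(3, 0.01, 100), c(0.01, 1, 100))
  ratios <- g[-1] / g[-length(g)]
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_error(beta_grid(1), ">= 2")
  expect_error(beta_grid(10, 1, 0.5), "lo < hi")
})

test_that("a participant runs blocks of complete random permutations", {
  tr <- run_participant(1, "DIVA", n_blocks = 20, order_seed = 5, init_seed = 6)
  expect_equal(nrow(tr), 160L)
  expect_equal(unique(tr$block), 1:20)
  for (b in 1:20) expect_setequal(tr$stimulus[tr$block == b], 1:8)
  expect_true(all(tr$correct %in% 0:1))
  # correctness is consistent with the canonical assignment
  p <- shj_assignment(1)
  expect_equal(tr$correct, as.integer(tr$response == p$assignment[tr$stimulus]))
  # identical seeds reproduce the identical record list
  tr2 <- run_participant(1, "DIVA", n_blocks = 20, order_seed = 5, init_seed = 6)
  expect_identical(tr, tr2)
  expect_error(run_participant(3, "BRDIVA", beta = NA), "beta")
})

test_that("the vectorised participant loop equals the step-by-step API", {
  # DIVA: same seeds, same RNG consumption -> bit-identical responses
  n_blocks <- 4L
  tr <- run_participant(4, "DIVA", n_blocks = n_blocks,
                        order_seed = 31, init_seed = 32, return_state = TRUE)
  p <- shj_assignment(4)
  stim <- shj_stimuli()
  set.seed(31)
  orders <- vapply(seq_len(n_blocks), function(b) sample.int(8L), integer(8L))
  m <- diva(seed = 32)
  resp <- integer(0)
  for (b in seq_len(n_blocks)) for (s in orders[, b]) {
    f <- diva_forward(m, stim[s, ])
    resp <- c(resp, classify(f$channel_errors))
    m <- diva_learn(m, stim[s, ], p$assignment[s])
  }
  expect_identical(tr$stimulus, as.integer(c(orders)))
  expect_identical(tr$response, resp)
  expect_equal(attr(tr, "state")$W_enc, m$W_enc)
  expect_equal(attr(tr, "state")$W_dec, m$W_dec)

  # BR-DIVA: one epsilon per trial, shared between response and update
  tr <- run_participant(5, "BRDIVA", beta = 0.1, n_blocks = n_blocks,
                        order_seed = 41, init_seed = 42, return_state = TRUE)
  p <- shj_assignment(5)
  set.seed(41)
  orders <- vapply(seq_len(n_blocks), function(b) sample.int(8L), integer(8L))
  m <- br_diva(beta = 0.1, seed = 42)
  resp <- integer(0)
  for (b in seq_len(n_blocks)) for (s in orders[, b]) {
    f <- brdiva_forward(m, stim[s, ])
    resp <- c(resp, classify(f$channel_errors))
    m <- brdiva_learn(m, stim[s, ], p$assignment[s], epsilon = f$latent$epsilon)
  }
  expect_identical(tr$response, resp)
  expect_equal(attr(tr, "state")$W_mu, m$W_mu)
  expect_equal(attr(tr, "state")$W_logvar, m$W_logvar)
  expect_equal(attr(tr, "state")$W_dec, m$W_dec)
})

test_that("seed derivation is deterministic and separates design cells", {
  s1 <- participant_seeds(1, "BRDIVA", 3, 10, 42)
  expect_identical(s1, participant_seeds(1, "BRDIVA", 3, 10, 42))
  # order seed ignores model and beta: matched stimulus orders across models
  expect_equal(participant_seeds(1, "DIVA", 3, 0, 42)$order_seed, s1$order_seed)
  expect_equal(participant_seeds(1, "BRDIVA", 3, 7, 42)$order_seed, s1$order_seed)
  # init seeds distinct across the full default design
  grid <- expand.grid(model = c("DIVA", "BRDIVA"), type = 1:6, beta = 0:50,
                      part = c(1, 50, 100))
  seeds <- mapply(function(m, t, b, p) {
    participant_seeds(1, as.character(m), t, if (m == "DIVA") 0 else b, p)$init_seed
  }, grid$model, grid$type, grid$beta, grid$part)
  keep <- !(grid$model == "DIVA" & grid$beta > 0)
  expect_equal(anyDuplicated(seeds[keep]), 0L)
  expect_true(all(seeds < 2^31))
})

test_that("matched participants see identical stimulus orders in both models", {
  sd <- participant_seeds(9, "DIVA", 2, 0, 3)
  sb <- participant_seeds(9, "BRDIVA", 2, 5, 3)
  td <- run_participant(2, "DIVA", n_blocks = 5,
                        order_seed = sd$order_seed, init_seed = sd$init_seed)
  tb <- run_participant(2, "BRDIVA", beta = 1, n_blocks = 5,
                        order_seed = sb$order_seed, init_seed = sb$init_seed)
  expect_identical(td$stimulus, tb$stimulus)
})

test_that("run_experiment produces the complete design cross, reproducibly", {
  cfg <- sim_config(model = "BRDIVA", types = c(1, 3), n_participants = 2,
                    n_blocks = 2, betas = c(0.01, 0.1), base_seed = 77)
  tr <- run_experiment(cfg)
  expect_s3_class(tr, "shj_trials")
  expect_equal(nrow(tr), 2 * 2 * 2 * 16)
  cross <- unique(tr[c("type", "beta", "participant")])
  expect_equal(nrow(cross), 8L)
  expect_true(all(tr$correct %in% 0:1))
  tr2 <- run_experiment(cfg)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))

  cfg_d <- sim_config(model = "DIVA", types = 1, n_participants = 2,
                      n_blocks = 2, base_seed = 77)
  tr_d <- run_experiment(cfg_d)
  expect_equal(nrow(tr_d), 2 * 16)
  expect_true(all(is.na(tr_d$beta)))
})

test_that("models improve from first to final block on learnable structures", {
  tr <- shj_experiment(model = "DIVA", types = 1:5, n_participants = 25,
                       base_seed = 5150)
  first <- aggregate_accuracy(tr[tr$block == 1, ], by = "type")$accuracy
  final <- aggregate_accuracy(tr[tr$block == 20, ], by = "type")$accuracy
  # clear learning on Types 1-4; Type 5 improves but retains exception errors
  expect_true(all(final[1:4] > first[1:4] + 0.15))
  expect_gt(final[5], first[5])
})

test_that("config validation and printing", {
  expect_error(sim_config(types = 7), "subset of 1:6")
  expect_error(sim_config(n_participants = 0), ">= 1")
  expect_error(sim_config(model = "BRDIVA", betas = numeric(0)), "nonempty")
  cfg <- sim_config(model = "DIVA", types = 2, n_participants = 1, n_blocks = 1)
  expect_output(print(cfg), "DIVA")
})
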