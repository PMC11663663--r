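#' Headline simulation statistics
#'
#' Computes, from trial tables of the two models, the quantities that
#' summarise the benchmark: the order-of-difficulty regression coefficients,
#' the best final-block Type 5 accuracy across the capacity grid, the block
#' at which baseline DIVA first exceeds a criterion accuracy on Type 5, the
#' Type 3-vs-5 coefficients of the rule-plus-exception regression, and the
#' block/model effects of the per-type block-by-model regressions.
#'
#' @param trials_br BR-DIVA trial table (types 1-6, beta grid).
#' @param trials_diva DIVA trial table (types 1-6).
#' @param criterion Accuracy level for the DIVA Type 5 criterion block
#'   (default 0.96).
#' @return A list of class `shj_headline` with named numeric entries:
#'   `type2_coef`, `type6_coef` (order-of-difficulty regression, reference
#'   Type 1), `type5_best_final_pct` (percent), `diva_type5_criterion_block`,
#'   `type3_vs5_coef`, `type3_block_interaction` (rule-plus-exception
#'   regression, reference Type 5), `block_slope_type5` and
#'   `model_effect_type6` (block x model regressions, reference DIVA), plus
#'   `fits` holding the three underlying `fit_summary` objects.
#' @export
shj_headline_stats <- function(trials_br, trials_diva, criterion = 0.96) {
  fit_diff <- fit_difficulty(trials_br)
  fit_exc <- fit_exception_types(trials_br)
  both5 <- rbind(as.data.frame(trials_br[trials_br$type == 5L, ]),
                 as.data.frame(trials_diva[trials_diva$type == 5L, ]))
  both6 <- rbind(as.data.frame(trials_br[trials_br$type == 6L, ]),
                 as.data.frame(trials_diva[trials_diva$type == 6L, ]))
  fit_bm5 <- fit_block_model(both5, 5L)
  fit_bm6 <- fit_block_model(both6, 6L)

  # best final-block Type 5 accuracy over the beta grid
  t5 <- trials_br[trials_br$type == 5L, , drop = FALSE]
  final5 <- t5[t5$block == max(t5$block), , drop = FALSE]
  per_beta <- aggregate_accuracy(final5, by = "beta")
  best_final <- max(per_beta$accuracy)

  # first block at which DIVA's mean Type 5 accuracy strictly exceeds criterion
  d5 <- trials_diva[trials_diva$type == 5L, , drop = FALSE]
  curve <- aggregate_accuracy(d5, by = "block")
  hit <- curve$block[curve$accuracy > criterion]
  crit_block <- if (length(hit)) min(hit) else NA_integer_

  structure(list(
    type2_coef = ols_coef(fit_diff, "type2"),
    type6_coef = ols_coef(fit_diff, "type6"),
    type5_best_final_pct = 100 * best_final,
    diva_type5_criterion_block = as.numeric(crit_block),
    type3_vs5_coef = ols_coef(fit_exc, "type3"),
    type3_block_interaction = ols_coef(fit_exc, "block:type3"),
    block_slope_type5 = ols_coef(fit_bm5, "block"),
    model_effect_type6 = ols_coef(fit_bm6, "modelBRDIVA"),
    fits = list(difficulty = fit_diff, exception_types = fit_exc,
                block_model_type5 = fit_bm5, block_model_type6 = fit_bm6)
  ), class = "shj_headline")
}

#' @export
print.shj_headline <- function(x, ...) {
  cat("Headline simulation statistics\n")
  nm <- setdiff(names(x), "fits")
  for (n in nm) cat(sprintf("  %-28s %.4f\n", n, x[[n]]))
  invisible(x)
}

# Reference values for the benchmark report: the published simulation
# results this protocol reproduces, with the comparison tolerance used by
# cmd_benchmark (absolute for coefficients, percentage points / blocks for
# the learning-curve quantities).
.reference_values <- list(
  type2_coef = list(value = -0.09, tol = 0.05),
  type6_coef = list(value = -0.40, tol = 0.05),
  type5_best_final_pct = list(value = 96, tol = 5),
  diva_type5_criterion_block = list(value = 13, tol = 3),
  type3_vs5_coef = list(value = 0.14, tol = 0.05),
  type3_block_interaction = list(value = -0.006, tol = 0.05),
  block_slope_type5 = list(value = 0.02, tol = 0.05),
  model_effect_type6 = list(value = 0.02, tol = 0.05)
)

#' Run the benchmark protocol and report against reference values
#'
#' Simulates both models at the requested scale, computes
#' [shj_headline_stats()] and compares each quantity with its stored
#' reference value and tolerance. The default scale is the full protocol
#' (100 participants, 20 blocks, 50 betas); pass smaller numbers for a
#' quick smoke run.
#'
#' @param base_seed Master seed.
#' @param n_participants,n_blocks,n_betas Protocol scale.
#' @param verbose Print progress.
#' @return A data.frame report (one row per quantity: computed value,
#'   reference, tolerance, pass) with the `shj_headline` object attached as
#'   attribute `"stats"` and run metadata as attribute `"meta"`.
#' @export
run_benchmark <- function(base_seed = 1L, n_participants = 100L,
                          n_blocks = 20L, n_betas = 50L, verbose = FALSE) {
  t0 <- Sys.time()
  trials_br <- shj_experiment(model = "BRDIVA", types = 1:6,
                              n_participants = n_participants,
                              n_blocks = n_blocks,
                              betas = beta_grid(n_betas),
                              base_seed = base_seed, verbose = verbose)
  trials_diva <- shj_experiment(model = "DIVA", types = 1:6,
                                n_participants = n_participants,
                                n_blocks = n_blocks,
                                base_seed = base_seed, verbose = verbose)
  stats <- shj_headline_stats(trials_br, trials_diva)
  nm <- names(.reference_values)
  report <- data.frame(
    quantity = nm,
    value = vapply(nm, function(n) unname(stats[[n]]), numeric(1)),
    reference = vapply(nm, function(n) .reference_values[[n]]$value, numeric(1)),
    tolerance = vapply(nm, function(n) .reference_values[[n]]$tol, numeric(1)),
    row.names = NULL
  )
  report$pass <- !is.na(report$value) &
    abs(report$value - report$reference) <= report$tolerance
  attr(report, "stats") <- stats
  attr(report, "meta") <- list(
    base_seed = base_seed, n_participants = n_participants,
    n_blocks = n_blocks, n_betas = n_betas,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("brdiva"))
  )
  report
}
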